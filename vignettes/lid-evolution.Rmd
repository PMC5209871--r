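---
title: "Reconstructing lid evolution in versatile lipases: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing lid evolution in versatile lipases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lidasr)
```

This vignette is the package's own account of its methods: the models it
fits, the parameters that matter and their defaults, what the synthetic
data generator does and does not emulate, and the places where the design
was genuinely open and a choice had to be made.

## The analysis in one paragraph

Candidate proteins are screened for the signatures of the *Candida
rugosa*-like (versatile) lipase family; the accepted set is aligned,
placed on a phylogeny under the WAG(+F) amino-acid model, and ancestral
sequences are reconstructed at every internal node by marginal
maximum-likelihood.  Because gaps are treated as missing data, ancestral
sequences are inferred across the *entire* lid alignment block — a block
widened by lineage-specific insertions — so every ancestral lid initially
has block length.  Trimming residues whose maximum posterior falls below
a threshold (0.65–0.90) recovers each ancestor's well-supported lid core,
and the trajectory of trimmed lid length and hydrophobicity across nodes
summarises how the lid changed through time.

## Substitution model

The model is WAG: symmetric exchangeabilities $S$ and frequencies $\pi$,
$Q_{ij} = S_{ij}\pi_j$ for $i \neq j$, rows summing to zero, scaled to
one expected substitution per site ($-\sum_i \pi_i Q_{ii} = 1$).  The
numerical WAG table ships with the package as a plain-text file
(`inst/extdata/wag.dat`) rather than being transcribed into code, so its
provenance and digits are auditable; `read_rate_table()` parses it.

Two frequency modes exist.  `"wag_default"` uses the frequencies
published with the matrix; `"empirical_plus_F"` (the pipeline default)
replaces them with the frequencies observed in the analysed alignment.
Observed frequencies are floored at $10^{-4}$ and renormalised so that an
alignment missing some residue cannot produce a singular model.  The same
model object is used for distance estimation, tree likelihood and
ancestral reconstruction; using different frequency handling per stage is
possible in principle but hard to justify, so the package deliberately
keeps one model throughout.

$P(t) = e^{Qt}$ is computed from the symmetric eigendecomposition of
$\Pi^{1/2} Q \Pi^{-1/2}$ — stable for reversible models — with negative
entries (eigen-roundoff at the $10^{-16}$ scale) clipped and rows
renormalised.  There is no among-site rate variation: the analysis this
package implements names only WAG(+F), and adding $\Gamma$ categories
would change every downstream posterior while validating against nothing.

## Alignment and screening

Pairwise alignment is global Needleman–Wunsch–Gotoh with BLOSUM62 and
affine penalties; a gap of length $L$ costs
$\mathrm{open} + L\cdot\mathrm{ext}$ with open = 10 and ext = 0.5
(conventional protein defaults, and the same cost convention as
`Biostrings::pairwiseAlignment`, which the tests use as an independent
score oracle).  Ties are broken deterministically: diagonal over gap-in-A
over gap-in-B.  Percent identity divides identical columns by the number
of columns containing at least one residue — a stated, testable
convention, since published identity figures rarely define one.

The multiple aligner is progressive: a UPGMA guide tree on identity
distances, then profile–profile alignment with mean-of-pairs scores.  It
is explicitly a convenience substitute for a dedicated aligner, adequate
at desk scale; every pipeline stage therefore also accepts a precomputed
aligned FASTA.

Screening applies four criteria, all always evaluated, reported in a
fixed order purely so the `reasons` column is stable: identity to the
annotated reference $\geq$ 0.30; a predicted signal peptide; both
conserved motifs (oxyanion region `GGG[FL]`, catalytic serine
`G[EQ]SAG`); and an aligned lid of at least 20 residues (shorter lids
cannot form the helix flap).  The sequence-length criterion familiar from
genome-mining pipelines has no defensible universal bound, so it is
available (`min_length`/`max_length`) but off by default.

The signal-peptide call is a transparent heuristic stand-in for a
dedicated predictor, which would be an external service: present iff the
sequence starts with M and some 8-residue window within the first 35
residues has mean Kyte–Doolittle hydropathy $\geq 1.6$ (the h-region).
For real data, externally computed calls can be injected per id via
`signal_flags`, which overrides the heuristic entirely.

## Phylogeny

Pairwise distances maximise $\sum_s \log \pi_{x_s} P_{x_s y_s}(t)$ over
$t \in [0, 20]$ (gap/`X` columns skipped).  The topology is Saitou–Nei
neighbor joining with the Studier–Keppler criterion, negative branch
estimates clamped to zero, and ties broken by the lexicographically
smallest pair of cluster representatives so results are reproducible.
NJ is exact on additive matrices (tested).  A full ML topology search is
out of scope: it is a large engineering effort orthogonal to the
reconstruction machinery, which accepts any user-supplied Newick tree.
Branch lengths are then re-optimised by coordinate-wise scalar ML on the
fixed topology, sweeping until the log-likelihood improves by less than
$10^{-6}$ or 50 sweeps.

Rooting places the root at the midpoint of the outgroup's pendant edge;
the pipeline's default outgroup is the most divergent sequence (largest
mean ML distance).  Under reversibility the root placement does not
affect marginal posteriors at other internal nodes (tested), so rooting
mainly fixes which node is "the deepest ancestor".

Bootstrap support resamples columns, rebuilds the NJ tree per replicate,
and counts bipartitions.  Branch lengths cannot change which
bipartitions a replicate contains, so per-replicate ML branch
re-optimisation is skipped — the support values are identical either way
and the replicates two orders of magnitude cheaper.

Internal nodes are numbered with tips 1..N in input order and internal
nodes N+1, N+2, ... from the root outward, depth-first — the convention
of the standard reconstruction software, under which the root of an
N-sequence analysis is node N+1.  Coordinates everywhere in the package
are 1-based inclusive, the R idiom.

## Ancestral reconstruction and lid trimming

Marginal posteriors are computed by one pruning (down) pass and one
up pass; at node $v$, $p_{v,s}(a) \propto F_v(a) L_v(a)$.  The MAP
residue per site is reported with its posterior; argmax ties break toward
the lowest index in the fixed alphabet order, a reproducibility choice.
The down/up pass runs unscaled — per-site partial products underflow only
on trees far deeper than this package targets — while the likelihood
itself uses per-site rescaling.

Gaps are missing data, *not* deleted columns.  This is the only reading
under which every ancestral lid spans the full alignment block, which is
precisely the artefact the trimming step exists to correct; the
alternative (deleting gapped columns before reconstruction) would remove
the hypervariable lid from the analysis altogether.

Trimming keeps residues with max posterior $\geq \theta$: "below the
threshold" is read strictly, so ties at $\theta$ survive (documented and
tested; extant lids, all posteriors 1, are unchanged for any
$\theta \leq 1$).  The default sweep is $\theta \in \{0.65, 0.70, 0.75,
0.80, 0.85, 0.90\}$, and the trajectory table always emits all six so
any of them can be compared downstream.

"Hydrophobic" is not self-defining; the package's default set is the
residues with positive Kyte–Doolittle hydropathy (I, V, L, F, C, M, A),
configurable and recorded in every output header.  Percentages are
truncated to one decimal, `floor(1000·count/n)/10`, not rounded —
truncation is the arithmetic consistent with how such figures are
conventionally reported in this literature (e.g. 23/36 printed as 63.8,
22/35 as 62.8); rounding is available via `truncate = FALSE`.

## Habitat statistics

Per-genome lipase counts are summarised per habitat as mean ± SEM
(sample SD/$\sqrt{n}$); the "±" is SEM, not SD — SEMs of the magnitudes
typically reported are consistent with group sizes of a handful to a few
dozen genomes with integer counts.  The two-group comparison defaults to
Welch's *t*-test (two-sided, unequal variances — a defensible default
for small unbalanced count groups), with a permutation test on the mean
difference (exact when enumerable, else seeded Monte Carlo) as the
assumption-free alternative.  The tests verify that Welch holds its
nominal type-I error on Poisson nulls and agrees with the permutation
test on small samples.

## The synthetic-data generator

`simulate_family()` is the test substrate for everything above.  A root
sequence is drawn from $\pi$ with planted blocks: an 18-residue signal
peptide (invariant initiator M, then a hydrophobic h-region), the two
family motifs, and a 30-residue lid.  Sites evolve along a Yule tree
(random joins, exponential branch lengths) under $P(t)$, with the lid at
3$\times$ the background rate and the signal/motif blocks at
0.1$\times$ (near-conserved).  Indels act *only* inside the lid: per
branch, each lid position starts a deletion with probability $p/2$ and
anchors an insertion with probability $p/2$ (total indel probability
$p = 0.05$ per position per branch), with geometric lengths of mean 2.
Confining indels to the lid isolates the phenomenon of interest — a
widened lid alignment block over variable extant lids — without a full
indel-process model, and keeps the rest of the alignment column-stable
so homology is known exactly.  The simulator emits that true alignment,
so reconstruction accuracy is measured free of aligner error; a
re-aligned variant is exercised separately through the progressive
aligner's tests.

Default conditions (chosen once, for realism at desk scale): 12 leaves,
300-residue root, and mean branch length 0.25.  The branch length is the
one number worth justifying: families assembled with a 30% identity
screening floor are deep, and at 0.25 expected substitutions/site per
branch the simulated families span pairwise identities from roughly 30%
to 90% with extant lid lengths spreading over ~15–45 residues —
hypervariable, like the families this analysis targets.  (The ASR
parameter-recovery experiments use 8 leaves, 200 columns and mean branch
lengths 0.05–1.0, stated with each experiment.)  Validation experiments
in the tests and the acceptance script use 20 replicate seeds per
condition; exhaustive-enumeration oracles run on all trees of 3–5 leaves
with 3–5 sites, where brute force over all internal state assignments is
feasible.

What the generator does **not** emulate: time-varying indel rates (real
lid expansion was likely insertion-biased toward the present), domain
rearrangements, alignment error in the "true alignment" route,
rate variation outside the three planted rate classes, and any 3D
structure.  Passing tests therefore demonstrate that the machinery is
correct and that the trimming mechanism behaves as designed under a
known process — not that any particular biological conclusion about real
genomes is reproduced.

`make_screening_fixture()` plants recoverable positives (mutated
homologs of an emitted reference, conserved signal and motif blocks) and
composition-matched shuffled decoys, rejection-sampled until each decoy
fails the identity, signal and both motif criteria; a decoy's "lid
length" against a non-homologous reference is alignment noise, so it is
not constrained.  Exact recovery of the planted set is then a designed
property, which the acceptance experiments confirm across seeds.

## Numerical and degenerate-input choices

* $t = 0$ branches give (numerically) the identity matrix; zero-variation
  alignments drive optimised branch lengths to 0.
* Sites with residues in no leaf fall back to the prior $\pi$ at every
  node.
* Posterior rows are normalised per site; row sums are tested to
  $10^{-9}$ and the enumeration oracle bounds total error at the same
  tolerance.
* NJ clamps negative branch estimates at 0; duplicate taxa form
  zero-length cherries.
* Empty screening inputs, missing references, trees without branch
  lengths, and negative branch lengths are errors naming the offending
  object; the pipeline wraps every stage so failures name the stage.

## Known limitations

No ML topology search, no rate heterogeneity, no joint (as opposed to
marginal) reconstruction, no indel-aware reconstruction (ancestral gaps
are handled by posterior trimming, not modelled), a heuristic signal
peptide call, and a progressive aligner that is serviceable rather than
state of the art.  Each of these is behind an interface that accepts
external results, so a stronger tool can replace any stage without
touching the rest.
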