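# Synthetic protein families with known trees, known ancestral sequences,
# a hypervariable indel-prone lid, planted motifs and signal peptides, and
# composition-matched decoys.  This module is the ground-truth substrate
# for validating screening, phylogeny, ancestral reconstruction and lid
# trimming: homology is known exactly (the simulator emits the true
# alignment), so downstream accuracy measurements are not confounded by
# aligner error.
#
# Model of the data: a root sequence drawn from the model's equilibrium
# frequencies, with a signal-peptide block, two conserved motifs and a lid
# interval planted; sites evolve along the tree under P(t) with the lid at
# an elevated rate (hypervariable) and the motif/signal blocks at a
# reduced rate (near-conserved); insertions and deletions occur only
# within the lid, so extant lid lengths vary while the rest of the
# alignment stays column-stable.

.M_IDX <- 13L  # "M" in AA_ALPHABET

#' Simulate a tree
#'
#' `"yule"` draws a random-join (Yule) topology with independent
#' exponential branch lengths of the stated mean and a trifurcating root
#' (the unrooted representation: 2N-2 nodes for N leaves);
#' `"fixed_newick"` parses the supplied string.
#'
#' @param n_leaves Number of leaves (>= 3).
#' @param mode `"yule"` or `"fixed_newick"`.
#' @param mean_branch Mean branch length (expected substitutions/site).
#' @param newick Newick string for `"fixed_newick"`.
#' @param seed Optional RNG seed.
#' @return ape `phylo` with internal labels from [set_node_labels()].
#' @export
simulate_tree <- function(n_leaves, mode = c("yule", "fixed_newick"),
                          mean_branch = 0.1, newick = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (mode == "fixed_newick") {
    if (is.null(newick)) stop("fixed_newick mode requires a newick string")
    return(read_newick(text = newick))
  }
  if (n_leaves < 3) stop("need at least 3 leaves")
  fmt <- function(x) sprintf("%.12g", x)
  nwk <- sprintf("t%02d", seq_len(n_leaves))
  while (length(nwk) > 3L) {
    pick <- sample.int(length(nwk), 2L)
    bl <- rexp(2, rate = 1 / mean_branch)
    merged <- sprintf("(%s:%s,%s:%s)", nwk[pick[1]], fmt(bl[1]),
                      nwk[pick[2]], fmt(bl[2]))
    nwk <- c(nwk[-pick], merged)
  }
  bl <- rexp(3, rate = 1 / mean_branch)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[1], fmt(bl[1]),
                 nwk[2], fmt(bl[2]), nwk[3], fmt(bl[3]))
  set_node_labels(ape::read.tree(text = txt))
}

#' Simulation configuration
#'
#' Defaults describe a desk-scale versatile-lipase-like family: 12 leaves,
#' 300-residue root with an 18-residue signal peptide, the two conserved
#' motifs outside the lid, a 30-residue lid evolving at 3x the background
#' rate with indels, and branch lengths of mean 0.25 (the divergence regime of a family screened at a 30% identity floor).
#'
#' @param n_leaves Number of leaves.
#' @param tree_mode `"yule"` or `"fixed_newick"`.
#' @param newick Newick string when `tree_mode = "fixed_newick"`.
#' @param mean_branch Mean branch length.
#' @param root_length Root sequence length (residues).
#' @param lid_start,lid_end Lid interval on the root (1-based inclusive).
#' @param lid_rate_mult Rate multiplier for lid sites.
#' @param lid_indel_prob Indel probability per branch per lid position
#'   (split evenly between deletion and insertion events).
#' @param indel_mean_len Mean geometric indel length.
#' @param signal_length Signal-peptide block length (first residue M, then
#'   a hydrophobic h-region).
#' @param oxyanion_pos,catalytic_pos 1-based start positions of the planted
#'   GGGF / GESAG motifs.
#' @param motif_rate_mult Rate multiplier for motif and signal blocks
#'   (near-conserved).
#' @param model An `aa_subst_model` (default: WAG with its published
#'   frequencies).
#' @param seed RNG seed; every simulation output is a pure function of
#'   (config, seed).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_leaves = 12, tree_mode = "yule", newick = NULL,
                       mean_branch = 0.25, root_length = 300,
                       lid_start = 180, lid_end = 209,
                       lid_rate_mult = 3.0, lid_indel_prob = 0.05,
                       indel_mean_len = 2, signal_length = 18,
                       oxyanion_pos = 60, catalytic_pos = 100,
                       motif_rate_mult = 0.1, model = NULL, seed = NULL) {
  stopifnot(n_leaves >= 3, root_length > 0, mean_branch >= 0,
            lid_rate_mult >= 0, lid_indel_prob >= 0, indel_mean_len >= 1,
            motif_rate_mult >= 0)
  if (lid_start < 1 || lid_end > root_length || lid_start > lid_end)
    stop("lid interval must lie within the root sequence")
  blocks <- list(signal = c(1, signal_length),
                 oxyanion = c(oxyanion_pos, oxyanion_pos + 3),
                 catalytic = c(catalytic_pos, catalytic_pos + 4))
  for (b in names(blocks)) {
    iv <- blocks[[b]]
    if (iv[1] < 1 || iv[2] > root_length)
      stop(sprintf("%s block outside the root sequence", b))
    if (iv[1] <= lid_end && iv[2] >= lid_start)
      stop(sprintf("%s block overlaps the lid interval", b))
  }
  if (is.null(model)) model <- build_wag_model()
  structure(list(n_leaves = n_leaves, tree_mode = tree_mode,
                 newick = newick, mean_branch = mean_branch,
                 root_length = root_length, lid_start = lid_start,
                 lid_end = lid_end, lid_rate_mult = lid_rate_mult,
                 lid_indel_prob = lid_indel_prob,
                 indel_mean_len = indel_mean_len,
                 signal_length = signal_length,
                 oxyanion_pos = oxyanion_pos,
                 catalytic_pos = catalytic_pos,
                 motif_rate_mult = motif_rate_mult,
                 model = model, seed = seed),
            class = "sim_config")
}

# Root sequence (integer indices) with planted blocks, plus per-column
# rate multipliers and lid membership.
.sim_root <- function(cfg) {
  L <- cfg$root_length
  pi <- cfg$model$pi
  aa <- sample.int(20, L, replace = TRUE, prob = pi)
  hyd <- match(c("L", "V", "I", "F", "A"), AA_ALPHABET)
  aa[1] <- .M_IDX
  if (cfg$signal_length >= 2)
    aa[2:cfg$signal_length] <- sample(hyd, cfg$signal_length - 1L,
                                      replace = TRUE,
                                      prob = c(0.35, 0.25, 0.2, 0.1, 0.1))
  aa[cfg$oxyanion_pos:(cfg$oxyanion_pos + 3)] <-
    match(c("G", "G", "G", "F"), AA_ALPHABET)
  aa[cfg$catalytic_pos:(cfg$catalytic_pos + 4)] <-
    match(c("G", "E", "S", "A", "G"), AA_ALPHABET)
  mult <- rep(1, L)
  mult[cfg$lid_start:cfg$lid_end] <- cfg$lid_rate_mult
  mult[1:cfg$signal_length] <- cfg$motif_rate_mult
  mult[1] <- 0   # initiator methionine is invariant
  mult[cfg$oxyanion_pos:(cfg$oxyanion_pos + 3)] <- cfg$motif_rate_mult
  mult[cfg$catalytic_pos:(cfg$catalytic_pos + 4)] <- cfg$motif_rate_mult
  is_lid <- rep(FALSE, L)
  is_lid[cfg$lid_start:cfg$lid_end] <- TRUE
  list(aa = aa, mult = mult, is_lid = is_lid)
}

# Substitute states along one branch; `mult` gives each site's rate
# multiplier.
.sim_substitute <- function(aa, mult, t, model) {
  if (t <= 0) return(aa)
  for (m in unique(mult)) {
    if (t * m <= 0) next
    P <- transition_matrix(model, t * m)
    sel <- which(mult == m)
    groups <- split(sel, aa[sel])
    for (s in names(groups)) {
      pos <- groups[[s]]
      aa[pos] <- sample.int(20, length(pos), replace = TRUE,
                            prob = P[as.integer(s), ])
    }
  }
  aa
}

#' Simulate a protein family with known ancestors
#'
#' Evolves a planted root sequence along a (simulated or supplied) tree
#' under the configured substitution model, with lid-restricted indels,
#' and records the full ground truth: the tree, every ancestral sequence,
#' the true alignment (homology known by construction) and the true lid
#' columns.
#'
#' @param config A [sim_config()].
#' @return Object of class `synthetic_family` with fields `tree` (labelled
#'   ape `phylo`), `extant` (list of [protein_record()] with `signal` and
#'   `lid` features), `true_alignment` ([protein_msa()] of the extant
#'   rows), `true_ancestors` (named ungapped sequences, one per internal
#'   node label), `ancestor_alignment` (gapped ancestor rows),
#'   `true_lid_columns` (alignment column indices) and `config`.
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  tree <- if (cfg$tree_mode == "fixed_newick")
    simulate_tree(cfg$n_leaves, "fixed_newick", newick = cfg$newick)
  else simulate_tree(cfg$n_leaves, "yule", mean_branch = cfg$mean_branch)
  nt <- length(tree$tip.label)

  root <- .sim_root(cfg)
  L <- cfg$root_length
  col_mult <- root$mult          # indexed by column id
  col_lid <- root$is_lid
  global_order <- seq_len(L)
  next_id <- L + 1L
  gp <- 1 / cfg$indel_mean_len
  p_half <- cfg$lid_indel_prob / 2

  node_state <- vector("list", nt + tree$Nnode)
  rt <- .root_node(tree)
  node_state[[rt]] <- list(ids = seq_len(L), aa = root$aa)

  cw <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(cw$edge))) {
    v <- cw$edge[k, 1]; ch <- cw$edge[k, 2]; t <- cw$edge.length[k]
    st <- node_state[[v]]
    ids <- st$ids
    aa <- .sim_substitute(st$aa, col_mult[ids], t, cfg$model)
    if (p_half > 0) {
      lp <- which(col_lid[ids])
      if (length(lp)) {
        # deletions: geometric runs of consecutive lid positions
        del <- logical(length(ids))
        starts <- which(runif(length(lp)) < p_half)
        for (k0 in starts) {
          len <- rgeom(1, gp) + 1L
          del[lp[k0:min(k0 + len - 1L, length(lp))]] <- TRUE
        }
        # insertions: anchored on surviving lid positions, applied
        # right-to-left so earlier anchors stay valid
        anchors <- lp[runif(length(lp)) < p_half]
        anchors <- anchors[!del[anchors]]
        for (anc in rev(anchors)) {
          len <- rgeom(1, gp) + 1L
          new_ids <- seq(next_id, length.out = len)
          next_id <- next_id + len
          col_mult[new_ids] <- cfg$lid_rate_mult
          col_lid[new_ids] <- TRUE
          new_aa <- sample.int(20, len, replace = TRUE, prob = cfg$model$pi)
          pos_g <- match(ids[anc], global_order)
          global_order <- append(global_order, new_ids, after = pos_g)
          ids <- append(ids, new_ids, after = anc)
          aa <- append(aa, new_aa, after = anc)
          del <- append(del, rep(FALSE, len), after = anc)
        }
        ids <- ids[!del]; aa <- aa[!del]
      }
    }
    node_state[[ch]] <- list(ids = ids, aa = aa)
  }

  C <- length(global_order)
  row_of <- function(st) {
    row <- rep("-", C)
    row[match(st$ids, global_order)] <- AA_ALPHABET[st$aa]
    paste(row, collapse = "")
  }
  tip_records <- lapply(seq_len(nt), function(i) {
    st <- node_state[[i]]
    feats <- list(signal = c(1L, cfg$signal_length))
    lid_pos <- which(col_lid[st$ids])
    if (length(lid_pos)) feats$lid <- c(min(lid_pos), max(lid_pos))
    protein_record(tree$tip.label[i],
                   paste(AA_ALPHABET[st$aa], collapse = ""),
                   features = feats)
  })
  aligned_tips <- lapply(seq_len(nt), function(i) {
    r <- tip_records[[i]]
    protein_record(r$id, row_of(node_state[[i]]), features = r$features)
  })
  imap <- .internal_map(tree)
  anc_ungapped <- vapply(names(imap), function(lab)
    paste(AA_ALPHABET[node_state[[imap[[lab]]]]$aa], collapse = ""), "")
  anc_aligned <- lapply(names(imap), function(lab)
    protein_record(lab, row_of(node_state[[imap[[lab]]]])))

  structure(list(tree = tree,
                 extant = setNames(tip_records, tree$tip.label),
                 true_alignment = protein_msa(aligned_tips),
                 true_ancestors = anc_ungapped,
                 ancestor_alignment = protein_msa(anc_aligned),
                 true_lid_columns = which(col_lid[global_order]),
                 root_label = names(imap)[imap == rt],
                 config = cfg),
            class = "synthetic_family")
}

#' @export
print.synthetic_family <- function(x, ...) {
  cat(sprintf(
    "<synthetic_family> %d extant x %d columns, %d ancestors, lid block %d cols\n",
    length(x$extant), x$true_alignment$n_columns,
    length(x$true_ancestors), length(x$true_lid_columns)))
  invisible(x)
}

#' Screening fixture with planted positives and decoys
#'
#' Generates a reference lipase (signal block, both motifs, annotated
#' lid), `n_true` mutated homologs that retain all four screened
#' properties, and `n_decoys` composition-matched shuffles of those
#' homologs, rejection-sampled so each decoy lacks both motifs, fails the
#' signal-peptide heuristic and falls below the identity threshold.
#'
#' @param n_true,n_decoys Numbers of planted positives and decoys (>= 0).
#' @param seed Optional RNG seed.
#' @param ref_length Reference length (residues).
#' @param mut_rate Per-site substitution probability for the homologs
#'   (outside the conserved signal/motif blocks).
#' @param model An `aa_subst_model` supplying background frequencies.
#' @return List with `records` (positives then decoys), `reference`
#'   (a [protein_record()] with `signal` and `lid` features), and `labels`
#'   (data frame of id and `planted` flag).
#' @export
make_screening_fixture <- function(n_true = 5, n_decoys = 5, seed = NULL,
                                   ref_length = 260, mut_rate = 0.3,
                                   model = NULL) {
  stopifnot(n_true >= 0, n_decoys >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(model)) model <- build_wag_model()
  pi <- model$pi
  cfg <- sim_config(root_length = ref_length, lid_start = 150, lid_end = 179,
                    model = model)
  root <- .sim_root(cfg)
  ref_seq <- paste(AA_ALPHABET[root$aa], collapse = "")
  reference <- protein_record("REF", ref_seq,
                              features = list(signal = c(1L, cfg$signal_length),
                                              lid = c(150L, 179L)))
  conserved <- logical(ref_length)
  conserved[1:cfg$signal_length] <- TRUE
  conserved[cfg$oxyanion_pos:(cfg$oxyanion_pos + 3)] <- TRUE
  conserved[cfg$catalytic_pos:(cfg$catalytic_pos + 4)] <- TRUE

  make_true <- function(i) {
    aa <- root$aa
    mut <- which(!conserved & runif(ref_length) < mut_rate)
    aa[mut] <- sample.int(20, length(mut), replace = TRUE, prob = pi)
    protein_record(sprintf("TRUE%02d", i),
                   paste(AA_ALPHABET[aa], collapse = ""))
  }
  trues <- lapply(seq_len(n_true), make_true)

  make_decoy <- function(i) {
    src <- if (n_true > 0) trues[[(i - 1L) %% n_true + 1L]]$sequence
           else ref_seq
    ch <- .chars(src)
    for (try in seq_len(200)) {
      perm <- paste(sample(ch), collapse = "")
      mh <- find_motifs(perm)
      if (nrow(mh$oxyanion) || nrow(mh$catalytic)) next
      if (predict_signal_peptide(perm)$present) next
      if (global_align(perm, reference)$identity >= 0.30) next
      return(protein_record(sprintf("DECOY%02d", i), perm))
    }
    stop("could not generate a decoy lacking all screened properties")
  }
  decoys <- lapply(seq_len(n_decoys), make_decoy)

  records <- .record_list(c(trues, decoys))
  list(records = records, reference = reference,
       labels = data.frame(id = names(records),
                           planted = rep(c(TRUE, FALSE),
                                         c(n_true, n_decoys))))
}
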