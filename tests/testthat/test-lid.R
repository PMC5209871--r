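test_that("lid columns form the contiguous reference block", {
  # ungapped reference: columns equal the lid interval itself
  msa <- msa_from_strings(c(ref = "AAAAIVLFIVAAAA", oth = "AAAA------AAAA"))
  msa$records$ref$features$lid <- c(5L, 10L)
  expect_equal(lid_columns(msa, "ref"), 5:10)
  # insertion columns inside the lid are included in the block
  msa2 <- msa_from_strings(c(ref = "AAAAIVL--FIVAAAA", oth = "AAAAIVLWWFIVAAAA"))
  msa2$records$ref$features$lid <- c(5L, 10L)
  expect_equal(lid_columns(msa2, "ref"), 5:12)
  expect_gte(length(lid_columns(msa2, "ref")), 6)
  expect_error(lid_columns(msa, "nope"), "not found")
  # simulated family: block equals the true lid columns when the reference
  # row is a leaf of the true alignment
  fam <- simulate_family(small_cfg(n_leaves = 6, root_length = 120,
                                   lid_start = 60, lid_end = 89, seed = 71))
  ids <- names(fam$extant)
  withlid <- ids[vapply(ids, function(i)
    !is.null(fam$extant[[i]]$features$lid), TRUE)]
  got <- lid_columns(fam$true_alignment, withlid[1])
  expect_true(all(fam$true_lid_columns >= min(got) - 0 &
                  got %in% fam$true_lid_columns))
})

test_that("posterior trimming keeps ties, is monotone and idempotent", {
  lr <- lid_region("n", "IVL", 1:3, c(0.9, 0.6, 0.95))
  tr <- trim_by_posterior(lr, 0.85)
  expect_equal(tr$residues, "IL")
  expect_equal(tr$columns, c(1L, 3L))
  # ties at the threshold are kept (strictly-below rule)
  tie <- trim_by_posterior(lid_region("n", "AW", 1:2, c(0.85, 0.8499)), 0.85)
  expect_equal(tie$residues, "A")
  # extant lids are unchanged for any threshold
  ext <- lid_region("e", "IVLF", 1:4, rep(1, 4))
  for (th in c(0.65, 0.9, 1))
    expect_equal(trim_by_posterior(ext, th)$residues, "IVLF")
  # monotone in the threshold over random posteriors, and idempotent
  set.seed(72)
  for (rep in 1:10) {
    n <- 30
    lr <- lid_region("n", strrep("A", n), 1:n, runif(n))
    lens <- vapply(c(0.65, 0.70, 0.75, 0.80, 0.85, 0.90), function(th)
      nchar(trim_by_posterior(lr, th)$residues), 0)
    expect_true(all(diff(lens) <= 0))
    t1 <- trim_by_posterior(lr, 0.8)
    expect_equal(trim_by_posterior(t1, 0.8), t1)
  }
  expect_error(trim_by_posterior(lr, 0), "0, 1")
})

test_that("hydrophobic fraction counts and truncates like the reported values", {
  expect_equal(hydrophobic_fraction("IVLF"), c(count = 4, percent = 100.0))
  expect_equal(hydrophobic_fraction("GSGS"), c(count = 0, percent = 0.0))
  # 5 of 12 -> 41.666... truncated to 41.6 (not rounded to 41.7)
  expect_equal(hydrophobic_fraction("IVLFM" %+% strrep("G", 7)),
               c(count = 5, percent = 41.6))
  # 22 of 35 -> 62.857... truncated to 62.8; 23 of 36 -> 63.888... -> 63.8
  expect_equal(hydrophobic_fraction(strrep("I", 22) %+% strrep("S", 13)),
               c(count = 22, percent = 62.8))
  expect_equal(hydrophobic_fraction(strrep("I", 23) %+% strrep("S", 13)),
               c(count = 23, percent = 63.8))
  # rounding is available as an option
  expect_equal(hydrophobic_fraction("IVLFM" %+% strrep("G", 7),
                                    truncate = FALSE)[["percent"]], 41.7)
  # invariant under residue permutation
  set.seed(73)
  s <- random_protein(40)
  p <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(hydrophobic_fraction(s), hydrophobic_fraction(p))
  expect_error(hydrophobic_fraction(""), "non-empty")
})

test_that("the trajectory table sweeps nodes x thresholds with motif checks", {
  set.seed(74)
  fam <- simulate_family(sim_config(n_leaves = 8, seed = 74))
  fit <- reconstruct_ancestors(fam$tree, fam$true_alignment, WAG)
  cols <- fam$true_lid_columns
  tj <- lid_trajectory(fit, cols)
  expect_s3_class(tj, "lid_trajectory")
  expect_equal(nrow(tj), length(fit$node_labels) * 6)
  expect_true(all(tj$hydrophobic_count <= tj$lid_length))
  expect_true(!is.unsorted(tj$node[tj$node == tj$node[1]]))
  # the motif columns report exactly what the MAP sequences contain, and
  # the near-conserved planted motifs survive into most ancestors
  for (nd in unique(tj$node)) {
    mh <- find_motifs(fit$map[[nd]])
    expect_equal(unique(tj$oxyanion_present[tj$node == nd]),
                 nrow(mh$oxyanion) > 0)
    expect_equal(unique(tj$catalytic_present[tj$node == nd]),
                 nrow(mh$catalytic) > 0)
  }
  expect_gte(mean(tj$oxyanion_present), 0.5)
  expect_gte(mean(tj$catalytic_present), 0.5)
  # a node whose lid posteriors all clear 0.9 keeps one length throughout
  hi <- lid_region("n", strrep("A", 10), 1:10, seq(0.91, 0.99, length.out = 10))
  lens <- vapply(c(0.65, 0.70, 0.75, 0.80, 0.85, 0.90), function(th)
    nchar(trim_by_posterior(hi, th)$residues), 0)
  expect_true(all(lens == 10))
  # TSV round trip with the hydrophobic-set header
  p <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(tj, p)
  expect_match(readLines(p, n = 1), "hydrophobic set")
  back <- read.delim(p, comment.char = "#")
  expect_equal(nrow(back), nrow(tj))
})

test_that("older nodes have shorter high-threshold lids when lid indels act", {
  # the mechanism behind the shortened ancestral lids: depth below the
  # root correlates positively with trimmed lid length across nodes
  rhos <- vapply(1:20, function(s) {
    fam <- simulate_family(sim_config(seed = 700 + s))
    fit <- reconstruct_ancestors(fam$tree, fam$true_alignment, WAG)
    cols <- fam$true_lid_columns
    nt <- length(fam$tree$tip.label)
    depth <- ape::node.depth.edgelength(fam$tree)[nt + seq_len(fam$tree$Nnode)]
    lens <- vapply(fit$node_labels, function(nd)
      nchar(trim_by_posterior(ancestral_lid(fit, nd, cols), 0.85)$residues), 0)
    imap <- setNames(seq(nt + 1L, nt + fam$tree$Nnode), fam$tree$node.label)
    suppressWarnings(cor(depth[imap[fit$node_labels] - nt], lens,
                         method = "spearman"))
  }, 0)
  # rho >= 0: nodes further from the root keep longer trimmed lids
  expect_gte(median(rhos, na.rm = TRUE), 0)
  # and the root lid is shorter at 0.90 than at 0.65 (low-confidence
  # columns accumulate at the deepest node)
  fam <- simulate_family(sim_config(seed = 75))
  fit <- reconstruct_ancestors(fam$tree, fam$true_alignment, WAG)
  al <- ancestral_lid(fit, fam$root_label, fam$true_lid_columns)
  expect_lt(nchar(trim_by_posterior(al, 0.90)$residues),
            nchar(trim_by_posterior(al, 0.65)$residues))
})
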