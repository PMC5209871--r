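test_that("ML pairwise distance: boundary, grid dominance and simulation recovery", {
  s <- random_protein(200)
  expect_lt(ml_pairwise_distance(s, s, WAG), 1e-6)
  expect_error(ml_pairwise_distance("--X", "A--", WAG), "no comparable")

  # likelihood at the optimum dominates a fine grid
  set.seed(51)
  a <- random_protein(100)
  P <- transition_matrix(WAG, 0.7)
  ia <- match(strsplit(a, "")[[1]], AA_ALPHABET)
  b <- paste(AA_ALPHABET[vapply(ia, function(i)
    sample.int(20, 1, prob = P[i, ]), 0L)], collapse = "")
  that <- ml_pairwise_distance(a, b, WAG)
  ll <- function(t) {
    Pt <- transition_matrix(WAG, t)
    ib <- match(strsplit(b, "")[[1]], AA_ALPHABET)
    sum(log(WAG$pi[ia] * Pt[cbind(ia, ib)]))
  }
  grid <- seq(1e-6, 20, length.out = 1000)
  expect_gte(ll(that) + 1e-9, max(vapply(grid, ll, 0)))

  # recovery within 10% (median of 20 replicates per true distance)
  for (t_true in c(0.1, 0.5, 1.0)) {
    est <- vapply(1:20, function(r) {
      set.seed(1000 * t_true + r)
      x <- random_protein(1000)
      ix <- match(strsplit(x, "")[[1]], AA_ALPHABET)
      Pt <- transition_matrix(WAG, t_true)
      y <- paste(AA_ALPHABET[vapply(ix, function(i)
        sample.int(20, 1, prob = Pt[i, ]), 0L)], collapse = "")
      ml_pairwise_distance(x, y, WAG)
    }, 0)
    expect_lt(abs(median(est) - t_true) / t_true, 0.10,
              label = sprintf("median recovery at t = %g", t_true))
  }
})

test_that("neighbor joining recovers three-taxon and four-taxon trees exactly", {
  D <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  got <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_equal(got, D, tolerance = 1e-10)

  # additive case from the tree ((A:1,B:2):1,(C:3,D:4)): the six pairwise
  # path distances determine the topology AB|CD and all branch lengths
  t0 <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):1);")
  D4 <- ape::cophenetic.phylo(t0)
  tr4 <- neighbor_joining(D4)
  expect_equal(ape::dist.topo(ape::unroot(t0), ape::unroot(tr4)),
               structure(0, names = "PH85"), ignore_attr = TRUE)
  expect_equal(ape::cophenetic.phylo(tr4)[rownames(D4), colnames(D4)], D4,
               tolerance = 1e-10)

  # identical taxa form a zero-length cherry
  D0 <- matrix(c(0, 0, 4, 4,
                 0, 0, 4, 4,
                 4, 4, 0, 2,
                 4, 4, 2, 0), 4,
               dimnames = list(letters[1:4], letters[1:4]))
  tr0 <- neighbor_joining(D0)
  co <- ape::cophenetic.phylo(tr0)
  expect_equal(co["a", "b"], 0, tolerance = 1e-12)
  expect_error(neighbor_joining(D[1:2, 1:2]), ">= 3 taxa")
})

test_that("neighbor joining is exact on random additive matrices", {
  set.seed(52)
  for (rep in 1:20) {
    case <- random_additive_case(sample(5:8, 1))
    tr <- neighbor_joining(case$D)
    expect_equal(ape::dist.topo(ape::unroot(case$tree), ape::unroot(tr)),
                 structure(0, names = "PH85"), ignore_attr = TRUE)
    got <- ape::cophenetic.phylo(tr)[rownames(case$D), colnames(case$D)]
    expect_lt(max(abs(got - case$D)), 1e-8)
  }
})

test_that("pruning likelihood matches simple closed forms and the exhaustive oracle", {
  # one site, two leaves, zero branch lengths: logL = log pi_A
  tr <- read_newick(text = "(x:0,y:0);")
  msa <- msa_from_strings(c(x = "A", y = "A"))
  expect_equal(log_likelihood(tr, msa, WAG), log(WAG$pi[["A"]]),
               tolerance = 1e-9)

  set.seed(53)
  for (rep in 1:6) {
    n <- sample(3:5, 1)
    tr <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
    tr$tip.label <- paste0("t", seq_len(n))
    strs <- setNames(vapply(seq_len(n), function(i) random_protein(3), ""),
                     tr$tip.label)
    # sprinkle missing data
    substr(strs[1], 2, 2) <- "-"
    msa <- msa_from_strings(strs)
    expect_equal(log_likelihood(tr, msa, WAG), oracle_loglik(tr, msa, WAG),
                 tolerance = 1e-9)
  }
})

test_that("likelihood is invariant under re-rooting (pulley principle)", {
  set.seed(54)
  fam <- simulate_family(small_cfg(n_leaves = 6, root_length = 60,
                                   lid_start = 30, lid_end = 44,
                                   lid_indel_prob = 0, seed = 54))
  ll0 <- log_likelihood(fam$tree, fam$true_alignment, WAG)
  for (tip in fam$tree$tip.label[1:3]) {
    rr <- root_with_outgroup(fam$tree, tip)
    expect_equal(log_likelihood(rr, fam$true_alignment, WAG), ll0,
                 tolerance = 1e-8)
  }
})

test_that("branch-length optimisation is monotone and dominates the truth", {
  set.seed(55)
  fam <- simulate_family(small_cfg(n_leaves = 5, root_length = 120,
                                   lid_start = 60, lid_end = 79,
                                   lid_indel_prob = 0, seed = 55))
  truth_ll <- log_likelihood(fam$tree, fam$true_alignment, WAG)
  perturbed <- fam$tree
  perturbed$edge.length <- pmax(perturbed$edge.length * 2 + 0.05, 0.01)
  fit <- optimize_branch_lengths(perturbed, fam$true_alignment, WAG)
  expect_true(all(diff(fit$trace) >= -1e-9))
  expect_gte(fit$loglik, truth_ll - 1e-6)

  # single-branch problem: optimum within 1e-4 of a dense grid search
  tr2 <- read_newick(text = "(x:0.3,y:0.3);")
  msa2 <- msa_from_strings(c(x = random_protein(150),
                             y = random_protein(150)))
  f2 <- optimize_branch_lengths(tr2, msa2, WAG)
  grid <- seq(1e-4, 10, length.out = 10000)
  best_grid <- max(vapply(grid, function(t) {
    tr2$edge.length[] <- c(t / 2, t / 2)
    log_likelihood(tr2, msa2, WAG)
  }, 0))
  expect_gte(f2$loglik, best_grid - 1e-4)

  # zero-variation alignment drives every branch to zero
  flat <- msa_from_strings(c(x = "AAAA", y = "AAAA", z = "AAAA"))
  tr3 <- read_newick(text = "(x:0.5,y:0.5,z:0.5);")
  f3 <- optimize_branch_lengths(tr3, flat, WAG)
  expect_lt(max(f3$tree$edge.length), 1e-3)
})

test_that("outgroup rooting bisects the pendant edge and is reversible", {
  tr <- read_newick(text = "(a:1,b:2,c:3);")
  r <- root_with_outgroup(tr, "c")
  expect_true(ape::is.rooted(r))
  # bipartition {a,b} vs {c}; c's pendant edge split at its midpoint
  co <- ape::cophenetic.phylo(r)
  expect_equal(co["a", "b"], 3)
  expect_equal(co["a", "c"], 4)
  rt <- setdiff(unique(r$edge[, 1]), r$edge[, 2])
  kids <- r$edge.length[r$edge[, 1] == rt]
  expect_equal(sort(kids), c(1.5, 1.5))

  set.seed(56)
  t0 <- ape::unroot(ape::rtree(7))
  r2 <- root_with_outgroup(t0, t0$tip.label[3])
  # leaf-to-leaf path lengths unchanged
  expect_equal(ape::cophenetic.phylo(r2)[t0$tip.label, t0$tip.label],
               ape::cophenetic.phylo(t0)[t0$tip.label, t0$tip.label],
               tolerance = 1e-10)
  # re-rooting then unrooting recovers the unrooted topology
  expect_equal(ape::dist.topo(ape::unroot(r2), t0),
               structure(0, names = "PH85"), ignore_attr = TRUE)
  expect_error(root_with_outgroup(t0, "nope"), "unknown outgroup")
})

test_that("bootstrap support is reproducible, bounded, and saturates on clean signal", {
  # conflict-free alignment: each clade marked by many private columns
  block <- function(members, all, n = 30) {
    col <- setNames(rep("A", length(all)), all)
    col[members] <- "W"
    matrix(rep(col, n), nrow = length(all),
           dimnames = list(all, NULL))
  }
  taxa <- paste0("t", 1:6)
  m <- cbind(block(c("t1", "t2"), taxa), block(c("t1", "t2", "t3"), taxa),
             block(c("t5", "t6"), taxa))
  msa <- protein_msa(lapply(taxa, function(id)
    protein_record(id, paste(m[id, ], collapse = ""))))
  bs <- bootstrap_support(msa, WAG, n_reps = 30, seed = 57)
  expect_true(all(bs$support$support >= 0 & bs$support$support <= 1))
  internal <- bs$support$support[-1]  # drop the trivial root split
  expect_true(all(internal == 1))
  bs2 <- bootstrap_support(msa, WAG, n_reps = 30, seed = 57)
  expect_equal(bs$support$support, bs2$support$support)
  # taxon order does not change the supports
  msa_rev <- protein_msa(rev(msa$records))
  bs3 <- bootstrap_support(msa_rev, WAG, n_reps = 30, seed = 57)
  expect_equal(sort(bs3$support$support), sort(bs$support$support))
})
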