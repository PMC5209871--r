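# Shared fixtures and independent oracles used across the suite.
# The oracles deliberately use dumb exhaustive computation so they stay
# independent of the pruning/DP code paths they validate.

WAG <- build_wag_model()

`%+%` <- function(a, b) paste0(a, b)

# sim_config with motif blocks tucked between the signal peptide and the
# lid, for the short root sequences used in unit tests (lid_start >= 29)
small_cfg <- function(...) sim_config(oxyanion_pos = 19, catalytic_pos = 24, ...)

# 20-state model with uniform frequencies and equal exchangeabilities;
# its transition probabilities have the closed form
# P_ii(t) = 1/20 + (19/20) exp(-20 t / 19) under unit-rate scaling.
equal_rates_model <- function() {
  S <- matrix(1, 20, 20)
  substitution_model(S, rep(1 / 20, 20))
}

random_protein <- function(n, model = WAG) {
  paste(sample(AA_ALPHABET, n, replace = TRUE, prob = model$pi),
        collapse = "")
}

msa_from_strings <- function(strs) {
  protein_msa(Map(protein_record, names(strs), strs))
}

# ---- exhaustive likelihood / posterior oracle -------------------------

# Per-site likelihood by summing over every assignment of internal-node
# states.  Missing leaf states (gap / X) contribute a factor of 1.
.oracle_site <- function(tree, leaf_states, model) {
  nt <- length(tree$tip.label)
  internal <- seq(nt + 1L, nt + tree$Nnode)
  grid <- as.matrix(expand.grid(rep(list(1:20), length(internal))))
  colnames(grid) <- internal
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])
  w <- model$pi[grid[, as.character(root)]]
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    P <- transition_matrix(model, tree$edge.length[k])
    ps <- grid[, as.character(p)]
    if (ch <= nt) {
      s <- leaf_states[tree$tip.label[ch]]
      if (!is.na(s)) w <- w * P[cbind(ps, s)]
    } else {
      w <- w * P[cbind(ps, grid[, as.character(ch)])]
    }
  }
  list(lik = sum(w), w = w, grid = grid)
}

oracle_loglik <- function(tree, msa, model) {
  m <- msa_matrix(msa)
  idx <- matrix(match(m, AA_ALPHABET), nrow(m), ncol(m),
                dimnames = dimnames(m))
  sum(vapply(seq_len(ncol(idx)), function(s)
    log(.oracle_site(tree, idx[, s], model)$lik), 0))
}

# Marginal posterior at one internal node (by ape node index), sites x 20.
oracle_posteriors <- function(tree, msa, model, node) {
  m <- msa_matrix(msa)
  idx <- matrix(match(m, AA_ALPHABET), nrow(m), ncol(m),
                dimnames = dimnames(m))
  t(vapply(seq_len(ncol(idx)), function(s) {
    o <- .oracle_site(tree, idx[, s], model)
    p <- vapply(1:20, function(a)
      sum(o$w[o$grid[, as.character(node)] == a]), 0)
    p / sum(p)
  }, numeric(20)))
}

# ---- exhaustive global-alignment oracle -------------------------------

# Maximum affine-gap global alignment score by enumerating every alignment
# path.  A gap of length L costs open + L * ext (matching global_align).
brute_force_align_score <- function(a, b, sm, open = 10, ext = 0.5) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  rec <- function(i, j, prev) {
    if (i > na && j > nb) return(0)
    best <- -Inf
    if (i <= na && j <= nb)
      best <- max(best, sm[ca[i], cb[j]] + rec(i + 1, j + 1, "M"))
    if (j <= nb)
      best <- max(best, -(if (prev == "E") ext else open + ext) +
                    rec(i, j + 1, "E"))
    if (i <= na)
      best <- max(best, -(if (prev == "F") ext else open + ext) +
                    rec(i + 1, j, "F"))
    best
  }
  rec(1, 1, "S")
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Random rooted tree with known branch lengths and its additive distance
# matrix.
random_additive_case <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, br = function(n) runif(n, 0.2, 1.5))
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}
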