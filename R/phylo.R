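# Phylogeny construction and likelihood: ML pairwise distances, neighbor
# joining, Felsenstein pruning, branch-length optimisation, outgroup
# rooting and bootstrap support.
#
# Trees are ape "phylo" objects.  Gap and X characters are treated as
# missing data (all-ones partial likelihood vectors), so every alignment
# column contributes at every node - the behaviour that lets ancestral
# sequences be reconstructed across the full hypervariable lid block.

# Integer-encoded alignment: ntaxa x S matrix of indices into AA_ALPHABET,
# NA for gap/X.
.encode_msa <- function(msa) {
  m <- msa_matrix(msa)
  idx <- matrix(match(m, AA_ALPHABET), nrow(m), ncol(m),
                dimnames = dimnames(m))
  idx
}

.leaf_partial <- function(idx_row) {
  S <- length(idx_row)
  L <- matrix(0, 20, S)
  obs <- !is.na(idx_row)
  L[cbind(idx_row[obs], which(obs))] <- 1
  L[, !obs] <- 1
  L
}

# Postorder pruning pass.  Returns per-node partial likelihood matrices
# (20 x S), per-edge child contributions P(t) %*% L_child, per-site log
# scalers, and the total log-likelihood.  `scale` should be TRUE for plain
# likelihood computation; the ancestral-reconstruction pass runs unscaled
# (posteriors are normalised per site) which is safe for desk-scale trees.
.pruning <- function(tree, X, model, scale = TRUE) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  S <- ncol(X)
  partial <- vector("list", nn)
  edge_contrib <- vector("list", nn)   # indexed by child node
  logsc <- numeric(S)
  ord <- match(tree$tip.label, rownames(X))
  if (anyNA(ord))
    stop(sprintf("leaf without sequence: %s",
                 paste(tree$tip.label[is.na(ord)], collapse = ", ")))
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    Lc <- if (ch <= nt) .leaf_partial(X[ord[ch], ]) else partial[[ch]]
    M <- transition_matrix(model, po$edge.length[k]) %*% Lc
    edge_contrib[[ch]] <- M
    partial[[p]] <- if (is.null(partial[[p]])) M else partial[[p]] * M
    if (scale) {
      mx <- apply(partial[[p]], 2, max)
      low <- mx > 0 & mx < 1e-200
      if (any(low)) {
        partial[[p]][, low] <- partial[[p]][, low] / rep(mx[low], each = 20)
        logsc[low] <- logsc[low] + log(mx[low])
      }
    }
  }
  root <- po$edge[nrow(po$edge), 1]
  site_lik <- colSums(partial[[root]] * model$pi)
  list(partial = partial, edge_contrib = edge_contrib, logsc = logsc,
       root = root, po = po, nt = nt,
       site_loglik = log(site_lik) + logsc,
       loglik = sum(log(site_lik)) + sum(logsc))
}

#' Total log-likelihood of an alignment on a tree
#'
#' Felsenstein pruning over sites under a reversible amino-acid model.
#' Gaps and `X` contribute all-ones partial vectors (missing data);
#' per-site scaling guards against underflow.
#'
#' @param tree ape `phylo` with branch lengths (rooted or with a basal
#'   multifurcation).
#' @param msa A [protein_msa()] whose ids cover the tree's tips.
#' @param model An `aa_subst_model`.
#' @return Total log-likelihood (finite for valid inputs).
#' @export
log_likelihood <- function(tree, msa, model) {
  stopifnot(inherits(tree, "phylo"), inherits(msa, "protein_msa"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  X <- .encode_msa(msa)
  .pruning(tree, X, model, scale = TRUE)$loglik
}

#' Maximum-likelihood pairwise distance
#'
#' Distance between two aligned (gapped) sequences under the model,
#' maximising the likelihood `sum_sites log(pi_x P_xy(t))` over
#' `t` in `[0, max_t]`.  Columns with a gap or `X` in either sequence are
#' skipped.
#'
#' @param a,b Gapped sequences (strings or [protein_record()]) of equal
#'   length.
#' @param model An `aa_subst_model`.
#' @param max_t Upper bound of the search interval (expected
#'   substitutions/site).
#' @return Estimated distance (expected substitutions per site).
#' @export
ml_pairwise_distance <- function(a, b, model, max_t = 20) {
  sa <- .chars(.seq_of(a)); sb <- .chars(.seq_of(b))
  if (length(sa) != length(sb)) stop("sequences must be aligned (equal length)")
  ia <- match(sa, AA_ALPHABET); ib <- match(sb, AA_ALPHABET)
  ok <- !is.na(ia) & !is.na(ib)
  if (!any(ok)) stop("no comparable columns between the two sequences")
  N <- matrix(0, 20, 20)
  tab <- table(ia[ok], ib[ok])
  N[cbind(as.integer(rownames(tab))[row(tab)],
          as.integer(colnames(tab))[col(tab)])] <- as.numeric(tab)
  nz <- which(N > 0)
  lpi <- log(model$pi)[((nz - 1) %% 20) + 1]
  f <- function(t) {
    P <- transition_matrix(model, t)
    sum(N[nz] * (lpi + log(pmax(P[nz], 1e-300))))
  }
  opt <- optimize(f, c(0, max_t), maximum = TRUE, tol = 1e-9)
  # the optimum can sit on the t = 0 boundary (identical sequences)
  if (f(0) >= opt$objective) 0 else opt$maximum
}

#' Pairwise ML distance matrix of an alignment
#'
#' @param msa A [protein_msa()].
#' @param model An `aa_subst_model`.
#' @param max_t Search bound passed to [ml_pairwise_distance()].
#' @return Symmetric matrix with zero diagonal, dimnames = record ids.
#' @export
distance_matrix <- function(msa, model, max_t = 20) {
  stopifnot(inherits(msa, "protein_msa"))
  ids <- names(msa$records)
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    D[i, j] <- D[j, i] <- ml_pairwise_distance(msa$records[[i]],
                                               msa$records[[j]], model,
                                               max_t = max_t)
  }
  D
}

#' Neighbor joining
#'
#' Saitou-Nei neighbor joining with the Studier-Keppler selection
#' criterion.  Negative branch-length estimates are clamped to zero;
#' selection ties are broken by the lexicographically smallest pair of
#' cluster representatives (each cluster represented by its smallest leaf
#' name), so the result is deterministic.
#'
#' @param D Symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return Unrooted ape `phylo` (trifurcating root representation) with
#'   internal labels assigned by [set_node_labels()].
#' @export
neighbor_joining <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D) || nrow(D) < 3)
    stop("neighbor joining needs a square distance matrix with >= 3 taxa")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  labs <- rownames(D)
  if (is.null(labs)) stop("distance matrix must have taxon names")
  fmt <- function(x) sprintf("%.12g", max(x, 0))
  nwk <- labs          # growing subtree strings
  rep_leaf <- labs     # smallest leaf name per cluster
  Dm <- D
  while (length(nwk) > 3L) {
    n <- nrow(Dm)
    r <- rowSums(Dm)
    # scan pairs in lexicographic representative order; strict improvement
    # only, so ties resolve to the lexicographically first pair
    ordm <- order(rep_leaf)
    best <- NULL; bestQ <- Inf
    for (ii in seq_len(n - 1L)) for (jj in seq(ii + 1L, n)) {
      i <- ordm[ii]; j <- ordm[jj]
      q <- (n - 2) * Dm[i, j] - r[i] - r[j]
      if (q < bestQ - 1e-12) { bestQ <- q; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    vi <- Dm[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- Dm[i, j] - vi
    merged <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(vi), nwk[j], fmt(vj))
    keep <- setdiff(seq_len(n), c(i, j))
    du <- (Dm[i, keep] + Dm[j, keep] - Dm[i, j]) / 2
    Dm <- rbind(cbind(Dm[keep, keep, drop = FALSE], du),
                c(du, 0))
    nwk <- c(nwk[keep], merged)
    rep_leaf <- c(rep_leaf[keep], min(rep_leaf[c(i, j)]))
    rownames(Dm) <- colnames(Dm) <- NULL
  }
  d12 <- Dm[1, 2]; d13 <- Dm[1, 3]; d23 <- Dm[2, 3]
  x <- (d12 + d13 - d23) / 2
  y <- (d12 + d23 - d13) / 2
  z <- (d13 + d23 - d12) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[1], fmt(x), nwk[2], fmt(y),
                 nwk[3], fmt(z))
  set_node_labels(ape::read.tree(text = txt))
}

#' Optimise branch lengths by maximum likelihood
#'
#' Coordinate-wise scalar optimisation of each branch on a fixed topology,
#' sweeping until the log-likelihood improves by less than `tol` or
#' `max_sweeps` sweeps have run.  The log-likelihood never decreases
#' across sweeps.
#'
#' @param tree ape `phylo` with starting branch lengths.
#' @param msa A [protein_msa()].
#' @param model An `aa_subst_model`.
#' @param max_t Upper bound for any single branch length.
#' @param tol Convergence tolerance on the log-likelihood.
#' @param max_sweeps Maximum number of sweeps.
#' @return List with `tree` (optimised lengths), `loglik`, per-sweep
#'   `trace`, and `converged`.  Warns on non-convergence.
#' @export
optimize_branch_lengths <- function(tree, msa, model, max_t = 10,
                                    tol = 1e-6, max_sweeps = 50) {
  stopifnot(inherits(tree, "phylo"), inherits(msa, "protein_msa"))
  X <- .encode_msa(msa)
  cur <- .pruning(tree, X, model)$loglik
  trace <- cur
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    for (k in seq_along(tree$edge.length)) {
      f <- function(t) {
        tr2 <- tree
        tr2$edge.length[k] <- t
        .pruning(tr2, X, model)$loglik
      }
      opt <- optimize(f, c(0, max_t), maximum = TRUE, tol = 1e-8)
      cand_t <- opt$maximum
      cand_ll <- opt$objective
      ll0 <- f(0)
      if (ll0 >= cand_ll) { cand_t <- 0; cand_ll <- ll0 }
      if (cand_ll >= cur) {
        tree$edge.length[k] <- cand_t
        cur <- cand_ll
      }
    }
    trace <- c(trace, cur)
    if (cur - trace[length(trace) - 1L] < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("branch-length optimisation did not converge in %d sweeps",
                    max_sweeps))
  list(tree = tree, loglik = cur, trace = trace, converged = converged)
}

#' Root a tree on an outgroup
#'
#' Places the root at the midpoint of the outgroup's pendant edge and
#' renumbers internal nodes.
#'
#' @param tree ape `phylo` (rooted input is unrooted first).
#' @param outgroup_id A tip label.
#' @return Rooted ape `phylo` with fresh internal labels.
#' @export
root_with_outgroup <- function(tree, outgroup_id) {
  stopifnot(inherits(tree, "phylo"))
  if (!outgroup_id %in% tree$tip.label)
    stop(sprintf("unknown outgroup '%s'", outgroup_id))
  tr <- tree
  if (ape::is.rooted(tr)) tr <- ape::unroot(tr)
  r <- ape::root(tr, outgroup = outgroup_id, resolve.root = TRUE)
  root <- .root_node(r)
  kids <- which(r$edge[, 1] == root)
  total <- sum(r$edge.length[kids])
  r$edge.length[kids] <- total / 2
  set_node_labels(r)
}

#' Bootstrap support for the NJ tree of an alignment
#'
#' Resamples alignment columns with replacement, rebuilds the ML-distance
#' NJ tree for each replicate, and reports for every internal edge of the
#' original tree the fraction of replicates containing the same
#' bipartition.  (Branch-length re-optimisation cannot change which
#' bipartitions a replicate contains, so replicates are NJ topologies.)
#'
#' @param msa A [protein_msa()].
#' @param model An `aa_subst_model`.
#' @param n_reps Number of bootstrap replicates.
#' @param seed Optional RNG seed for reproducible resampling.
#' @param tree Optional reference tree; defaults to the NJ tree of `msa`.
#' @return List of class `bootstrap_support`: `tree` (reference tree with
#'   supports as internal labels), `support` (data frame of node and
#'   support in `[0, 1]`), `n_reps`.
#' @export
bootstrap_support <- function(msa, model, n_reps = 100, seed = NULL,
                              tree = NULL) {
  stopifnot(inherits(msa, "protein_msa"), n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tree))
    tree <- neighbor_joining(distance_matrix(msa, model))
  m <- msa_matrix(msa)
  reps <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    bmsa <- .msa_from_matrix(m[, cols, drop = FALSE])
    reps[[b]] <- neighbor_joining(distance_matrix(bmsa, model))
  }
  class(reps) <- "multiPhylo"
  cnt <- ape::prop.clades(tree, reps, rooted = FALSE)
  cnt[is.na(cnt)] <- 0
  sup <- cnt / n_reps
  nt <- length(tree$tip.label)
  out_tree <- tree
  out_tree$node.label <- sprintf("%.2f", sup)
  structure(list(tree = out_tree,
                 support = data.frame(node = seq(nt + 1L, nt + tree$Nnode),
                                      label = tree$node.label,
                                      support = sup),
                 n_reps = n_reps),
            class = "bootstrap_support")
}

#' @export
print.bootstrap_support <- function(x, ...) {
  cat(sprintf("<bootstrap_support> %d replicates; mean support %.2f\n",
              x$n_reps, mean(x$support$support)))
  invisible(x)
}
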