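# Marginal ancestral sequence reconstruction.
#
# For internal node v and site s, the marginal posterior of state a is
#   p_vs(a)  proportional to  F_v(a) * L_v(a)
# where L_v is the usual pruning (below-node) partial likelihood and F_v
# propagates the prior and the data everywhere else down to v:
#   F_root = pi,   F_c = t(P(t_c)) %*% (F_v * prod_{siblings s} P(t_s) L_s).
# Under a reversible model this equals the posterior obtained by re-rooting
# the tree at v, so (except at the root itself) the reconstruction does not
# depend on where the tree was rooted - a property the tests verify.
# Gaps and X are missing data, so every alignment column is reconstructed
# at every node; in a column gapped in all leaves the posterior is the
# prior pi.  The MAP residue per site, with ties broken toward the lowest
# index in AA_ALPHABET, is the reconstructed ancestral sequence.

.updown <- function(tree, X, model) {
  pr <- .pruning(tree, X, model, scale = FALSE)
  nt <- pr$nt
  S <- ncol(X)
  kids <- .children_of(tree)
  Fmat <- vector("list", nt + tree$Nnode)
  Fmat[[pr$root]] <- matrix(model$pi, 20, S)
  cw <- ape::reorder.phylo(tree, "cladewise")
  elen <- setNames(cw$edge.length, cw$edge[, 2])
  for (k in seq_len(nrow(cw$edge))) {
    v <- cw$edge[k, 1]; ch <- cw$edge[k, 2]
    if (ch <= nt) next
    sibs <- setdiff(kids[[v]], ch)
    A <- Fmat[[v]]
    for (s in sibs) A <- A * pr$edge_contrib[[s]]
    Fmat[[ch]] <- t(transition_matrix(model, elen[as.character(ch)])) %*% A
  }
  list(pruning = pr, Fmat = Fmat)
}

#' Marginal ancestral reconstruction at every internal node
#'
#' @param tree ape `phylo` with branch lengths; a rooted tree or one with a
#'   basal multifurcation (which then serves as the root).  Internal labels
#'   are assigned by [set_node_labels()] when absent.
#' @param msa A [protein_msa()] covering the tree's tips.
#' @param model An `aa_subst_model`.
#' @return Object of class `asr_fit`: `posterior` (per internal node label,
#'   a sites x 20 matrix of marginal posteriors, rows summing to 1), `map`
#'   (MAP sequence per node, one residue per alignment column),
#'   `max_posterior` (per-site maximum posterior per node), the labelled
#'   `tree`, and the total `loglik`.
#' @export
reconstruct_ancestors <- function(tree, msa, model) {
  stopifnot(inherits(tree, "phylo"), inherits(msa, "protein_msa"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  tree <- set_node_labels(tree, overwrite = is.null(tree$node.label))
  X <- .encode_msa(msa)
  ud <- .updown(tree, X, model)
  nt <- length(tree$tip.label)
  imap <- .internal_map(tree)
  posterior <- map_seq <- maxp <- list()
  for (lab in names(imap)) {
    v <- imap[[lab]]
    W <- ud$Fmat[[v]] * ud$pruning$partial[[v]]      # 20 x S
    tot <- colSums(W)
    if (any(tot <= 0)) stop("zero site likelihood; check branch lengths")
    Pst <- t(W) / tot                                # S x 20
    colnames(Pst) <- AA_ALPHABET
    best <- max.col(Pst, ties.method = "first")
    posterior[[lab]] <- Pst
    map_seq[[lab]] <- paste(AA_ALPHABET[best], collapse = "")
    maxp[[lab]] <- Pst[cbind(seq_len(nrow(Pst)), best)]
  }
  ll <- sum(log(colSums(ud$pruning$partial[[ud$pruning$root]] * model$pi)))
  structure(list(tree = tree, node_labels = names(imap),
                 posterior = posterior, map = unlist(map_seq),
                 max_posterior = maxp, n_columns = msa$n_columns,
                 loglik = ll),
            class = "asr_fit")
}

#' Marginal posteriors at one internal node
#'
#' @inheritParams reconstruct_ancestors
#' @param node_id Internal node label (see [set_node_labels()]).
#' @return Sites x 20 matrix of marginal posterior probabilities.
#' @export
marginal_posteriors <- function(tree, msa, model, node_id) {
  tree <- set_node_labels(tree, overwrite = is.null(tree$node.label))
  node_id <- as.character(node_id)
  if (node_id %in% tree$tip.label ||
      (suppressWarnings(!is.na(as.integer(node_id))) &&
       as.integer(node_id) <= length(tree$tip.label)))
    stop("node_id must name an internal node, not a leaf")
  fit <- reconstruct_ancestors(tree, msa, model)
  if (!node_id %in% names(fit$posterior))
    stop(sprintf("unknown internal node '%s'", node_id))
  fit$posterior[[node_id]]
}

#' @export
print.asr_fit <- function(x, ...) {
  cat(sprintf(
    "<asr_fit> %d internal nodes x %d columns, log-likelihood %.3f\n",
    length(x$node_labels), x$n_columns, x$loglik))
  cat(sprintf("  mean per-site MAP posterior: %.3f\n",
              mean(unlist(x$max_posterior))))
  invisible(x)
}

#' @export
summary.asr_fit <- function(object, ...) {
  tab <- data.frame(
    node = object$node_labels,
    mean_max_posterior = vapply(object$max_posterior[object$node_labels],
                                mean, 0),
    min_max_posterior = vapply(object$max_posterior[object$node_labels],
                               min, 0))
  structure(list(table = tab, loglik = object$loglik,
                 n_columns = object$n_columns),
            class = "summary.asr_fit")
}

#' @export
print.summary.asr_fit <- function(x, ...) {
  cat(sprintf("Marginal ancestral reconstruction: %d nodes, %d columns\n",
              nrow(x$table), x$n_columns))
  cat(sprintf("Log-likelihood: %.3f\n\n", x$loglik))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write MAP ancestral sequences as FASTA
#'
#' @param fit An `asr_fit`.
#' @param path Output path; node labels become FASTA ids.
#' @export
write_asr_fasta <- function(fit, path) {
  stopifnot(inherits(fit, "asr_fit"))
  write_fasta(Map(protein_record, fit$node_labels,
                  fit$map[fit$node_labels]), path)
}

#' Write per-node posterior matrices as TSV
#'
#' One file per internal node (`<prefix><label>.tsv`) with columns: site,
#' the 20 state probabilities, the MAP residue and its posterior - a
#' stable plain-text analog of the rst matrices a reconstruction program
#' would emit.
#'
#' @param fit An `asr_fit`.
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix.
#' @return Written paths, invisibly.
#' @export
write_posteriors <- function(fit, dir, prefix = "node_") {
  stopifnot(inherits(fit, "asr_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (lab in fit$node_labels) {
    P <- fit$posterior[[lab]]
    df <- data.frame(site = seq_len(nrow(P)), round(P, 6),
                     map = .chars(fit$map[[lab]]),
                     max_posterior = round(fit$max_posterior[[lab]], 6))
    p <- file.path(dir, paste0(prefix, lab, ".tsv"))
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
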