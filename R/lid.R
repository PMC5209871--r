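# Lid-region evolution analysis: mapping the reference lid onto alignment
# columns, posterior-threshold trimming of reconstructed ancestral lids,
# hydrophobicity, and the node x threshold trajectory table.
#
# Because gaps are treated as missing data, every ancestral lid is
# reconstructed across the full alignment block, including columns present
# in only a few extant sequences.  Such columns carry low posterior
# confidence, so deleting residues whose maximum posterior falls below a
# threshold shortens ancestral lids toward their best-supported core -
# the adjustment this module implements for thresholds 0.65-0.90.

#' Alignment columns spanned by the reference lid
#'
#' The contiguous block of MSA columns from the reference's first lid
#' residue to its last, including any insertion columns from other taxa
#' that interrupt the reference lid.
#'
#' @param msa A [protein_msa()] containing the reference row.
#' @param reference_id Id of the reference record in `msa`.
#' @param lid Optional 1-based inclusive interval in reference (ungapped)
#'   coordinates; defaults to the reference record's `lid` feature.
#' @return Integer vector of consecutive column indices.
#' @export
lid_columns <- function(msa, reference_id, lid = NULL) {
  stopifnot(inherits(msa, "protein_msa"))
  if (!reference_id %in% names(msa$records))
    stop(sprintf("reference '%s' not found in the alignment", reference_id))
  ref <- msa$records[[reference_id]]
  if (is.null(lid)) lid <- ref$features$lid
  if (is.null(lid)) stop("reference record has no 'lid' feature")
  ch <- .chars(ref$sequence)
  pos <- cumsum(ch != "-")
  pos[ch == "-"] <- NA
  start_col <- match(lid[1], pos)
  end_col <- match(lid[2], pos)
  if (is.na(start_col) || is.na(end_col))
    stop("lid interval outside the reference sequence")
  start_col:end_col
}

#' Construct a lid region
#'
#' @param id Node or record identifier.
#' @param residues Ungapped residue string (possibly empty).
#' @param columns Source MSA columns, one per residue.
#' @param posterior Per-residue maximum posterior (1.0 for extant
#'   sequences).
#' @return Object of class `lid_region`.
#' @export
lid_region <- function(id, residues, columns, posterior) {
  n <- nchar(residues)
  if (length(columns) != n || length(posterior) != n)
    stop("residues, columns and posterior must have equal length")
  structure(list(id = id, residues = residues, columns = as.integer(columns),
                 posterior = as.numeric(posterior)),
            class = "lid_region")
}

#' @export
print.lid_region <- function(x, ...) {
  cat(sprintf("<lid_region> %s: %d residues, min posterior %.2f\n",
              x$id, nchar(x$residues),
              if (nchar(x$residues)) min(x$posterior) else NA))
  if (nchar(x$residues)) cat(" ", x$residues, "\n")
  invisible(x)
}

#' Ancestral lid of a reconstructed node
#'
#' @param fit An `asr_fit` from [reconstruct_ancestors()].
#' @param node Internal node label.
#' @param columns Lid columns from [lid_columns()].
#' @return A [lid_region()] with the node's MAP residues and their
#'   posteriors over the lid block.
#' @export
ancestral_lid <- function(fit, node, columns) {
  stopifnot(inherits(fit, "asr_fit"))
  node <- as.character(node)
  if (!node %in% fit$node_labels) stop(sprintf("unknown node '%s'", node))
  ch <- .chars(fit$map[[node]])[columns]
  lid_region(node, paste(ch, collapse = ""), columns,
             fit$max_posterior[[node]][columns])
}

#' Extant lid of an aligned sequence
#'
#' @param msa A [protein_msa()].
#' @param id Record id.
#' @param columns Lid columns from [lid_columns()].
#' @return A [lid_region()] with the record's non-gap residues in the lid
#'   block (posterior 1 per residue).
#' @export
extant_lid <- function(msa, id, columns) {
  stopifnot(inherits(msa, "protein_msa"))
  if (!id %in% names(msa$records)) stop(sprintf("unknown record '%s'", id))
  ch <- .chars(msa$records[[id]]$sequence)[columns]
  keep <- ch != "-"
  lid_region(id, paste(ch[keep], collapse = ""), columns[keep],
             rep(1, sum(keep)))
}

#' Trim a lid by posterior threshold
#'
#' Keeps exactly the residues whose maximum posterior is `>= threshold`
#' (residues *below* the threshold are deleted; ties at the threshold are
#' kept), preserving order.  Extant lids (all posteriors 1) are returned
#' unchanged for any threshold <= 1.
#'
#' @param lid A [lid_region()].
#' @param threshold Posterior threshold in `(0, 1]`.
#' @return The trimmed [lid_region()].
#' @export
trim_by_posterior <- function(lid, threshold) {
  stopifnot(inherits(lid, "lid_region"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  keep <- lid$posterior >= threshold
  lid_region(lid$id, paste(.chars(lid$residues)[keep], collapse = ""),
             lid$columns[keep], lid$posterior[keep])
}

#' Hydrophobic residue count and percentage
#'
#' Counts residues belonging to the hydrophobic set (default: positive
#' Kyte-Doolittle hydropathy, [KD_HYDROPHOBIC]).  The percentage is
#' truncated - not rounded - to one decimal (`floor(1000 * count / n) /
#' 10`); set `truncate = FALSE` for conventional rounding.
#'
#' @param residues A residue string or a [lid_region()] (non-empty).
#' @param hydrophobic_set Character vector of residues counted as
#'   hydrophobic.
#' @param truncate Truncate (default) or round the percentage.
#' @return Named numeric vector `c(count = ..., percent = ...)`.
#' @export
hydrophobic_fraction <- function(residues, hydrophobic_set = KD_HYDROPHOBIC,
                                 truncate = TRUE) {
  if (inherits(residues, "lid_region")) residues <- residues$residues
  if (!is.character(residues) || length(residues) != 1L || !nzchar(residues))
    stop("residues must be a non-empty string")
  ch <- .chars(residues)
  n <- length(ch)
  count <- sum(ch %in% hydrophobic_set)
  percent <- if (truncate) floor(1000 * count / n) / 10
             else round(100 * count / n, 1)
  c(count = count, percent = percent)
}

#' Lid trajectory across nodes and posterior thresholds
#'
#' For each selected internal node and each threshold, trims the node's
#' reconstructed lid by posterior and reports its length, hydrophobic
#' count and (truncated) hydrophobic percentage; each row also records
#' whether the node's full MAP sequence contains the oxyanion and
#' catalytic motifs.  Rows are sorted by node then threshold.
#'
#' @param fit An `asr_fit`.
#' @param columns Lid columns from [lid_columns()].
#' @param thresholds Posterior thresholds (default the six assayed values
#'   0.65-0.90).
#' @param nodes Internal node labels (default: all).
#' @param hydrophobic_set Residues counted as hydrophobic.
#' @param oxyanion,catalytic Motif patterns for the ancestor motif check.
#' @return Object of class `lid_trajectory`: a data frame with columns
#'   node, threshold, lid_length, hydrophobic_count, hydrophobic_percent
#'   (`NA` when the trimmed lid is empty), oxyanion_present,
#'   catalytic_present.
#' @export
lid_trajectory <- function(fit, columns,
                           thresholds = c(0.65, 0.70, 0.75, 0.80, 0.85, 0.90),
                           nodes = NULL,
                           hydrophobic_set = KD_HYDROPHOBIC,
                           oxyanion = "GGG[FL]", catalytic = "G[EQ]SAG") {
  stopifnot(inherits(fit, "asr_fit"))
  if (any(thresholds <= 0 | thresholds > 1))
    stop("thresholds must lie in (0, 1]")
  if (is.null(nodes)) nodes <- fit$node_labels
  nodes <- as.character(nodes)
  num <- suppressWarnings(as.numeric(nodes))
  nodes <- if (anyNA(num)) sort(nodes) else nodes[order(num)]
  rows <- list()
  for (nd in nodes) {
    mh <- find_motifs(fit$map[[nd]], oxyanion, catalytic)
    full <- ancestral_lid(fit, nd, columns)
    for (th in sort(thresholds)) {
      tr <- trim_by_posterior(full, th)
      len <- nchar(tr$residues)
      hf <- if (len > 0) hydrophobic_fraction(tr$residues, hydrophobic_set)
            else c(count = 0, percent = NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        node = nd, threshold = th, lid_length = len,
        hydrophobic_count = unname(hf["count"]),
        hydrophobic_percent = unname(hf["percent"]),
        oxyanion_present = nrow(mh$oxyanion) > 0,
        catalytic_present = nrow(mh$catalytic) > 0)
    }
  }
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))
  structure(tab, class = c("lid_trajectory", "data.frame"),
            hydrophobic_set = hydrophobic_set)
}

#' Write a lid trajectory table as TSV
#'
#' A header comment records the hydrophobic set the percentages refer to.
#'
#' @param trajectory A [lid_trajectory()].
#' @param path Output path.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "lid_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# hydrophobic set: %s",
                     paste(attr(trajectory, "hydrophobic_set"),
                           collapse = "")), con)
  write.table(as.data.frame(trajectory), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
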