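# Pairwise global alignment, percent identity and a progressive multiple
# aligner.  Alignment scores follow the usual protein conventions: BLOSUM62
# substitution scores and affine gap penalties where a gap of length L
# costs gap_open + L * gap_extension (the same convention as
# Biostrings::pairwiseAlignment, so the two agree score-for-score).

.blosum_env <- new.env(parent = emptyenv())

.builtin_matrix <- function(name) {
  if (is.null(.blosum_env[[name]])) {
    e <- new.env()
    ok <- tryCatch({
      utils::data(list = name, package = "Biostrings", envir = e)
      TRUE
    }, warning = function(w) FALSE, error = function(e) FALSE)
    if (!ok) stop(sprintf("unknown built-in scoring matrix '%s'", name))
    .blosum_env[[name]] <- get(name, envir = e)
  }
  .blosum_env[[name]]
}

#' Read a scoring matrix in NCBI format
#'
#' Plain-text matrix with `#` comments, a header row of residue letters and
#' one labelled row per residue (the format of the NCBI/BLAST matrix
#' files).
#'
#' @param path Path to the matrix file.
#' @return Numeric matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*#", ln) & nzchar(trimws(ln))]
  header <- strsplit(trimws(ln[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(ln[-1]), "\\s+")
  m <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(header))))
  rownames(m) <- vapply(rows, `[[`, "", 1)
  colnames(m) <- header
  m
}

.score_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (file.exists(x)) return(read_score_matrix(x))
    return(.builtin_matrix(x))
  }
  stop("scoring matrix must be a matrix, a built-in name, or a file path")
}

.seq_of <- function(x) {
  if (inherits(x, "protein_record")) x$sequence else as.character(x)
}

.id_of <- function(x, default) {
  if (inherits(x, "protein_record")) x$id else default
}

#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch-Gotoh alignment of two ungapped protein sequences.
#' A gap of length L is penalised `gap_open + L * gap_extension`.  Ties are
#' broken deterministically (match/mismatch preferred over a gap in `a`,
#' which is preferred over a gap in `b`).
#'
#' @param a,b [protein_record()] objects or plain strings (ungapped,
#'   non-empty).
#' @param matrix Scoring matrix: a built-in name (default `"BLOSUM62"`), a
#'   numeric matrix, or a path to an NCBI-format matrix file.
#' @param gap_open,gap_extension Gap penalties (positive numbers).
#' @return Object of class `pairwise_alignment`: equal-length gapped
#'   strings `gapped_a`/`gapped_b`, the optimal `score`, and `identity`
#'   (fraction of aligned columns with identical residues).
#' @export
global_align <- function(a, b, matrix = "BLOSUM62", gap_open = 10,
                         gap_extension = 0.5) {
  sa <- .seq_of(a); sb <- .seq_of(b)
  if (!nzchar(sa) || !nzchar(sb)) stop("sequences must be non-empty")
  if (grepl("-", sa, fixed = TRUE) || grepl("-", sb, fixed = TRUE))
    stop("sequences must be ungapped")
  sm <- .score_matrix(matrix)
  ca <- .chars(sa); cb <- .chars(sb)
  if (!all(ca %in% rownames(sm)) || !all(cb %in% colnames(sm)))
    stop("sequence contains letters absent from the scoring matrix")
  C <- sm[ca, cb, drop = FALSE]
  res <- affine_global_dp(C, gap_open, gap_extension)
  ga <- ifelse(res$a == 0L, "-", ca[pmax(res$a, 1L)])
  gb <- ifelse(res$b == 0L, "-", cb[pmax(res$b, 1L)])
  ga <- paste(ga, collapse = ""); gb <- paste(gb, collapse = "")
  out <- structure(list(id_a = .id_of(a, "a"), id_b = .id_of(b, "b"),
                        gapped_a = ga, gapped_b = gb,
                        score = res$score, identity = NA_real_),
                   class = "pairwise_alignment")
  out$identity <- percent_identity(out)
  out
}

#' Percent identity of a pairwise alignment
#'
#' Identical-residue columns divided by the number of aligned columns that
#' contain at least one residue (global alignments never produce gap-gap
#' columns, so this is every column).
#'
#' @param alignment A `pairwise_alignment`.
#' @return Fraction in `[0, 1]`.
#' @export
percent_identity <- function(alignment) {
  stopifnot(inherits(alignment, "pairwise_alignment"))
  ca <- .chars(alignment$gapped_a); cb <- .chars(alignment$gapped_b)
  keep <- !(ca == "-" & cb == "-")
  sum(ca[keep] == cb[keep] & ca[keep] != "-") / sum(keep)
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %s / %s  score %.1f  identity %.1f%%\n",
              x$id_a, x$id_b, x$score, 100 * x$identity))
  invisible(x)
}

# Residue-frequency profile of a set of gapped rows (20 x L matrix; gaps
# and X contribute no mass).
.profile_of <- function(chmat) {
  L <- ncol(chmat)
  p <- matrix(0, 20, L)
  for (k in seq_len(20))
    p[k, ] <- colSums(chmat == AA_ALPHABET[k])
  p / nrow(chmat)
}

#' Progressive multiple sequence alignment
#'
#' Convenience aligner for desk-scale analyses: a UPGMA guide tree is built
#' from pairwise identity distances (1 - identity), and groups are merged
#' by profile-profile Needleman-Wunsch with mean-of-pairs column scores and
#' affine gap penalties.  Deterministic given the input order.  The
#' pipeline also accepts a precomputed aligned FASTA wherever an alignment
#' is required, so an external aligner can be substituted at any point.
#'
#' @param records List of [protein_record()] (ungapped); at least 2 for a
#'   non-trivial alignment (a single record is returned as-is with a
#'   warning).
#' @inheritParams global_align
#' @return A [protein_msa()] with rows in the input order.
#' @export
progressive_msa <- function(records, matrix = "BLOSUM62", gap_open = 10,
                            gap_extension = 0.5) {
  records <- .record_list(records)
  if (length(records) == 1L) {
    warning("single record: returning a trivial alignment")
    return(protein_msa(records))
  }
  sm <- .score_matrix(matrix)
  S20 <- sm[AA_ALPHABET, AA_ALPHABET]
  n <- length(records)
  ids <- names(records)

  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    pid <- global_align(records[[i]], records[[j]], matrix = sm,
                        gap_open = gap_open,
                        gap_extension = gap_extension)$identity
    D[i, j] <- D[j, i] <- 1 - pid
  }
  hc <- hclust(as.dist(D), method = "average")

  # clusters hold character matrices (rows = members); negative hclust
  # indices are original records, positive are prior merges
  leaf_cluster <- function(i) {
    m <- matrix(.chars(records[[i]]$sequence), nrow = 1)
    rownames(m) <- ids[i]
    m
  }
  merged <- vector("list", nrow(hc$merge))
  get_cluster <- function(k) if (k < 0) leaf_cluster(-k) else merged[[k]]
  for (s in seq_len(nrow(hc$merge))) {
    A <- get_cluster(hc$merge[s, 1]); B <- get_cluster(hc$merge[s, 2])
    C <- t(.profile_of(A)) %*% S20 %*% .profile_of(B)
    path <- affine_global_dp(C, gap_open, gap_extension)
    gapcol <- function(m) matrix("-", nrow(m), 1)
    newA <- do.call(cbind, lapply(seq_along(path$a), function(k)
      if (path$a[k] == 0L) gapcol(A) else A[, path$a[k], drop = FALSE]))
    newB <- do.call(cbind, lapply(seq_along(path$b), function(k)
      if (path$b[k] == 0L) gapcol(B) else B[, path$b[k], drop = FALSE]))
    rownames(newA) <- rownames(A); rownames(newB) <- rownames(B)
    merged[[s]] <- rbind(newA, newB)
  }
  final <- merged[[length(merged)]][ids, , drop = FALSE]
  protein_msa(lapply(ids, function(id) {
    r <- records[[id]]
    protein_record(id, paste(final[id, ], collapse = ""),
                   features = r$features)
  }))
}
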