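# Sequence records, FASTA I/O and the multiple-alignment container.
#
# Coordinates are 1-based inclusive throughout the package, both internally
# and in every report.

.VALID_CHARS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                  "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X", "-")

.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

.ungap <- function(s) gsub("-", "", s, fixed = TRUE)

#' Create a protein record
#'
#' A named amino-acid sequence with optional interval features (e.g. a
#' `signal` peptide span or the `lid` span of a reference lipase).
#'
#' @param id Non-empty record identifier.
#' @param sequence Amino-acid string over the 20 canonical letters plus
#'   `X` (unknown) and, in alignment context, `-` (gap).  Lower case is
#'   accepted and upper-cased.
#' @param features Optional named list of integer intervals `c(start, end)`,
#'   1-based inclusive, within the sequence bounds.
#' @return An object of class `protein_record` with fields `id`, `sequence`
#'   and `features`.
#' @export
protein_record <- function(id, sequence, features = list()) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("record id must be a non-empty string")
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop(sprintf("record '%s': sequence must be a non-empty string", id))
  sequence <- toupper(sequence)
  bad <- setdiff(unique(.chars(sequence)), .VALID_CHARS)
  if (length(bad))
    stop(sprintf("record '%s': invalid characters %s", id,
                 paste(bad, collapse = ", ")))
  n <- nchar(sequence)
  if (length(features)) {
    if (is.null(names(features)) || any(!nzchar(names(features))))
      stop(sprintf("record '%s': features must be named", id))
    for (fn in names(features)) {
      iv <- features[[fn]]
      if (length(iv) != 2L || anyNA(iv) || iv[1] > iv[2] ||
          iv[1] < 1L || iv[2] > n)
        stop(sprintf("record '%s': feature '%s' outside sequence bounds",
                     id, fn))
      features[[fn]] <- as.integer(iv)
    }
  }
  structure(list(id = id, sequence = sequence, features = features),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa)\n", x$id,
              nchar(.ungap(x$sequence))))
  s <- x$sequence
  cat(" ", if (nchar(s) > 60) paste0(substr(s, 1, 57), "...") else s, "\n")
  for (fn in names(x$features))
    cat(sprintf("  feature %s: %d-%d\n", fn, x$features[[fn]][1],
                x$features[[fn]][2]))
  invisible(x)
}

.record_list <- function(records) {
  if (inherits(records, "protein_record")) records <- list(records)
  if (!is.list(records) || !all(vapply(records, inherits, TRUE,
                                       "protein_record")))
    stop("expected a list of protein_record objects")
  ids <- vapply(records, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate record id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  names(records) <- ids
  records
}

#' Read protein sequences from FASTA
#'
#' Sequences are upper-cased; letters outside the 20 canonical amino acids
#' (and `-`) are mapped to `X` with a warning.  Duplicate ids, zero-length
#' sequences and empty files are errors naming the offending record.
#'
#' @param path Path to a FASTA file.
#' @return Named list of [protein_record()] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop(sprintf("empty FASTA file: %s", path))
  ids <- sub("\\s.*$", "", names(ss))
  if (any(!nzchar(ids))) stop(sprintf("FASTA record with empty id in %s", path))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate FASTA id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  seqs <- toupper(as.character(ss))
  empty <- !nzchar(seqs)
  if (any(empty))
    stop(sprintf("zero-length sequence for record '%s'", ids[which(empty)[1]]))
  cleaned <- gsub(sprintf("[^%s]", paste(.VALID_CHARS, collapse = "")), "X",
                  seqs)
  changed <- cleaned != seqs
  if (any(changed))
    warning(sprintf("unknown letters mapped to 'X' in: %s",
                    paste(ids[changed], collapse = ", ")))
  .record_list(Map(protein_record, ids, cleaned))
}

#' Write protein records to FASTA
#'
#' @param records List of [protein_record()] (or a single record).
#' @param path Output path.
#' @param line_width Residues per sequence line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 60) {
  if (length(records) == 0L) {
    warning("writing empty FASTA file")
    file.create(path)
    return(invisible(path))
  }
  records <- .record_list(records)
  ss <- Biostrings::BStringSet(vapply(records, `[[`, "", "sequence"))
  names(ss) <- names(records)
  Biostrings::writeXStringSet(ss, filepath = path, width = line_width)
  invisible(path)
}

#' Create a multiple alignment of protein records
#'
#' All gapped sequences must have identical length; ungapping any row
#' recovers the original sequence.
#'
#' @param records Named list of gapped [protein_record()] objects.
#' @return Object of class `protein_msa` with fields `records` and
#'   `n_columns`.
#' @export
protein_msa <- function(records) {
  records <- .record_list(records)
  if (length(records) == 0L) stop("alignment needs at least one record")
  lens <- vapply(records, function(r) nchar(r$sequence), 0L)
  if (length(unique(lens)) != 1L)
    stop("aligned sequences must all have the same length")
  structure(list(records = records, n_columns = unname(lens[1])),
            class = "protein_msa")
}

#' @export
print.protein_msa <- function(x, ...) {
  cat(sprintf("<protein_msa> %d sequences x %d columns\n",
              length(x$records), x$n_columns))
  invisible(x)
}

#' Alignment as character matrix
#'
#' @param msa A [protein_msa()].
#' @return Character matrix, rows named by record id, one column per
#'   alignment column.
#' @export
msa_matrix <- function(msa) {
  stopifnot(inherits(msa, "protein_msa"))
  m <- do.call(rbind, lapply(msa$records, function(r) .chars(r$sequence)))
  rownames(m) <- names(msa$records)
  m
}

.msa_from_matrix <- function(m) {
  protein_msa(lapply(rownames(m), function(id)
    protein_record(id, paste(m[id, ], collapse = ""))))
}

#' Read an aligned FASTA file as a multiple alignment
#'
#' @param path Path to aligned FASTA.
#' @return A [protein_msa()].
#' @export
read_alignment <- function(path) protein_msa(read_fasta(path))

#' Write a multiple alignment as aligned FASTA
#'
#' @param msa A [protein_msa()].
#' @param path Output path.
#' @param line_width Residues per line.
#' @export
write_alignment <- function(msa, path, line_width = 60) {
  stopifnot(inherits(msa, "protein_msa"))
  write_fasta(msa$records, path, line_width)
}
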