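# Candidate screening: conserved motifs, signal peptide heuristic, lid
# extraction against an annotated reference, and the combined
# accept/reject report.
#
# The versatile-lipase family carries two signature motifs: the oxyanion
# hole region (G-G-G-[F/L]) and the catalytic serine (G-[E/Q]-S-A-G, a
# GxSxG-type nucleophile elbow).  Candidates are screened on four
# criteria: identity to an annotated reference lipase, presence of a
# predicted signal peptide, presence of both motifs, and a minimum lid
# length measured by alignment to the reference lid.

#' Find conserved lipase motifs
#'
#' Reports all non-overlapping, left-to-right occurrences of the oxyanion
#' hole pattern (default `GGG[FL]`) and the catalytic serine pattern
#' (default `G[EQ]SAG`).
#'
#' @param record A [protein_record()] or ungapped string.
#' @param oxyanion,catalytic Regular expressions for the two motif classes.
#' @return Object of class `motif_hits`: data frames `oxyanion` and
#'   `catalytic` with 1-based `position` and `match` columns.
#' @export
find_motifs <- function(record, oxyanion = "GGG[FL]", catalytic = "G[EQ]SAG") {
  s <- .seq_of(record)
  if (grepl("-", s, fixed = TRUE)) stop("sequence must be ungapped")
  one <- function(pat) {
    m <- gregexpr(pat, s)[[1]]
    if (m[1] == -1L)
      return(data.frame(position = integer(), match = character()))
    data.frame(position = as.integer(m),
               match = substring(s, m, m + attr(m, "match.length") - 1L))
  }
  structure(list(oxyanion = one(oxyanion), catalytic = one(catalytic)),
            class = "motif_hits")
}

#' @export
print.motif_hits <- function(x, ...) {
  cat(sprintf("<motif_hits> oxyanion: %d, catalytic: %d\n",
              nrow(x$oxyanion), nrow(x$catalytic)))
  invisible(x)
}

#' Heuristic signal peptide prediction
#'
#' A transparent stand-in for a dedicated predictor: a signal peptide is
#' called when the sequence starts with M and some 8-residue window within
#' the first 35 residues has mean Kyte-Doolittle hydropathy >= 1.6 (the
#' hydrophobic h-region).  The cleavage site guess is the end of the best
#' window plus 5, capped at residue 40.  Externally computed calls can be
#' injected into [screen_candidates()] instead.
#'
#' @param record A [protein_record()] or ungapped string.
#' @param window H-region window width (residues).
#' @param search_within Windows must end within this many N-terminal
#'   residues.
#' @param min_hydropathy Mean-hydropathy threshold for the h-region.
#' @return Object of class `signal_peptide_call`: `present`,
#'   `h_region_score` (mean hydropathy of the best window),
#'   `cleavage_guess` (or `NA`), and `reason` for negative calls.
#' @export
predict_signal_peptide <- function(record, window = 8, search_within = 35,
                                   min_hydropathy = 1.6) {
  s <- .seq_of(record)
  if (grepl("-", s, fixed = TRUE)) stop("sequence must be ungapped")
  n <- nchar(s)
  if (n < 25)
    return(structure(list(present = FALSE, h_region_score = -Inf,
                          cleavage_guess = NA_integer_,
                          reason = "too_short"),
                     class = "signal_peptide_call"))
  ch <- .chars(s)
  h <- unname(KD_HYDROPATHY[ch])
  h[is.na(h)] <- 0  # X
  last_start <- min(search_within, n) - window + 1L
  means <- vapply(seq_len(last_start), function(i)
    mean(h[i:(i + window - 1L)]), 0)
  best <- which.max(means)
  score <- means[best]
  present <- ch[1] == "M" && score >= min_hydropathy
  structure(list(present = present, h_region_score = score,
                 cleavage_guess = if (present)
                   min(best + window - 1L + 5L, 40L) else NA_integer_,
                 reason = if (present) NA_character_
                          else if (ch[1] != "M") "no_initial_methionine"
                          else "h_region_below_threshold"),
            class = "signal_peptide_call")
}

#' @export
print.signal_peptide_call <- function(x, ...) {
  cat(sprintf("<signal_peptide_call> present: %s (h-region %.2f%s)\n",
              x$present, x$h_region_score,
              if (x$present) sprintf(", cleavage ~%d", x$cleavage_guess)
              else sprintf(", %s", x$reason)))
  invisible(x)
}

# Lid mapping given a precomputed candidate/reference alignment.
.lid_from_alignment <- function(aln, lid_interval) {
  cb <- .chars(aln$gapped_b)            # reference row
  ca <- .chars(aln$gapped_a)            # candidate row
  ref_pos <- cumsum(cb != "-")
  ref_pos[cb == "-"] <- NA
  start_col <- match(lid_interval[1], ref_pos)
  end_col <- match(lid_interval[2], ref_pos)
  if (is.na(start_col) || is.na(end_col))
    stop("reference lid interval outside the alignment")
  cols <- start_col:end_col
  in_lid <- ca[cols] != "-"
  cand_pos <- cumsum(ca != "-")
  if (!any(in_lid))
    return(list(sequence = "", start = NA_integer_, end = NA_integer_,
                length = 0L))
  pos <- cand_pos[cols][in_lid]
  list(sequence = paste(ca[cols][in_lid], collapse = ""),
       start = pos[1], end = pos[length(pos)], length = length(pos))
}

#' Extract a candidate's lid region by alignment to a reference
#'
#' Globally aligns the candidate to a reference lipase whose `lid` feature
#' is annotated, and returns the candidate residues that fall within the
#' reference lid columns (gaps excluded).
#'
#' @param candidate A [protein_record()] or ungapped string.
#' @param reference A [protein_record()] carrying a `lid` feature.
#' @inheritParams global_align
#' @return List with `sequence`, 1-based `start`/`end` in candidate
#'   coordinates (`NA` when empty) and `length`.
#' @export
extract_lid <- function(candidate, reference, matrix = "BLOSUM62",
                        gap_open = 10, gap_extension = 0.5) {
  if (!inherits(reference, "protein_record") ||
      is.null(reference$features$lid))
    stop("reference must be a protein_record with a 'lid' feature")
  aln <- global_align(candidate, reference, matrix = matrix,
                      gap_open = gap_open, gap_extension = gap_extension)
  .lid_from_alignment(aln, reference$features$lid)
}

#' Screening configuration
#'
#' @param min_identity Minimum fraction identity to the reference
#'   (default 0.30).
#' @param min_lid Minimum lid length in residues (default 20; candidates
#'   with fewer lid residues lack the helix-forming flap).
#' @param min_length,max_length Optional whole-sequence length bounds
#'   (default: no length filter).
#' @param oxyanion,catalytic Motif patterns, as in [find_motifs()].
#' @param matrix,gap_open,gap_extension Alignment scoring parameters.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(min_identity = 0.30, min_lid = 20,
                          min_length = NULL, max_length = NULL,
                          oxyanion = "GGG[FL]", catalytic = "G[EQ]SAG",
                          matrix = "BLOSUM62", gap_open = 10,
                          gap_extension = 0.5) {
  stopifnot(min_identity >= 0, min_identity <= 1, min_lid >= 0)
  structure(list(min_identity = min_identity, min_lid = min_lid,
                 min_length = min_length, max_length = max_length,
                 oxyanion = oxyanion, catalytic = catalytic,
                 matrix = matrix, gap_open = gap_open,
                 gap_extension = gap_extension),
            class = "screen_config")
}

#' Screen candidate sequences against the versatile-lipase criteria
#'
#' Applies, in a fixed reporting order: identity to the reference,
#' predicted signal peptide, presence of both conserved motifs, lid length,
#' and (optionally) sequence length bounds.  All criteria are always
#' evaluated; the fixed order only stabilises the `reasons` column.
#'
#' @param records List of ungapped [protein_record()] objects.
#' @param reference A [protein_record()] with a `lid` feature.
#' @param config A [screen_config()].
#' @param signal_flags Optional named logical vector of externally computed
#'   signal-peptide calls, overriding the built-in heuristic per id.
#' @return Object of class `screening_report`: `table` (one row per
#'   candidate with id, identity, signal call, motif counts, lid length,
#'   decision and semicolon-joined reasons) and `summary` (counts per
#'   reason plus accepted/rejected totals).
#' @export
screen_candidates <- function(records, reference, config = screen_config(),
                              signal_flags = NULL) {
  records <- .record_list(records)
  if (length(records) == 0L) stop("no candidate records")
  if (!inherits(reference, "protein_record") ||
      is.null(reference$features$lid))
    stop("reference must be a protein_record with a 'lid' feature")
  stopifnot(inherits(config, "screen_config"))
  lid_iv <- reference$features$lid

  rows <- lapply(records, function(r) {
    aln <- global_align(r, reference, matrix = config$matrix,
                        gap_open = config$gap_open,
                        gap_extension = config$gap_extension)
    sp <- if (!is.null(signal_flags) && r$id %in% names(signal_flags))
      isTRUE(signal_flags[[r$id]])
    else predict_signal_peptide(r)$present
    mh <- find_motifs(r, config$oxyanion, config$catalytic)
    lid <- .lid_from_alignment(aln, lid_iv)
    n <- nchar(r$sequence)
    reasons <- character()
    if (aln$identity < config$min_identity) reasons <- c(reasons, "low_identity")
    if (!sp) reasons <- c(reasons, "no_signal_peptide")
    if (nrow(mh$oxyanion) == 0L) reasons <- c(reasons, "missing_oxyanion_motif")
    if (nrow(mh$catalytic) == 0L) reasons <- c(reasons, "missing_catalytic_motif")
    if (lid$length < config$min_lid) reasons <- c(reasons, "lid_too_short")
    if (!is.null(config$min_length) && n < config$min_length)
      reasons <- c(reasons, "too_short")
    if (!is.null(config$max_length) && n > config$max_length)
      reasons <- c(reasons, "too_long")
    data.frame(id = r$id, identity = aln$identity, signal_peptide = sp,
               n_oxyanion = nrow(mh$oxyanion), n_catalytic = nrow(mh$catalytic),
               lid_length = lid$length,
               decision = if (length(reasons)) "rejected" else "accepted",
               reasons = paste(reasons, collapse = ";"))
  })
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))
  all_reasons <- unlist(strsplit(tab$reasons[nzchar(tab$reasons)], ";"))
  structure(list(
    table = tab,
    summary = list(n = nrow(tab),
                   accepted = sum(tab$decision == "accepted"),
                   rejected = sum(tab$decision == "rejected"),
                   by_reason = as.list(table(all_reasons))),
    config = config),
    class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report> %d candidates: %d accepted, %d rejected\n",
              x$summary$n, x$summary$accepted, x$summary$rejected))
  if (length(x$summary$by_reason))
    for (r in names(x$summary$by_reason))
      cat(sprintf("  %-26s %d\n", r, x$summary$by_reason[[r]]))
  invisible(x)
}

#' Accepted record ids of a screening report
#' @param report A `screening_report`.
#' @return Character vector of accepted ids.
#' @export
accepted_ids <- function(report) {
  stopifnot(inherits(report, "screening_report"))
  report$table$id[report$table$decision == "accepted"]
}

#' Write a screening report
#'
#' The per-candidate table goes to TSV; the summary to JSON alongside
#' (same path with extension `.json`) when `summary = TRUE`.
#'
#' @param report A `screening_report`.
#' @param path Output TSV path.
#' @param summary Also write the JSON summary.
#' @export
write_screening_report <- function(report, path, summary = TRUE) {
  stopifnot(inherits(report, "screening_report"))
  write.table(report$table, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (summary)
    jsonlite::write_json(report$summary,
                         sub("\\.tsv$", ".json", path, ignore.case = TRUE),
                         auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
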