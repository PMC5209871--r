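# End-to-end orchestration: screen -> align -> tree -> root -> ancestral
# reconstruction -> lid trajectory -> habitat statistics, writing every
# intermediate artifact plus a machine-readable run manifest.  Each stage
# consumes and produces files/objects, so any stage can be replaced by an
# external tool's output (e.g. a precomputed alignment or tree).

#' Pipeline configuration
#'
#' @param min_identity,min_lid Screening thresholds (see [screen_config()]).
#' @param frequency_mode Model frequencies for tree building and
#'   reconstruction (`"empirical_plus_F"` or `"wag_default"`).
#' @param thresholds Posterior thresholds for lid trimming.
#' @param hydrophobic_set Residues counted as hydrophobic.
#' @param gap_open,gap_extension Alignment gap penalties.
#' @param optimize_branches Re-optimise NJ branch lengths by ML.
#' @param outgroup Tip id to root on, or `NULL` to use the most divergent
#'   sequence (largest mean ML distance).
#' @param seed RNG seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed feeds optional bootstrap resampling).
#' @param bootstrap Number of bootstrap replicates (0 = skip).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(min_identity = 0.30, min_lid = 20,
                            frequency_mode = "empirical_plus_F",
                            thresholds = c(0.65, 0.70, 0.75, 0.80, 0.85, 0.90),
                            hydrophobic_set = KD_HYDROPHOBIC,
                            gap_open = 10, gap_extension = 0.5,
                            optimize_branches = TRUE, outgroup = NULL,
                            seed = 1, bootstrap = 0) {
  stopifnot(all(thresholds > 0), all(thresholds <= 1),
            min_identity >= 0, min_identity <= 1)
  structure(list(min_identity = min_identity, min_lid = min_lid,
                 frequency_mode = frequency_mode, thresholds = thresholds,
                 hydrophobic_set = hydrophobic_set, gap_open = gap_open,
                 gap_extension = gap_extension,
                 optimize_branches = optimize_branches,
                 outgroup = outgroup, seed = seed, bootstrap = bootstrap),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full lid-evolution pipeline
#'
#' Screens the candidates, aligns the accepted set together with the
#' reference, fits the WAG(+F) model, builds the ML-distance NJ tree,
#' roots it on the outgroup (by default the most divergent sequence),
#' optionally re-optimises branch lengths, reconstructs ancestral
#' sequences, computes the lid trajectory across posterior thresholds,
#' and (when a habitat table is supplied) summarises lipase counts per
#' habitat with a wood-vs-ectomycorrhizal/parasite comparison.
#'
#' @param records Candidate records: a list of [protein_record()] or a
#'   FASTA path.
#' @param reference A [protein_record()] with a `lid` feature, or a FASTA
#'   path whose first record carries the lid via `lid_interval`.
#' @param out_dir Output directory for artifacts.
#' @param config A [pipeline_config()].
#' @param msa Optional precomputed alignment ([protein_msa()] or aligned
#'   FASTA path) containing the accepted candidates and the reference.
#' @param tree Optional precomputed tree (`phylo` or Newick path).
#' @param habitat Optional habitat table (data frame or TSV path; see
#'   [read_habitat_table()]).
#' @param lid_interval 1-based inclusive lid interval when `reference` is
#'   a path without features.
#' @return Invisibly, a list with every stage's object (`screening`,
#'   `msa`, `model`, `tree`, `asr`, `trajectory`, `stats`) and the
#'   artifact `paths`.
#' @export
run_pipeline <- function(records, reference, out_dir,
                         config = pipeline_config(), msa = NULL,
                         tree = NULL, habitat = NULL, lid_interval = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  input_path <- if (is.character(records)) records else NULL

  if (is.character(records)) records <- read_fasta(records)
  if (is.character(reference)) {
    ref_recs <- read_fasta(reference)
    reference <- ref_recs[[1]]
    if (!is.null(lid_interval))
      reference <- protein_record(reference$id, reference$sequence,
                                  features = list(lid = lid_interval))
  }

  screening <- .stage("screening", {
    if (!inherits(reference, "protein_record") ||
        is.null(reference$features$lid))
      stop("reference with an annotated lid is required")
    screen_candidates(records, reference,
                      screen_config(min_identity = config$min_identity,
                                    min_lid = config$min_lid,
                                    gap_open = config$gap_open,
                                    gap_extension = config$gap_extension))
  })
  paths$screening <- file.path(out_dir, "screening.tsv")
  write_screening_report(screening, paths$screening)

  acc <- accepted_ids(screening)
  if (length(acc) < 3)
    stop(sprintf("stage 'screening' failed: only %d candidates accepted; need >= 3",
                 length(acc)), call. = FALSE)

  aln <- .stage("alignment", {
    if (is.null(msa)) {
      progressive_msa(c(records[acc], list(reference)),
                      gap_open = config$gap_open,
                      gap_extension = config$gap_extension)
    } else {
      if (is.character(msa)) msa <- read_alignment(msa)
      missing <- setdiff(c(acc, reference$id), names(msa$records))
      if (length(missing))
        stop(sprintf("supplied alignment lacks: %s",
                     paste(missing, collapse = ", ")))
      msa
    }
  })
  paths$alignment <- file.path(out_dir, "alignment.fasta")
  write_alignment(aln, paths$alignment)

  model <- .stage("model", build_wag_model(config$frequency_mode, aln))

  phy <- .stage("tree", {
    if (is.null(tree)) {
      D <- distance_matrix(aln, model)
      nj <- neighbor_joining(D)
      og <- config$outgroup
      if (is.null(og)) og <- names(which.max(rowMeans(D)))
      rooted <- root_with_outgroup(nj, og)
      if (config$optimize_branches)
        rooted <- optimize_branch_lengths(rooted, aln, model)$tree
      rooted
    } else {
      if (is.character(tree)) tree <- read_newick(tree)
      tree
    }
  })
  paths$tree <- file.path(out_dir, "tree.nwk")
  write_newick(phy, paths$tree)

  boot <- NULL
  if (config$bootstrap > 0)
    boot <- .stage("bootstrap",
                   bootstrap_support(aln, model, n_reps = config$bootstrap,
                                     seed = config$seed))
  if (!is.null(boot)) {
    paths$bootstrap <- file.path(out_dir, "bootstrap.tsv")
    write.table(boot$support, paths$bootstrap, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  fit <- .stage("asr", reconstruct_ancestors(phy, aln, model))
  paths$ancestors <- file.path(out_dir, "ancestors.fasta")
  write_asr_fasta(fit, paths$ancestors)
  paths$posteriors <- file.path(out_dir, "posteriors")
  write_posteriors(fit, paths$posteriors)

  trajectory <- .stage("lid", {
    cols <- lid_columns(aln, reference$id, lid = reference$features$lid)
    lid_trajectory(fit, cols, thresholds = config$thresholds,
                   hydrophobic_set = config$hydrophobic_set)
  })
  paths$trajectory <- file.path(out_dir, "lid_trajectory.tsv")
  write_trajectory(trajectory, paths$trajectory)

  stats <- NULL
  if (!is.null(habitat)) {
    stats <- .stage("stats", {
      if (is.character(habitat)) habitat <- read_habitat_table(habitat)
      gs <- group_summary(habitat)
      cmp <- NULL
      if (all(c("wood", "ecto_parasite") %in% habitat$habitat)) {
        w <- habitat$lipase_count[habitat$habitat == "wood"]
        e <- habitat$lipase_count[habitat$habitat == "ecto_parasite"]
        if (length(w) >= 2 && length(e) >= 2) cmp <- compare_groups(w, e)
      }
      list(groups = gs, comparison = cmp)
    })
    paths$stats <- file.path(out_dir, "habitat_stats.json")
    jsonlite::write_json(list(
      groups = stats$groups,
      comparison = if (is.null(stats$comparison)) NULL else
        stats$comparison[c("method", "statistic", "p_value")]),
      paths$stats, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  manifest <- list(
    package = "lidasr",
    version = as.character(packageVersion("lidasr")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = config[setdiff(names(config), "hydrophobic_set")],
    hydrophobic_set = paste(config$hydrophobic_set, collapse = ""),
    n_candidates = length(records),
    n_accepted = length(acc),
    input_md5 = if (!is.null(input_path))
      unname(tools::md5sum(input_path)) else NULL,
    artifact_md5 = local({
      fs <- unlist(paths[vapply(paths, is.character, TRUE)])
      as.list(tools::md5sum(fs[file_test("-f", fs)]))
    }))
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(screening = screening, msa = aln, model = model,
                 tree = phy, bootstrap = boot, asr = fit,
                 trajectory = trajectory, stats = stats, paths = paths))
}
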