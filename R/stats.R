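# Habitat-group summaries of per-genome lipase counts and the two-group
# comparison.  The "mean +/- value" presentation is mean +/- SEM (standard
# error of the mean, sample SD / sqrt(n)).

#' Read a habitat table
#'
#' TSV with columns `genome_id`, `habitat` and `lipase_count`.
#'
#' @param path Path to the TSV.
#' @return Validated data frame.
#' @export
read_habitat_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "habitat", "lipase_count")
  if (!all(need %in% names(tab)))
    stop(sprintf("habitat table must have columns: %s",
                 paste(need, collapse = ", ")))
  if (anyDuplicated(tab$genome_id)) stop("duplicate genome_id in habitat table")
  if (any(tab$lipase_count < 0) || any(tab$lipase_count != round(tab$lipase_count)))
    stop("lipase_count must be non-negative integers")
  tab
}

#' Per-habitat summary of lipase counts
#'
#' @param table Data frame with columns `habitat` and `lipase_count` (e.g.
#'   from [read_habitat_table()]).
#' @return Data frame with one row per habitat: `n`, `mean`, `sem`
#'   (sample SD / sqrt(n), `NA` when n = 1) and the conventional
#'   `mean +/- SEM` presentation to two decimals.
#' @export
group_summary <- function(table) {
  if (!all(c("habitat", "lipase_count") %in% names(table)))
    stop("table must have 'habitat' and 'lipase_count' columns")
  if (nrow(table) == 0L) stop("empty table")
  sp <- split(table$lipase_count, table$habitat)
  out <- do.call(rbind, lapply(names(sp), function(h) {
    x <- sp[[h]]
    sem <- if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_
    data.frame(habitat = h, n = length(x), mean = mean(x), sem = sem,
               formatted = if (is.na(sem)) sprintf("%.2f", mean(x))
                           else sprintf("%.2f ± %.2f", mean(x), sem))
  }))
  out[order(out$habitat), , drop = FALSE]
}

# Welch's t statistic and two-sided p, robust to zero-variance input.
.welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(statistic = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
                p.value = if (eq) 1 else 0,
                df = NA_real_))
  }
  tt <- t.test(a, b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       df = unname(tt$parameter))
}

#' Compare lipase counts between two habitat groups
#'
#' Default: two-sided Welch's t-test (unequal variances).  Alternative: a
#' permutation test on the difference of group means, exact when the
#' number of reassignments is small enough to enumerate and otherwise
#' Monte Carlo with `n_perm` seeded resamples.
#'
#' @param a,b Numeric vectors of per-genome counts (each of length >= 2).
#' @param method `"welch"` or `"permutation"`.
#' @param n_perm Monte Carlo resamples for the permutation test.
#' @param seed Optional RNG seed for the Monte Carlo permutation test.
#' @return List of class `group_comparison`: `statistic` (Welch t, or the
#'   observed mean difference for the permutation test), `p_value`,
#'   `method`, and the group means.
#' @export
compare_groups <- function(a, b, method = c("welch", "permutation"),
                           n_perm = 1e5, seed = NULL) {
  method <- match.arg(method)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations")
  if (method == "welch") {
    w <- .welch(a, b)
    out <- list(statistic = w$statistic, p_value = w$p.value, df = w$df,
                method = "welch")
  } else {
    pool <- c(a, b)
    na <- length(a); n <- length(pool)
    obs <- mean(a) - mean(b)
    tot <- sum(pool)
    if (choose(n, na) <= 2e5) {
      idx <- combn(n, na)
      ma <- colSums(matrix(pool[idx], nrow = na)) / na
      mb <- (tot - ma * na) / (n - na)
      d <- ma - mb
      p <- mean(abs(d) >= abs(obs) - 1e-12)
      exact <- TRUE
    } else {
      if (!is.null(seed)) set.seed(seed)
      d <- replicate(n_perm, {
        i <- sample.int(n, na)
        mean(pool[i]) - mean(pool[-i])
      })
      p <- (1 + sum(abs(d) >= abs(obs) - 1e-12)) / (1 + n_perm)
      exact <- FALSE
    }
    out <- list(statistic = obs, p_value = p, method = "permutation",
                exact = exact)
  }
  out$mean_a <- mean(a); out$mean_b <- mean(b)
  structure(out, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic %.4g, P = %.4g\n",
              x$method, x$statistic, x$p_value))
  cat(sprintf("  group means: %.2f vs %.2f\n", x$mean_a, x$mean_b))
  invisible(x)
}
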