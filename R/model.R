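# The WAG(+F) amino-acid substitution model.
#
# A model bundles the symmetric exchangeability matrix S, the equilibrium
# frequencies pi, and the rate matrix Q with Q_ij = S_ij * pi_j (i != j),
# rows summing to zero and scaled to one expected substitution per site
# (-sum_i pi_i Q_ii = 1).  Transition probabilities P(t) = exp(Qt) are
# computed through the symmetric eigendecomposition of
# diag(sqrt(pi)) Q diag(1/sqrt(pi)), which is numerically stable for
# reversible models.

.wag_env <- new.env(parent = emptyenv())

#' Read an exchangeability/frequency table
#'
#' Parses the plain-text model layout shipped in
#' `inst/extdata/wag.dat`: comment lines starting with `#`, 19 lines of
#' lower-triangular exchangeabilities, and one line of 20 equilibrium
#' frequencies, all in [AA_ALPHABET] order.
#'
#' @param path Path to the table.
#' @return List with `S` (symmetric 20x20 matrix) and `pi` (length 20).
#' @export
read_rate_table <- function(path) {
  ln <- readLines(path)
  ln <- trimws(ln[!grepl("^\\s*#", ln)])
  ln <- ln[nzchar(ln)]
  if (length(ln) != 20L)
    stop("expected 19 exchangeability lines plus one frequency line")
  S <- matrix(0, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  for (i in 2:20) {
    v <- as.numeric(strsplit(ln[i - 1L], "\\s+")[[1]])
    if (length(v) != i - 1L) stop(sprintf("bad exchangeability row %d", i))
    S[i, 1:(i - 1L)] <- v
  }
  S <- S + t(S)
  pi <- as.numeric(strsplit(ln[20], "\\s+")[[1]])
  if (length(pi) != 20L) stop("bad frequency line")
  list(S = S, pi = setNames(pi, AA_ALPHABET))
}

.wag_table <- function() {
  if (is.null(.wag_env$tab))
    .wag_env$tab <- read_rate_table(system.file("extdata", "wag.dat",
                                                package = "lidasr"))
  .wag_env$tab
}

#' Construct a reversible amino-acid substitution model
#'
#' @param S Symmetric 20x20 exchangeability matrix (non-negative
#'   off-diagonals; the diagonal is ignored).
#' @param pi Length-20 equilibrium frequency vector (strictly positive; it
#'   is renormalised to sum to 1).
#' @return An object of class `aa_subst_model` with fields `S`, `pi`, `Q`
#'   plus the cached eigendecomposition used by [transition_matrix()].
#' @export
substitution_model <- function(S, pi) {
  stopifnot(is.matrix(S), dim(S) == c(20, 20))
  if (max(abs(S - t(S))) > 1e-8) stop("exchangeability matrix must be symmetric")
  if (any(pi <= 0)) stop("equilibrium frequencies must be strictly positive")
  pi <- pi / sum(pi)
  diag(S) <- 0
  Q <- S * rep(pi, each = 20)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  if (mu <= 0) stop("degenerate rate matrix")
  Q <- Q / mu
  sp <- sqrt(pi)
  B <- Q * outer(sp, 1 / sp)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  structure(list(S = S, pi = setNames(pi, AA_ALPHABET), Q = Q,
                 U = e$vectors, lambda = e$values, sp = sp),
            class = "aa_subst_model")
}

#' @export
print.aa_subst_model <- function(x, ...) {
  cat("<aa_subst_model> reversible 20-state amino-acid model\n")
  cat(sprintf("  expected rate 1; top frequencies: %s\n",
              paste(sprintf("%s=%.3f", names(sort(x$pi, decreasing = TRUE))[1:3],
                            sort(x$pi, decreasing = TRUE)[1:3]),
                    collapse = ", ")))
  invisible(x)
}

#' Observed amino-acid frequencies of an alignment
#'
#' Counts every non-gap, non-`X` character, floors each frequency at 1e-4
#' and renormalises (the floor keeps `+F` models invertible when a residue
#' is absent from the alignment).
#'
#' @param alignment A [protein_msa()].
#' @return Length-20 frequency vector in [AA_ALPHABET] order, summing to 1.
#' @export
empirical_frequencies <- function(alignment) {
  stopifnot(inherits(alignment, "protein_msa"))
  ch <- unlist(lapply(alignment$records, function(r) .chars(r$sequence)),
               use.names = FALSE)
  cnt <- table(factor(ch, levels = AA_ALPHABET))
  if (sum(cnt) == 0L) stop("alignment contains no amino-acid characters")
  f <- as.numeric(cnt) / sum(cnt)
  f <- pmax(f, 1e-4)
  setNames(f / sum(f), AA_ALPHABET)
}

#' Build the WAG or WAG+F substitution model
#'
#' `"wag_default"` uses the equilibrium frequencies published with the WAG
#' matrix; `"empirical_plus_F"` replaces them with the frequencies observed
#' in `alignment` (the `+F` option).
#'
#' @param frequency_mode `"wag_default"` or `"empirical_plus_F"`.
#' @param alignment A [protein_msa()]; required for `"empirical_plus_F"`.
#' @return An `aa_subst_model`.
#' @export
build_wag_model <- function(frequency_mode = c("wag_default",
                                               "empirical_plus_F"),
                            alignment = NULL) {
  frequency_mode <- match.arg(frequency_mode)
  tab <- .wag_table()
  pi <- if (frequency_mode == "empirical_plus_F") {
    if (is.null(alignment))
      stop("empirical_plus_F requires an alignment")
    empirical_frequencies(alignment)
  } else tab$pi
  substitution_model(tab$S, pi)
}

#' Transition probability matrix P(t)
#'
#' @param model An `aa_subst_model`.
#' @param t Branch length in expected substitutions per site (`t >= 0`).
#' @return 20x20 stochastic matrix; entry (i, j) is the probability of
#'   ending in state j after time t having started in state i.
#' @export
transition_matrix <- function(model, t) {
  stopifnot(inherits(model, "aa_subst_model"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("branch length t must be a single non-negative number")
  E <- model$U * rep(exp(model$lambda * t), each = 20)
  P <- E %*% t(model$U)
  P <- P * outer(1 / model$sp, model$sp)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(AA_ALPHABET, AA_ALPHABET)
  P
}
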