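#' AIC and Akaike weights for a set of fitted models
#'
#' `AIC = 2k - 2 lnL`; `dAIC` is the difference to the best model and the
#' Akaike weight is `exp(-dAIC/2)` normalized over the compared set.
#'
#' @param fits List of `dec_fit` objects, or a data frame with columns
#'   `model`, `lnL`, `k`.
#' @return Data frame (`model`, `lnL`, `k`, `AIC`, `dAIC`, `w`) sorted by
#'   AIC, best model first.
#' @export
aic_table <- function(fits) {
  if (is.data.frame(fits)) {
    df <- fits[, c("model", "lnL", "k")]
  } else {
    df <- do.call(rbind, lapply(fits, function(f)
      data.frame(model = f$model, lnL = f$lnL, k = f$k, stringsAsFactors = FALSE)))
  }
  if (nrow(df) < 2L) stop("need at least 2 fits to compare")
  if (any(!is.finite(df$lnL))) stop("non-finite log-likelihood in fit set")
  df$AIC <- 2 * df$k - 2 * df$lnL
  df$dAIC <- df$AIC - min(df$AIC)
  df$w <- exp(-df$dAIC / 2) / sum(exp(-df$dAIC / 2))
  df <- df[order(df$AIC), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Harmonic-mean estimate of the log marginal likelihood
#'
#' The harmonic-mean estimator over post-burn-in log-likelihood samples,
#' `lnML = -(logsumexp(-lnL_i) - ln n)`, computed in a numerically
#' stabilized way. The standard error is obtained by a moving-block
#' bootstrap (block length `ceiling(sqrt(n))`, `n_boot` resamples, private
#' fixed seed) because MCMC traces are autocorrelated. The estimator is
#' known to be unstable when the likelihood has lighter tails than the
#' prior; a top-truncation variant that drops the `trim` smallest
#' log-likelihoods is available but off by default.
#'
#' @param trace An `mcmc_trace`, or a numeric vector of lnL samples.
#' @param n_boot Bootstrap resamples for the SE (default 1000).
#' @param trim Fraction (0 to <1) of the smallest lnL samples to drop before
#'   estimation (default 0, the plain estimator).
#' @param boot_seed Seed of the private bootstrap RNG stream.
#' @return A `marginal_likelihood`: list with `lnML`, `SE`, `n_samples`,
#'   `estimator`.
#' @export
harmonic_mean_lnml <- function(trace, n_boot = 1000L, trim = 0,
                               boot_seed = 1L) {
  x <- if (inherits(trace, "mcmc_trace")) trace_lnl(trace) else as.numeric(trace)
  if (length(x) < 10L) stop("need at least 10 post-burn-in samples")
  if (any(!is.finite(x))) stop("non-finite lnL sample")
  if (trim < 0 || trim >= 1) stop("trim must be in [0, 1)")
  if (trim > 0) x <- sort(x, decreasing = TRUE)[seq_len(ceiling((1 - trim) * length(x)))]
  hm <- function(v) -(logsumexp(-v) - log(length(v)))
  n <- length(x)
  b <- ceiling(sqrt(n))
  nblk <- ceiling(n / b)
  starts_max <- n - b + 1L
  se <- with_private_seed(boot_seed, {
    reps <- vapply(seq_len(n_boot), function(i) {
      s <- sample.int(starts_max, nblk, replace = TRUE)
      idx <- as.vector(outer(0:(b - 1L), s, `+`))[seq_len(n)]
      hm(x[idx])
    }, numeric(1))
    sd(reps)
  })
  structure(list(lnML = hm(x), SE = se, n_samples = n,
                 estimator = if (trim > 0) "harmonic-mean (trimmed)" else "harmonic-mean"),
            class = "marginal_likelihood")
}

#' @export
print.marginal_likelihood <- function(x, ...) {
  cat(sprintf("lnML = %.2f +- %.2f (%s, n = %d)\n",
              x$lnML, x$SE, x$estimator, x$n_samples))
  invisible(x)
}

#' Log10 Bayes factor from two log marginal likelihoods
#'
#' @param lnml_a,lnml_b Log marginal likelihoods in nats.
#' @return `(lnml_a - lnml_b) / ln(10)`; positive values favour model a.
#' @export
log10_bf <- function(lnml_a, lnml_b) {
  if (!is.finite(lnml_a) || !is.finite(lnml_b)) stop("non-finite lnML")
  (lnml_a - lnml_b) / log(10)
}

#' Support category of a log10 Bayes factor
#'
#' Conventional thresholds: above 0.48 substantial (`*`), above 1.00 strong
#' (`**`), above 1.48 very strong (`***`); anything at or below 0.48
#' (including all negative values) is unsupported.
#'
#' @param x Log10 Bayes factor(s).
#' @return Character vector in `none`, `substantial`, `strong`,
#'   `very strong`; star marks in attribute `"stars"`.
#' @export
bf_category <- function(x) {
  if (any(!is.finite(x))) stop("non-finite log10 BF")
  cat <- ifelse(x > 1.48, "very strong",
         ifelse(x > 1.00, "strong",
         ifelse(x > 0.48, "substantial", "none")))
  structure(cat, stars = c(none = "", substantial = "*", strong = "**",
                           `very strong` = "***")[cat])
}

#' Pairwise log10 Bayes-factor matrix
#'
#' Builds the pairwise comparison table of a set of models from their log
#' marginal likelihoods: entry (i, j) is `log10_bf(lnML_i, lnML_j)`, so the
#' matrix is antisymmetric with an empty diagonal. Categories are computed
#' on the unrounded values; printing rounds half-up to 2 decimals and
#' appends the star marks.
#'
#' @param lnml Named numeric vector of log marginal likelihoods (names are
#'   the model labels), or a list of `marginal_likelihood` objects with a
#'   `labels` argument.
#' @param labels Model labels when `lnml` is a list.
#' @return A `bf_matrix`: list with `log10bf` (numeric matrix), `category`
#'   (character matrix), `lnml`.
#' @export
bf_matrix <- function(lnml, labels = names(lnml)) {
  if (is.list(lnml)) lnml <- vapply(lnml, function(m) m$lnML, numeric(1))
  if (length(lnml) < 2L) stop("need at least 2 models")
  if (is.null(labels) || anyDuplicated(labels)) stop("models need unique labels")
  names(lnml) <- labels
  m <- outer(lnml, lnml, function(a, b) (a - b) / log(10))
  cats <- matrix(as.character(bf_category(as.vector(m))), nrow(m),
                 dimnames = dimnames(m))
  diag(cats) <- ""
  structure(list(log10bf = m, category = cats, lnml = lnml), class = "bf_matrix")
}

#' @export
print.bf_matrix <- function(x, digits = 2, ...) {
  stars <- c(none = "", substantial = "*", strong = "**", `very strong` = "***")
  disp <- matrix("-", nrow(x$log10bf), ncol(x$log10bf),
                 dimnames = dimnames(x$log10bf))
  off <- row(disp) != col(disp)
  disp[off] <- paste0(format(round_half_up(x$log10bf[off], digits), nsmall = digits),
                      stars[x$category[off]])
  print(noquote(disp))
  invisible(x)
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval containing `ceiling(level * n)` of the
#' sorted samples; ties between equal-width windows are broken toward the
#' lowest lower bound.
#'
#' @param samples Numeric vector (at least 20 values).
#' @param level Probability mass, in (0, 1) (default 0.95).
#' @return Numeric `c(lo, hi)`.
#' @export
hpd_interval <- function(samples, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  x <- sort(as.numeric(samples))
  n <- length(x)
  if (n < 20L) stop("need at least 20 samples")
  m <- ceiling(level * n)
  lo <- seq_len(n - m + 1L)
  widths <- x[lo + m - 1L] - x[lo]
  i <- which.min(widths)  # first minimum = lowest lower bound
  c(lo = x[i], hi = x[i + m - 1L])
}
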