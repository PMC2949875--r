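#' Offset-gamma fossil calibration prior
#'
#' A node-age prior equal to a gamma density shifted so that its support
#' starts at the fossil's minimum age (the "lower cut-off"): the density at
#' age `x` is `dgamma(x - offset, shape, scale)` for `x >= offset` and 0
#' below. The shape parameter expresses how far beyond the fossil age the
#' node is expected to lie (mean = offset + shape * scale).
#'
#' @param offset Minimum node age in Ma (the fossil age).
#' @param shape,scale Gamma shape and scale (scale defaults to 1 Ma).
#' @param node Optional node label, e.g. `"MRCA(tipX,tipY)"`.
#' @return An `offset_gamma` object.
#' @export
offset_gamma <- function(offset, shape, scale = 1, node = NULL) {
  if (shape <= 0 || scale <= 0) stop("shape and scale must be positive")
  if (offset < 0) stop("offset must be nonnegative")
  structure(list(offset = offset, shape = shape, scale = scale, node = node),
            class = "offset_gamma")
}

#' @rdname offset_gamma
#' @param x Ages (Ma) at which to evaluate the density.
#' @param prior An `offset_gamma`.
#' @export
doffset_gamma <- function(x, prior) {
  stopifnot(inherits(prior, "offset_gamma"))
  ifelse(x >= prior$offset,
         dgamma(x - prior$offset, shape = prior$shape, scale = prior$scale),
         0)
}

#' @rdname offset_gamma
#' @param n Number of draws.
#' @export
roffset_gamma <- function(n, prior) {
  stopifnot(inherits(prior, "offset_gamma"))
  prior$offset + rgamma(n, shape = prior$shape, scale = prior$scale)
}

#' @export
print.offset_gamma <- function(x, ...) {
  cat(sprintf("offset-gamma calibration%s: offset %.3g Ma, shape %.3g, scale %.3g (mean %.3g Ma)\n",
              if (is.null(x$node)) "" else paste0(" [", x$node, "]"),
              x$offset, x$shape, x$scale, x$offset + x$shape * x$scale))
  invisible(x)
}

#' Default fossil calibration set of the crab dating design
#'
#' Three offset-gamma calibrations: 16.5 Ma (shape 4.0), 6 Ma (shape 2.0)
#' and 2.5 Ma (shape 3.0), all with scale 1 Ma.
#'
#' @return List of `offset_gamma` priors.
#' @export
default_calibrations <- function() {
  list(offset_gamma(16.5, 4.0, 1.0, node = "potamid"),
       offset_gamma(6.0, 2.0, 1.0, node = "potamonautid"),
       offset_gamma(2.5, 3.0, 1.0, node = "gecarcinucid"))
}

#' Read a calibration config (YAML or JSON)
#'
#' Each entry needs `offset` and `shape` and may give `scale` (default 1)
#' and `node`.
#'
#' @param path Path to a YAML (or JSON) file listing calibrations.
#' @return List of `offset_gamma` priors.
#' @export
read_calibrations <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = FALSE)
         else yaml::read_yaml(path)
  lapply(cfg, function(cc)
    offset_gamma(cc$offset, cc$shape,
                 scale = if (is.null(cc$scale)) 1 else cc$scale,
                 node = cc$node))
}

#' Node-age constraint for a temporal hypothesis
#'
#' A normal prior on a node's age with the stated mean and a standard
#' deviation of 20% of the mean, expressing general temporal uncertainty
#' around a hypothesized geological timing (e.g. 45, 35 or 25 Ma).
#'
#' @param mean_age Hypothesized age in Ma (> 0).
#' @param sd_frac SD as a fraction of the mean (default 0.20).
#' @param node Optional node label.
#' @return A `temporal_constraint` with fields `mean`, `sd`.
#' @export
temporal_constraint <- function(mean_age, sd_frac = 0.20, node = NULL) {
  if (mean_age <= 0) stop("mean age must be positive")
  structure(list(mean = mean_age, sd = sd_frac * mean_age, node = node),
            class = "temporal_constraint")
}

#' @rdname temporal_constraint
#' @param x Ages (Ma).
#' @param constraint A `temporal_constraint`.
#' @export
dtemporal <- function(x, constraint) {
  stopifnot(inherits(constraint, "temporal_constraint"))
  dnorm(x, mean = constraint$mean, sd = constraint$sd)
}

#' Substitution-rate prior of the rate-calibrated clock
#'
#' Normal prior on the clock rate (% substitutions per Ma), truncated at 0
#' and renormalized, with default mean 0.88 %/Ma and SD 10% of the mean --
#' the externally calibrated rate used as an alternative to fossil
#' calibration.
#'
#' @param rate Rates (%/Ma) at which to evaluate the density.
#' @param mean,sd Prior mean and SD (%/Ma).
#' @return Density values (0 for `rate <= 0`).
#' @export
dclock_rate <- function(rate, mean = 0.88, sd = 0.1 * mean) {
  z <- pnorm(0, mean, sd, lower.tail = FALSE)  # renormalization over (0, Inf)
  ifelse(rate > 0, dnorm(rate, mean, sd) / z, 0)
}
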