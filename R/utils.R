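#' Round half away from zero
#'
#' Standard "commercial" rounding: halves round away from zero, as in the
#' reporting conventions of most nutrition tables (contrast with R's
#' banker's rounding in [round()]).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded to `digits` decimals.
#' @export
#' @examples
#' round_half_up(8.05, 1)  # 8.1, where round(8.05, 1) gives 8
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# Lognormal parameters (meanlog, sdlog) matching a target mean and sd.
# Degenerate sd = 0 gives a point mass encoded as sdlog = 0.
lnorm_params <- function(mean, sd) {
  stopifnot(mean >= 0, sd >= 0)
  if (mean == 0 || sd == 0) {
    return(list(meanlog = if (mean > 0) log(mean) else -Inf, sdlog = 0))
  }
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

rlnorm_matched <- function(n, mean, sd) {
  if (n == 0L) return(numeric(0))
  p <- lnorm_params(mean, sd)
  if (p$sdlog == 0) return(rep(mean, n))
  stats::rlnorm(n, meanlog = p$meanlog, sdlog = p$sdlog)
}

# Deterministic quantile-grid moments of f(X) for X lognormal(mean, sd);
# used for noise calibration, no RNG involved.
lnorm_pushforward_moments <- function(mean, sd, f, n_grid = 2000L) {
  p <- lnorm_params(mean, sd)
  q <- if (p$sdlog == 0) rep(mean, n_grid) else
    stats::qlnorm((seq_len(n_grid) - 0.5) / n_grid, p$meanlog, p$sdlog)
  y <- f(q)
  list(mean = mean(y), var = stats::var(y) * (n_grid - 1) / n_grid)
}

abort_bad_arg <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "vitdfort_error")
}
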