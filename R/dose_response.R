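#' Saturating intake-status dose-response model
#'
#' The relationship between daily vitamin D intake \eqn{x} (\eqn{\mu}g/day)
#' and serum 25(OH)D \eqn{y} (nmol/L) is modelled by the asymptotic
#' (pseudo-Hill) form
#' \deqn{y = a + b\,(1 - e^{-c x}),}
#' where \eqn{a} is the zero-intake baseline (UV and body stores), \eqn{b}
#' the attainable response span, and \eqn{c} the rate at which the curve
#' approaches its plateau \eqn{a + b}. `dose_response()` builds a model
#' object from known coefficients (e.g. published ones);
#' [fit_dose_response()] estimates them from data.
#'
#' @param a Baseline serum concentration at zero intake, nmol/L.
#' @param b Response span, nmol/L; must be positive.
#' @param c Rate constant, per (\eqn{\mu}g/day); must be positive.
#' @param vcov Optional 3x3 covariance matrix of `(a, b, c)`.
#' @param n Optional number of observations behind the coefficients.
#' @return An object of class `dose_response_fit` with elements `a`, `b`,
#'   `c`, `vcov`, `n`, `plateau` (`a + b`), `plateau_ci` (95% delta-method
#'   interval when `vcov` is available), `converged`, `boundary`.
#' @export
#' @examples
#' m <- dose_response(21.38, 30.77, 2.42)
#' plateau(m)
#' predict_serum(m, c(0, 1.1, 5))
dose_response <- function(a, b, c, vcov = NULL, n = NA_integer_) {
  if (!is.numeric(a) || !is.numeric(b) || !is.numeric(c) ||
      length(a) != 1L || length(b) != 1L || length(c) != 1L) {
    abort_bad_arg("dose_response coefficients must be single numbers")
  }
  if (b <= 0) abort_bad_arg("response span b must be > 0 (got %g)", b)
  if (c <= 0) abort_bad_arg("rate constant c must be > 0 (got %g)", c)
  fit <- structure(
    list(a = a, b = b, c = c, vcov = vcov, n = n,
         plateau = a + b, plateau_ci = c(NA_real_, NA_real_),
         converged = TRUE, boundary = FALSE),
    class = "dose_response_fit"
  )
  if (!is.null(vcov)) fit$plateau_ci <- plateau_ci_delta(fit)
  fit
}

# Delta-method 95% CI on a + b: var = V[a,a] + V[b,b] + 2 V[a,b];
# t quantile when n is known, normal otherwise.
plateau_ci_delta <- function(fit) {
  v <- fit$vcov[1, 1] + fit$vcov[2, 2] + 2 * fit$vcov[1, 2]
  se <- sqrt(max(v, 0))
  q <- if (is.finite(fit$n) && fit$n > 3) stats::qt(0.975, fit$n - 3) else stats::qnorm(0.975)
  fit$plateau + c(-1, 1) * q * se
}

#' Predict serum 25(OH)D from daily intake
#'
#' @param fit A `dose_response_fit`.
#' @param intake Daily vitamin D intake, \eqn{\mu}g/day; nonnegative,
#'   vectorized.
#' @return Predicted serum 25(OH)D, nmol/L; strictly increasing in intake,
#'   bounded in `[a, a + b)`.
#' @export
predict_serum <- function(fit, intake) {
  stopifnot(inherits(fit, "dose_response_fit"))
  if (any(intake < 0)) abort_bad_arg("intake must be nonnegative")
  fit$a - fit$b * expm1(-fit$c * intake)
}

#' Plateau (asymptotic serum concentration) of a dose-response model
#'
#' The serum level the model predicts at unbounded intake, `a + b`.
#'
#' @inheritParams predict_serum
#' @return Plateau concentration, nmol/L.
#' @export
plateau <- function(fit) {
  stopifnot(inherits(fit, "dose_response_fit"))
  fit$a + fit$b
}

#' Intake required to reach a target serum concentration
#'
#' Closed-form inversion of the saturating model:
#' \eqn{x = -\ln(1 - (y - a)/b)/c}. Only targets strictly between the
#' baseline `a` and the plateau `a + b` are attainable.
#'
#' @inheritParams predict_serum
#' @param target_serum Target serum 25(OH)D, nmol/L.
#' @return Required daily intake, \eqn{\mu}g/day. A target at or below the
#'   baseline returns 0 with a message-carrying attribute; a target at or
#'   above the plateau is an error (unreachable).
#' @export
#' @examples
#' invert_for_intake(dose_response(21.38, 30.77, 2.42), 50)  # ~1.1
invert_for_intake <- function(fit, target_serum) {
  stopifnot(inherits(fit, "dose_response_fit"), length(target_serum) == 1L)
  if (target_serum >= fit$plateau) {
    abort_bad_arg(
      "target %.2f nmol/L is at or above the plateau %.2f nmol/L: unreachable at any intake",
      target_serum, fit$plateau)
  }
  if (target_serum <= fit$a) {
    x <- 0
    attr(x, "note") <- "target at or below baseline; zero intake suffices"
    return(x)
  }
  -log1p(-(target_serum - fit$a) / fit$b) / fit$c
}

#' Marginal serum gain from extra intake
#'
#' The increase in predicted serum from adding `delta` \eqn{\mu}g/day on
#' top of a given intake. Positive and decreasing in intake (diminishing
#' returns); the `delta -> 0` limit per unit is the derivative
#' \eqn{b\,c\,e^{-c x}}.
#'
#' @inheritParams predict_serum
#' @param delta Extra daily intake, \eqn{\mu}g/day (> 0), or 0 to request
#'   the instantaneous derivative.
#' @return Serum gain, nmol/L (for `delta = 0`, nmol/L per \eqn{\mu}g/day).
#' @export
marginal_gain <- function(fit, intake, delta = 1) {
  stopifnot(inherits(fit, "dose_response_fit"))
  if (any(intake < 0)) abort_bad_arg("intake must be nonnegative")
  if (any(delta < 0)) abort_bad_arg("delta must be nonnegative")
  ifelse(delta == 0,
         fit$b * fit$c * exp(-fit$c * intake),
         predict_serum(fit, intake + delta) - predict_serum(fit, intake))
}

#' Fit the saturating dose-response model to intake/serum pairs
#'
#' Nonlinear least squares (Levenberg-Marquardt) estimation of
#' \eqn{y = a + b(1 - e^{-cx})}. Start values are taken from the data
#' (`a0 = min(y)`, `b0 = max(y) - min(y)`, `c0 = 1/mean(x)`); `b` and `c`
#' are bounded below at `1e-6` to keep the parameterization identifiable.
#' Observations are treated as independent; design-aware standard errors
#' belong to the survey-statistics functions, not to this fit.
#'
#' @param data A data frame of observations.
#' @param intake,serum Columns of `data` (tidy-eval) holding daily intake
#'   (\eqn{\mu}g/day) and serum 25(OH)D (nmol/L). Defaults `intake`, `serum`.
#' @return A `dose_response_fit` (see [dose_response()]) with coefficient
#'   covariance from the Jacobian at the optimum, delta-method 95% plateau
#'   CI, `converged`, and `boundary` (TRUE when `b` or `c` is pinned at its
#'   lower bound, with a warning).
#' @export
#' @examples
#' d <- tibble::tibble(intake = seq(0.5, 10, length.out = 20))
#' d$serum <- predict_serum(dose_response(35.78, 20.26, 0.20), d$intake)
#' fit_dose_response(d)
fit_dose_response <- function(data, intake = intake, serum = serum) {
  x <- dplyr::pull(data, {{ intake }})
  y <- dplyr::pull(data, {{ serum }})
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 10L) abort_bad_arg("need at least 10 complete intake/serum pairs, got %d", length(x))
  if (length(unique(x)) < 2L) abort_bad_arg("intakes are all equal; dose-response is unidentifiable")
  if (any(x < 0)) abort_bad_arg("intake must be nonnegative")

  start <- list(a = min(y), b = max(max(y) - min(y), 1e-3), c = 1 / max(mean(x), 1e-6))
  lower <- c(a = -Inf, b = 1e-6, c = 1e-6)
  nls_fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a + b * (1 - exp(-c * x)),
      data = data.frame(x = x, y = y),
      start = start, lower = lower,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      rlang::abort(
        sprintf("dose-response fit failed to converge: %s", conditionMessage(e)),
        class = "vitdfort_fit_error")
    }
  )
  cf <- stats::coef(nls_fit)
  vc <- tryCatch(stats::vcov(nls_fit), error = function(e) matrix(NA_real_, 3, 3))
  boundary <- cf[["b"]] <= 1e-5 || cf[["c"]] <= 1e-5
  if (boundary) {
    rlang::warn("coefficient b or c is pinned at its lower bound; the response may be flat or unidentifiable")
  }
  fit <- dose_response(cf[["a"]], max(cf[["b"]], 1e-6), max(cf[["c"]], 1e-6),
                       vcov = vc, n = length(x))
  fit$converged <- nls_fit$convInfo$isConv %||% TRUE
  fit$boundary <- boundary
  fit$rss <- sum(stats::resid(nls_fit)^2)
  fit
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("Saturating dose-response: y = a + b(1 - exp(-c x))\n")
  cat(sprintf("  a = %.3f nmol/L, b = %.3f nmol/L, c = %.4f per ug/day\n", x$a, x$b, x$c))
  cat(sprintf("  plateau = %.2f nmol/L", x$plateau))
  if (all(is.finite(x$plateau_ci))) {
    cat(sprintf(" (95%% CI %.2f-%.2f)", x$plateau_ci[1], x$plateau_ci[2]))
  }
  cat(sprintf(", n = %s\n", ifelse(is.na(x$n), "?", x$n)))
  if (isTRUE(x$boundary)) cat("  note: coefficient at bound\n")
  invisible(x)
}

#' Tidy a dose-response fit
#'
#' @param x A `dose_response_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`.
#' @export
tidy.dose_response_fit <- function(x, ...) {
  se <- if (!is.null(x$vcov) && all(is.finite(diag(x$vcov)))) sqrt(diag(x$vcov)) else rep(NA_real_, 3)
  tibble::tibble(term = c("a", "b", "c"),
                 estimate = c(x$a, x$b, x$c),
                 std.error = unname(se))
}

#' One-row summary of a dose-response fit
#'
#' @inheritParams tidy.dose_response_fit
#' @return A one-row tibble: `plateau`, `plateau_low`, `plateau_high`,
#'   `n`, `converged`, `boundary`.
#' @export
glance.dose_response_fit <- function(x, ...) {
  tibble::tibble(plateau = x$plateau,
                 plateau_low = x$plateau_ci[1], plateau_high = x$plateau_ci[2],
                 n = x$n, converged = x$converged, boundary = x$boundary)
}

#' Plot a dose-response fit
#'
#' @param object A `dose_response_fit`.
#' @param data Optional data frame with `intake` and `serum` columns to
#'   overlay as points.
#' @param max_intake Upper end of the intake axis (\eqn{\mu}g/day).
#' @param ... Unused.
#' @return A ggplot object: fitted curve, plateau asymptote (dashed).
#' @export
autoplot.dose_response_fit <- function(object, data = NULL, max_intake = 20, ...) {
  grid <- tibble::tibble(intake = seq(0, max_intake, length.out = 200))
  grid$serum <- predict_serum(object, grid$intake)
  p <- ggplot2::ggplot(grid, ggplot2::aes(.data$intake, .data$serum)) +
    ggplot2::geom_hline(yintercept = object$plateau, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line(colour = "#2c7fb8", linewidth = 1) +
    ggplot2::labs(x = "Vitamin D intake (µg/day)",
                  y = "Serum 25(OH)D (nmol/L)",
                  title = sprintf("Plateau %.1f nmol/L", object$plateau)) +
    ggplot2::theme_minimal()
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(data = data, alpha = 0.3)
  }
  p
}
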