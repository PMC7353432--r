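#' Seasonal (calendar-month) models of serum 25(OH)D
#'
#' Serum 25(OH)D follows the annual UV cycle. With the month of blood draw
#' coded as an integer \eqn{m \in \{1,\dots,12\}} (1 = January), the
#' primary model is the concave quadratic
#' \deqn{y = \alpha m^2 + \beta m + \gamma,}
#' whose peak month is obtained analytically from the first derivative as
#' \eqn{-\beta / (2\alpha)}. A first-harmonic trigonometric model
#' \eqn{y = \alpha\cos(2\pi m/12) + \beta\sin(2\pi m/12) + \gamma}
#' is kept as the wrap-aware comparator ([fit_trig_season()],
#' [compare_seasonal_models()]). Months are deliberately not wrapped in the
#' quadratic model: the December-to-January discontinuity is part of the
#' model's definition.
#'
#' `seasonal_fit()` builds a fit object from known quadratic coefficients
#' (e.g. published ones); [fit_polynomial_season()] estimates them by OLS.
#'
#' @param alpha Quadratic coefficient, nmol/L per month^2 (negative for a
#'   concave annual cycle), or the cosine amplitude for `model_type
#'   = "trigonometric"`.
#' @param beta Linear coefficient, nmol/L per month, or the sine amplitude.
#' @param gamma Intercept, nmol/L.
#' @param model_type `"polynomial"` or `"trigonometric"`.
#' @param r_squared Optional fraction of variance explained.
#' @param n Optional number of observations.
#' @return An object of class `seasonal_fit` with elements `model_type`,
#'   `alpha`, `beta`, `gamma`, `r_squared`, `n`, and `peak_month`
#'   (real-valued, populated for concave polynomial fits).
#' @export
#' @examples
#' f <- seasonal_fit(-0.65, 10.58, 10.38)
#' peak_month(f)  # 8.1: early August
seasonal_fit <- function(alpha, beta, gamma, model_type = "polynomial",
                         r_squared = NA_real_, n = NA_integer_) {
  model_type <- match.arg(model_type, c("polynomial", "trigonometric"))
  fit <- structure(
    list(model_type = model_type, alpha = alpha, beta = beta, gamma = gamma,
         r_squared = r_squared, n = n, rss = NA_real_, peak_month = NA_real_),
    class = "seasonal_fit"
  )
  if (model_type == "polynomial" && is.finite(alpha) && alpha < 0) {
    fit$peak_month <- -beta / (2 * alpha)
  }
  fit
}

#' Evaluate a seasonal fit at given months
#'
#' @param fit A `seasonal_fit`.
#' @param month Month index, 1-12 scale (real values allowed for the
#'   polynomial model).
#' @return Predicted serum 25(OH)D, nmol/L.
#' @export
predict_season <- function(fit, month) {
  stopifnot(inherits(fit, "seasonal_fit"))
  if (fit$model_type == "polynomial") {
    fit$alpha * month^2 + fit$beta * month + fit$gamma
  } else {
    w <- 2 * pi * month / 12
    fit$alpha * cos(w) + fit$beta * sin(w) + fit$gamma
  }
}

ols_season <- function(data, month, serum, formula_rhs, model_type) {
  m <- dplyr::pull(data, {{ month }})
  y <- dplyr::pull(data, {{ serum }})
  keep <- is.finite(m) & is.finite(y)
  m <- m[keep]; y <- y[keep]
  if (length(unique(m)) < 3L) {
    abort_bad_arg("seasonal fit needs observations in at least 3 distinct months (got %d)",
                  length(unique(m)))
  }
  df <- data.frame(m = m, y = y)
  lm_fit <- stats::lm(stats::as.formula(paste("y ~", formula_rhs)), data = df)
  cf <- stats::coef(lm_fit)
  rss <- sum(stats::resid(lm_fit)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NaN
  fit <- seasonal_fit(alpha = unname(cf[3]), beta = unname(cf[2]),
                      gamma = unname(cf[1]), model_type = model_type,
                      r_squared = r2, n = length(y))
  fit$rss <- rss
  fit
}

#' Fit the quadratic seasonal model by ordinary least squares
#'
#' @param data Data frame of observations.
#' @param month,serum Columns of `data` (tidy-eval): integer month of blood
#'   draw (1-12) and serum 25(OH)D (nmol/L). Defaults `month`, `serum`.
#' @return A `seasonal_fit` (see [seasonal_fit()]); `peak_month` is
#'   populated when the fitted quadratic is concave (`alpha < 0`).
#' @export
fit_polynomial_season <- function(data, month = month, serum = serum) {
  fit <- ols_season(data, {{ month }}, {{ serum }}, "m + I(m^2)", "polynomial")
  # near-flat data: report exact zeros rather than numerical dust
  if (abs(fit$alpha) < 1e-10 && abs(fit$beta) < 1e-10) {
    fit$alpha <- 0; fit$beta <- 0; fit$peak_month <- NA_real_
  }
  fit
}

#' Fit the first-harmonic trigonometric seasonal model
#'
#' @inheritParams fit_polynomial_season
#' @return A `seasonal_fit` with `model_type = "trigonometric"`; `alpha`
#'   and `beta` are the cosine and sine amplitudes.
#' @export
fit_trig_season <- function(data, month = month, serum = serum) {
  ols_season(data, {{ month }}, {{ serum }},
             "sin(2 * pi * m / 12) + I(cos(2 * pi * m / 12))", "trigonometric")
}

#' Peak month of a concave quadratic seasonal fit
#'
#' The month at which the fitted annual cycle attains its maximum, from the
#' root of the first derivative: \eqn{-\beta/(2\alpha)}.
#'
#' @param fit A polynomial `seasonal_fit` with `alpha < 0`.
#' @param digits Decimals for reporting (round-half-up); use `NULL` for
#'   full precision.
#' @return Peak month on the 1-12 scale (1 = January). A value outside
#'   `[1, 12]` is returned with a warning (the maximum falls outside the
#'   modelled year).
#' @export
peak_month <- function(fit, digits = 1) {
  stopifnot(inherits(fit, "seasonal_fit"))
  if (fit$model_type != "polynomial") {
    abort_bad_arg("peak_month is defined for polynomial fits; got %s", fit$model_type)
  }
  if (!is.finite(fit$alpha) || fit$alpha >= 0) {
    abort_bad_arg("quadratic is not concave (alpha = %g): no interior maximum", fit$alpha)
  }
  pk <- -fit$beta / (2 * fit$alpha)
  if (pk < 1 || pk > 12) {
    rlang::warn(sprintf("peak month %.2f falls outside the 1-12 month scale", pk))
  }
  if (is.null(digits)) pk else round_half_up(pk, digits)
}

#' Month-specific deviation of serum status from its annual mean
#'
#' Evaluates the fitted seasonal curve at a month and subtracts its mean
#' over the twelve months, so the deviations sum to zero across the year.
#' This centered deviation is the seasonal component shared by the
#' synthetic-cohort simulator and the fortification counterfactual
#' (where holding the month constant makes it cancel from with-minus-without
#' differences).
#'
#' @param fit A polynomial `seasonal_fit`.
#' @param month Integer month(s), 1-12.
#' @return Deviation(s) in nmol/L; the mean over months 1..12 is 0.
#' @export
seasonal_deviation <- function(fit, month) {
  stopifnot(inherits(fit, "seasonal_fit"))
  if (any(!(month %in% 1:12))) abort_bad_arg("month must be an integer in 1..12")
  predict_season(fit, month) - mean(predict_season(fit, 1:12))
}

#' Compare polynomial and trigonometric seasonal fits
#'
#' Both models spend three parameters, so the comparison is descriptive: the
#' coefficient of determination of each, their difference, and the ratio of
#' residual sums of squares.
#'
#' @param poly,trig `seasonal_fit` objects fitted to the same observations
#'   (equal `n`).
#' @return A one-row tibble: `r_squared_poly`, `r_squared_trig`,
#'   `r_squared_diff`, `rss_ratio` (polynomial over trigonometric; < 1
#'   favours the polynomial), `preferred`, `n`.
#' @export
compare_seasonal_models <- function(poly, trig) {
  stopifnot(inherits(poly, "seasonal_fit"), inherits(trig, "seasonal_fit"))
  if (poly$model_type != "polynomial" || trig$model_type != "trigonometric") {
    abort_bad_arg("arguments must be a polynomial fit and a trigonometric fit, in that order")
  }
  if (!isTRUE(poly$n == trig$n)) {
    abort_bad_arg("fits were not computed on the same observations (n = %s vs %s)",
                  poly$n, trig$n)
  }
  tibble::tibble(
    r_squared_poly = poly$r_squared,
    r_squared_trig = trig$r_squared,
    r_squared_diff = poly$r_squared - trig$r_squared,
    rss_ratio = poly$rss / trig$rss,
    preferred = ifelse(poly$r_squared >= trig$r_squared, "polynomial", "trigonometric"),
    n = poly$n
  )
}

#' @export
print.seasonal_fit <- function(x, ...) {
  if (x$model_type == "polynomial") {
    cat(sprintf("Seasonal quadratic: y = %.3f m^2 + %.3f m + %.3f\n", x$alpha, x$beta, x$gamma))
    if (is.finite(x$peak_month)) {
      cat(sprintf("  peak month %.1f (1 = January)\n", round_half_up(x$peak_month, 1)))
    }
  } else {
    cat(sprintf("Seasonal first harmonic: y = %.3f cos(2pi m/12) + %.3f sin(2pi m/12) + %.3f\n",
                x$alpha, x$beta, x$gamma))
  }
  if (is.finite(x$r_squared)) cat(sprintf("  R^2 = %.3f, n = %s\n", x$r_squared, x$n))
  invisible(x)
}

#' Tidy a seasonal fit
#'
#' @param x A `seasonal_fit`.
#' @param ... Unused.
#' @return A tibble with `term` and `estimate` for the three coefficients.
#' @export
tidy.seasonal_fit <- function(x, ...) {
  terms <- if (x$model_type == "polynomial") c("month^2", "month", "intercept")
           else c("cos", "sin", "intercept")
  tibble::tibble(term = terms, estimate = c(x$alpha, x$beta, x$gamma))
}

#' One-row summary of a seasonal fit
#'
#' @inheritParams tidy.seasonal_fit
#' @return A one-row tibble: `model_type`, `r_squared`, `peak_month`, `n`.
#' @export
glance.seasonal_fit <- function(x, ...) {
  tibble::tibble(model_type = x$model_type, r_squared = x$r_squared,
                 peak_month = x$peak_month, n = x$n)
}

#' Plot a seasonal fit over the year
#'
#' @param object A `seasonal_fit`.
#' @param data Optional data frame with `month` and `serum` to overlay.
#' @param ... Unused.
#' @return A ggplot object; the peak month is marked for concave quadratics.
#' @export
autoplot.seasonal_fit <- function(object, data = NULL, ...) {
  grid <- tibble::tibble(month = seq(1, 12, length.out = 200))
  grid$serum <- predict_season(object, grid$month)
  p <- ggplot2::ggplot(grid, ggplot2::aes(.data$month, .data$serum)) +
    ggplot2::geom_line(colour = "#d95f02", linewidth = 1) +
    ggplot2::scale_x_continuous(breaks = 1:12) +
    ggplot2::labs(x = "Month of blood draw (1 = January)",
                  y = "Serum 25(OH)D (nmol/L)") +
    ggplot2::theme_minimal()
  if (is.finite(object$peak_month)) {
    p <- p + ggplot2::geom_vline(xintercept = object$peak_month,
                                 linetype = "dashed", colour = "grey50")
  }
  if (!is.null(data)) p <- p + ggplot2::geom_point(data = data, alpha = 0.3)
  p
}
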