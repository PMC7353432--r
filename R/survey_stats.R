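#' Design-based mean and standard error (Taylor linearization)
#'
#' Weighted mean of a survey variable with its standard error from the
#' with-replacement Taylor-linearization estimator: residual scores are
#' totalled per primary sampling unit (PSU) and their between-PSU variance
#' accumulated within strata, with no finite-population correction. Strata
#' containing a single PSU contribute no variance; when any are present the
#' SE is reported as not applicable (`NA`) and the stratum ids are flagged,
#' mirroring the "n.a." convention of survey reports.
#'
#' @param data Data frame of records.
#' @param value Column holding the analysis variable (tidy-eval).
#' @param psu,stratum Columns with the PSU and stratum identifiers
#'   (defaults `psu`, `stratum`); every PSU must lie in exactly one stratum.
#' @param weight Optional column of positive sampling weights; default all
#'   1 (unweighted analysis).
#' @return A one-row tibble: `mean`, `se`, `n`, `n_psu`, `n_strata`,
#'   `df` (design degrees of freedom, PSUs minus strata), and
#'   `single_psu_strata` (list-column of offending stratum ids, if any).
#' @export
survey_mean <- function(data, value, psu = psu, stratum = stratum, weight = NULL) {
  y <- dplyr::pull(data, {{ value }})
  p <- as.character(dplyr::pull(data, {{ psu }}))
  s <- as.character(dplyr::pull(data, {{ stratum }}))
  w <- if (rlang::quo_is_null(rlang::enquo(weight))) rep(1, length(y))
       else dplyr::pull(data, {{ weight }})
  keep <- is.finite(y)
  y <- y[keep]; p <- p[keep]; s <- s[keep]; w <- w[keep]
  if (length(y) == 0L) abort_bad_arg("no complete observations")
  if (any(w <= 0)) abort_bad_arg("weights must be strictly positive")
  psu_strata <- tapply(s, p, function(z) length(unique(z)))
  if (any(psu_strata > 1)) {
    abort_bad_arg("PSU(s) %s appear in more than one stratum",
                  paste(names(psu_strata)[psu_strata > 1], collapse = ", "))
  }
  mu <- sum(w * y) / sum(w)
  # linearized scores for the ratio mean
  z <- w * (y - mu) / sum(w)
  psu_tot <- tapply(z, paste(s, p, sep = "\r"), sum)
  psu_str <- sub("\r.*$", "", names(psu_tot))
  v <- 0
  singles <- character(0)
  for (h in unique(psu_str)) {
    zh <- psu_tot[psu_str == h]
    nh <- length(zh)
    if (nh < 2L) { singles <- c(singles, h); next }
    v <- v + nh / (nh - 1) * sum((zh - mean(zh))^2)
  }
  n_psu <- length(psu_tot)
  n_strata <- length(unique(psu_str))
  tibble::tibble(
    mean = mu,
    se = if (length(singles)) NA_real_ else sqrt(v),
    n = length(y), n_psu = n_psu, n_strata = n_strata,
    df = n_psu - n_strata,
    single_psu_strata = list(singles)
  )
}

#' Adjusted Wald test on a vector of group means
#'
#' Tests equality of `k + 1` group means given their design-based
#' covariance matrix, using the survey-design degrees-of-freedom
#' adjustment: with `d` design df (PSUs minus strata) and `k` contrasts,
#' \deqn{F = \frac{d - k + 1}{d\,k}\,W, \qquad F \sim F(k,\; d - k + 1)}
#' where `W` is the Wald statistic of the pairwise-difference contrasts.
#'
#' @param means Numeric vector of group means (length >= 2).
#' @param covariance Covariance matrix of the group means (design-based).
#' @param df_design Design degrees of freedom `d` = #PSUs - #strata; must
#'   exceed the number of contrasts minus 1.
#' @return A one-row tibble: `statistic` (F), `df1`, `df2`, `p.value`,
#'   `wald`.
#' @export
adjusted_wald <- function(means, covariance, df_design) {
  g <- length(means)
  if (g < 2L) abort_bad_arg("need at least two groups")
  covariance <- as.matrix(covariance)
  stopifnot(nrow(covariance) == g, ncol(covariance) == g)
  k <- g - 1L
  d <- df_design
  if (d < k) abort_bad_arg("insufficient design df (%g) for %d contrasts", d, k)
  C <- cbind(-1, diag(1, k))       # differences vs the first group
  delta <- drop(C %*% means)
  Vd <- C %*% covariance %*% t(C)
  W <- drop(t(delta) %*% solve(Vd, delta))
  f_stat <- (d - k + 1) / (d * k) * W
  df2 <- d - k + 1
  tibble::tibble(statistic = f_stat, df1 = k, df2 = df2,
                 p.value = stats::pf(f_stat, k, df2, lower.tail = FALSE),
                 wald = W)
}

#' Adjusted Wald test of a group difference from survey records
#'
#' Convenience wrapper: computes group means and their design-based
#' covariance (between-PSU, within-stratum, with-replacement), then calls
#' [adjusted_wald()].
#'
#' @inheritParams survey_mean
#' @param group Column defining the groups (tidy-eval).
#' @return As [adjusted_wald()], plus a `means` list-column with the named
#'   group means.
#' @export
adjusted_wald_test <- function(data, value, group, psu = psu, stratum = stratum) {
  y <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  p <- as.character(dplyr::pull(data, {{ psu }}))
  s <- as.character(dplyr::pull(data, {{ stratum }}))
  keep <- is.finite(y)
  y <- y[keep]; g <- g[keep]; p <- p[keep]; s <- s[keep]
  groups <- sort(unique(g))
  if (length(groups) < 2L) abort_bad_arg("need at least two groups")
  mus <- vapply(groups, function(gr) mean(y[g == gr]), 0)
  # per-record linearized scores, one column per group mean
  Z <- vapply(groups, function(gr) {
    ind <- g == gr
    z <- numeric(length(y))
    z[ind] <- (y[ind] - mus[[gr]]) / sum(ind)
    z
  }, numeric(length(y)))
  key <- paste(s, p, sep = "\r")
  psu_scores <- rowsum(Z, key)
  psu_str <- sub("\r.*$", "", rownames(psu_scores))
  V <- matrix(0, length(groups), length(groups))
  for (h in unique(psu_str)) {
    Zh <- psu_scores[psu_str == h, , drop = FALSE]
    nh <- nrow(Zh)
    if (nh < 2L) next
    Zc <- sweep(Zh, 2, colMeans(Zh))
    V <- V + nh / (nh - 1) * crossprod(Zc)
  }
  d <- nrow(psu_scores) - length(unique(psu_str))
  out <- adjusted_wald(mus, V, d)
  out$means <- list(mus)
  out
}

# two-sided Grubbs critical value at level alpha for sample size n
grubbs_critical <- function(n, alpha) {
  t2 <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)^2
  (n - 1) / sqrt(n) * sqrt(t2 / (n - 2 + t2))
}

#' Grubbs test for a single outlier
#'
#' Two-sided Grubbs statistic \eqn{G = \max_i |x_i - \bar x| / s} compared
#' against the t-based critical value at level `alpha`. A zero-variance
#' sample returns a no-outlier verdict.
#'
#' @param values Numeric vector, length >= 3; approximate normality under
#'   the null is assumed.
#' @param alpha Two-sided significance level (default 0.05).
#' @return A one-row tibble: `statistic` (G), `critical`, `outlier`
#'   (logical), `index` (position of the most extreme point, `NA` when no
#'   outlier), `value`, `n`.
#' @export
grubbs_test <- function(values, alpha = 0.05) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 3L) abort_bad_arg("Grubbs test needs at least 3 values, got %d", n)
  s <- stats::sd(x)
  if (s == 0) {
    return(tibble::tibble(statistic = 0, critical = grubbs_critical(n, alpha),
                          outlier = FALSE, index = NA_integer_,
                          value = NA_real_, n = n))
  }
  dev <- abs(x - mean(x))
  i <- which.max(dev)
  G <- dev[i] / s
  crit <- grubbs_critical(n, alpha)
  out <- G > crit
  tibble::tibble(statistic = G, critical = crit, outlier = out,
                 index = if (out) which(!is.na(values))[i] else NA_integer_,
                 value = if (out) x[i] else NA_real_, n = n)
}

#' Iterative Grubbs outlier screening
#'
#' Repeatedly applies [grubbs_test()], removing the single most extreme
#' point per pass, until no outlier is flagged or fewer than 3 values
#' remain.
#'
#' @inheritParams grubbs_test
#' @return A list with `values` (the retained values, original order) and
#'   `removed` (tibble log: `pass`, `value`, `statistic`, `critical`).
#' @export
remove_outliers <- function(values, alpha = 0.05) {
  x <- values
  log <- tibble::tibble(pass = integer(0), value = numeric(0),
                        statistic = numeric(0), critical = numeric(0))
  pass <- 0L
  while (sum(!is.na(x)) >= 3L) {
    verdict <- grubbs_test(x, alpha)
    if (!verdict$outlier) break
    pass <- pass + 1L
    log <- dplyr::bind_rows(log, tibble::tibble(
      pass = pass, value = verdict$value,
      statistic = verdict$statistic, critical = verdict$critical))
    x <- x[-verdict$index]
  }
  list(values = x, removed = log)
}
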