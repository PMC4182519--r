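#' @title Design-based estimation for stratified cluster samples
#' @description Inverse-probability-weighted means and proportions with
#'   Taylor-linearized variances that honour stratification and
#'   enumeration-area clustering, plus weighted quantiles. These are the
#'   variance machinery behind all confidence intervals in the package.
#' @name survey-estimation
NULL

# variance of a weighted total of linearized scores z_i under the
# with-replacement PSU approximation: between-PSU, within-stratum.
# Strata with a single PSU contribute zero variance (certainty units).
.svy_total_var <- function(z, stratum, psu, warn_lonely = TRUE) {
  stratum <- as.character(stratum)
  psu <- as.character(psu)
  v <- 0
  lonely <- character(0)
  for (h in unique(stratum)) {
    idx <- stratum == h
    totals <- tapply(z[idx], psu[idx], sum)
    nh <- length(totals)
    if (nh < 2L) {
      lonely <- c(lonely, h)
      next
    }
    v <- v + nh / (nh - 1) * sum((totals - mean(totals))^2)
  }
  if (length(lonely) && warn_lonely)
    warning("stratum with a single PSU treated as a certainty unit: ",
            paste(lonely, collapse = ", "), call. = FALSE)
  v
}

.check_design <- function(design, n) {
  stopifnot(is.data.frame(design),
            all(c("weight", "stratum", "psu") %in% names(design)))
  if (nrow(design) != n)
    stop("design rows do not match data length", call. = FALSE)
  if (any(!is.finite(design$weight)) || any(design$weight <= 0))
    stop("design weights must be positive and finite", call. = FALSE)
  invisible(design)
}

#' Weighted mean with a design-based confidence interval
#'
#' Estimates a population mean as the Hajek ratio
#' \eqn{\hat\mu = \sum_i s_i x_i / \sum_i s_i} with sampling weights
#' \eqn{s_i}, and its variance by Taylor linearization: the linearized score
#' \eqn{z_i = s_i (x_i - \hat\mu) / \sum s} is totalled per PSU and the
#' between-PSU variance is accumulated within strata (with-replacement PSU
#' approximation, no finite-population correction). The confidence interval
#' uses a normal reference.
#'
#' A stratum containing a single PSU is treated as a certainty unit
#' (contributing zero variance) with a warning.
#'
#' @param x Numeric vector of household-level values.
#' @param design Data frame with columns `weight` (positive sampling
#'   weights), `stratum` and `psu`, one row per element of `x`.
#' @param level Confidence level (default 0.95).
#' @param warn_lonely Warn about single-PSU strata? Default `TRUE`.
#' @return List with `estimate`, `se`, `ci` (length-2 vector) and `level`.
#' @export
#' @examples
#' d <- data.frame(weight = rep(1, 50), stratum = "a", psu = as.character(1:50))
#' svymean_ci(rnorm(50), d)$se   # matches sd(x)/sqrt(n) up to n/(n-1) scaling
svymean_ci <- function(x, design, level = 0.95, warn_lonely = TRUE) {
  .check_design(design, length(x))
  if (anyNA(x)) stop("missing values in 'x'", call. = FALSE)
  sw <- sum(design$weight)
  if (sw <= 0) stop("total weight must be positive", call. = FALSE)
  est <- sum(design$weight * x) / sw
  z <- design$weight * (x - est) / sw
  v <- .svy_total_var(z, design$stratum, design$psu, warn_lonely)
  se <- sqrt(max(v, 0))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  list(estimate = est, se = se, ci = c(est - zq * se, est + zq * se),
       level = level)
}

#' Weighted proportion with a design-based confidence interval
#'
#' A proportion is the weighted mean of a binary indicator; this delegates
#' to [svymean_ci()] after validating that `flags` is binary.
#'
#' @param flags Binary (0/1 or logical) vector.
#' @inheritParams svymean_ci
#' @return As [svymean_ci()].
#' @export
svyprop_ci <- function(flags, design, level = 0.95, warn_lonely = TRUE) {
  flags <- as.numeric(flags)
  if (anyNA(flags) || !all(flags %in% c(0, 1)))
    stop("'flags' must be binary with no missing values", call. = FALSE)
  svymean_ci(flags, design, level, warn_lonely)
}

#' Weighted ratio with a design-based confidence interval
#'
#' Estimates \eqn{R = \sum s y / \sum s x} with linearized scores
#' \eqn{z_i = s_i (y_i - R x_i) / \widehat{X}}. Used internally for the
#' average deprivation intensity A, a ratio of censored-score to poor-flag
#' totals.
#'
#' @param y,x Numerator and denominator variables.
#' @inheritParams svymean_ci
#' @return As [svymean_ci()].
#' @export
svyratio_ci <- function(y, x, design, level = 0.95, warn_lonely = TRUE) {
  .check_design(design, length(y))
  stopifnot(length(x) == length(y))
  xhat <- sum(design$weight * x)
  if (xhat <= 0) stop("denominator total must be positive", call. = FALSE)
  est <- sum(design$weight * y) / xhat
  z <- design$weight * (y - est * x) / xhat
  v <- .svy_total_var(z, design$stratum, design$psu, warn_lonely)
  se <- sqrt(max(v, 0))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  list(estimate = est, se = se, ci = c(est - zq * se, est + zq * se),
       level = level)
}

#' Weighted quantile
#'
#' Returns the smallest data value whose cumulative normalized weight
#' reaches `q` — the left-continuous inverse of the weighted empirical
#' distribution function. This is the estimator used for weighted medians,
#' quartiles and the wealth-quintile boundary.
#'
#' @param x Numeric values.
#' @param w Positive weights, recycled if scalar. Default: equal weights.
#' @param q Quantile(s) in \[0, 1\]; vectorized.
#' @return Numeric vector of quantiles, one per element of `q`.
#' @export
#' @examples
#' weighted_quantile(1:5, rep(1, 5), 0.5)  # 3
weighted_quantile <- function(x, w = rep(1, length(x)), q) {
  if (length(x) == 0L) stop("empty input", call. = FALSE)
  if (length(w) == 1L) w <- rep(w, length(x))
  stopifnot(length(w) == length(x), all(w > 0), all(q >= 0), all(q <= 1))
  if (anyNA(x) || anyNA(w)) stop("missing values in input", call. = FALSE)
  ord <- order(x)
  xs <- x[ord]
  cw <- cumsum(w[ord]) / sum(w)
  vapply(q, function(qq) xs[which(cw >= qq - 1e-12)[1]], numeric(1))
}
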