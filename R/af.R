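#' @title Alkire-Foster dual-cutoff counting engine
#' @description Identification of the multidimensionally poor, censoring,
#'   and aggregation into the headcount ratio H, average deprivation
#'   intensity A among the poor, and the adjusted headcount M0 = H x A,
#'   together with indicator/dimension decompositions, subgroup
#'   decomposition and the poverty-cut-off robustness curve.
#' @name alkire-foster
NULL

# integer deprivation score numerators (exact, over weights_den)
.score_num <- function(dm) as.vector(dm$g0 %*% dm$weights_num)

.dm_subset <- function(dm, idx) {
  structure(list(
    g0 = dm$g0[idx, , drop = FALSE],
    household_id = dm$household_id[idx],
    weights_num = dm$weights_num,
    weights_den = dm$weights_den,
    dimension = dm$dimension,
    design = dm$design[idx, , drop = FALSE]
  ), class = "deprivation_matrix")
}

#' Weighted deprivation score per household
#'
#' Computes \eqn{c_i = \sum_j w_j g_{ij}}, the weighted share of indicators
#' in which household i is deprived. With the default weights every
#' attainable score is an exact multiple of 1/36; scores are computed in
#' integer arithmetic over that common denominator and converted to numeric
#' on return.
#'
#' @param dm A [deprivation_matrix()].
#' @return Numeric vector of scores in \[0, 1\].
#' @export
deprivation_scores <- function(dm) {
  stopifnot(inherits(dm, "deprivation_matrix"))
  .score_num(dm) / dm$weights_den
}

#' Identify the multidimensionally poor
#'
#' Dual-cutoff identification: a household is poor when its weighted
#' deprivation score reaches the poverty cut-off k. The default is the
#' inclusive rule (poor iff c >= k), so with k = 1/3 a household deprived in
#' exactly one third of the weighted indicators counts as poor; set
#' `inclusive = FALSE` for the strict rule (c > k). Comparisons are made
#' with a small numeric guard so that scores landing exactly on an
#' attainable cut-off (e.g. 12/36 against k = 1/3) are classified exactly.
#'
#' @param scores Deprivation scores in \[0, 1\].
#' @param k Poverty cut-off in (0, 1\].
#' @param inclusive Poor iff c >= k (default) rather than c > k.
#' @return Integer 0/1 poverty flags.
#' @export
#' @examples
#' identify_poor(c(0.5, 0.2, 1/3, 0), k = 1/3)  # 1 0 1 0
identify_poor <- function(scores, k, inclusive = TRUE) {
  stopifnot(k > 0, k <= 1, all(scores >= -1e-12), all(scores <= 1 + 1e-12))
  if (inclusive) as.integer(scores >= k - 1e-9)
  else as.integer(scores > k + 1e-9)
}

#' Censor the scores of the non-poor
#'
#' Sets the deprivation score of every non-poor household to zero; the mean
#' of the censored scores is the adjusted headcount M0.
#'
#' @param scores Deprivation scores.
#' @param poor 0/1 poverty flags aligned with `scores`.
#' @return Censored scores c(k).
#' @export
censor_scores <- function(scores, poor) {
  stopifnot(length(scores) == length(poor))
  scores * (poor != 0)
}

#' Fit the Alkire-Foster adjusted headcount to a deprivation matrix
#'
#' The central estimator of the package. Identifies the poor at cut-off `k`,
#' censors the non-poor, and aggregates with the household sampling weights:
#' \deqn{H = \frac{\sum_i s_i \, \mathrm{poor}_i}{\sum_i s_i}, \quad
#'       A = \frac{\sum_i s_i c_i \, \mathrm{poor}_i}{\sum_i s_i \,
#'       \mathrm{poor}_i}, \quad M_0 = H \times A,}
#' where \eqn{M_0} equals the weighted mean censored score and also
#' \eqn{\sum_j w_j \, \mathrm{CH}_j} with censored headcounts
#' \eqn{\mathrm{CH}_j} (the weighted share of households both poor and
#' deprived in indicator j). Confidence intervals for H, A and M0 are
#' design-based (Taylor linearization over strata and enumeration-area
#' PSUs; see [svymean_ci()]).
#'
#' When no household is poor, A is defined as 0 (keeping M0 = H x A) and
#' indicator contributions are reported as `NA` (undefined), never `NaN`.
#'
#' @param dm A [deprivation_matrix()].
#' @param k Poverty cut-off in (0, 1\]; default 1/3.
#' @param inclusive Identification rule; see [identify_poor()].
#' @param level Confidence level for intervals.
#' @return An object of class `af_fit` with components `H`, `A`, `M0`
#'   (each a list with `estimate`, `se`, `ci`), `censored_headcounts`,
#'   `contributions`, `dimension_contributions`, `poor`, `scores`,
#'   `n`, `n_poor`, `n_effective`, `k`, `inclusive`, `level`.
#' @seealso [af_by()] for subgroup decomposition, [af_robustness()] for the
#'   cut-off curve.
#' @export
#' @examples
#' sim <- simulate_survey(sim_config(n_eas = 20, households_per_ea = 10, seed = 7))
#' fit <- af_fit(deprivation_matrix(sim$households))
#' coef(fit)
af_fit <- function(dm, k = 1/3, inclusive = TRUE, level = 0.95) {
  stopifnot(inherits(dm, "deprivation_matrix"))
  if (nrow(dm$g0) == 0L) stop("empty deprivation matrix", call. = FALSE)
  sn <- .score_num(dm)
  den <- dm$weights_den
  scores <- sn / den
  poor <- if (inclusive) as.integer(sn >= k * den - 1e-9)
          else as.integer(sn > k * den + 1e-9)
  cens <- scores * poor
  des <- dm$design

  H <- svyprop_ci(poor, des, level, warn_lonely = FALSE)
  M0 <- svymean_ci(cens, des, level, warn_lonely = FALSE)
  A <- if (any(poor == 1L)) {
    svyratio_ci(cens, poor, des, level, warn_lonely = FALSE)
  } else {
    list(estimate = 0, se = NA_real_, ci = c(NA_real_, NA_real_),
         level = level)
  }

  sw <- des$weight / sum(des$weight)
  ch <- as.vector(crossprod(dm$g0 * poor, sw))
  names(ch) <- colnames(dm$g0)
  w <- dm$weights_num / den
  contrib <- if (M0$estimate > 0) w * ch / M0$estimate
             else rep(NA_real_, length(ch))
  names(contrib) <- names(ch)
  dim_contrib <- if (all(is.na(contrib))) {
    stats::setNames(rep(NA_real_, length(unique(dm$dimension))),
                    unique(dm$dimension))
  } else {
    tapply(contrib, factor(dm$dimension, levels = unique(dm$dimension)), sum)
  }

  structure(list(
    H = H, A = A, M0 = M0,
    censored_headcounts = ch,
    contributions = contrib,
    dimension_contributions = dim_contrib,
    poor = poor, scores = scores,
    n = length(poor), n_poor = sum(poor),
    n_effective = sum(des$weight),
    k = k, inclusive = inclusive, level = level
  ), class = "af_fit")
}

#' Adjusted headcount from headcount and intensity
#'
#' The defining identity of the adjusted headcount: M0 = H x A. A
#' convenience for recombining published or subgroup (H, A) pairs.
#'
#' @param H Headcount ratio(s).
#' @param A Average deprivation intensity(ies) among the poor.
#' @return M0 = H * A.
#' @export
#' @examples
#' adjusted_headcount(0.58, 0.46)  # 0.2668, printed as 0.27
adjusted_headcount <- function(H, A) {
  stopifnot(all(H >= 0 & H <= 1), all(A >= 0 & A <= 1))
  H * A
}

#' Subgroup decomposition of the adjusted headcount
#'
#' Fits the AF estimator within each subgroup and reports each group's
#' population share (of total sampling weight). The adjusted headcount is
#' additively decomposable: the share-weighted subgroup M0s recombine
#' exactly to the pooled M0.
#'
#' @param dm A [deprivation_matrix()].
#' @param groups Vector of group labels, one per household (no missing
#'   values allowed).
#' @inheritParams af_fit
#' @return An object of class `af_by`: list with `fits` (named list of
#'   `af_fit`), `shares` (named weight shares), `table` (data frame of
#'   group, share, H, A, M0) and `overall` (pooled `af_fit`).
#' @export
af_by <- function(dm, groups, k = 1/3, inclusive = TRUE, level = 0.95) {
  stopifnot(inherits(dm, "deprivation_matrix"),
            length(groups) == nrow(dm$g0))
  if (anyNA(groups)) stop("every household must be labeled", call. = FALSE)
  groups <- as.character(groups)
  labs <- unique(groups)
  keep <- labs[vapply(labs, function(g) any(groups == g), logical(1))]
  fits <- lapply(keep, function(g)
    af_fit(.dm_subset(dm, groups == g), k, inclusive, level))
  names(fits) <- keep
  tw <- sum(dm$design$weight)
  shares <- vapply(keep, function(g)
    sum(dm$design$weight[groups == g]) / tw, numeric(1))
  tab <- data.frame(
    group = keep, share = shares,
    H = vapply(fits, function(f) f$H$estimate, numeric(1)),
    A = vapply(fits, function(f) f$A$estimate, numeric(1)),
    M0 = vapply(fits, function(f) f$M0$estimate, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(fits = fits, shares = shares, table = tab,
                 overall = af_fit(dm, k, inclusive, level)),
            class = "af_by")
}

#' Attainable weighted deprivation scores
#'
#' Enumerates, by subset-sum dynamic programming in integer arithmetic, all
#' weighted scores a household can attain under a given indicator weight
#' vector. Useful for choosing poverty-cut-off grids when the weights are
#' not the default.
#'
#' @param weights_num Integer weight numerators.
#' @param weights_den Common denominator.
#' @return Sorted numeric vector of attainable scores (including 0).
#' @export
attainable_scores <- function(weights_num, weights_den) {
  stopifnot(all(weights_num > 0), sum(weights_num) <= weights_den)
  reach <- logical(sum(weights_num) + 1L)
  reach[1L] <- TRUE
  for (w in weights_num) {
    shifted <- c(rep(FALSE, w), reach[seq_len(length(reach) - w)])
    reach <- reach | shifted
  }
  (which(reach) - 1L) / weights_den
}

# published 19-value robustness grid for the default 11-indicator weights:
# 4/36, 6/36, then every multiple of 1/36 from 8/36 through 24/36
.default_k_grid <- function(dm) {
  default_num <- c(6L, 6L, 6L, 3L, 3L, 2L, 2L, 2L, 2L, 2L, 2L)
  if (identical(dm$weights_num, default_num) && dm$weights_den == 36L)
    c(4L, 6L, 8:24) / 36
  else {
    a <- attainable_scores(dm$weights_num, dm$weights_den)
    a[a > 0]
  }
}

#' Headcount robustness across poverty cut-offs
#'
#' Re-identifies the poor at every cut-off in a grid and reports the
#' design-based headcount with its confidence interval. The headcount is
#' non-increasing in k by construction. The default grid for the standard
#' 11-indicator weights is the 19 published cut-offs 11.1%, 16.7% and every
#' multiple of 1/36 from 22.2% through 66.7%; for other weight vectors the
#' full attainable-score grid from [attainable_scores()] is used.
#'
#' @param dm A [deprivation_matrix()].
#' @param k_grid Increasing vector of cut-offs; `NULL` for the default.
#' @inheritParams af_fit
#' @return An object of class `af_robustness`: a data frame with columns
#'   `k`, `H`, `ci_lo`, `ci_hi`.
#' @export
af_robustness <- function(dm, k_grid = NULL, inclusive = TRUE, level = 0.95) {
  stopifnot(inherits(dm, "deprivation_matrix"))
  if (is.null(k_grid)) k_grid <- .default_k_grid(dm)
  if (length(k_grid) == 0L) stop("empty cut-off grid", call. = FALSE)
  k_grid <- sort(k_grid)
  sn <- .score_num(dm)
  den <- dm$weights_den
  rows <- lapply(k_grid, function(k) {
    poor <- if (inclusive) as.integer(sn >= k * den - 1e-9)
            else as.integer(sn > k * den + 1e-9)
    est <- svyprop_ci(poor, dm$design, level, warn_lonely = FALSE)
    c(k = k, H = est$estimate, ci_lo = est$ci[1], ci_hi = est$ci[2])
  })
  out <- as.data.frame(do.call(rbind, rows))
  class(out) <- c("af_robustness", "data.frame")
  out
}

# ---- methods ---------------------------------------------------------------

#' @export
print.af_fit <- function(x, digits = 4, ...) {
  cat("Alkire-Foster adjusted headcount (k =", format(x$k, digits = 4),
      if (x$inclusive) ", poor iff c >= k)" else ", poor iff c > k)", "\n")
  cat(sprintf("  n = %d households (%d poor), effective weight %.1f\n",
              x$n, x$n_poor, x$n_effective))
  fm <- function(e) sprintf("%.*f  (%s%% CI %.*f, %.*f)", digits, e$estimate,
                            format(100 * e$level), digits, e$ci[1],
                            digits, e$ci[2])
  cat("  Headcount (H): ", fm(x$H), "\n")
  cat("  Intensity (A): ", fm(x$A), "\n")
  cat("  Adjusted headcount (M0 = H x A):", fm(x$M0), "\n")
  invisible(x)
}

#' @export
summary.af_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.af_fit")
}

#' @export
print.summary.af_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nCensored headcounts and contributions to M0:\n")
  tab <- data.frame(
    censored_headcount = round(f$censored_headcounts, 4),
    contribution = round(f$contributions, 4)
  )
  print(tab)
  cat("\nDimension contributions:\n")
  print(round(f$dimension_contributions, 4))
  invisible(x)
}

#' @export
coef.af_fit <- function(object, ...) {
  c(H = object$H$estimate, A = object$A$estimate, M0 = object$M0$estimate)
}

#' @export
confint.af_fit <- function(object, parm = c("H", "A", "M0"), level = NULL, ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  m <- t(vapply(parm, function(p) object[[p]]$ci, numeric(2)))
  colnames(m) <- c("lower", "upper")
  m
}

#' @export
plot.af_fit <- function(x, ...) {
  graphics::barplot(x$dimension_contributions,
                    ylab = "contribution to M0",
                    main = sprintf("M0 = %.3f decomposition by dimension",
                                   x$M0$estimate), ...)
  invisible(x)
}

#' @export
print.af_by <- function(x, ...) {
  cat("Alkire-Foster subgroup decomposition (k =",
      format(x$overall$k, digits = 4), ")\n")
  print(transform(x$table, share = round(share, 3), H = round(H, 4),
                  A = round(A, 4), M0 = round(M0, 4)))
  cat(sprintf("Pooled M0 = %.4f (share-weighted recombination %.4f)\n",
              x$overall$M0$estimate, sum(x$shares * x$table$M0)))
  invisible(x)
}

#' @export
plot.af_robustness <- function(x, type = "b", ...) {
  graphics::plot(x$k, x$H, type = type, xlab = "poverty cut-off k",
                 ylab = "headcount H", ylim = c(0, 1), ...)
  graphics::lines(x$k, x$ci_lo, lty = 2)
  graphics::lines(x$k, x$ci_hi, lty = 2)
  invisible(x)
}
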