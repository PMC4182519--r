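#' @title Permanent-income wealth from dichotomous asset items
#' @description A one-factor binary-probit latent-trait model (the form a
#'   dichotomous hierarchical ordered probit takes for binary items):
#'   household wealth is a standard-normal latent variable z and item l is
#'   owned with probability \eqn{\Phi(\alpha_l + \beta_l z)}. The model is
#'   fitted by marginal maximum likelihood with an EM algorithm over
#'   Gauss-Hermite quadrature nodes; households are scored by their
#'   expected a-posteriori latent wealth, min-max rescaled to \[0, 1\].
#' @name wealth-index
NULL

# log-likelihood pieces: log P(y_i | z = node_q) for all i, q
.wealth_loglik_mat <- function(items, alpha, beta, nodes) {
  eta <- outer(beta, nodes) + alpha          # items x nodes
  lp1 <- stats::pnorm(eta, log.p = TRUE)
  lp0 <- stats::pnorm(eta, log.p = TRUE, lower.tail = FALSE)
  items %*% lp1 + (1 - items) %*% lp0        # n x nodes
}

#' Fit the latent-trait wealth model
#'
#' Marginal maximum likelihood for the one-factor binary-probit model with
#' a standard-normal latent prior, via EM: the E-step computes posterior
#' weights of each household over Gauss-Hermite quadrature nodes; the
#' M-step refits each item's intercept and loading by weighted probit
#' likelihood on the node grid. The observed-data log-likelihood is
#' non-decreasing across iterations; convergence is declared when its
#' change falls below `tol`. Items owned by everyone or no one carry no
#' information about the latent trait and are dropped with a warning.
#' Loadings are constrained positive, orienting the score so that owning
#' items indicates higher wealth.
#'
#' @param items n x p binary (0/1) matrix of asset ownership; column names
#'   identify items.
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param nodes Number of Gauss-Hermite quadrature nodes (default 21).
#' @return Object of class `wealth_fit` with `alpha` (item intercepts),
#'   `beta` (positive loadings), `items` (retained item names),
#'   `dropped` (degenerate items), `loglik` (trace), `converged`,
#'   `nodes`, `weights` (quadrature grid) and `scores` (EAP scores of the
#'   training sample rescaled to \[0, 1\]).
#' @export
#' @examples
#' \donttest{
#' set.seed(1)
#' z <- rnorm(400)
#' y <- sapply(1:10, function(l) rbinom(400, 1, pnorm(0.8 * z)))
#' colnames(y) <- paste0("item", 1:10)
#' fit <- wealth_fit(y)
#' }
wealth_fit <- function(items, max_iter = 200L, tol = 1e-6, nodes = 21L) {
  items <- as.matrix(items)
  if (is.null(colnames(items)))
    colnames(items) <- sprintf("item_%02d", seq_len(ncol(items)))
  if (anyNA(items) || !all(items %in% c(0, 1)))
    stop("'items' must be a binary 0/1 matrix with no missing values",
         call. = FALSE)
  if (nrow(items) < 5L) stop("too few households to fit", call. = FALSE)
  rates <- colMeans(items)
  degen <- rates %in% c(0, 1)
  dropped <- colnames(items)[degen]
  if (any(degen)) {
    warning("dropping degenerate item(s) with no ownership variation: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    items <- items[, !degen, drop = FALSE]
  }
  p <- ncol(items)
  if (p < 2L) stop("need at least 2 non-degenerate items", call. = FALSE)

  gq <- statmod::gauss.quad.prob(nodes, dist = "normal")
  xq <- gq$nodes
  wq <- gq$weights

  alpha <- stats::qnorm(pmin(pmax(colMeans(items), 0.01), 0.99))
  beta <- rep(1, p)
  ll_trace <- numeric(0)
  converged <- FALSE
  post <- NULL
  for (it in seq_len(max_iter)) {
    lmat <- .wealth_loglik_mat(items, alpha, beta, xq)
    lw <- sweep(lmat, 2, log(wq), "+")
    mx <- apply(lw, 1, max)
    pw <- exp(lw - mx)
    marg <- rowSums(pw)
    ll <- sum(mx + log(marg))
    post <- pw / marg
    ll_trace <- c(ll_trace, ll)
    if (it > 1 && abs(ll - ll_trace[it - 1]) < tol) {
      converged <- TRUE
      break
    }
    # M-step sufficient statistics: per node, expected n and item successes
    nq <- colSums(post)
    rq <- crossprod(items, post)           # p x nodes
    for (l in seq_len(p)) {
      fn <- function(par) {
        eta <- par[1] + par[2] * xq
        -sum(rq[l, ] * stats::pnorm(eta, log.p = TRUE) +
               (nq - rq[l, ]) * stats::pnorm(eta, log.p = TRUE,
                                             lower.tail = FALSE))
      }
      opt <- stats::optim(c(alpha[l], beta[l]), fn, method = "L-BFGS-B",
                          lower = c(-Inf, 1e-6), upper = c(Inf, 25))
      alpha[l] <- opt$par[1]
      beta[l] <- opt$par[2]
    }
  }
  if (!converged)
    warning("wealth model did not converge in ", max_iter,
            " iterations; returning best iterate", call. = FALSE)

  fit <- structure(list(
    alpha = stats::setNames(alpha, colnames(items)),
    beta = stats::setNames(beta, colnames(items)),
    items = colnames(items), dropped = dropped,
    loglik = ll_trace, converged = converged,
    nodes = xq, weights = wq
  ), class = "wealth_fit")
  fit$scores <- predict(fit, items)
  fit
}

#' Score households on the fitted wealth index
#'
#' Expected a-posteriori (EAP) latent wealth for each household under a
#' fitted model, min-max rescaled to \[0, 1\] over the scored sample.
#' Scoring is a pure function of the fitted parameters: no refitting
#' occurs, so a single household can be scored against a prefit model.
#' Item columns are matched by name, making the score invariant to column
#' order; items the model dropped as degenerate are ignored.
#'
#' @param object A `wealth_fit`.
#' @param newdata Binary item matrix with (at least) the model's item
#'   columns.
#' @param rescale Min-max rescale to \[0, 1\] (default) or return raw EAP
#'   values.
#' @param ... Unused.
#' @return Numeric score vector, one per row of `newdata`.
#' @export
predict.wealth_fit <- function(object, newdata, rescale = TRUE, ...) {
  newdata <- as.matrix(newdata)
  miss <- setdiff(object$items, colnames(newdata))
  if (length(miss))
    stop("newdata lacks item column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  items <- newdata[, object$items, drop = FALSE]
  if (anyNA(items) || !all(items %in% c(0, 1)))
    stop("items must be binary with no missing values", call. = FALSE)
  lmat <- .wealth_loglik_mat(items, object$alpha, object$beta, object$nodes)
  lw <- sweep(lmat, 2, log(object$weights), "+")
  mx <- apply(lw, 1, max)
  pw <- exp(lw - mx)
  eap <- as.vector(pw %*% object$nodes) / rowSums(pw)
  if (!rescale) return(eap)
  rng <- range(eap)
  if (rng[1] == rng[2]) return(rep(0.5, length(eap)))
  (eap - rng[1]) / (rng[2] - rng[1])
}

#' @export
print.wealth_fit <- function(x, ...) {
  cat(sprintf(
    "Latent-trait wealth model: %d items, log-likelihood %.2f (%s, %d EM iterations)\n",
    length(x$items), utils::tail(x$loglik, 1),
    if (x$converged) "converged" else "NOT converged", length(x$loglik)))
  if (length(x$dropped))
    cat("  dropped degenerate items:", paste(x$dropped, collapse = ", "),
        "\n")
  cat(sprintf("  loadings: min %.2f, median %.2f, max %.2f\n",
              min(x$beta), stats::median(x$beta), max(x$beta)))
  invisible(x)
}

#' @export
coef.wealth_fit <- function(object, ...) {
  cbind(intercept = object$alpha, loading = object$beta)
}

#' Flag households in the lowest wealth quintile
#'
#' Computes the (survey-weighted) 20th percentile of the wealth scores via
#' [weighted_quantile()] and flags every household at or below it. Ties at
#' the boundary are all flagged.
#'
#' @param scores Wealth scores.
#' @param weights Sampling weights (default equal).
#' @return Logical flag vector.
#' @export
lowest_quintile <- function(scores, weights = rep(1, length(scores))) {
  if (length(scores) < 5L) stop("need at least 5 households", call. = FALSE)
  b <- weighted_quantile(scores, weights, 0.2)
  scores <= b
}

#' Households below the $1.25/day income line
#'
#' Converts monthly household income in meticais to per-capita dollars per
#' day and compares it with the unidimensional poverty line:
#' income / days-per-month / household size / exchange rate < line.
#'
#' @param monthly_income_mzn Monthly household income (meticais, >= 0).
#' @param household_size Persons in the household (>= 1).
#' @param exchange_rate Meticais per USD (default 30).
#' @param line Poverty line in USD/person/day (default 1.25).
#' @param days_per_month Days per month for the conversion (default 30.44).
#' @return Logical flags.
#' @export
#' @examples
#' below_dollar_line(150, 4)  # TRUE: well below $1.25/day
below_dollar_line <- function(monthly_income_mzn, household_size,
                              exchange_rate = 30, line = 1.25,
                              days_per_month = 30.44) {
  if (any(monthly_income_mzn < 0))
    stop("negative income", call. = FALSE)
  stopifnot(all(household_size >= 1), exchange_rate > 0,
            days_per_month > 0)
  daily_usd <- monthly_income_mzn / days_per_month / household_size /
    exchange_rate
  daily_usd < line
}
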