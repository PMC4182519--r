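#' @title EA-level poverty surfaces by ordinary kriging
#' @description Aggregates the adjusted headcount to enumeration-area level
#'   and smooths it over space: empirical semivariogram, weighted
#'   least-squares variogram fitting (exponential, spherical or Gaussian),
#'   and ordinary kriging with the unbiasedness constraint, producing
#'   gridded surfaces exportable as CSV or GeoJSON.
#' @name poverty-mapping
NULL

#' Adjusted headcount per enumeration area
#'
#' Computes each EA's M0 as the weighted mean censored deprivation score of
#' its households (the within-EA adjusted headcount) and attaches the EA's
#' planar coordinates. EAs present in the coordinate table but with no
#' households are omitted.
#'
#' @param dm A [deprivation_matrix()]; its `design$psu` labels the EA of
#'   each household.
#' @param ea_table Data frame with columns `ea_id`, `x`, `y` (and
#'   optionally `district`).
#' @inheritParams af_fit
#' @return Data frame with `ea_id`, `x`, `y`, `district` (if supplied),
#'   `m0`, `n_households`.
#' @export
ea_headcounts <- function(dm, ea_table, k = 1/3, inclusive = TRUE) {
  stopifnot(inherits(dm, "deprivation_matrix"),
            all(c("ea_id", "x", "y") %in% names(ea_table)))
  ea <- dm$design$psu
  if (!all(ea %in% ea_table$ea_id))
    stop("household EA not present in ea_table", call. = FALSE)
  sn <- .score_num(dm)
  scores <- sn / dm$weights_den
  poor <- if (inclusive) as.integer(sn >= k * dm$weights_den - 1e-9)
          else as.integer(sn > k * dm$weights_den + 1e-9)
  cens <- scores * poor
  w <- dm$design$weight
  m0 <- tapply(w * cens, ea, sum) / tapply(w, ea, sum)
  cnt <- as.vector(table(ea)[names(m0)])
  out <- data.frame(ea_id = names(m0), m0 = as.vector(m0),
                    n_households = cnt, stringsAsFactors = FALSE)
  keep <- c("ea_id", "x", "y", intersect("district", names(ea_table)))
  out <- merge(ea_table[, keep], out, by = "ea_id")
  out[order(out$ea_id), , drop = FALSE]
}

#' Empirical semivariogram
#'
#' The classical (Matheron) estimator: for each distance bin, half the mean
#' squared difference of the field over all point pairs falling in the bin.
#' Bins with no pairs are dropped.
#'
#' @param coords Two-column matrix/data frame of planar coordinates.
#' @param values Field values, one per point.
#' @param n_bins Number of equal-width distance bins.
#' @param max_dist Maximum pair distance considered; default half the
#'   largest inter-point distance.
#' @return Data frame with `dist` (bin midpoint of contributing pairs),
#'   `gamma` (semivariance) and `n_pairs`.
#' @export
empirical_variogram <- function(coords, values, n_bins = 15, max_dist = NULL) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) >= 2L, length(values) == nrow(coords))
  d <- stats::dist(coords)
  if (max(d) == 0) stop("all points coincident", call. = FALSE)
  if (is.null(max_dist)) max_dist <- max(d) / 2
  stopifnot(max_dist > 0)
  dv <- as.vector(d)
  gv <- as.vector(stats::dist(values))^2 / 2
  keep <- dv <= max_dist & dv > 0
  dv <- dv[keep]; gv <- gv[keep]
  if (!length(dv)) stop("no pairs within max_dist", call. = FALSE)
  bin <- pmin(ceiling(dv / (max_dist / n_bins)), n_bins)
  out <- data.frame(
    dist = as.vector(tapply(dv, bin, mean)),
    gamma = as.vector(tapply(gv, bin, mean)),
    n_pairs = as.vector(tapply(gv, bin, length))
  )
  out[order(out$dist), , drop = FALSE]
}

# model semivariance at distance d (nugget applies at d > 0)
.vgm_gamma <- function(d, model, nugget, psill, range_param) {
  g <- switch(model,
    exponential = psill * (1 - exp(-d / range_param)),
    spherical = ifelse(d >= range_param, psill,
                       psill * (1.5 * d / range_param -
                                  0.5 * (d / range_param)^3)),
    gaussian = psill * (1 - exp(-(d / range_param)^2)),
    stop("unknown variogram model: ", model, call. = FALSE)
  )
  ifelse(d > 0, nugget + g, 0)
}

#' Fit a variogram model by weighted least squares
#'
#' Fits nugget, partial sill and range of an exponential, spherical or
#' Gaussian semivariogram to an empirical variogram, minimising the
#' pair-count-weighted squared deviation with non-negativity enforced via
#' box constraints. If the optimisation degenerates (non-finite objective
#' or zero spatial structure recoverable), a nugget-only model is returned
#' with a warning.
#'
#' @param ev Empirical variogram from [empirical_variogram()] (needs >= 3
#'   bins).
#' @param model Model family: "exponential" (default), "spherical" or
#'   "gaussian".
#' @return List of class `variogram_model` with `model`, `nugget`,
#'   `psill`, `range_param`, `converged`.
#' @export
fit_variogram <- function(ev, model = c("exponential", "spherical",
                                        "gaussian")) {
  model <- match.arg(model)
  stopifnot(is.data.frame(ev), all(c("dist", "gamma", "n_pairs") %in%
                                     names(ev)))
  if (nrow(ev) < 3L) stop("need at least 3 variogram bins", call. = FALSE)
  obj <- function(par) {
    g <- .vgm_gamma(ev$dist, model, par[1], par[2], par[3])
    sum(ev$n_pairs * (g - ev$gamma)^2)
  }
  s0 <- max(ev$gamma)
  init <- c(nugget = 0.1 * s0 + 1e-8, psill = 0.9 * s0 + 1e-8,
            range_param = max(ev$dist) / 3)
  fit <- try(stats::optim(init, obj, method = "L-BFGS-B",
                          lower = c(0, 0, 1e-6 * max(ev$dist)),
                          upper = c(2 * s0 + 1, 2 * s0 + 1,
                                    10 * max(ev$dist)),
                          control = list(factr = 10, maxit = 500)),
             silent = TRUE)
  if (inherits(fit, "try-error") || !all(is.finite(fit$par))) {
    warning("degenerate variogram fit; falling back to nugget-only model",
            call. = FALSE)
    return(structure(list(model = model,
                          nugget = stats::weighted.mean(ev$gamma,
                                                        ev$n_pairs),
                          psill = 0, range_param = max(ev$dist),
                          converged = FALSE),
                     class = "variogram_model"))
  }
  structure(list(model = model, nugget = fit$par[[1]], psill = fit$par[[2]],
                 range_param = fit$par[[3]],
                 converged = fit$convergence == 0),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("%s variogram: nugget %.4g, partial sill %.4g, range %.4g%s\n",
              x$model, x$nugget, x$psill, x$range_param,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

# covariance from the variogram: C(d) = sill_total - gamma(d)
.vgm_cov <- function(d, m) {
  total <- m$nugget + m$psill
  total - .vgm_gamma(d, m$model, m$nugget, m$psill, m$range_param)
}

#' Ordinary kriging of EA-level values onto a grid
#'
#' Best linear unbiased spatial prediction: at every target node the
#' kriging weights solve the ordinary-kriging system (data covariances
#' augmented with the unbiasedness constraint that weights sum to one) and
#' the prediction is the weighted combination of the observed values, with
#' the kriging variance as a by-product. With a zero nugget the predictor
#' interpolates the data exactly; a constant input field is reproduced
#' exactly everywhere. If the data covariance matrix is numerically
#' singular, a ridge of 1e-10 is added once before failing.
#'
#' Predictions are returned raw; `m0_clamped` additionally restricts them
#' to \[0, 1\] for display of proportions.
#'
#' @param eas Data frame with `x`, `y` and the value column.
#' @param model A `variogram_model` (see [fit_variogram()]).
#' @param grid_x,grid_y Numeric vectors of grid coordinates; default a
#'   100 x 100 lattice over the data bounding box. Predictions are made at
#'   every (x, y) combination.
#' @param value_col Name of the value column (default "m0").
#' @return Object of class `kriged_surface`: data frame `grid` with
#'   columns `x`, `y`, `pred`, `m0_clamped`, `ok_variance`, plus
#'   `max_weight_dev` (largest |sum of weights - 1| across nodes) and the
#'   model.
#' @export
krige_ok <- function(eas, model, grid_x = NULL, grid_y = NULL,
                     value_col = "m0") {
  stopifnot(inherits(model, "variogram_model"),
            all(c("x", "y", value_col) %in% names(eas)),
            nrow(eas) >= 2L)
  xs <- eas$x; ys <- eas$y; v <- eas[[value_col]]
  if (is.null(grid_x)) grid_x <- seq(min(xs), max(xs), length.out = 100)
  if (is.null(grid_y)) grid_y <- seq(min(ys), max(ys), length.out = 100)
  n <- length(xs)
  D <- as.matrix(stats::dist(cbind(xs, ys)))
  C <- .vgm_cov(D, model)
  A <- rbind(cbind(C, 1), c(rep(1, n), 0))
  Ai <- try(solve(A), silent = TRUE)
  if (inherits(Ai, "try-error")) {
    A[seq_len(n), seq_len(n)] <- C + diag(1e-10, n)
    Ai <- solve(A)  # errors if still singular
  }
  gp <- expand.grid(x = grid_x, y = grid_y)
  dx <- outer(xs, gp$x, function(a, b) (a - b))
  dy <- outer(ys, gp$y, function(a, b) (a - b))
  d0 <- sqrt(dx^2 + dy^2)
  c0 <- .vgm_cov(d0, model)                # n x m
  # at zero distance the target coincides with a datum: C(0) = total sill
  c0[d0 == 0] <- model$nugget + model$psill
  rhs <- rbind(c0, 1)
  sol <- Ai %*% rhs                        # (n+1) x m
  lambda <- sol[seq_len(n), , drop = FALSE]
  mu <- sol[n + 1L, ]
  pred <- as.vector(crossprod(lambda, v))
  total <- model$nugget + model$psill
  okvar <- pmax(total - colSums(lambda * c0) - mu, 0)
  wdev <- max(abs(colSums(lambda) - 1))
  grid <- data.frame(x = gp$x, y = gp$y, pred = pred,
                     m0_clamped = pmin(pmax(pred, 0), 1),
                     ok_variance = okvar)
  structure(list(grid = grid, model = model, max_weight_dev = wdev,
                 n_data = n), class = "kriged_surface")
}

#' @export
print.kriged_surface <- function(x, ...) {
  cat(sprintf(
    "Ordinary-kriged surface: %d nodes from %d data points (%s model)\n",
    nrow(x$grid), x$n_data, x$model$model))
  cat(sprintf("  prediction range [%.4f, %.4f]; max |sum(weights)-1| = %.2e\n",
              min(x$grid$pred), max(x$grid$pred), x$max_weight_dev))
  invisible(x)
}

#' @export
plot.kriged_surface <- function(x, ...) {
  xs <- sort(unique(x$grid$x)); ys <- sort(unique(x$grid$y))
  z <- matrix(x$grid$m0_clamped, length(xs), length(ys))
  graphics::image(xs, ys, z, xlab = "x", ylab = "y",
                  main = "kriged adjusted headcount", ...)
  invisible(x)
}

#' Write planar points as a GeoJSON FeatureCollection
#'
#' Minimal RFC 7946 writer: each row becomes a Point feature with the named
#' columns as properties. Coordinates are taken from columns `x` and `y`.
#'
#' @param df Data frame with `x`, `y` and property columns.
#' @param path Output file.
#' @param properties Character vector of property column names.
#' @return Invisibly, `path`.
#' @export
write_geojson_points <- function(df, path, properties = character(0)) {
  stopifnot(all(c("x", "y") %in% names(df)),
            all(properties %in% names(df)))
  feats <- lapply(seq_len(nrow(df)), function(i) {
    props <- as.list(df[i, properties, drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(df$x[i], df$y[i])),
         properties = props)
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
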