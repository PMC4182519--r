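#' @title Synthetic two-stage cluster household surveys
#' @description A calibrated generator emulating a rural household survey:
#'   enumeration areas (EAs) scattered over a planar region and grouped into
#'   districts, a spatially autocorrelated EA-level poverty propensity, raw
#'   household fields whose deprivation rules hit prescribed marginal rates,
#'   a two-stage sampling design with inverse-probability weights, household
#'   income with a point mass at zero, and a 37-item asset block driven by a
#'   latent wealth variable.
#' @name synthetic-survey
NULL

# Table of default per-indicator deprivation targets (proportions)
.default_marginals <- c(
  low_literacy = 0.147, child_not_in_school = 0.176,
  child_acute_illness = 0.215, low_dietary_diversity = 0.154,
  food_lack_episode = 0.304, no_electricity = 0.951,
  unsafe_water = 0.297, no_latrine = 0.756, grass_roof = 0.925,
  wood_fuel = 0.959, low_assets = 0.432
)

.default_districts <- c(Morrumbala = 0.25, Namacurra = 0.25,
                        `Alto Molocue` = 0.245, Other = 0.26)

#' Configuration for the synthetic survey generator
#'
#' Collects and validates every knob of the generator. Defaults describe the
#' survey the package's analyses assume: 259 EAs of 15 households each, 96%
#' rural, indicator deprivation targets equal to the standard 11-indicator
#' marginal rates, a spatially autocorrelated EA effect (exponential
#' covariance), and 49% of households reporting zero monetary income.
#'
#' @param n_eas Number of enumeration areas (>= 2).
#' @param households_per_ea Households interviewed per EA (>= 1).
#' @param rural_fraction Proportion of EAs designated rural.
#' @param district_shares Named vector of district EA-allocation shares
#'   (will be normalized); districts are laid out as contiguous vertical
#'   bands of the bounding box.
#' @param target_marginals Named vector of 11 target deprivation
#'   proportions in the indicator order of [indicator_specs()].
#' @param latent_spatial_range Range (distance units) of the exponential
#'   spatial covariance of the EA poverty propensity.
#' @param latent_sill Variance of the EA poverty propensity (>= 0).
#' @param ea_bbox Planar bounding box `c(xmin, ymin, xmax, ymax)`.
#' @param income_zero_fraction Probability a household reports zero income.
#' @param seed Integer RNG seed; fixed seed gives byte-identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_eas = 259L,
                       households_per_ea = 15L,
                       rural_fraction = 0.96,
                       district_shares = .default_districts,
                       target_marginals = .default_marginals,
                       latent_spatial_range = 10,
                       latent_sill = 0.3,
                       ea_bbox = c(0, 0, 100, 100),
                       income_zero_fraction = 0.49,
                       seed = 1L) {
  chk <- function(ok, field, what) {
    if (!ok) stop("invalid configuration field '", field, "': ", what,
                  call. = FALSE)
  }
  chk(is.numeric(n_eas) && n_eas >= 2, "n_eas", "need at least 2 EAs")
  chk(is.numeric(households_per_ea) && households_per_ea >= 1,
      "households_per_ea", "need at least 1 household per EA")
  chk(rural_fraction >= 0 && rural_fraction <= 1, "rural_fraction",
      "must be a proportion in [0,1]")
  chk(length(target_marginals) == 11 && all(target_marginals >= 0) &&
        all(target_marginals <= 1), "target_marginals",
      "need 11 proportions in [0,1]")
  chk(latent_sill >= 0, "latent_sill", "variance must be non-negative")
  chk(latent_spatial_range > 0 || latent_sill == 0, "latent_spatial_range",
      "must be positive when latent_sill > 0")
  chk(length(ea_bbox) == 4 && ea_bbox[3] > ea_bbox[1] &&
        ea_bbox[4] > ea_bbox[2], "ea_bbox", "need c(xmin,ymin,xmax,ymax)")
  chk(income_zero_fraction >= 0 && income_zero_fraction <= 1,
      "income_zero_fraction", "must be a proportion in [0,1]")
  chk(length(district_shares) >= 1 && all(district_shares > 0),
      "district_shares", "need positive shares")
  chk(is.numeric(seed) && is.finite(seed), "seed", "need a finite integer")
  if (is.null(names(target_marginals)))
    names(target_marginals) <- indicator_specs()$name
  structure(list(
    n_eas = as.integer(n_eas),
    households_per_ea = as.integer(households_per_ea),
    rural_fraction = rural_fraction,
    district_shares = district_shares / sum(district_shares),
    target_marginals = target_marginals,
    latent_spatial_range = latent_spatial_range,
    latent_sill = latent_sill,
    ea_bbox = ea_bbox,
    income_zero_fraction = income_zero_fraction,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Draw a zero-mean Gaussian process over EA locations
#'
#' Simulates one realisation of a zero-mean Gaussian field with exponential
#' covariance \eqn{C(d) = \mathrm{sill} \cdot e^{-d/\mathrm{range}}} at the
#' given planar points (Cholesky of the dense covariance, with a tiny
#' diagonal jitter so coincident points remain admissible). `sill = 0`
#' returns exact zeros.
#'
#' @param coords Two-column matrix or data frame of planar x, y.
#' @param range_param Correlation range (> 0 unless `sill = 0`).
#' @param sill Marginal variance (>= 0).
#' @param seed Integer seed.
#' @return Numeric vector, one field value per point.
#' @export
spatial_latent_field <- function(coords, range_param, sill, seed) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1L) stop("need at least one point", call. = FALSE)
  if (any(!is.finite(coords))) stop("non-finite coordinates", call. = FALSE)
  if (sill < 0) stop("sill must be non-negative", call. = FALSE)
  if (sill == 0) return(rep(0, nrow(coords)))
  if (range_param <= 0) stop("range_param must be positive", call. = FALSE)
  d <- as.matrix(stats::dist(coords))
  cv <- sill * exp(-d / range_param)
  diag(cv) <- diag(cv) + 1e-10
  L <- chol(cv)
  set.seed(seed)
  as.vector(crossprod(L, stats::rnorm(nrow(coords))))
}

#' Probit-scale threshold for a target deprivation rate
#'
#' The generator classifies a household as deprived on an indicator when
#' (EA effect + standard-normal noise) falls below a threshold t. Given the
#' EA-effect standard deviation, this returns the t for which
#' \eqn{P(\mathrm{latent} + \mathrm{noise} < t)} equals the target rate:
#' \eqn{t = \Phi^{-1}(\mathrm{rate}) \sqrt{1 + \mathrm{sd}^2}}. Rates of 0
#' and 1 map to -Inf/+Inf sentinels (no household / every household
#' deprived).
#'
#' @param target_rate Desired marginal deprivation rate in \[0, 1\].
#' @param latent_sd Standard deviation of the EA-level latent effect.
#' @return Threshold on the probit scale.
#' @export
#' @examples
#' calibrate_threshold(0.951, 0)  # qnorm(0.951)
calibrate_threshold <- function(target_rate, latent_sd = 0) {
  stopifnot(target_rate >= 0, target_rate <= 1, latent_sd >= 0)
  stats::qnorm(target_rate) * sqrt(1 + latent_sd^2)
}

#' Generate a synthetic two-stage cluster household survey
#'
#' Produces a household table and an EA table emulating the sampling design
#' the package's estimators assume. EAs are scattered uniformly over the
#' bounding box and partitioned into contiguous district bands; each EA
#' receives a spatially autocorrelated poverty propensity \eqn{a_e} (see
#' [spatial_latent_field()]). For each indicator j a household is deprived
#' when \eqn{a_e + \varepsilon < t_j} with standard-normal noise and the
#' threshold from [calibrate_threshold()], so each observed deprivation rate
#' matches its target marginally in expectation while households within an
#' EA are positively correlated. Raw survey fields (literacy/numeracy
#' scores, dietary diversity, water variables, asset flags, ...) are then
#' drawn uniformly within the deprived or non-deprived region of each rule,
#' so that [deprivation_matrix()] recovers exactly the simulated flags.
#'
#' Sampling design: EAs carry a synthetic size measure; first-stage
#' inclusion probabilities are proportional to size, households are drawn
#' equal-probability within EA, and `sampling_probability` is the product.
#' Stratum = district x urban/rural. Income is zero with probability
#' `income_zero_fraction` and lognormal otherwise; a 37-item binary asset
#' block is generated from a one-factor probit model on a latent wealth
#' score negatively correlated with the EA poverty propensity.
#'
#' @param config A [sim_config()].
#' @return List of class `survey_tables` with data frames `households` and
#'   `eas`.
#' @export
#' @examples
#' sim <- simulate_survey(sim_config(n_eas = 10, households_per_ea = 5, seed = 3))
#' nrow(sim$households)  # 50
simulate_survey <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("'config' must be created by sim_config()", call. = FALSE)
  set.seed(config$seed)
  n_eas <- config$n_eas
  hh_per <- config$households_per_ea
  n <- n_eas * hh_per
  bb <- config$ea_bbox

  # --- EA frame: coordinates, contiguous district bands, strata ----------
  ex <- stats::runif(n_eas, bb[1], bb[3])
  ey <- stats::runif(n_eas, bb[2], bb[4])
  shares <- config$district_shares
  cuts <- bb[1] + cumsum(c(0, shares)) * (bb[3] - bb[1])
  district <- names(shares)[pmin(findInterval(ex, cuts,
                                              rightmost.closed = TRUE),
                                 length(shares))]
  urban <- stats::runif(n_eas) > config$rural_fraction
  stratum <- paste(district, ifelse(urban, "urban", "rural"), sep = ":")
  size_measure <- pmax(round(exp(stats::rnorm(n_eas, log(120), 0.3))),
                       hh_per)
  p_ea <- pmin(size_measure / max(size_measure), 1)
  p_hh <- pmin(hh_per / size_measure, 1)
  ea_id <- sprintf("EA%04d", seq_len(n_eas))

  # EA-level poverty propensity from the spatial field
  a <- spatial_latent_field(cbind(ex, ey), config$latent_spatial_range,
                            config$latent_sill,
                            seed = (config$seed %% 1000000L) + 1L)
  set.seed(config$seed + 2L)  # field draw consumed its own stream

  eas <- data.frame(ea_id = ea_id, district = district, stratum = stratum,
                    urban = urban, x = ex, y = ey,
                    size_measure = size_measure,
                    sampling_probability = p_ea,
                    stringsAsFactors = FALSE)

  # --- deprivation flags per indicator (probit threshold model) ----------
  idx <- rep(seq_len(n_eas), each = hh_per)
  sd_lat <- sqrt(config$latent_sill)
  marg <- config$target_marginals
  flags <- matrix(0L, n, 11L, dimnames = list(NULL, names(marg)))
  for (j in seq_len(11L)) {
    t_j <- calibrate_threshold(marg[j], sd_lat)
    flags[, j] <- as.integer(a[idx] + stats::rnorm(n) < t_j)
  }

  # --- raw fields drawn inside the proper region of each rule ------------
  rint <- function(lo, hi) lo + floor(stats::runif(n) * (hi - lo + 1))
  hh <- data.frame(
    household_id = sprintf("HH%05d", seq_len(n)),
    ea_id = ea_id[idx], district = district[idx], stratum = stratum[idx],
    urban = urban[idx], stringsAsFactors = FALSE
  )

  # literacy rule: deprived iff literacy<16 AND numeracy<5
  lit_d <- flags[, "low_literacy"] == 1L
  which_pass <- stats::runif(n) < 0.5  # non-deprived escape: literacy or numeracy
  hh$literacy_score <- ifelse(lit_d, rint(0, 15),
                              ifelse(which_pass, rint(16, 24), rint(0, 15)))
  hh$numeracy_score <- ifelse(lit_d, rint(0, 4),
                              ifelse(which_pass, rint(0, 8), rint(5, 10)))

  # child enrollment: deprived households have a non-attending child
  enr_d <- flags[, "child_not_in_school"] == 1L
  has_child <- ifelse(enr_d, TRUE, stats::runif(n) < 0.7)
  hh$has_school_age_child <- has_child
  hh$school_age_child_attending <- ifelse(!has_child, NA, !enr_d)

  hh$child_acute_illness <- flags[, "child_acute_illness"] == 1L
  hh$hdds <- ifelse(flags[, "low_dietary_diversity"] == 1L,
                    rint(0, 3), rint(4, 12))
  hh$lack_food_episode <- flags[, "food_lack_episode"] == 1L
  hh$electricity <- flags[, "no_electricity"] == 0L

  # water: deprived iff river OR (>30min AND on foot)
  wat_d <- flags[, "unsafe_water"] == 1L
  river <- wat_d & stats::runif(n) < 0.5
  hh$water_source_river <- river
  hh$water_time_gt30 <- ifelse(wat_d & !river, TRUE,
                               ifelse(wat_d, stats::runif(n) < 0.3,
                                      stats::runif(n) < 0.3))
  hh$water_on_foot <- ifelse(wat_d & !river, TRUE,
                             ifelse(wat_d, stats::runif(n) < 0.8,
                                    # non-deprived: on foot only if quick
                                    ifelse(hh$water_time_gt30, FALSE,
                                           stats::runif(n) < 0.8)))
  hh$uses_latrine <- flags[, "no_latrine"] == 0L
  hh$roof_grass <- flags[, "grass_roof"] == 1L
  hh$cooks_with_wood <- flags[, "wood_fuel"] == 1L

  # assets: deprived iff owns none of radio/tv/bicycle
  ast_d <- flags[, "low_assets"] == 1L
  r <- stats::runif(n) < 0.55
  tv <- stats::runif(n) < 0.10
  bk <- stats::runif(n) < 0.45
  none <- !(r | tv | bk)
  r[none] <- TRUE  # force at least one for the non-deprived draw
  hh$owns_radio <- ifelse(ast_d, FALSE, r)
  hh$owns_tv <- ifelse(ast_d, FALSE, tv)
  hh$owns_bicycle <- ifelse(ast_d, FALSE, bk)

  # income: point mass at zero, lognormal otherwise
  zero <- stats::runif(n) < config$income_zero_fraction
  hh$monthly_income_mzn <- ifelse(zero, 0,
                                  round(stats::rlnorm(n, log(300), 1)))
  hh$household_size <- 1L + stats::rpois(n, 3.5)

  # language: mostly homogeneous within EA
  langs <- c(Cisena = 0.443, Elomwe = 0.276, Echuabo = 0.256,
             Portuguese = 0.013, Cinyanja = 0.008, Emakhuwa = 0.004)
  ea_lang <- sample(names(langs), n_eas, replace = TRUE, prob = langs)
  hh$language <- ea_lang[idx]

  # 37-item asset block from a one-factor probit on latent wealth
  z <- -(0.8 * a[idx]) + stats::rnorm(n)
  z <- (z - mean(z)) / stats::sd(z)
  bet <- stats::runif(37, 0.5, 1.5)
  tau <- stats::runif(37, -1.5, 1.5)
  items <- matrix(0L, n, 37L,
                  dimnames = list(NULL, sprintf("asset_%02d", 1:37)))
  for (l in 1:37)
    items[, l] <- as.integer(bet[l] * z + stats::rnorm(n) > tau[l])
  hh <- cbind(hh, as.data.frame(items))

  hh$sampling_probability <- p_ea[idx] * p_hh[idx]

  structure(list(households = hh, eas = eas, config = config),
            class = "survey_tables")
}

#' @export
print.survey_tables <- function(x, ...) {
  cat("Synthetic household survey:", nrow(x$households), "households in",
      nrow(x$eas), "EAs,",
      length(unique(x$eas$district)), "districts\n")
  invisible(x)
}

#' Write the survey tables to disk
#'
#' Writes `households.csv`, `eas.csv`, `eas.geojson` (RFC 7946 Point
#' features with ea_id/district/stratum properties) and a `config.yaml`
#' echo of the generator configuration into a directory.
#'
#' @param sim A `survey_tables` object from [simulate_survey()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_survey <- function(sim, dir) {
  stopifnot(inherits(sim, "survey_tables"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ph <- file.path(dir, "households.csv")
  pe <- file.path(dir, "eas.csv")
  pg <- file.path(dir, "eas.geojson")
  pc <- file.path(dir, "config.yaml")
  utils::write.csv(sim$households, ph, row.names = FALSE)
  utils::write.csv(sim$eas, pe, row.names = FALSE)
  write_geojson_points(sim$eas, pg,
                       properties = c("ea_id", "district", "stratum"))
  yaml::write_yaml(unclass(sim$config), pc)
  invisible(c(ph, pe, pg, pc))
}

#' Expected superpopulation headcount under the generator's model
#'
#' Computes, by Gauss-Hermite quadrature over the EA effect and exact
#' dynamic programming over the 11 conditionally independent indicator
#' Bernoullis, the probability that a household's weighted deprivation
#' score reaches the poverty cut-off — i.e. the true headcount the
#' generator's configuration implies. Used as the ground truth in coverage
#' simulations.
#'
#' @param marginals 11 target deprivation rates.
#' @param sill EA-effect variance (`latent_sill` of the generator).
#' @param k Poverty cut-off (default 1/3).
#' @param specs Indicator specification table (for the exact weights).
#' @param inclusive Identification rule, as in [af_fit()].
#' @param nodes Number of quadrature nodes.
#' @return The expected headcount H, a single proportion.
#' @export
expected_headcount <- function(marginals, sill, k = 1/3,
                               specs = indicator_specs(),
                               inclusive = TRUE, nodes = 41) {
  stopifnot(length(marginals) == nrow(specs))
  wnum <- specs$weight_num
  den <- specs$weight_den[1]
  thr <- vapply(marginals, calibrate_threshold, numeric(1),
                latent_sd = sqrt(sill))
  gq <- if (sill > 0)
    statmod::gauss.quad.prob(nodes, dist = "normal", sigma = sqrt(sill))
  else list(nodes = 0, weights = 1)
  kcut <- k * den
  H <- 0
  for (q in seq_along(gq$nodes)) {
    p <- stats::pnorm(thr - gq$nodes[q])  # P(deprived_j | a)
    # DP over exact integer score
    dist <- c(1, rep(0, sum(wnum)))
    for (j in seq_along(wnum)) {
      shifted <- c(rep(0, wnum[j]), dist[seq_len(length(dist) - wnum[j])])
      dist <- dist * (1 - p[j]) + shifted * p[j]
    }
    sc <- seq_along(dist) - 1L
    ppoor <- if (inclusive) sum(dist[sc >= kcut - 1e-9])
             else sum(dist[sc > kcut + 1e-9])
    H <- H + gq$weights[q] * ppoor
  }
  H
}
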