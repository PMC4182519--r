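test_that("fixed seed gives byte-identical surveys", {
  cfg <- sim_config(n_eas = 15, households_per_ea = 6, seed = 123)
  s1 <- simulate_survey(cfg)
  s2 <- simulate_survey(cfg)
  expect_identical(s1$households, s2$households)
  expect_identical(s1$eas, s2$eas)
})

test_that("observed deprivation rates track their targets", {
  sim <- simulate_survey(sim_config(n_eas = 200, households_per_ea = 15,
                                    seed = 42))
  dm <- deprivation_matrix(sim$households)
  rates <- colMeans(dm$g0)
  # Monte-Carlo SE of each overall rate from the between-EA variation
  # (EAs have equal size, so the overall rate is the mean of EA rates)
  ea <- dm$design$psu
  for (j in seq_len(ncol(dm$g0))) {
    ea_rates <- tapply(dm$g0[, j], ea, mean)
    se <- stats::sd(ea_rates) / sqrt(length(ea_rates))
    expect_lt(abs(rates[j] - table1_marginals[j]), 4 * se + 1e-12)
  }
  # spec headline: electricity deprivation within 1.5pp of its target
  expect_lt(abs(rates["no_electricity"] - 0.951), 0.015)
})

test_that("degenerate marginals yield no deprivations at all", {
  cfg <- sim_config(n_eas = 5, households_per_ea = 10,
                    target_marginals = rep(0, 11), seed = 2)
  dm <- deprivation_matrix(simulate_survey(cfg)$households)
  expect_true(all(dm$g0 == 0L))
})

test_that("invalid configuration errors name the offending field", {
  expect_error(sim_config(n_eas = 1), "n_eas")
  expect_error(sim_config(households_per_ea = 0), "households_per_ea")
  expect_error(sim_config(target_marginals = rep(0.5, 10)),
               "target_marginals")
  expect_error(sim_config(latent_sill = -1), "latent_sill")
  expect_error(sim_config(income_zero_fraction = 1.2),
               "income_zero_fraction")
  expect_error(sim_config(ea_bbox = c(0, 0, 0, 0)), "ea_bbox")
})

test_that("spatial latent field honours sill, range and coincidence", {
  xy <- cbind(runif(100, 0, 50), runif(100, 0, 50))
  expect_identical(spatial_latent_field(xy, 5, 0, seed = 1), rep(0, 100))
  # negligible range: values behave as iid N(0, sill)
  set.seed(31)
  xy2 <- cbind(runif(500, 0, 100), runif(500, 0, 100))
  z <- spatial_latent_field(xy2, 1e-4, 1, seed = 9)
  ord <- order(xy2[, 1])
  r <- cor(z[ord][-1], z[ord][-500])  # neighbours along x
  expect_lt(abs(r), 3 / sqrt(500))
  expect_lt(abs(var(z) - 1), 4 * sqrt(2 / 499))
  # coincident points share the field value (zero-distance correlation 1)
  z2 <- spatial_latent_field(rbind(c(1, 1), c(1, 1), c(9, 4)), 3, 1,
                             seed = 4)
  expect_lt(abs(z2[1] - z2[2]), 1e-3)
  expect_error(spatial_latent_field(rbind(c(NA, 1)), 3, 1, seed = 1),
               "non-finite")
})

test_that("probit thresholds invert the target rates", {
  expect_equal(calibrate_threshold(0.5, 0), 0)
  expect_equal(calibrate_threshold(0.951, 0), qnorm(0.951))
  expect_identical(calibrate_threshold(0, 3), -Inf)
  expect_identical(calibrate_threshold(1, 3), Inf)
  # with an EA effect of sd s the marginal is Phi(t / sqrt(1 + s^2))
  t <- calibrate_threshold(0.3, 2)
  expect_equal(pnorm(t / sqrt(1 + 4)), 0.3)
})

test_that("income zero share and design fields are as configured", {
  cfg <- sim_config(n_eas = 100, households_per_ea = 10,
                    income_zero_fraction = 0.49, seed = 8)
  sim <- simulate_survey(cfg)
  hh <- sim$households
  p0 <- mean(hh$monthly_income_mzn == 0)
  se <- sqrt(0.49 * 0.51 / nrow(hh))
  expect_lt(abs(p0 - 0.49), 3 * se)
  expect_true(all(hh$sampling_probability > 0 &
                    hh$sampling_probability <= 1))
  expect_true(all(hh$ea_id %in% sim$eas$ea_id))
  expect_setequal(unique(hh$district), names(cfg$district_shares))
})

test_that("independent households arise when sill is 0 and EAs are singletons", {
  cfg <- sim_config(n_eas = 600, households_per_ea = 1, latent_sill = 0,
                    target_marginals = rep(0.5, 11), seed = 77)
  dm <- deprivation_matrix(simulate_survey(cfg)$households)
  # pairwise correlation between indicator columns near zero
  cors <- cor(dm$g0)[upper.tri(diag(11))]
  expect_lt(max(abs(cors)), 3 / sqrt(600))
})

test_that("survey tables round-trip through disk", {
  sim <- simulate_survey(sim_config(n_eas = 6, households_per_ea = 3,
                                    seed = 5))
  dir <- tempfile("survey")
  paths <- write_survey(sim, dir)
  expect_true(all(file.exists(paths)))
  hh <- read.csv(file.path(dir, "households.csv"))
  expect_equal(nrow(hh), 18)
  gj <- jsonlite::read_json(file.path(dir, "eas.geojson"))
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, 6)
  expect_equal(gj$features[[1]]$geometry$type, "Point")
})
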