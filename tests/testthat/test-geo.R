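exp_model <- function(nugget = 0, psill = 1, range_param = 5) {
  structure(list(model = "exponential", nugget = nugget, psill = psill,
                 range_param = range_param, converged = TRUE),
            class = "variogram_model")
}

test_that("EA aggregation respects the pooled decomposition identity", {
  sim <- simulate_survey(sim_config(n_eas = 30, households_per_ea = 8,
                                    seed = 21))
  dm <- deprivation_matrix(sim$households)
  ea <- ea_headcounts(dm, sim$eas)
  expect_true(all(ea$m0 >= 0 & ea$m0 <= 1))
  expect_equal(nrow(ea), 30L)
  # weight-share-weighted EA m0 recombines to the overall M0
  w_ea <- tapply(dm$design$weight, dm$design$psu, sum)
  shares <- as.vector(w_ea[ea$ea_id]) / sum(w_ea)
  fit <- af_fit(dm)
  expect_lt(abs(sum(shares * ea$m0) - fit$M0$estimate), 1e-12)
})

test_that("single-EA and all-nonpoor EAs are handled", {
  sim <- simulate_survey(sim_config(n_eas = 2, households_per_ea = 10,
                                    seed = 3))
  dm <- deprivation_matrix(sim$households)
  idx <- dm$design$psu == sim$eas$ea_id[1]
  dm1 <- structure(list(g0 = dm$g0[idx, , drop = FALSE],
                        household_id = dm$household_id[idx],
                        weights_num = dm$weights_num,
                        weights_den = dm$weights_den,
                        dimension = dm$dimension,
                        design = dm$design[idx, , drop = FALSE]),
                   class = "deprivation_matrix")
  ea1 <- ea_headcounts(dm1, sim$eas)
  expect_equal(nrow(ea1), 1L)  # empty EA omitted
  expect_equal(ea1$m0, af_fit(dm1)$M0$estimate)
  # an EA of fully non-deprived households has m0 = 0
  g0 <- matrix(0L, 5, 11)
  dm0 <- make_dm(g0, indicator_specs()$weight_num, 36L,
                 psu = rep("EA0001", 5))
  ea_tab <- data.frame(ea_id = "EA0001", x = 0, y = 0)
  expect_equal(ea_headcounts(dm0, ea_tab)$m0, 0)
})

test_that("empirical variogram definition on small cases", {
  # two points: one bin with gamma = (v1 - v2)^2 / 2
  ev <- empirical_variogram(cbind(c(0, 3), c(0, 4)), c(1, 4), n_bins = 1,
                            max_dist = 10)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$gamma, (1 - 4)^2 / 2)
  expect_equal(ev$dist, 5)
  expect_equal(ev$n_pairs, 1L)
  # constant field: all semivariances zero
  set.seed(11)
  xy <- cbind(runif(30), runif(30))
  evc <- empirical_variogram(xy, rep(2, 30))
  expect_true(all(evc$gamma == 0))
  expect_error(empirical_variogram(cbind(c(1, 1), c(2, 2)), c(1, 2)),
               "coincident")
})

test_that("noiseless model bins are recovered to high precision", {
  d <- seq(1, 30, length.out = 12)
  for (fam in c("exponential", "spherical", "gaussian")) {
    vm <- structure(list(model = fam, nugget = 0.05, psill = 0.8,
                         range_param = 6, converged = TRUE),
                    class = "variogram_model")
    g <- afpoverty:::.vgm_gamma(d, fam, 0.05, 0.8, 6)
    ev <- data.frame(dist = d, gamma = g, n_pairs = 50L)
    f <- fit_variogram(ev, fam)
    expect_lt(abs(f$nugget - 0.05), 1e-6)
    expect_lt(abs(f$psill - 0.8), 1e-6)
    expect_lt(abs(f$range_param - 6), 1e-4)
  }
  expect_error(fit_variogram(data.frame(dist = 1, gamma = 1, n_pairs = 1)),
               "3 variogram bins")
})

test_that("pure-nugget fields fit with negligible partial sill", {
  set.seed(12)
  xy <- cbind(runif(300, 0, 100), runif(300, 0, 100))
  v <- rnorm(300)
  f <- fit_variogram(empirical_variogram(xy, v), "exponential")
  expect_lt(f$psill / (f$nugget + f$psill + 1e-12), 0.25)
})

test_that("ordinary kriging: constant field, exact interpolation, weights", {
  set.seed(13)
  eas <- data.frame(x = runif(25, 0, 10), y = runif(25, 0, 10),
                    m0 = rep(0.4, 25))
  ks <- krige_ok(eas, exp_model(), grid_x = seq(0, 10, 2),
                 grid_y = seq(0, 10, 2))
  expect_true(all(abs(ks$grid$pred - 0.4) < 1e-8))   # constant reproduced
  expect_lt(ks$max_weight_dev, 1e-8)                 # unbiasedness
  # exact interpolation at data sites when nugget = 0
  eas2 <- data.frame(x = c(0, 4, 9), y = c(1, 5, 2),
                     m0 = c(0.1, 0.7, 0.3))
  ks2 <- krige_ok(eas2, exp_model(), grid_x = c(0, 4, 9), grid_y = c(1, 5, 2))
  at_data <- merge(ks2$grid, eas2, by = c("x", "y"))
  expect_equal(at_data$pred, at_data$m0, tolerance = 1e-8)
  expect_true(all(ks2$grid$ok_variance >= 0))
  expect_true(all(ks2$grid$m0_clamped >= 0 & ks2$grid$m0_clamped <= 1))
})

test_that("symmetric midpoint of two data points predicts their mean", {
  eas <- data.frame(x = c(0, 10), y = c(0, 0), m0 = c(0.2, 0.6))
  for (fam in c("exponential", "spherical", "gaussian")) {
    vm <- structure(list(model = fam, nugget = 0, psill = 1,
                         range_param = 5, converged = TRUE),
                    class = "variogram_model")
    ks <- krige_ok(eas, vm, grid_x = 5, grid_y = 0)
    expect_equal(ks$grid$pred, 0.4)
  }
})

test_that("kriging beats the global-mean predictor on smooth fields", {
  set.seed(14)
  rmse_k <- rmse_m <- numeric(10)
  for (r in 1:10) {
    xy <- cbind(runif(120, 0, 50), runif(120, 0, 50))
    v <- spatial_latent_field(xy, range_param = 10, sill = 1,
                              seed = 900L + r)
    train <- 1:80; test <- 81:120
    ev <- empirical_variogram(xy[train, ], v[train])
    vm <- fit_variogram(ev, "exponential")
    preds <- vapply(test, function(i) {
      krige_ok(data.frame(x = xy[train, 1], y = xy[train, 2],
                          m0 = v[train]), vm,
               grid_x = xy[i, 1], grid_y = xy[i, 2])$grid$pred
    }, numeric(1))
    rmse_k[r] <- sqrt(mean((preds - v[test])^2))
    rmse_m[r] <- sqrt(mean((mean(v[train]) - v[test])^2))
  }
  expect_lt(mean(rmse_k), mean(rmse_m))
})

test_that("GeoJSON point export is a valid FeatureCollection", {
  df <- data.frame(x = c(1, 2), y = c(3, 4), ea_id = c("a", "b"),
                   m0 = c(0.1, 0.9))
  p <- tempfile(fileext = ".geojson")
  write_geojson_points(df, p, properties = c("ea_id", "m0"))
  gj <- jsonlite::read_json(p)
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, 2)
  f1 <- gj$features[[1]]
  expect_equal(f1$geometry$coordinates, list(1, 3))
  expect_equal(f1$properties$ea_id, "a")
})
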