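test_that("deprivation scores are exact weighted sums", {
  specs <- indicator_specs()
  g0 <- matrix(0L, 3, 11, dimnames = list(NULL, specs$name))
  g0[1, ] <- 1L                      # deprived in everything
  g0[2, "no_electricity"] <- 1L      # one 1/18 indicator
  g0[3, c("low_literacy", "no_latrine")] <- 1L  # 1/6 + 1/18 = 2/9
  dm <- make_dm(g0, specs$weight_num, specs$weight_den[1])
  expect_equal(deprivation_scores(dm), c(1, 1/18, 2/9))
})

test_that("identification: inclusive rule at the exact cut-off", {
  expect_equal(identify_poor(c(0.5, 0.2, 1/3, 0), k = 1/3),
               c(1L, 0L, 1L, 0L))
  expect_equal(identify_poor(1/3, k = 1/3, inclusive = FALSE), 0L)
  expect_equal(identify_poor(0, k = 0.01), 0L)          # c = 0 never poor
  expect_equal(identify_poor(12/36, k = 1/3), 1L)       # exact boundary
  expect_equal(identify_poor(11/36, k = 1/3), 0L)
})

test_that("censoring zeroes exactly the non-poor", {
  cc <- c(0.5, 0.2, 1/3, 0)
  poor <- identify_poor(cc, 1/3)
  expect_equal(censor_scores(cc, poor), c(0.5, 0, 1/3, 0))
  expect_equal(censor_scores(cc, rep(1L, 4)), cc)
  expect_equal(censor_scores(cc, rep(0L, 4)), rep(0, 4))
})

test_that("toy aggregation: H = 1/2, A = 5/12, M0 = 5/24", {
  # weights (10, 5, 6, 9)/30 attain the scores (1/2, 1/5, 1/3, 0)
  g0 <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 0), c(1, 0, 0, 0), c(0, 0, 0, 0))
  dm <- make_dm(g0, c(10L, 5L, 6L, 9L), 30L)
  fit <- af_fit(dm, k = 1/3)
  expect_equal(fit$H$estimate, 0.5)
  expect_equal(fit$A$estimate, 5/12)
  expect_equal(fit$M0$estimate, 5/24)
  expect_equal(unname(coef(fit)), c(0.5, 5/12, 5/24))
})

test_that("printed-identity check: H = 0.58, A = 0.46 give M0 = 0.27", {
  expect_equal(round(adjusted_headcount(0.58, 0.46), 2), 0.27)
})

test_that("degenerate fits: everyone poor, no one poor", {
  g1 <- matrix(1L, 5, 11)
  specs <- indicator_specs()
  dm1 <- make_dm(g1, specs$weight_num, 36L)
  f1 <- af_fit(dm1)
  expect_equal(unname(coef(f1)), c(1, 1, 1))
  dm0 <- make_dm(matrix(0L, 5, 11), specs$weight_num, 36L)
  f0 <- af_fit(dm0)
  expect_equal(f0$H$estimate, 0)
  expect_equal(f0$A$estimate, 0)          # A defined as 0 when H = 0
  expect_equal(f0$M0$estimate, 0)
  expect_true(all(is.na(f0$contributions)))   # undefined, not NaN
  expect_false(any(is.nan(f0$contributions)))
})

test_that("vectorized engine equals the brute-force oracle on random inputs", {
  set.seed(2024)
  for (rep in 1:100) {
    n <- sample(20:200, 1)
    p <- 11L
    w <- random_weights(p)
    g0 <- matrix(rbinom(n * p, 1, runif(1, 0.1, 0.6)), n, p)
    s <- runif(n, 0.5, 5)
    k <- runif(1, 0.05, 0.9)
    dm <- make_dm(g0, w$num, w$den, weight = s)
    fit <- af_fit(dm, k = k)
    orc <- af_oracle(g0, w$num / w$den, s, k)
    expect_lt(abs(fit$H$estimate - orc$H), 1e-12)
    expect_lt(abs(fit$A$estimate - orc$A), 1e-12)
    expect_lt(abs(fit$M0$estimate - orc$M0), 1e-12)
    expect_lt(max(abs(fit$censored_headcounts - orc$CH)), 1e-12)
    if (orc$M0 > 0)
      expect_lt(max(abs(fit$contributions - orc$contrib)), 1e-12)
  }
})

test_that("three-way M0 identity and bounds hold on random inputs", {
  set.seed(55)
  specs <- indicator_specs()
  for (rep in 1:20) {
    n <- 150
    g0 <- matrix(rbinom(n * 11, 1, runif(11, 0.1, 0.9)), n, 11,
                 byrow = TRUE)
    s <- runif(n, 0.2, 4)
    dm <- make_dm(g0, specs$weight_num, 36L, weight = s)
    k <- sample(c(1/3, 0.2, 0.5), 1)
    fit <- af_fit(dm, k = k)
    H <- fit$H$estimate; A <- fit$A$estimate; M0 <- fit$M0$estimate
    expect_lt(abs(M0 - H * A), 1e-12)
    cens <- censor_scores(deprivation_scores(dm), fit$poor)
    expect_lt(abs(M0 - sum(s * cens) / sum(s)), 1e-12)
    w <- specs$weight_num / 36
    expect_lt(abs(M0 - sum(w * fit$censored_headcounts)), 1e-12)
    expect_true(k * H <= M0 + 1e-12 && M0 <= H + 1e-12 && H <= 1)
    if (M0 > 0) expect_equal(sum(fit$contributions), 1)
    if (H > 0) expect_gte(A, k - 1e-12)
  }
})

test_that("subgroup decomposition recombines exactly to the pooled M0", {
  set.seed(9)
  specs <- indicator_specs()
  n <- 300
  g0 <- matrix(rbinom(n * 11, 1, 0.35), n, 11)
  s <- runif(n, 0.5, 3)
  dm <- make_dm(g0, specs$weight_num, 36L, weight = s)
  groups <- sample(c("a", "b", "c"), n, replace = TRUE)
  dec <- af_by(dm, groups)
  expect_lt(abs(sum(dec$shares * dec$table$M0) - dec$overall$M0$estimate),
            1e-12)
  # single group reproduces the overall fit
  one <- af_by(dm, rep("all", n))
  expect_equal(one$table$M0, dec$overall$M0$estimate)
  # two identical halves have identical subgroup M0
  dm2 <- make_dm(rbind(g0, g0), specs$weight_num, 36L,
                 weight = c(s, s), psu = as.character(seq_len(2 * n)))
  dec2 <- af_by(dm2, rep(c("x", "y"), each = n))
  expect_equal(dec2$table$M0[1], dec2$table$M0[2])
  expect_error(af_by(dm, c(NA, groups[-1])), "labeled")
})

test_that("robustness curve: default grid, monotone headcount, k below minimum", {
  sim <- simulate_survey(sim_config(n_eas = 40, households_per_ea = 10,
                                    seed = 14))
  dm <- deprivation_matrix(sim$households)
  rob <- af_robustness(dm)
  expect_equal(nrow(rob), 19L)
  expect_equal(rob$k, c(4L, 6L, 8:24) / 36)
  expect_true(all(diff(rob$H) <= 1e-12))
  # brute-force headcount at each k
  sc <- deprivation_scores(dm)
  w <- dm$design$weight
  for (i in seq_len(nrow(rob))) {
    expect_equal(rob$H[i],
                 sum(w * (sc >= rob$k[i] - 1e-9)) / sum(w))
  }
  # any k at or below the smallest positive attainable score counts
  # every household with any deprivation
  rob2 <- af_robustness(dm, k_grid = 1/36)
  expect_equal(rob2$H, sum(w * (sc > 0)) / sum(w))
})

test_that("attainable scores come from exact subset sums", {
  expect_equal(attainable_scores(c(1L, 2L), 3L), c(0, 1/3, 2/3, 1))
  a36 <- attainable_scores(indicator_specs()$weight_num, 36L)
  expect_true(all((c(4, 5, 6, 7, 12, 24, 36) / 36) %in% a36))
  expect_false((1 / 36) %in% a36)  # smallest weight is 2/36
  # non-default weights fall back to the attainable grid
  dm <- make_dm(matrix(rbinom(40, 1, 0.5), 10, 4), c(1L, 1L, 1L, 1L), 4L)
  rob <- af_robustness(dm)
  expect_equal(rob$k, c(0.25, 0.5, 0.75, 1))
})
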