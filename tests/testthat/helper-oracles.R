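# Brute-force per-household Alkire-Foster oracle, written with explicit
# loops and kept independent of the vectorized engine it checks.
af_oracle <- function(g0, w, s, k, inclusive = TRUE) {
  n <- nrow(g0)
  p <- ncol(g0)
  scores <- numeric(n)
  poor <- integer(n)
  for (i in seq_len(n)) {
    ci <- 0
    for (j in seq_len(p)) ci <- ci + w[j] * g0[i, j]
    scores[i] <- ci
    poor[i] <- if (inclusive) as.integer(ci >= k - 1e-9)
               else as.integer(ci > k + 1e-9)
  }
  H <- sum(s * poor) / sum(s)
  M0 <- sum(s * scores * poor) / sum(s)
  A <- if (any(poor == 1L)) sum(s * scores * poor) / sum(s * poor) else 0
  CH <- numeric(p)
  for (j in seq_len(p)) CH[j] <- sum(s * poor * g0[, j]) / sum(s)
  contrib <- if (M0 > 0) w * CH / M0 else rep(NA_real_, p)
  list(H = H, A = A, M0 = M0, CH = CH, contrib = contrib,
       poor = poor, scores = scores)
}

# Assemble a deprivation_matrix object directly from parts, bypassing the
# record-level rules, for engine-level tests.
make_dm <- function(g0, weights_num, weights_den,
                    weight = rep(1, nrow(g0)),
                    stratum = rep("s1", nrow(g0)),
                    psu = as.character(seq_len(nrow(g0))),
                    dimension = NULL) {
  if (is.null(colnames(g0)))
    colnames(g0) <- sprintf("ind_%02d", seq_len(ncol(g0)))
  if (is.null(dimension)) dimension <- rep("all", ncol(g0))
  structure(list(
    g0 = matrix(as.integer(g0), nrow(g0), dimnames = dimnames(g0)),
    household_id = seq_len(nrow(g0)),
    weights_num = as.integer(weights_num),
    weights_den = as.integer(weights_den),
    dimension = dimension,
    design = data.frame(weight = weight, stratum = as.character(stratum),
                        psu = as.character(psu), stringsAsFactors = FALSE)
  ), class = "deprivation_matrix")
}

random_weights <- function(p) {
  num <- sample(1:6, p, replace = TRUE)
  list(num = as.integer(num), den = sum(num))
}

# One fully non-deprived household record with valid design metadata;
# tests mutate individual fields to exercise each rule.
base_record <- function(n = 1L) {
  data.frame(
    household_id = sprintf("H%03d", seq_len(n)),
    ea_id = "EA0001", district = "d1", stratum = "d1:rural",
    sampling_probability = 0.5,
    literacy_score = 20L, numeracy_score = 8L,
    has_school_age_child = FALSE, school_age_child_attending = NA,
    child_acute_illness = FALSE, hdds = 8L, lack_food_episode = FALSE,
    electricity = TRUE, water_source_river = FALSE,
    water_time_gt30 = FALSE, water_on_foot = TRUE,
    uses_latrine = TRUE, roof_grass = FALSE, cooks_with_wood = FALSE,
    owns_radio = TRUE, owns_tv = FALSE, owns_bicycle = FALSE,
    monthly_income_mzn = 500, household_size = 4L,
    stringsAsFactors = FALSE
  )
}

table1_marginals <- c(0.147, 0.176, 0.215, 0.154, 0.304, 0.951, 0.297,
                      0.756, 0.925, 0.959, 0.432)
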