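#' Indicator definitions for the 11-indicator household MPI
#'
#' Returns the definitions of the eleven weighted binary deprivation
#' indicators used throughout the package, in canonical order: two education
#' indicators (weight 1/6 each), three health indicators (1/6, 1/12, 1/12)
#' and six living-standard indicators (1/18 each). Weights are stored as
#' exact integer fractions over a common denominator (36) so that the weight
#' vector sums to one exactly and attainable deprivation scores are exact
#' multiples of 1/36.
#'
#' Each row of the returned data frame carries the indicator name, its
#' dimension, the weight numerator/denominator, and a short description of
#' the deprivation cut-off; the classification rules themselves are applied
#' by [evaluate_indicator()].
#'
#' @return A data frame of class `indicator_specs` with columns `name`,
#'   `dimension`, `weight_num`, `weight_den`, `weight` (numeric) and
#'   `description`.
#' @seealso [evaluate_indicator()], [deprivation_matrix()]
#' @export
#' @examples
#' specs <- indicator_specs()
#' sum(specs$weight_num) == specs$weight_den[1]   # weights sum to 1 exactly
indicator_specs <- function() {
  specs <- data.frame(
    name = c("low_literacy", "child_not_in_school", "child_acute_illness",
             "low_dietary_diversity", "food_lack_episode", "no_electricity",
             "unsafe_water", "no_latrine", "grass_roof", "wood_fuel",
             "low_assets"),
    dimension = c("education", "education", "health", "health", "health",
                  rep("living_standard", 6L)),
    weight_num = c(6L, 6L, 6L, 3L, 3L, 2L, 2L, 2L, 2L, 2L, 2L),
    weight_den = 36L,
    stringsAsFactors = FALSE
  )
  specs$weight <- specs$weight_num / specs$weight_den
  specs$description <- c(
    "literacy score < 16 and numeracy score < 5",
    "school-aged child (7-14) in household not attending school",
    "child fever, diarrhea or difficulty breathing in last 30 days",
    "household dietary diversity score < 4",
    "episode of lack of food during last month",
    "no electricity",
    "water source is a river, or more than 30 minutes away on foot",
    "household does not use a latrine",
    "roof of grass/cane/leaves/straw",
    "cooks with wood",
    "owns none of radio, television, bicycle"
  )
  class(specs) <- c("indicator_specs", "data.frame")
  specs
}

# fields each rule needs; used for fail-fast missing-data checks
.indicator_fields <- list(
  low_literacy = c("literacy_score", "numeracy_score"),
  child_not_in_school = c("has_school_age_child", "school_age_child_attending"),
  child_acute_illness = "child_acute_illness",
  low_dietary_diversity = "hdds",
  food_lack_episode = "lack_food_episode",
  no_electricity = "electricity",
  unsafe_water = c("water_source_river", "water_time_gt30", "water_on_foot"),
  no_latrine = "uses_latrine",
  grass_roof = "roof_grass",
  wood_fuel = "cooks_with_wood",
  low_assets = c("owns_radio", "owns_tv", "owns_bicycle")
)

#' Apply one deprivation rule to household records
#'
#' Evaluates a single indicator's deprivation cut-off on one or more
#' household records and returns a binary vector (1 = deprived). Rules are
#' pure functions of the record fields; missing values in a required field
#' raise an error rather than being imputed. The only tolerated missingness
#' is `school_age_child_attending` for households with no school-aged child,
#' which are classified non-deprived on the enrollment indicator.
#'
#' The water rule classifies a household as deprived when its source is a
#' river, or when water is more than 30 minutes away *and* reached on foot;
#' a long motorised trip is not a deprivation. The asset rule requires
#' owning none of radio, television and bicycle. The literacy rule is the
#' conjunction: literacy score below 16 *and* numeracy score below 5.
#'
#' @param records Data frame of household records (see
#'   [simulate_survey()] for the field list).
#' @param indicator Indicator name, one of `indicator_specs()$name`.
#' @return Integer vector of 0/1 deprivation flags, one per record row.
#' @export
#' @examples
#' rec <- data.frame(literacy_score = 15, numeracy_score = 4)
#' evaluate_indicator(rec, "low_literacy")  # 1: both scores below cut-off
evaluate_indicator <- function(records, indicator) {
  if (!indicator %in% names(.indicator_fields))
    stop("unknown indicator: ", indicator, call. = FALSE)
  need <- .indicator_fields[[indicator]]
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing required field(s) for indicator '", indicator, "': ",
         paste(miss, collapse = ", "), call. = FALSE)
  # missing-value policy: no silent imputation
  check_na <- setdiff(need, "school_age_child_attending")
  for (f in check_na)
    if (anyNA(records[[f]]))
      stop("missing values in field '", f, "' required by indicator '",
           indicator, "'", call. = FALSE)

  out <- switch(indicator,
    low_literacy =
      records$literacy_score < 16 & records$numeracy_score < 5,
    child_not_in_school = {
      has <- as.logical(records$has_school_age_child)
      att <- records$school_age_child_attending
      if (any(has & is.na(att)))
        stop("missing values in field 'school_age_child_attending' for ",
             "households with a school-aged child", call. = FALSE)
      has & !ifelse(is.na(att), TRUE, as.logical(att))
    },
    child_acute_illness = as.logical(records$child_acute_illness),
    low_dietary_diversity = records$hdds < 4,
    food_lack_episode = as.logical(records$lack_food_episode),
    no_electricity = !as.logical(records$electricity),
    unsafe_water =
      as.logical(records$water_source_river) |
        (as.logical(records$water_time_gt30) & as.logical(records$water_on_foot)),
    no_latrine = !as.logical(records$uses_latrine),
    grass_roof = as.logical(records$roof_grass),
    wood_fuel = as.logical(records$cooks_with_wood),
    low_assets =
      !(as.logical(records$owns_radio) | as.logical(records$owns_tv) |
          as.logical(records$owns_bicycle))
  )
  as.integer(out)
}

#' Build the households-by-indicators deprivation matrix
#'
#' Applies every indicator rule to the household records and assembles the
#' n x 11 binary deprivation matrix `g0` together with the exact indicator
#' weight vector and the survey-design columns (sampling weight = inverse of
#' the household sampling probability, stratum and enumeration-area PSU)
#' needed for design-based estimation downstream.
#'
#' @param records Data frame with one row per household carrying the raw
#'   indicator fields plus `household_id`, `ea_id`, `stratum` and
#'   `sampling_probability`.
#' @param specs Indicator specification table; defaults to
#'   [indicator_specs()]. Weights must sum to one exactly (checked in
#'   integer arithmetic).
#' @return An object of class `deprivation_matrix`: a list with elements
#'   `g0` (integer matrix), `household_id`, `weights_num`, `weights_den`,
#'   `dimension` and `design` (data frame with `weight`, `stratum`, `psu`).
#' @export
#' @examples
#' sim <- simulate_survey(sim_config(n_eas = 5, households_per_ea = 4, seed = 1))
#' dm <- deprivation_matrix(sim$households)
#' dim(dm$g0)
deprivation_matrix <- function(records, specs = indicator_specs()) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("'records' must be a data frame with at least one row", call. = FALSE)
  if (sum(specs$weight_num) != specs$weight_den[1])
    stop("indicator weights must sum to exactly 1", call. = FALSE)
  for (f in c("sampling_probability", "stratum", "ea_id")) {
    if (!f %in% names(records))
      stop("records lack required design field '", f, "'", call. = FALSE)
  }
  if (any(!is.finite(records$sampling_probability)) ||
      any(records$sampling_probability <= 0) ||
      any(records$sampling_probability > 1))
    stop("sampling_probability must lie in (0, 1]", call. = FALSE)

  g0 <- vapply(specs$name, function(nm) evaluate_indicator(records, nm),
               integer(nrow(records)))
  g0 <- matrix(as.integer(g0), nrow = nrow(records),
               dimnames = list(NULL, specs$name))
  stopifnot(!anyNA(g0), all(g0 %in% c(0L, 1L)))

  ids <- if ("household_id" %in% names(records)) records$household_id
         else seq_len(nrow(records))
  structure(list(
    g0 = g0,
    household_id = ids,
    weights_num = specs$weight_num,
    weights_den = specs$weight_den[1],
    dimension = specs$dimension,
    design = data.frame(
      weight = 1 / records$sampling_probability,
      stratum = as.character(records$stratum),
      psu = as.character(records$ea_id),
      stringsAsFactors = FALSE
    )
  ), class = "deprivation_matrix")
}

#' @export
print.deprivation_matrix <- function(x, ...) {
  cat("Deprivation matrix:", nrow(x$g0), "households x", ncol(x$g0),
      "indicators\n")
  cat("Weights (exact):",
      paste0(x$weights_num, "/", x$weights_den, collapse = ", "), "\n")
  cat("Raw deprivation rates:\n")
  print(round(colMeans(x$g0), 3))
  invisible(x)
}
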