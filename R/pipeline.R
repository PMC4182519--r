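#' @title End-to-end poverty analysis pipeline
#' @description Orchestrates the full analysis from one configuration:
#'   simulate (or load) the household survey, build the deprivation matrix,
#'   fit the adjusted headcount with design-based intervals, decompose by
#'   subgroup, trace the cut-off robustness curve, krige EA-level poverty
#'   per district, fit the wealth index, and write a machine-readable
#'   report bundle.
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Input is
#' either a `simulate` block (arguments to [sim_config()]) or paths to
#' `households.csv`/`eas.csv` written by [write_survey()].
#'
#' @param simulate Named list of [sim_config()] arguments, or `NULL` when
#'   reading from files.
#' @param households_csv,eas_csv Paths to input tables (ignored when
#'   `simulate` is given).
#' @param k Poverty cut-off.
#' @param inclusive Identification rule.
#' @param k_grid Optional robustness-grid override.
#' @param groups Character vector of household grouping columns for
#'   subgroup decomposition (default `"district"`).
#' @param variogram_model Variogram family for kriging.
#' @param grid_n Kriging grid nodes per axis within each district.
#' @param level Confidence level.
#' @param seed Pipeline seed (overrides the simulate block's seed).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = list(), households_csv = NULL,
                            eas_csv = NULL, k = 1/3, inclusive = TRUE,
                            k_grid = NULL, groups = "district",
                            variogram_model = "exponential", grid_n = 40L,
                            level = 0.95, seed = 1L) {
  if (is.null(simulate) &&
      (is.null(households_csv) || is.null(eas_csv)))
    stop("either a 'simulate' block or both input CSV paths are required",
         call. = FALSE)
  stopifnot(k > 0, k <= 1, level > 0, level < 1, grid_n >= 2)
  structure(list(simulate = simulate, households_csv = households_csv,
                 eas_csv = eas_csv, k = k, inclusive = inclusive,
                 k_grid = k_grid, groups = groups,
                 variogram_model = variogram_model,
                 grid_n = as.integer(grid_n), level = level,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full multidimensional poverty pipeline
#'
#' Executes, in order: survey acquisition (simulation or CSV), deprivation
#' matrix construction, AF aggregation with confidence intervals, subgroup
#' decomposition, the robustness curve, per-district EA aggregation plus
#' ordinary kriging, and the wealth index with lowest-quintile and
#' $1.25/day flags. All stage outputs are written under `out_dir`:
#' `households.csv`, `eas.csv`, `eas.geojson`, `g0.csv`, `af_result.json`,
#' `robustness.csv`, `ea_m0.csv`, `ea_m0.geojson`, `surface.csv`,
#' `surface.geojson`, `wealth.csv` and `report.json`. Stage failures are
#' raised as errors naming the stage. The run is deterministic for a fixed
#' seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, the report list (also written as `report.json`).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[afpoverty] ", ...)
  stage <- function(name, expr) {
    say("stage: ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  sim <- stage("input", {
    if (length(config$simulate) || is.null(config$households_csv)) {
      args <- config$simulate
      args$seed <- config$seed
      s <- simulate_survey(do.call(sim_config, args))
      write_survey(s, out_dir)
      s
    } else {
      hh <- utils::read.csv(config$households_csv, stringsAsFactors = FALSE)
      ea <- utils::read.csv(config$eas_csv, stringsAsFactors = FALSE)
      list(households = hh, eas = ea)
    }
  })
  hh <- sim$households
  missing_groups <- setdiff(config$groups, names(hh))
  if (length(missing_groups))
    stop("grouping column(s) not present in household table: ",
         paste(missing_groups, collapse = ", "), call. = FALSE)

  dm <- stage("deprivation", {
    dm <- deprivation_matrix(hh)
    g0 <- data.frame(household_id = dm$household_id, dm$g0,
                     weight = dm$design$weight, stratum = dm$design$stratum,
                     ea_id = dm$design$psu)
    utils::write.csv(g0, file.path(out_dir, "g0.csv"), row.names = FALSE)
    dm
  })

  fit <- stage("mpi", af_fit(dm, config$k, config$inclusive, config$level))

  decomp <- stage("decomposition", {
    lapply(stats::setNames(config$groups, config$groups), function(g)
      af_by(dm, hh[[g]], config$k, config$inclusive, config$level))
  })

  rob <- stage("robustness", {
    r <- af_robustness(dm, config$k_grid, config$inclusive, config$level)
    utils::write.csv(r, file.path(out_dir, "robustness.csv"),
                     row.names = FALSE)
    r
  })

  surfaces <- stage("kriging", {
    ea_m0 <- ea_headcounts(dm, sim$eas, config$k, config$inclusive)
    utils::write.csv(ea_m0, file.path(out_dir, "ea_m0.csv"),
                     row.names = FALSE)
    write_geojson_points(ea_m0, file.path(out_dir, "ea_m0.geojson"),
                         properties = c("ea_id", "m0", "n_households"))
    per_district <- lapply(split(ea_m0, ea_m0$district), function(d) {
      if (nrow(d) < 5L) return(NULL)  # too few EAs to model spatially
      ev <- empirical_variogram(d[, c("x", "y")], d$m0)
      vm <- if (nrow(ev) >= 3) fit_variogram(ev, config$variogram_model)
            else structure(list(model = config$variogram_model,
                                nugget = stats::var(d$m0), psill = 0,
                                range_param = 1, converged = FALSE),
                           class = "variogram_model")
      ks <- krige_ok(d, vm,
                     grid_x = seq(min(d$x), max(d$x),
                                  length.out = config$grid_n),
                     grid_y = seq(min(d$y), max(d$y),
                                  length.out = config$grid_n))
      list(variogram = vm, surface = ks)
    })
    per_district <- Filter(Negate(is.null), per_district)
    all_grids <- do.call(rbind, lapply(names(per_district), function(nm) {
      g <- per_district[[nm]]$surface$grid
      g$district <- nm
      g
    }))
    utils::write.csv(all_grids, file.path(out_dir, "surface.csv"),
                     row.names = FALSE)
    write_geojson_points(all_grids, file.path(out_dir, "surface.geojson"),
                         properties = c("district", "m0_clamped",
                                        "ok_variance"))
    list(per_district = per_district, ea_m0 = ea_m0)
  })

  wealth <- stage("wealth", {
    item_cols <- grep("^asset_", names(hh), value = TRUE)
    wf <- wealth_fit(as.matrix(hh[, item_cols]))
    scores <- wf$scores
    lowq <- lowest_quintile(scores, 1 / hh$sampling_probability)
    below <- below_dollar_line(hh$monthly_income_mzn, hh$household_size)
    out <- data.frame(household_id = hh$household_id, score = scores,
                      lowest_quintile = lowq, below_125_line = below)
    utils::write.csv(out, file.path(out_dir, "wealth.csv"),
                     row.names = FALSE)
    list(fit = wf, table = out)
  })

  report <- stage("report", {
    af_block <- list(
      k = config$k, inclusive = config$inclusive, level = config$level,
      H = fit$H, A = fit$A, M0 = fit$M0,
      censored_headcounts = as.list(fit$censored_headcounts),
      contributions = as.list(fit$contributions),
      dimension_contributions = as.list(fit$dimension_contributions),
      groups = lapply(decomp, function(d) d$table)
    )
    jsonlite::write_json(af_block, file.path(out_dir, "af_result.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    rep <- list(
      package_version = as.character(utils::packageVersion("afpoverty")),
      seed = config$seed,
      k = config$k,
      inclusive = config$inclusive,
      level = config$level,
      n_households = nrow(hh),
      n_eas = length(unique(hh$ea_id)),
      headcount = fit$H$estimate, headcount_ci = fit$H$ci,
      intensity = fit$A$estimate, intensity_ci = fit$A$ci,
      adjusted_headcount = fit$M0$estimate,
      adjusted_headcount_ci = fit$M0$ci,
      censored_headcounts = as.list(fit$censored_headcounts),
      contributions = as.list(fit$contributions),
      dimension_contributions = as.list(fit$dimension_contributions),
      groups = lapply(decomp, function(d)
        lapply(seq_len(nrow(d$table)), function(i) as.list(d$table[i, ]))),
      robustness = list(k = rob$k, H = rob$H),
      wealth = list(
        converged = wealth$fit$converged,
        loglik = utils::tail(wealth$fit$loglik, 1),
        share_lowest_quintile = mean(wealth$table$lowest_quintile),
        share_below_125 = mean(wealth$table$below_125_line)
      )
    )
    jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    rep
  })
  say("done: ", out_dir)
  invisible(report)
}

# minimal structural schema for report.json; shipped at
# inst/schema/report_schema.json and checked by validate_report()
.report_schema <- function() {
  jsonlite::read_json(system.file("schema", "report_schema.json",
                                  package = "afpoverty"))
}

#' Validate a pipeline report against the shipped schema
#'
#' Checks that every required key of the report schema is present and of
#' the declared type ("number", "integer", "string", "boolean", "object",
#' "array"). This is a structural check of the report contract, not a full
#' JSON-Schema implementation.
#'
#' @param report Report list (from [run_pipeline()]) or a path to a
#'   `report.json`.
#' @return `TRUE` invisibly, or an error naming the offending key.
#' @export
validate_report <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  schema <- .report_schema()
  for (key in names(schema$required)) {
    type <- schema$required[[key]]
    if (!key %in% names(report))
      stop("report lacks required key '", key, "'", call. = FALSE)
    val <- report[[key]]
    ok <- switch(type,
      number = is.numeric(val) || (is.list(val) == FALSE && is.numeric(unlist(val))),
      integer = is.numeric(val) && all(unlist(val) == round(unlist(val))),
      string = is.character(val) || is.character(unlist(val)),
      boolean = is.logical(val) || is.logical(unlist(val)),
      object = is.list(val),
      array = is.list(val) || length(val) > 1,
      stop("unknown schema type: ", type, call. = FALSE))
    if (!isTRUE(ok))
      stop("report key '", key, "' is not of type '", type, "'",
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Human-readable summary table of a pipeline report
#'
#' Formats the headline estimates — overall and per subgroup H, A and M0
#' with confidence intervals — and the dimension contributions ordered
#' from most to least dominant, as a data frame plus a markdown rendering.
#'
#' @param report Report list from [run_pipeline()] or path to
#'   `report.json`.
#' @return List of class `mpi_summary` with elements `table` (data frame),
#'   `dimensions` (named contributions, decreasing) and `markdown`
#'   (character vector of table lines).
#' @export
summarize_report <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report,
                                                          simplifyVector = FALSE)
  num <- function(x) as.numeric(unlist(x))
  rows <- list(data.frame(
    group = "overall",
    H = num(report$headcount), A = num(report$intensity),
    M0 = num(report$adjusted_headcount),
    ci_lo = num(report$adjusted_headcount_ci)[1],
    ci_hi = num(report$adjusted_headcount_ci)[2],
    stringsAsFactors = FALSE))
  for (gname in names(report$groups)) {
    for (g in report$groups[[gname]]) {
      if (!length(g) || is.null(g$group)) next
      rows[[length(rows) + 1L]] <- data.frame(
        group = paste0(gname, ": ", g$group),
        H = num(g$H), A = num(g$A), M0 = num(g$M0),
        ci_lo = NA_real_, ci_hi = NA_real_, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  dims <- sort(num(report$dimension_contributions), decreasing = TRUE)
  names(dims) <- names(report$dimension_contributions)[
    order(num(report$dimension_contributions), decreasing = TRUE)]
  md <- c("| group | H | A | M0 |", "|---|---|---|---|",
          sprintf("| %s | %.3f | %.3f | %.3f |", tab$group, tab$H, tab$A,
                  tab$M0))
  structure(list(table = tab, dimensions = dims, markdown = md),
            class = "mpi_summary")
}

#' @export
print.mpi_summary <- function(x, ...) {
  cat(x$markdown, sep = "\n")
  cat("\nDimension contributions (decreasing):\n")
  print(round(x$dimensions, 3))
  invisible(x)
}
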