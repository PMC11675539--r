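#' End-to-end assessment for one year
#'
#' Ties the pipeline stages together: builds the production account
#' from raw masses, one demand account per requested dietary structure,
#' and a gap report per structure at total, nutrient and food
#' resolution, plus per-capita consumption. A run manifest records
#' input digests so identical inputs give verifiably identical bundles.
#'
#' @param production named per-food mass vector (kt) or data frame with
#'   `food` and `mass_kt` (optionally restricted by `year`).
#' @param pyramid a [population_pyramid()] for the assessment year.
#' @param structures named list of [dietary_structure()] objects.
#' @param factors a [factor_table()].
#' @param ecf energy-conversion coefficients.
#' @param year assessment year tag; when `production` is a multi-year
#'   data frame the matching rows are selected.
#' @param floor per-food production floor for the undefined-gap rule.
#' @return Object of class `assessment_bundle`: list with `production`
#'   (a [production_account()]), `demand` (named list of
#'   [demand_account()]), `gaps` (named list of [gap_report()]),
#'   `manifest`.
#' @export
run_assessment <- function(production, pyramid, structures, factors,
                           ecf = energy_conversion_coefficients(),
                           year = NA_integer_, floor = 0) {
  if (!is.list(structures) || is.null(names(structures))) {
    stop("structures must be a named list of dietary structures", call. = FALSE)
  }
  if (is.data.frame(production) && !is.na(year) && "year" %in% names(production)) {
    production <- production[production$year == year, , drop = FALSE]
    if (nrow(production) == 0) {
      stop("no production rows for year ", year, call. = FALSE)
    }
  }
  if (!is.na(year) && "year" %in% names(pyramid)) {
    sub <- pyramid[pyramid$year == year, , drop = FALSE]
    if (nrow(sub) == 0) stop("no pyramid rows for year ", year, call. = FALSE)
    pyramid <- population_pyramid(as.data.frame(sub))
  }
  pa <- production_account(production, factors, ecf = ecf, year = year)
  demand <- lapply(structures, function(s) {
    demand_account(pyramid, s, factors, ecf = ecf)
  })
  gaps <- lapply(demand, function(d) gap_report(d, pa, floor = floor))
  structure(list(
    production = pa,
    demand = demand,
    gaps = gaps,
    manifest = run_manifest("assessment",
                            inputs = list(production = production,
                                          pyramid = as.data.frame(pyramid),
                                          structures = structures,
                                          factors = as.data.frame(factors),
                                          ecf = ecf))
  ), class = "assessment_bundle")
}

#' @export
print.assessment_bundle <- function(x, ...) {
  print(x$production)
  for (nm in names(x$gaps)) {
    g <- x$gaps[[nm]]
    tot <- g$gap_pct[g$level == "total"]
    cat(sprintf("  Structure %s: total-calorie gap %s (%s)\n", nm,
                if (is.na(tot)) "undefined" else sprintf("%.2f%%", tot),
                g$flag[g$level == "total"]))
  }
  invisible(x)
}

#' Future-demand projection bundle
#'
#' For one SSP scenario: term-averages the regional cohort projection
#' over the basic/near/mid windows (downscaling a provincial projection
#' first when a share model is supplied), computes one demand account
#' per (term, structure), the gap of each against the frozen
#' baseline-year production, and the growth of total caloric demand of
#' the later terms relative to the basic term.
#'
#' @param scenario a [scenario_spec()].
#' @param projection a [population_pyramid()] time series covering the
#'   scenario windows (regional counts, or provincial counts when
#'   `share_model` is given).
#' @param structures named list of [dietary_structure()] objects.
#' @param baseline_production the baseline-year [production_account()].
#' @param factors a [factor_table()].
#' @param ecf energy-conversion coefficients.
#' @param share_model optional [calibrate_share_model()] result used to
#'   downscale a provincial projection.
#' @param floor per-food production floor for the undefined-gap rule.
#' @return Object of class `projection_bundle`: list with `scenario`,
#'   `demand` (list indexed `term.structure`), `gaps` (same indexing),
#'   `growth` (data frame: structure, term, tcd_Bkcal,
#'   growth_vs_basic_pct), `manifest`.
#' @export
run_projection <- function(scenario, projection, structures,
                           baseline_production, factors,
                           ecf = energy_conversion_coefficients(),
                           share_model = NULL, floor = 0) {
  stopifnot(inherits(scenario, "scenario_spec"),
            inherits(baseline_production, "production_account"))
  if (!is.null(share_model)) {
    projection <- downscale_population(projection, share_model)
  }
  terms <- names(scenario$windows)
  demand <- list()
  gaps <- list()
  growth <- NULL
  for (s_id in names(structures)) {
    tcd_by_term <- numeric(0)
    for (tm in terms) {
      pyr <- term_average(projection, scenario$windows[[tm]])
      acc <- project_demand(pyr, structures[[s_id]], factors, ecf = ecf,
                            ssp_id = scenario$ssp_id, term = tm)
      key <- paste(tm, s_id, sep = ".")
      demand[[key]] <- acc
      gaps[[key]] <- future_gap(acc, baseline_production, floor = floor)
      tcd_by_term[tm] <- acc$tcd_kcal
    }
    growth <- rbind(growth, data.frame(
      structure = s_id,
      term = terms,
      tcd_Bkcal = convert_units(unname(tcd_by_term[terms]), "kcal", "B kcal"),
      growth_vs_basic_pct = (tcd_by_term[terms] / tcd_by_term[[terms[1]]] - 1) * 100,
      stringsAsFactors = FALSE
    ))
  }
  rownames(growth) <- NULL
  structure(list(
    scenario = scenario,
    demand = demand,
    gaps = gaps,
    growth = growth,
    manifest = run_manifest("projection",
                            inputs = list(scenario = unclass(scenario),
                                          projection = as.data.frame(projection),
                                          structures = structures,
                                          factors = as.data.frame(factors),
                                          ecf = ecf))
  ), class = "projection_bundle")
}

#' @export
print.projection_bundle <- function(x, ...) {
  cat(sprintf("Future-demand projection (%s, baseline %d)\n",
              x$scenario$ssp_id, x$scenario$baseline_year))
  print(x$growth, row.names = FALSE)
  invisible(x)
}
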