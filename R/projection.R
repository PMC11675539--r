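#' Scenario specification for future-demand projection
#'
#' Couples an SSP population scenario with the three assessment term
#' windows: basic term 2011-2030, near term 2021-2040, mid term
#' 2041-2060 (inclusive year ranges), and the baseline production year
#' against which future gaps are measured.
#'
#' @param ssp_id one of `"SSP1-2.6"`, `"SSP2-4.5"`, `"SSP5-8.5"`.
#' @param windows named list of `c(first, last)` year pairs; default the
#'   basic/near/mid triples above.
#' @param baseline_year production baseline year for future gaps.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(ssp_id = c("SSP1-2.6", "SSP2-4.5", "SSP5-8.5"),
                          windows = list(basic = c(2011, 2030),
                                         near = c(2021, 2040),
                                         mid = c(2041, 2060)),
                          baseline_year = 2020) {
  ssp_id <- match.arg(ssp_id)
  for (w in windows) {
    if (length(w) != 2 || w[1] > w[2]) {
      stop("each term window must be an inclusive c(first, last) year range",
           call. = FALSE)
    }
  }
  structure(list(ssp_id = ssp_id, windows = windows,
                 baseline_year = baseline_year),
            class = "scenario_spec")
}

#' Read a scenario specification from a YAML file
#'
#' Expected keys: `ssp_id`, optional `windows` (mapping of term name to
#' `[first, last]`), optional `baseline_year`.
#'
#' @param path YAML file path.
#' @return A [scenario_spec()].
#' @export
read_scenario_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$ssp_id)) stop("scenario config is missing ssp_id", call. = FALSE)
  args <- list(ssp_id = cfg$ssp_id)
  if (!is.null(cfg$windows)) {
    args$windows <- lapply(cfg$windows, function(w) as.numeric(unlist(w)))
  }
  if (!is.null(cfg$baseline_year)) args$baseline_year <- cfg$baseline_year
  do.call(scenario_spec, args)
}

#' Calibrate a regional-to-provincial population share model
#'
#' The regional pyramid is modelled as a constant per-stratum share of
#' the provincial pyramid (stratum = age stage x sex x residence).
#' Calibration averages, per stratum, the yearly regional/provincial
#' count ratios over the overlapping years -- the geometric mean when
#' all ratios are positive (the consistent estimator under
#' multiplicative noise), the arithmetic mean otherwise -- and reports
#' the Pearson correlation of the two count series as a fit diagnostic
#' (NA when fewer than two overlapping years or a degenerate series).
#'
#' @param regional,provincial [population_pyramid()] time series with
#'   at least two overlapping years.
#' @return Object of class `share_model`: data frame with columns
#'   `age_stage`, `sex`, `residence`, `share`, `correlation`, `n_years`.
#' @export
calibrate_share_model <- function(regional, provincial) {
  stopifnot(inherits(regional, "population_pyramid"),
            inherits(provincial, "population_pyramid"))
  years <- intersect(unique(regional$year), unique(provincial$year))
  if (length(years) < 1) stop("no overlapping years to calibrate on", call. = FALSE)
  strata <- unique(provincial[c("age_stage", "sex", "residence")])
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    a <- strata$age_stage[i]; s <- strata$sex[i]; r <- strata$residence[i]
    pv <- sapply(years, function(y) {
      sum(provincial$count[provincial$year == y & provincial$age_stage == a &
                             provincial$sex == s & provincial$residence == r])
    })
    rv <- sapply(years, function(y) {
      sum(regional$count[regional$year == y & regional$age_stage == a &
                           regional$sex == s & regional$residence == r])
    })
    ok <- pv > 0
    share <- if (!any(ok)) {
      NA_real_
    } else if (all(rv[ok] > 0)) {
      exp(mean(log(rv[ok] / pv[ok])))
    } else {
      mean(rv[ok] / pv[ok])
    }
    corr <- if (length(years) >= 2 && stats::sd(pv) > 0 && stats::sd(rv) > 0) {
      stats::cor(rv, pv)
    } else NA_real_
    data.frame(age_stage = a, sex = s, residence = r, share = share,
               correlation = corr, n_years = length(years),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("share_model", "data.frame"))
}

#' Downscale a provincial cohort projection to the region
#'
#' Regional cohort = provincial cohort x calibrated stratum share, per
#' year and stratum.
#'
#' @param provincial a [population_pyramid()] time series (the
#'   provincial projection).
#' @param model a [calibrate_share_model()] result.
#' @return A [population_pyramid()] with regional counts.
#' @export
downscale_population <- function(provincial, model) {
  stopifnot(inherits(provincial, "population_pyramid"),
            inherits(model, "share_model"))
  key_p <- paste(provincial$age_stage, provincial$sex, provincial$residence)
  key_m <- paste(model$age_stage, model$sex, model$residence)
  idx <- match(key_p, key_m)
  if (anyNA(idx)) {
    missing <- unique(key_p[is.na(idx)])
    stop("share model has no stratum for: ", paste(missing, collapse = "; "),
         call. = FALSE)
  }
  out <- as.data.frame(provincial)
  out$count <- out$count * model$share[idx]
  population_pyramid(out)
}

#' Average a pyramid time series over a term window
#'
#' Arithmetic mean of cohort counts over the inclusive year range; the
#' result is a single pyramid tagged with the window's first year.
#'
#' @param series a [population_pyramid()] time series.
#' @param window inclusive `c(first, last)` year range.
#' @return A [population_pyramid()] of mean counts.
#' @export
term_average <- function(series, window) {
  stopifnot(inherits(series, "population_pyramid"))
  years <- seq(window[1], window[2])
  missing <- setdiff(years, unique(series$year))
  if (length(missing) > 0) {
    stop("series does not cover year(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sub <- series[series$year %in% years, , drop = FALSE]
  agg <- stats::aggregate(count ~ age_stage + sex + residence, data = sub,
                          FUN = function(v) sum(v) / length(years))
  agg$year <- window[1]
  population_pyramid(agg)
}

#' Project food demand for a term population
#'
#' Delegates to [demand_account()] and tags the result with the
#' scenario id, term name and dietary-structure id.
#'
#' @param term_pyramid a term-averaged [population_pyramid()].
#' @param structure a [dietary_structure()].
#' @param factors a [factor_table()].
#' @param ecf energy-conversion coefficients.
#' @param ssp_id,term scenario and term labels carried into the result.
#' @return A [demand_account()] with `ssp_id` and `term` elements.
#' @export
project_demand <- function(term_pyramid, structure, factors,
                           ecf = energy_conversion_coefficients(),
                           ssp_id = NA_character_, term = NA_character_) {
  acc <- demand_account(term_pyramid, structure, factors, ecf)
  acc$ssp_id <- ssp_id
  acc$term <- term
  acc
}

#' Gap of projected demand against frozen baseline production
#'
#' Future gaps are measured against a fixed baseline-year production
#' account (production capacity assumed unchanged), at all three
#' resolutions.
#'
#' @param projected a projected [demand_account()].
#' @param baseline_production the baseline-year [production_account()].
#' @param floor per-food production floor, as in [gap_report()].
#' @return A [gap_report()].
#' @export
future_gap <- function(projected, baseline_production, floor = 0) {
  gap_report(projected, baseline_production, floor = floor)
}
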