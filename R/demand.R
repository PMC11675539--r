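#' Population pyramid
#'
#' Cohort counts by age stage, sex and residence for one or more years.
#'
#' @param x data frame with columns `year`, `age_stage`, `sex`
#'   (`"female"`/`"male"`), `residence` (`"urban"`/`"rural"`), `count`.
#' @return Object of class `population_pyramid` (validated data frame).
#' @export
population_pyramid <- function(x) {
  req <- c("year", "age_stage", "sex", "residence", "count")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    stop("pyramid is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(x$count) | x$count < 0)) {
    stop("pyramid counts must be finite and non-negative", call. = FALSE)
  }
  if (!all(x$sex %in% c("female", "male"))) {
    stop("pyramid sex must be 'female' or 'male'", call. = FALSE)
  }
  if (!all(x$residence %in% c("urban", "rural"))) {
    stop("pyramid residence must be 'urban' or 'rural'", call. = FALSE)
  }
  x <- x[req]
  rownames(x) <- NULL
  structure(x, class = c("population_pyramid", "data.frame"))
}

#' @rdname population_pyramid
#' @param pyramid a `population_pyramid`.
#' @return `pyramid_total()` returns the total head count (summed over
#'   all cells, all years present).
#' @export
pyramid_total <- function(pyramid) sum(pyramid$count)

#' Dietary structure: per-capita intake per food
#'
#' A dietary structure gives the annual per-capita intake FI of each of
#' the nine foods, optionally differentiated by age stage and by
#' urban/rural residence (rows with `age_stage` or `residence` equal to
#' `"all"` apply to every stage or residence). Intake is stored
#' internally in grams per person per year; tables supplied in
#' kg/person/year are converted on construction.
#'
#' Structure ids follow the S0/S1/S2 convention: S0 is the historical
#' (observed) consumption structure, S1 the dietary-guideline upper
#' consumption limit, S2 the guideline lower limit.
#'
#' @param id structure id: `"S0"`, `"S1"`, `"S2"` or a custom label.
#' @param intake data frame with columns `food`, `kg_per_person_year`
#'   (or `g_per_person_year`) and optionally `age_stage`, `residence`.
#' @param provenance free-text note on where the intake values come from.
#' @return Object of class `dietary_structure`: list with `id`,
#'   `intake` (food, age_stage, residence, g_per_person_year),
#'   `provenance`.
#' @export
dietary_structure <- function(id, intake, provenance = "") {
  if (!"food" %in% names(intake)) stop("intake needs a 'food' column", call. = FALSE)
  if ("g_per_person_year" %in% names(intake)) {
    g <- intake$g_per_person_year
  } else if ("kg_per_person_year" %in% names(intake)) {
    g <- convert_units(intake$kg_per_person_year, "kg", "g")
  } else {
    stop("intake needs a kg_per_person_year or g_per_person_year column",
         call. = FALSE)
  }
  if (any(!is.finite(g) | g < 0)) {
    stop("intake values must be finite and non-negative", call. = FALSE)
  }
  out <- data.frame(
    food = intake$food,
    age_stage = if ("age_stage" %in% names(intake)) as.character(intake$age_stage) else "all",
    residence = if ("residence" %in% names(intake)) as.character(intake$residence) else "all",
    g_per_person_year = g,
    stringsAsFactors = FALSE
  )
  check_foods(unique(out$food), sprintf("dietary structure %s", id))
  key <- paste(out$food, out$age_stage, out$residence)
  if (anyDuplicated(key)) {
    stop("duplicated (food, age_stage, residence) rows in intake table",
         call. = FALSE)
  }
  structure(list(id = id, intake = out, provenance = provenance),
            class = "dietary_structure")
}

# internal: per-capita intake (g/yr) of each food for one (age, residence)
# cell; "all" rows act as wildcards with exact matches taking precedence.
intake_for_cell <- function(structure, age, residence) {
  tab <- structure$intake
  out <- numeric(9)
  names(out) <- food_names()
  for (j in food_names()) {
    rows <- tab[tab$food == j, , drop = FALSE]
    score <- (rows$age_stage == age) * 2 + (rows$residence == residence) * 2 +
      (rows$age_stage == "all") + (rows$residence == "all")
    ok <- (rows$age_stage == age | rows$age_stage == "all") &
      (rows$residence == residence | rows$residence == "all")
    if (!any(ok)) {
      stop(sprintf("dietary structure %s has no intake for food '%s', age stage '%s', residence '%s'",
                   structure$id, j, age, residence), call. = FALSE)
    }
    best <- which(ok)[which.max(score[ok])]
    out[j] <- rows$g_per_person_year[best]
  }
  out
}

#' Per-food caloric demand of a population
#'
#' TCD_j = sum over cohorts a of Pop_a x FI_aj x CalF_j: the cohort
#' count times its annual per-capita intake of food j times the food's
#' caloric factor. Uniform (age-invariant) structures treat every cohort
#' alike via `"all"` wildcard rows.
#'
#' @param pyramid a [population_pyramid()] (a single year's pyramid; if
#'   several years are present they are summed, so subset first).
#' @param structure a [dietary_structure()].
#' @param factors a [factor_table()] supplying CalF_j.
#' @return Named numeric vector of per-food caloric demand (kcal).
#' @export
cohort_caloric_demand <- function(pyramid, structure, factors) {
  stopifnot(inherits(pyramid, "population_pyramid"),
            inherits(structure, "dietary_structure"),
            inherits(factors, "factor_table"))
  calf <- stats::setNames(factors$calf, factors$food)
  tcd <- stats::setNames(numeric(9), food_names())
  cells <- unique(pyramid[c("age_stage", "residence")])
  for (k in seq_len(nrow(cells))) {
    a <- cells$age_stage[k]; r <- cells$residence[k]
    n <- sum(pyramid$count[pyramid$age_stage == a & pyramid$residence == r])
    fi <- intake_for_cell(structure, a, r)
    tcd <- tcd + n * fi * calf[names(tcd)]
  }
  tcd
}

#' Total caloric demand
#'
#' TCD = sum over the nine foods of TCD_j.
#'
#' @param tcd_j named per-food caloric demand (kcal), nine entries.
#' @return Total demand in kcal.
#' @export
total_caloric_demand <- function(tcd_j) {
  if (length(tcd_j) != 9) {
    stop("expected per-food demand for exactly nine foods", call. = FALSE)
  }
  if (any(tcd_j < 0)) stop("per-food demand must be non-negative", call. = FALSE)
  sum(tcd_j)
}

#' Macronutrient demand mass from caloric demand
#'
#' MND_qj = TCD_j x NRGP_qj / ECF_q: the nutrient's energy share of the
#' food's caloric demand, converted to mass by the energy-conversion
#' coefficient.
#'
#' @param tcd_j caloric demand (kcal), >= 0; vectorised.
#' @param nrgp energy ratio(s) in [0, 1].
#' @param ecf_q energy-conversion coefficient (kcal/g), > 0.
#' @return Nutrient mass demand in grams.
#' @export
macronutrient_demand <- function(tcd_j, nrgp, ecf_q) {
  macronutrient_production(tcd_j, nrgp, ecf_q)
}

#' Per-capita consumption
#'
#' @param total_g total intake mass of a food (grams), vectorised.
#' @param population head count, > 0.
#' @return kg per person per year.
#' @export
per_capita_consumption <- function(total_g, population) {
  if (any(total_g < 0)) stop("intake mass must be non-negative", call. = FALSE)
  if (length(population) != 1 || !is.finite(population) || population <= 0) {
    stop("population must be a single positive count", call. = FALSE)
  }
  convert_units(total_g, "g", "kg") / population
}

#' Build a demand account
#'
#' Full caloric and macronutrient demand of a population under a
#' dietary structure: per-food calories (TCD_j), total caloric demand,
#' per-food and total macronutrient mass demand (MND), and per-capita
#' consumption per food.
#'
#' The nutrient energy ratios NRGP_qj default to the factor table's
#' production-side energy proportions EP_jq (the same food composition
#' governs both sides); a different matrix can be supplied via `nrgp`.
#'
#' @param pyramid a [population_pyramid()].
#' @param structure a [dietary_structure()].
#' @param factors a [factor_table()].
#' @param ecf energy-conversion coefficients.
#' @param nrgp optional 9 x 3 matrix (foods x nutrients) of energy
#'   ratios overriding the factor table's EP columns.
#' @return Object of class `demand_account`: list with `per_food`
#'   (food, intake_g, tcd_kcal, carbohydrate_g, protein_g, fat_g,
#'   per_capita_kg), `tcd_kcal`, `mnd_g`, `population`, `structure_id`,
#'   `year`.
#' @export
demand_account <- function(pyramid, structure, factors,
                           ecf = energy_conversion_coefficients(),
                           nrgp = NULL) {
  tcd_j <- cohort_caloric_demand(pyramid, structure, factors)
  tcd <- total_caloric_demand(tcd_j)
  if (is.null(nrgp)) {
    nrgp <- as.matrix(factors[c("ep_carb", "ep_protein", "ep_fat")])
    colnames(nrgp) <- macronutrients()
    rownames(nrgp) <- factors$food
  }
  mnd <- sapply(macronutrients(), function(q) {
    macronutrient_demand(tcd_j, nrgp[food_names(), q], ecf[[q]])
  })

  # total intake mass per food (for per-capita reporting)
  intake_g <- stats::setNames(numeric(9), food_names())
  cells <- unique(pyramid[c("age_stage", "residence")])
  for (k in seq_len(nrow(cells))) {
    a <- cells$age_stage[k]; r <- cells$residence[k]
    n <- sum(pyramid$count[pyramid$age_stage == a & pyramid$residence == r])
    intake_g <- intake_g + n * intake_for_cell(structure, a, r)
  }
  pop <- pyramid_total(pyramid)

  per_food <- data.frame(
    food = food_names(),
    intake_g = unname(intake_g),
    tcd_kcal = unname(tcd_j),
    carbohydrate_g = mnd[, "carbohydrate"],
    protein_g = mnd[, "protein"],
    fat_g = mnd[, "fat"],
    per_capita_kg = if (pop > 0) unname(per_capita_consumption(intake_g, pop))
                    else NA_real_,
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(
    per_food = per_food,
    tcd_kcal = tcd,
    mnd_g = colSums(mnd),
    population = pop,
    structure_id = structure$id,
    ecf = ecf,
    year = if (length(unique(pyramid$year)) == 1) unique(pyramid$year) else NA_integer_
  ), class = "demand_account")
}

#' @export
print.demand_account <- function(x, ...) {
  cat(sprintf("Food demand account (structure %s%s, population %s)\n",
              x$structure_id,
              if (!is.na(x$year)) paste0(", ", x$year) else "",
              format(x$population, big.mark = ",")))
  cat(sprintf("  Total caloric demand: %.2f B kcal\n",
              convert_units(x$tcd_kcal, "kcal", "B kcal")))
  mnd_kt <- convert_units(x$mnd_g, "g", "kt")
  cat(sprintf("  Macronutrient demand: carbohydrate %.2f kt, protein %.2f kt, fat %.2f kt\n",
              mnd_kt[["carbohydrate"]], mnd_kt[["protein"]], mnd_kt[["fat"]]))
  invisible(x)
}

#' Build an S0/S1/S2 dietary structure from intake tables
#'
#' S0 is the arithmetic mean of one or more historical per-capita
#' consumption tables (per food, and per residence/age stage where
#' supplied); S1 takes the dietary-guideline upper consumption bounds;
#' S2 takes the guideline lower bounds.
#'
#' @param mode `"S0"`, `"S1"` or `"S2"`.
#' @param historical for S0: a list of intake data frames (columns as
#'   in [dietary_structure()]).
#' @param guideline for S1/S2: data frame with columns `food`,
#'   `lower_kg` and `upper_kg` (kg/person/year), optionally `age_stage`.
#' @param provenance free-text provenance note.
#' @return A [dietary_structure()].
#' @export
build_dietary_structure <- function(mode = c("S0", "S1", "S2"),
                                    historical = NULL, guideline = NULL,
                                    provenance = "") {
  mode <- match.arg(mode)
  if (mode == "S0") {
    if (is.null(historical) || length(historical) == 0) {
      stop("S0 requires at least one historical intake table", call. = FALSE)
    }
    tabs <- lapply(historical, function(h) {
      s <- dietary_structure("S0", h)
      s$intake
    })
    all_rows <- do.call(rbind, tabs)
    agg <- stats::aggregate(g_per_person_year ~ food + age_stage + residence,
                            data = all_rows, FUN = mean)
    dietary_structure("S0", agg, provenance = provenance)
  } else {
    if (is.null(guideline)) {
      stop(mode, " requires a guideline bounds table", call. = FALSE)
    }
    col <- if (mode == "S1") "upper_kg" else "lower_kg"
    if (!col %in% names(guideline)) {
      stop("guideline table is missing column ", col, call. = FALSE)
    }
    intake <- data.frame(
      food = guideline$food,
      kg_per_person_year = guideline[[col]],
      stringsAsFactors = FALSE
    )
    if ("age_stage" %in% names(guideline)) intake$age_stage <- guideline$age_stage
    dietary_structure(mode, intake, provenance = provenance)
  }
}
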