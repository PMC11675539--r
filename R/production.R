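#' Caloric production of a food
#'
#' TCP_j = FP_j x CF_j x CalF_j: raw production mass times the edible
#' fraction times the caloric factor. Vectorised over foods.
#'
#' @param fp_g raw production mass in grams, >= 0.
#' @param cf edible-conversion factor(s), > 0.
#' @param calf caloric factor(s) in kcal/g, > 0.
#' @return Caloric production in kcal.
#' @export
food_caloric_production <- function(fp_g, cf, calf) {
  if (any(fp_g < 0) || any(cf < 0) || any(calf < 0)) {
    stop("caloric production inputs must be non-negative", call. = FALSE)
  }
  fp_g * cf * calf
}

#' Total caloric production with plant/animal partition
#'
#' TCP = sum over the nine foods of TCP_j, partitioned by source class.
#'
#' @param tcp_j named numeric vector of per-food caloric production
#'   (kcal), one entry per food group.
#' @return List with `total`, `plant` and `animal` (kcal).
#' @export
total_caloric_production <- function(tcp_j) {
  fg <- food_groups()
  if (length(tcp_j) != 9) {
    stop("expected per-food calories for exactly nine foods", call. = FALSE)
  }
  check_foods(names(tcp_j), "per-food calories")
  if (any(tcp_j < 0)) stop("per-food calories must be non-negative", call. = FALSE)
  tcp_j <- tcp_j[fg$food]
  plant <- sum(tcp_j[fg$source_class == "plant"])
  animal <- sum(tcp_j[fg$source_class == "animal"])
  list(total = sum(tcp_j), plant = plant, animal = animal)
}

#' Macronutrient production (or demand) mass from caloric totals
#'
#' Converts a food's calories into macronutrient mass: the energy share
#' EP_jq of nutrient q gives the nutrient's energy, and dividing by the
#' energy-conversion coefficient ECF_q (kcal/g) gives mass in grams, so
#' that outputs are comparable to kt-denominated accounts.
#'
#' @param kcal_j per-food calories (kcal), >= 0; vectorised.
#' @param ep energy proportion(s) in [0, 1].
#' @param ecf_q energy-conversion coefficient (kcal/g), > 0.
#' @return Nutrient mass in grams.
#' @export
macronutrient_production <- function(kcal_j, ep, ecf_q) {
  if (any(kcal_j < 0)) stop("calories must be non-negative", call. = FALSE)
  if (any(ep < 0 | ep > 1)) stop("energy proportions must lie in [0, 1]", call. = FALSE)
  if (any(!is.finite(ecf_q) | ecf_q <= 0)) {
    stop("energy-conversion coefficient must be > 0", call. = FALSE)
  }
  kcal_j * ep / ecf_q
}

#' Share of protein mass from high-quality-protein foods
#'
#' @param protein_g per-food protein mass in grams (nine foods).
#' @param flags logical per-food quality-protein flags (defaults to the
#'   canonical flags: meat, eggs, dairy, aquatic products).
#' @return Fraction in [0, 1].
#' @export
quality_protein_share <- function(protein_g, flags = food_groups()$quality_protein) {
  if (any(protein_g < 0)) stop("protein masses must be non-negative", call. = FALSE)
  total <- sum(protein_g)
  if (total == 0) stop("total protein is zero; share undefined", call. = FALSE)
  sum(protein_g[flags]) / total
}

#' Build a production account
#'
#' Converts a year's raw per-food production masses into the full
#' caloric and macronutrient production account: per-food calories
#' (TCP_j), total and plant/animal caloric production, per-food and
#' total macronutrient masses (MNP), and the high-quality-protein share.
#'
#' @param mass named numeric vector of raw production mass per food, or
#'   a data frame with columns `food` and `mass_kt` (or `mass_g`).
#' @param factors a [factor_table()].
#' @param ecf energy-conversion coefficients, see
#'   [energy_conversion_coefficients()].
#' @param unit unit of `mass` when given as a vector or `mass_kt`
#'   column ("kt" default).
#' @param year optional calendar year tag.
#' @return Object of class `production_account`: a list with elements
#'   `per_food` (data frame: food, mass_g, tcp_kcal, carbohydrate_g,
#'   protein_g, fat_g), `tcp_kcal`, `plant_tcp_kcal`, `animal_tcp_kcal`,
#'   `mnp_g` (named totals per nutrient), `quality_protein_share`,
#'   `year`.
#' @examples
#' pa <- production_account(
#'   c(cereals = 420, tubers = 13, legumes = 0.2, vegetables = 1539,
#'     fruits = 670, meat = 137, eggs = 27, dairy = 129,
#'     "aquatic products" = 12),
#'   default_factor_table())
#' pa
#' @export
production_account <- function(mass, factors, ecf = energy_conversion_coefficients(),
                               unit = "kt", year = NA_integer_) {
  stopifnot(inherits(factors, "factor_table"))
  if (is.data.frame(mass)) {
    if ("mass_g" %in% names(mass)) {
      m <- stats::setNames(mass$mass_g, mass$food)
      unit <- "g"
    } else if ("mass_kt" %in% names(mass)) {
      m <- stats::setNames(mass$mass_kt, mass$food)
      unit <- "kt"
    } else stop("production data frame needs a mass_kt or mass_g column", call. = FALSE)
  } else m <- mass
  check_foods(names(m), "production record")
  if (any(m < 0)) stop("production masses must be non-negative", call. = FALSE)
  m <- m[food_names()]
  fp_g <- convert_units(m, unit, "g")

  tcp_j <- food_caloric_production(fp_g, factors$cf, factors$calf)
  names(tcp_j) <- factors$food
  totals <- total_caloric_production(tcp_j)

  ep_cols <- c(carbohydrate = "ep_carb", protein = "ep_protein", fat = "ep_fat")
  mnp <- sapply(macronutrients(), function(q) {
    macronutrient_production(tcp_j, factors[[ep_cols[[q]]]], ecf[[q]])
  })
  colnames(mnp) <- macronutrients()

  per_food <- data.frame(
    food = factors$food,
    mass_g = unname(fp_g),
    tcp_kcal = unname(tcp_j),
    carbohydrate_g = mnp[, "carbohydrate"],
    protein_g = mnp[, "protein"],
    fat_g = mnp[, "fat"],
    stringsAsFactors = FALSE, row.names = NULL
  )
  total_protein <- sum(mnp[, "protein"])
  structure(list(
    per_food = per_food,
    tcp_kcal = totals$total,
    plant_tcp_kcal = totals$plant,
    animal_tcp_kcal = totals$animal,
    mnp_g = colSums(mnp),
    quality_protein_share = if (total_protein > 0)
      quality_protein_share(mnp[, "protein"]) else NA_real_,
    ecf = ecf,
    year = year
  ), class = "production_account")
}

#' @export
print.production_account <- function(x, ...) {
  cat("Food production account",
      if (!is.na(x$year)) paste0("(", x$year, ")"), "\n")
  cat(sprintf("  Total caloric production: %.2f B kcal (plant %.2f, animal %.2f)\n",
              convert_units(x$tcp_kcal, "kcal", "B kcal"),
              convert_units(x$plant_tcp_kcal, "kcal", "B kcal"),
              convert_units(x$animal_tcp_kcal, "kcal", "B kcal")))
  mnp_kt <- convert_units(x$mnp_g, "g", "kt")
  cat(sprintf("  Macronutrient production: carbohydrate %.2f kt, protein %.2f kt, fat %.2f kt\n",
              mnp_kt[["carbohydrate"]], mnp_kt[["protein"]], mnp_kt[["fat"]]))
  if (!is.na(x$quality_protein_share)) {
    cat(sprintf("  High-quality protein share: %.0f%%\n",
                100 * x$quality_protein_share))
  }
  invisible(x)
}

#' @export
summary.production_account <- function(object, ...) {
  pf <- object$per_food
  data.frame(
    food = pf$food,
    mass_kt = convert_units(pf$mass_g, "g", "kt"),
    tcp_Bkcal = convert_units(pf$tcp_kcal, "kcal", "B kcal"),
    carbohydrate_kt = convert_units(pf$carbohydrate_g, "g", "kt"),
    protein_kt = convert_units(pf$protein_g, "g", "kt"),
    fat_kt = convert_units(pf$fat_g, "g", "kt"),
    stringsAsFactors = FALSE
  )
}
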