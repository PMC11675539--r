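#' Factor tables: edible-conversion, caloric and energy-proportion coefficients
#'
#' A factor table holds, per food group j: the edible-conversion factor
#' CF_j (dimensionless fraction of raw mass that is consumable), the
#' caloric factor CalF_j (kcal per gram of edible mass), and the energy
#' proportions EP_jq (fraction of the food's energy contributed by each
#' macronutrient q in carbohydrate, protein, fat).
#'
#' `factor_table()` validates a data frame with columns `food`, `cf`,
#' `calf`, `ep_carb`, `ep_protein`, `ep_fat`; all nine food groups must
#' be present, CF in (0, 1.5], CalF > 0, each EP in [0, 1].
#'
#' @param x data frame with the columns above.
#' @return An object of class `factor_table` (a validated data frame in
#'   canonical food order).
#' @seealso [default_factor_table()], [read_factor_table()],
#'   [validate_energy_proportions()]
#' @export
factor_table <- function(x) {
  req <- c("food", "cf", "calf", "ep_carb", "ep_protein", "ep_fat")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    stop("factor table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  check_foods(x$food, "factor table")
  if (anyDuplicated(x$food)) {
    stop("factor table has duplicated food rows", call. = FALSE)
  }
  x <- x[match(food_names(), x$food), req, drop = FALSE]
  rownames(x) <- NULL
  check_range <- function(col, lo, hi, lo_open = FALSE) {
    v <- x[[col]]
    bad <- !is.finite(v) | (if (lo_open) v <= lo else v < lo) | v > hi
    if (any(bad)) {
      stop(sprintf("factor table value out of range at %s/%s",
                   paste(x$food[bad], collapse = ","), col), call. = FALSE)
    }
  }
  check_range("cf", 0, 1.5, lo_open = TRUE)
  check_range("calf", 0, Inf, lo_open = TRUE)
  for (col in c("ep_carb", "ep_protein", "ep_fat")) check_range(col, 0, 1)
  structure(x, class = c("factor_table", "data.frame"))
}

#' Default factor table
#'
#' A set of default coefficients in the style of Chinese food-composition
#' compilations, suitable for demonstration and synthetic-data work.
#' These are package defaults, not the coefficients of any particular
#' regional study; analyses of real data should load the locally
#' appropriate table with [read_factor_table()].
#'
#' @return A `factor_table`.
#' @export
default_factor_table <- function() {
  factor_table(data.frame(
    food = food_names(),
    cf   = c(0.78, 0.85, 1.00, 0.82, 0.76, 0.75, 0.88, 1.00, 0.60),
    calf = c(3.46, 0.76, 3.81, 0.25, 0.52, 2.00, 1.44, 0.65, 1.04),
    ep_carb    = c(0.84, 0.90, 0.25, 0.70, 0.92, 0.02, 0.03, 0.30, 0.02),
    ep_protein = c(0.12, 0.08, 0.35, 0.20, 0.05, 0.30, 0.35, 0.22, 0.60),
    ep_fat     = c(0.04, 0.02, 0.40, 0.10, 0.03, 0.68, 0.62, 0.48, 0.38),
    stringsAsFactors = FALSE
  ))
}

#' Energy-conversion coefficients for macronutrients
#'
#' Atwater-style coefficients (kcal per gram of macronutrient), used to
#' convert a macronutrient's energy share into mass. Defaults are the
#' general factors 4, 4 and 9 kcal/g for carbohydrate, protein and fat.
#'
#' @param carbohydrate,protein,fat coefficients in kcal/g, all > 0.
#' @return Named numeric vector over the three macronutrients.
#' @export
energy_conversion_coefficients <- function(carbohydrate = 4, protein = 4,
                                           fat = 9) {
  ecf <- c(carbohydrate = carbohydrate, protein = protein, fat = fat)
  if (any(!is.finite(ecf) | ecf <= 0)) {
    stop("energy-conversion coefficients must be finite and > 0",
         call. = FALSE)
  }
  ecf
}

#' Check that per-food energy proportions are near-complete
#'
#' For each food the three macronutrient energy proportions should sum
#' to 1; sums slightly below 1 are tolerated (energy from alcohol,
#' fibre, organic acids). Sums below 0.9 or above 1 are flagged.
#'
#' @param table a `factor_table`.
#' @return Character vector of warnings, one per offending food; empty
#'   if all pass.
#' @export
validate_energy_proportions <- function(table) {
  stopifnot(inherits(table, "factor_table"))
  s <- table$ep_carb + table$ep_protein + table$ep_fat
  bad <- s < 0.9 | s > 1 + 1e-6
  sprintf("energy proportions for %s sum to %.3f (expected in [0.9, 1])",
          table$food[bad], s[bad])
}

#' Read and write factor tables
#'
#' CSV schema: columns `food`, `cf`, `calf`, `ep_carb`, `ep_protein`,
#' `ep_fat`; one row per food group, header mandatory, UTF-8, dot
#' decimal separator.
#'
#' @param path file path.
#' @return `read_factor_table()` returns a validated `factor_table`.
#' @export
read_factor_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  factor_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_factor_table
#' @param table a `factor_table`.
#' @export
write_factor_table <- function(table, path) {
  stopifnot(inherits(table, "factor_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
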