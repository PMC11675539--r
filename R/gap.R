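#' Production-demand gap percentage
#'
#' Gap = (demand - production) / production x 100. A gap <= 0 means
#' local production meets demand; a gap > 0 means demand must be met by
#' external supply.
#'
#' @param demand,production non-negative quantities in the same unit.
#' @return Signed percentage.
#' @examples
#' gap_percent(4368.1, 4044.8)   # 7.99
#' @export
gap_percent <- function(demand, production) {
  if (any(demand < 0) || any(production < 0)) {
    stop("demand and production must be non-negative", call. = FALSE)
  }
  if (length(demand) == 1 && length(production) == 1 &&
      production == 0 && demand > 0) {
    stop("gap undefined: production is zero with positive demand", call. = FALSE)
  }
  (demand - production) / production * 100
}

# internal: batch gap with flag handling for zero production
gap_with_flags <- function(demand, production, floor = 0) {
  undefined <- production <= floor & demand > 0
  gap <- rep(NA_real_, length(demand))
  both_zero <- production == 0 & demand == 0
  gap[both_zero] <- 0
  ok <- !undefined & !both_zero
  gap[ok] <- (demand[ok] - production[ok]) / production[ok] * 100
  flag <- ifelse(undefined, "undefined", ifelse(gap <= 0, "met", "deficit"))
  list(gap_pct = gap, flag = flag,
       shortfall = ifelse(undefined, demand - production, NA_real_))
}

#' Per-food production-demand gaps
#'
#' Applies [gap_percent()] food by food. Foods with production at or
#' below `floor` but positive demand are flagged `undefined` and their
#' absolute shortfall is reported instead of a percentage.
#'
#' @param demand_j,production_j named per-food quantities (same unit).
#' @param floor production floor below which the percentage is treated
#'   as undefined (default 0).
#' @return Data frame with columns `food`, `demand`, `production`,
#'   `gap_pct`, `flag` (`met`/`deficit`/`undefined`), `shortfall`.
#' @export
per_food_gap <- function(demand_j, production_j, floor = 0) {
  check_foods(names(demand_j), "per-food demand")
  check_foods(names(production_j), "per-food production")
  d <- demand_j[food_names()]
  p <- production_j[food_names()]
  if (any(d < 0) || any(p < 0)) {
    stop("demand and production must be non-negative", call. = FALSE)
  }
  g <- gap_with_flags(d, p, floor)
  data.frame(food = food_names(), demand = unname(d), production = unname(p),
             gap_pct = g$gap_pct, flag = g$flag, shortfall = g$shortfall,
             stringsAsFactors = FALSE)
}

#' Gap report at total, nutrient and food resolution
#'
#' Compares a demand account against a production account at the three
#' resolutions of the framework: total calories, the three
#' macronutrients, and the nine individual foods.
#'
#' @param demand a [demand_account()].
#' @param production a [production_account()].
#' @param floor per-food production floor for the undefined-gap rule
#'   (canonical units, grams/kcal; default 0).
#' @return Object of class `gap_report`: data frame with columns
#'   `level` (`total`/`nutrient`/`food`), `item`, `demand`,
#'   `production`, `gap_pct`, `flag`, `shortfall`. Quantities are in
#'   canonical units (kcal for the total row, grams for nutrient and
#'   food rows carry kcal for foods).
#' @export
gap_report <- function(demand, production, floor = 0) {
  stopifnot(inherits(demand, "demand_account"),
            inherits(production, "production_account"))
  tot <- gap_with_flags(demand$tcd_kcal, production$tcp_kcal, floor)
  nut <- gap_with_flags(demand$mnd_g[macronutrients()],
                        production$mnp_g[macronutrients()], floor)
  food_d <- stats::setNames(demand$per_food$tcd_kcal, demand$per_food$food)
  food_p <- stats::setNames(production$per_food$tcp_kcal, production$per_food$food)
  foo <- gap_with_flags(food_d[food_names()], food_p[food_names()], floor)
  out <- data.frame(
    level = c("total", rep("nutrient", 3), rep("food", 9)),
    item = c("total calories", macronutrients(), food_names()),
    demand = c(demand$tcd_kcal, unname(demand$mnd_g[macronutrients()]),
               unname(food_d[food_names()])),
    production = c(production$tcp_kcal, unname(production$mnp_g[macronutrients()]),
                   unname(food_p[food_names()])),
    gap_pct = c(tot$gap_pct, nut$gap_pct, foo$gap_pct),
    flag = c(tot$flag, nut$flag, foo$flag),
    shortfall = c(tot$shortfall, nut$shortfall, foo$shortfall),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("gap_report", "data.frame"),
            structure_id = demand$structure_id)
}

#' @export
print.gap_report <- function(x, ...) {
  cat(sprintf("Production-demand gap report (structure %s)\n",
              attr(x, "structure_id")))
  df <- as.data.frame(x)
  df$gap_pct <- ifelse(is.na(df$gap_pct), "-", sprintf("%.1f%%", df$gap_pct))
  print(df[c("level", "item", "gap_pct", "flag")], row.names = FALSE)
  invisible(x)
}

#' Deviation of consumption from a dietary-guideline bound
#'
#' For a below-lower-bound deviation the value is
#' (bound - consumption) / denominator x 100 (positive when consumption
#' falls short of the bound); for an above-upper-bound deviation it is
#' (consumption - bound) / denominator x 100 (positive when consumption
#' exceeds the bound). The denominator is either the guideline bound or
#' the observed consumption; reports should always name the convention.
#'
#' @param consumption observed per-capita consumption (kg/person/year).
#' @param bound guideline bound (kg/person/year).
#' @param denominator `"guideline"` (default) or `"consumption"`.
#' @param side `"below"` (deviation below a lower bound) or `"above"`
#'   (deviation above an upper bound).
#' @return Signed percentage.
#' @examples
#' guideline_deviation(3.7, 14.64)                       # 74.7
#' guideline_deviation(4.7, 5.49, "consumption")         # 16.8
#' @export
guideline_deviation <- function(consumption, bound,
                                denominator = c("guideline", "consumption"),
                                side = c("below", "above")) {
  denominator <- match.arg(denominator)
  side <- match.arg(side)
  if (any(consumption < 0) || any(bound < 0)) {
    stop("consumption and bound must be non-negative", call. = FALSE)
  }
  den <- if (denominator == "guideline") bound else consumption
  if (any(den == 0)) stop("deviation denominator is zero", call. = FALSE)
  num <- if (side == "below") bound - consumption else consumption - bound
  num / den * 100
}

#' Production trend ratio against a baseline year
#'
#' @param value_t quantity in the later year.
#' @param value_0 quantity in the baseline year, > 0.
#' @param mode `"fold"` (ratio) or `"percent"` (ratio x 100).
#' @return Fold change or percent of baseline.
#' @examples
#' production_trend_ratio(670.54, 22.76)              # ~29.5-fold
#' production_trend_ratio(13.16, 92.23, "percent")    # ~14.3
#' @export
production_trend_ratio <- function(value_t, value_0, mode = c("fold", "percent")) {
  mode <- match.arg(mode)
  if (any(value_0 <= 0)) stop("baseline value must be > 0", call. = FALSE)
  r <- value_t / value_0
  if (mode == "percent") r * 100 else r
}

#' Plant or animal share of total caloric production
#'
#' @param account a [production_account()].
#' @param class `"plant"` or `"animal"`.
#' @return Percentage of total caloric production.
#' @export
source_class_share <- function(account, class = c("plant", "animal")) {
  class <- match.arg(class)
  stopifnot(inherits(account, "production_account"))
  if (account$tcp_kcal <= 0) stop("total caloric production is zero", call. = FALSE)
  sub <- if (class == "plant") account$plant_tcp_kcal else account$animal_tcp_kcal
  sub / account$tcp_kcal * 100
}
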