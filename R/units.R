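#' Unit registry and conversion
#'
#' All internal computation is in canonical units (grams for mass,
#' kilocalories for energy); reporting layers convert to the customary
#' units of regional food accounts, kilotonnes (kt, thousand tonnes;
#' 1 kt = 1e9 g) and billion kilocalories (B kcal = 1e9 kcal).
#'
#' @return `unit_registry()` returns a data frame of registered units
#'   with their dimension and factor to the canonical unit.
#' @examples
#' convert_units(1, "kt", "g")        # 1e9
#' convert_units(4044.80, "B kcal", "kcal")
#' @export
unit_registry <- function() {
  data.frame(
    unit = c("g", "kg", "t", "kt", "kcal", "B kcal"),
    dimension = c("mass", "mass", "mass", "mass", "energy", "energy"),
    to_canonical = c(1, 1e3, 1e6, 1e9, 1, 1e9),
    stringsAsFactors = FALSE
  )
}

#' @rdname unit_registry
#' @param x numeric quantity (vectorised).
#' @param from,to registered unit names.
#' @export
convert_units <- function(x, from, to) {
  reg <- unit_registry()
  i <- match(from, reg$unit)
  j <- match(to, reg$unit)
  if (is.na(i)) stop(sprintf("unknown unit '%s'", from), call. = FALSE)
  if (is.na(j)) stop(sprintf("unknown unit '%s'", to), call. = FALSE)
  if (reg$dimension[i] != reg$dimension[j]) {
    stop(sprintf("incompatible dimensions: %s (%s) vs %s (%s)",
                 from, reg$dimension[i], to, reg$dimension[j]),
         call. = FALSE)
  }
  x * reg$to_canonical[i] / reg$to_canonical[j]
}
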