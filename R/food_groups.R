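#' Canonical nine food groups
#'
#' The accounting framework covers nine food groups. Animal-source foods
#' are meat, eggs, dairy and aquatic products; the same four groups are
#' the sources of high-quality (complete essential amino acid) protein.
#'
#' @return A data frame with columns `index` (1-9), `food`,
#'   `source_class` (`"plant"` or `"animal"`) and `quality_protein`
#'   (logical).
#' @examples
#' food_groups()
#' @export
food_groups <- function() {
  data.frame(
    index = 1:9,
    food = c("cereals", "tubers", "legumes", "vegetables", "fruits",
             "meat", "eggs", "dairy", "aquatic products"),
    source_class = c(rep("plant", 5), rep("animal", 4)),
    quality_protein = c(rep(FALSE, 5), rep(TRUE, 4)),
    stringsAsFactors = FALSE
  )
}

#' @rdname food_groups
#' @export
food_names <- function() food_groups()$food

#' The three macronutrients tracked by the accounts
#' @return Character vector `c("carbohydrate", "protein", "fat")`.
#' @export
macronutrients <- function() c("carbohydrate", "protein", "fat")

#' Default age-stage labels
#'
#' Nine age bands in the style of the Chinese dietary guidelines. Any
#' consistent nine-stage labelling can be substituted; all demand
#' operations align pyramids and intake tables by label, never by
#' position.
#'
#' @return Character vector of nine age-stage labels.
#' @export
age_stages <- function() {
  c("2-3", "4-6", "7-10", "11-13", "14-17", "18-49", "50-64", "65-79", "80+")
}

# internal: check a vector names/covers all nine foods, in canonical order
check_foods <- function(foods, what = "input") {
  fg <- food_names()
  missing <- setdiff(fg, foods)
  if (length(missing) > 0) {
    stop(sprintf("%s is missing food group(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(foods, fg)
  if (length(extra) > 0) {
    stop(sprintf("%s has unknown food group(s): %s", what,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}
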