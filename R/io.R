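#' Read pipeline input tables
#'
#' CSV schemas (header mandatory, UTF-8, dot decimal separator):
#' \describe{
#'   \item{production}{`year`, `food`, `mass_kt`.}
#'   \item{pyramid}{`year`, `age_stage`, `sex`, `residence`, `count`.}
#'   \item{intake}{`structure`, `food`, `kg_per_person_year`, optional
#'     `age_stage` and `residence` (use `"all"` for uniform rows).}
#' }
#'
#' @param path CSV file path.
#' @return `read_production_table()` returns a data frame (`year`,
#'   `food`, `mass_kt`); `read_pyramid()` a [population_pyramid()];
#'   `read_intake_tables()` a named list of [dietary_structure()]
#'   objects, one per `structure` value in the file.
#' @export
read_production_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("year", "food", "mass_kt")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    stop("production table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(x) == 0) stop("production table is empty", call. = FALSE)
  for (y in unique(x$year)) check_foods(x$food[x$year == y],
                                        sprintf("production year %s", y))
  if (any(x$mass_kt < 0)) stop("production masses must be non-negative", call. = FALSE)
  x[req]
}

#' @rdname read_production_table
#' @export
read_pyramid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  population_pyramid(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_production_table
#' @export
read_intake_tables <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("structure", "food") %in% names(x))) {
    stop("intake table needs 'structure' and 'food' columns", call. = FALSE)
  }
  ids <- unique(x$structure)
  out <- lapply(ids, function(id) {
    dietary_structure(id, x[x$structure == id,
                            setdiff(names(x), "structure"), drop = FALSE])
  })
  stats::setNames(out, ids)
}

#' Write pipeline tables
#'
#' @param x table to write (pyramid, production data frame, or a
#'   [gap_report()]).
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_pipeline_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

# internal: rolling polynomial digest of an R object, for run manifests
object_digest <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  bytes <- as.integer(raw[seq(1, length(raw),
                              by = max(1L, length(raw) %/% 4096L))])
  h <- as.double(length(raw) %% 2147483629)
  for (b in bytes) h <- (h * 257 + b) %% 2147483629
  sprintf("%08x", as.integer(h))
}

#' Run manifest for a report bundle
#'
#' Records what produced a bundle: the command label, digests of the
#' inputs, the seed, package version and timestamp, so that two runs
#' on identical inputs are verifiably identical.
#'
#' @param command command label.
#' @param inputs named list of input objects to digest.
#' @param seed seed used (NA if the run is deterministic).
#' @return Object of class `run_manifest`.
#' @export
run_manifest <- function(command, inputs = list(), seed = NA_integer_) {
  structure(list(
    command = command,
    input_digests = vapply(inputs, object_digest, character(1)),
    seed = seed,
    package_version = as.character(utils::packageVersion("foodgap")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "run_manifest")
}
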