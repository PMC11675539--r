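#' Configuration for the synthetic-data generators
#'
#' Defines a complete synthetic study region: a provincial nine-stage
#' age pyramid with sex and urban/rural splits growing exponentially, a
#' paired regional pyramid that is a fixed share of the provincial one,
#' nine-food production series with per-food trends (one food decaying
#' towards zero to exercise the undefined-gap path), and S0/S1/S2
#' intake tables with S1 >= S2 by construction. Multiplicative
#' log-normal noise (mean 1, coefficient of variation `noise_cv`) keeps
#' counts and masses positive.
#'
#' Defaults emulate the study conditions of an arid-region oasis
#' metropolitan area inside a province of ~25 million people: regional
#' share 0.4 of the provincial population, 1% yearly cohort growth,
#' production levels of the order of the region's 2000s accounts, and
#' observation noise cv 0.02.
#'
#' @param seed master seed; each generator derives its own stream from
#'   it by stable hashing of the generator name, so adding a generator
#'   never perturbs the others.
#' @param years calendar years covered.
#' @param base_pop named provincial base cohort counts per age stage
#'   (persons, in the first year).
#' @param growth yearly cohort growth rate (fraction).
#' @param sex_split fraction female.
#' @param urban_share fraction urban.
#' @param share regional-to-provincial population share in [0, 1].
#' @param production_level named per-food first-year production (kt).
#' @param production_trend named per-food yearly growth rate (fraction,
#'   negative for decaying foods).
#' @param noise_cv coefficient of variation of the multiplicative
#'   log-normal noise, >= 0 (0 disables noise).
#' @param s1_factor_range range of the per-food uniform factor (> 1)
#'   linking S1 to S2 intake.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(seed = 1,
                             years = 2000:2020,
                             base_pop = c("2-3" = 0.8e6, "4-6" = 1.1e6,
                                          "7-10" = 1.5e6, "11-13" = 1.1e6,
                                          "14-17" = 1.4e6, "18-49" = 12.5e6,
                                          "50-64" = 4.5e6, "65-79" = 2.2e6,
                                          "80+" = 0.5e6),
                             growth = 0.01,
                             sex_split = 0.49,
                             urban_share = 0.56,
                             share = 0.4,
                             production_level = c(cereals = 470, tubers = 90,
                                                  legumes = 10, vegetables = 1360,
                                                  fruits = 23, meat = 61,
                                                  eggs = 11, dairy = 72,
                                                  "aquatic products" = 6),
                             production_trend = c(cereals = 0.01, tubers = -0.08,
                                                  legumes = -0.18, vegetables = 0.01,
                                                  fruits = 0.18, meat = 0.04,
                                                  eggs = 0.045, dairy = 0.03,
                                                  "aquatic products" = 0.035),
                             noise_cv = 0.02,
                             s1_factor_range = c(1.2, 2)) {
  if (any(base_pop < 0)) stop("base cohort counts must be non-negative", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (share < 0 || share > 1) stop("share must lie in [0, 1]", call. = FALSE)
  check_foods(names(production_level), "production_level")
  check_foods(names(production_trend), "production_trend")
  if (any(s1_factor_range < 1)) {
    stop("s1_factor_range must be >= 1 so that S1 >= S2", call. = FALSE)
  }
  structure(list(seed = seed, years = years, base_pop = base_pop,
                 growth = growth, sex_split = sex_split,
                 urban_share = urban_share, share = share,
                 production_level = production_level[food_names()],
                 production_trend = production_trend[food_names()],
                 noise_cv = noise_cv, s1_factor_range = s1_factor_range),
            class = "generator_config")
}

# stable per-generator seed: polynomial hash of the stream name mixed
# with the master seed, kept inside 32-bit integer range
derive_seed <- function(seed, name) {
  h <- as.double(seed %% 2147483629)
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

# run expr under a derived seed, restoring the caller's RNG state
with_stream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }, add = TRUE)
  set.seed(derive_seed(seed, name))
  force(expr)
}

# mean-1 multiplicative log-normal noise with coefficient of variation cv
lognoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a paired regional/provincial pyramid time series
#'
#' Provincial cohorts follow an exponential trend with multiplicative
#' log-normal noise; the regional pyramid is the configured share of
#' the noise-free provincial trend (with its own noise draw), so the
#' share parameter is recoverable by [calibrate_share_model()].
#'
#' @param config a [generator_config()].
#' @return List with `regional` and `provincial`
#'   [population_pyramid()] time series.
#' @export
gen_population_pyramid <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_stream(config$seed, "pyramid", {
    grid <- expand.grid(year = config$years,
                        age_stage = names(config$base_pop),
                        sex = c("female", "male"),
                        residence = c("urban", "rural"),
                        stringsAsFactors = FALSE)
    t <- grid$year - min(config$years)
    sex_frac <- ifelse(grid$sex == "female", config$sex_split,
                       1 - config$sex_split)
    res_frac <- ifelse(grid$residence == "urban", config$urban_share,
                       1 - config$urban_share)
    det <- config$base_pop[grid$age_stage] * (1 + config$growth)^t *
      sex_frac * res_frac
    prov <- grid
    prov$count <- unname(det * lognoise(nrow(grid), config$noise_cv))
    reg <- grid
    reg$count <- unname(config$share * det * lognoise(nrow(grid), config$noise_cv))
    list(regional = population_pyramid(reg),
         provincial = population_pyramid(prov))
  })
}

#' Generate a nine-food production time series
#'
#' Per-food exponential trends with multiplicative noise; under the
#' default trends the legume series decays to under 2% of its initial
#' level over two decades, exercising the near-zero-production path of
#' the gap statistics.
#'
#' @param config a [generator_config()].
#' @return Data frame with columns `year`, `food`, `mass_kt`.
#' @export
gen_production_table <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_stream(config$seed, "production", {
    grid <- expand.grid(year = config$years, food = food_names(),
                        stringsAsFactors = FALSE)
    t <- grid$year - min(config$years)
    det <- config$production_level[grid$food] *
      (1 + config$production_trend[grid$food])^t
    grid$mass_kt <- unname(det * lognoise(nrow(grid), config$noise_cv))
    grid
  })
}

#' Generate an S0/S1/S2 dietary-structure triple
#'
#' S2 (guideline lower limit) is drawn first, per food, uniformly
#' around typical per-capita magnitudes; S1 = S2 x a per-food uniform
#' factor > 1, so S1 >= S2 holds elementwise by construction; S0
#' (historical) is drawn uniformly between 0.5 x S2 and 1.5 x S1, so
#' both below-lower and above-upper guideline deviations occur.
#'
#' @param config a [generator_config()].
#' @return Named list of three [dietary_structure()] objects
#'   (`S0`, `S1`, `S2`).
#' @export
gen_intake_tables <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_stream(config$seed, "intake", {
    base_kg <- c(cereals = 90, tubers = 25, legumes = 7, vegetables = 140,
                 fruits = 100, meat = 20, eggs = 16, dairy = 110,
                 "aquatic products" = 20)[food_names()]
    s2 <- base_kg * stats::runif(9, 0.7, 1.1)
    f <- stats::runif(9, config$s1_factor_range[1], config$s1_factor_range[2])
    s1 <- s2 * f
    s0 <- stats::runif(9, 0.5 * s2, 1.5 * s1)
    mk <- function(id, v, note) {
      dietary_structure(id, data.frame(food = food_names(),
                                       kg_per_person_year = unname(v),
                                       stringsAsFactors = FALSE),
                        provenance = note)
    }
    list(S0 = mk("S0", s0, "synthetic historical consumption"),
         S1 = mk("S1", s1, "synthetic guideline upper limit"),
         S2 = mk("S2", s2, "synthetic guideline lower limit"))
  })
}
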