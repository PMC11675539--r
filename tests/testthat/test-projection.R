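test_that("share calibration recovers exact proportionality", {
  cfg <- generator_config(seed = 5, noise_cv = 0, share = 0.4)
  pp <- gen_population_pyramid(cfg)
  sm <- calibrate_share_model(pp$regional, pp$provincial)
  expect_equal(sm$share, rep(0.4, nrow(sm)), tolerance = 1e-12)
  expect_equal(sm$correlation, rep(1, nrow(sm)), tolerance = 1e-9)
})

test_that("a single overlapping year yields a share but no correlation", {
  cfg <- generator_config(seed = 6, years = 2020, noise_cv = 0, share = 0.25)
  pp <- gen_population_pyramid(cfg)
  sm <- calibrate_share_model(pp$regional, pp$provincial)
  expect_equal(sm$share, rep(0.25, nrow(sm)), tolerance = 1e-12)
  expect_true(all(is.na(sm$correlation)))
})

test_that("calibration fails without overlapping years", {
  a <- gen_population_pyramid(generator_config(seed = 7, years = 2000:2005))
  b <- gen_population_pyramid(generator_config(seed = 7, years = 2010:2015))
  expect_error(calibrate_share_model(a$regional, b$provincial), "overlap")
})

test_that("share recovery from noisy series stays near the true value", {
  cfg <- generator_config(seed = 8, years = 2001:2020, share = 0.35,
                          noise_cv = 0.02)
  pp <- gen_population_pyramid(cfg)
  sm <- calibrate_share_model(pp$regional, pp$provincial)
  # each stratum share is a mean of 20 noisy ratios; cv 0.02 on both
  # series gives a ratio sd of ~0.35*0.028, se ~ 0.0022
  expect_true(all(abs(sm$share - 0.35) < 2 * 0.35 * 0.03 / sqrt(20) * 3))
  expect_equal(mean(sm$share), 0.35, tolerance = 0.01)
  # with 1%/yr growth against cv 0.02 noise the series correlate highly
  expect_true(all(sm$correlation > 0.8))
})

test_that("downscaling multiplies each stratum by its share", {
  cfg <- generator_config(seed = 9, years = 2011:2020)
  pp <- gen_population_pyramid(cfg)
  sm <- calibrate_share_model(pp$regional, pp$provincial)

  down <- downscale_population(pp$provincial, sm)
  key <- paste(down$age_stage, down$sex, down$residence)
  key_m <- paste(sm$age_stage, sm$sex, sm$residence)
  expect_equal(down$count,
               pp$provincial$count * sm$share[match(key, key_m)],
               tolerance = 1e-12)

  # share 1 is the identity; share 0 empties the region
  sm1 <- sm; sm1$share <- 1
  expect_equal(downscale_population(pp$provincial, sm1)$count,
               pp$provincial$count)
  sm0 <- sm; sm0$share <- 0
  expect_equal(sum(downscale_population(pp$provincial, sm0)$count), 0)

  # unknown stratum is an alignment error
  expect_error(downscale_population(pp$provincial, sm[-1, ]), "stratum")
})

test_that("term averaging is the per-cohort mean over the inclusive window", {
  cfg <- generator_config(seed = 10, years = 2011:2060, noise_cv = 0, growth = 0)
  pp <- gen_population_pyramid(cfg)
  avg <- term_average(pp$regional, c(2011, 2030))
  one_year <- pp$regional[pp$regional$year == 2011, ]
  key_a <- paste(avg$age_stage, avg$sex, avg$residence)
  key_o <- paste(one_year$age_stage, one_year$sex, one_year$residence)
  expect_equal(avg$count, one_year$count[match(key_a, key_o)],
               tolerance = 1e-12)

  # linear series: the window mean is the midpoint value
  lin <- do.call(rbind, lapply(2011:2030, function(y) {
    data.frame(year = y, age_stage = "18-49", sex = "female",
               residence = "urban", count = 100 + (y - 2011) * 10)
  }))
  avg_lin <- term_average(population_pyramid(lin), c(2011, 2030))
  expect_equal(avg_lin$count, 100 + 9.5 * 10)

  expect_error(term_average(population_pyramid(lin), c(2011, 2040)), "2031")

  # random series vs loop-mean oracle
  set.seed(51)
  rnd <- do.call(rbind, lapply(2021:2040, function(y) {
    data.frame(year = y, age_stage = "50-64", sex = "male",
               residence = "rural", count = runif(1, 0, 1e5))
  }))
  avg_rnd <- term_average(population_pyramid(rnd), c(2021, 2040))
  acc <- 0
  for (y in 2021:2040) acc <- acc + rnd$count[rnd$year == y]
  expect_equal(avg_rnd$count, acc / 20, tolerance = 1e-12)
})

test_that("projected demand delegates to the demand module with scenario tags", {
  ft <- default_factor_table()
  cfg <- generator_config(seed = 11, years = 2011:2060)
  pp <- gen_population_pyramid(cfg)
  its <- gen_intake_tables(cfg)
  pyr <- term_average(pp$regional, c(2011, 2030))

  zero <- population_pyramid(transform(as.data.frame(pyr), count = 0))
  z <- project_demand(zero, its$S1, ft)
  expect_equal(z$tcd_kcal, 0)

  d1 <- project_demand(pyr, its$S1, ft, ssp_id = "SSP1-2.6", term = "basic")
  d2 <- project_demand(pyr, its$S2, ft, ssp_id = "SSP1-2.6", term = "basic")
  expect_gte(d1$tcd_kcal, d2$tcd_kcal)
  expect_equal(d1$ssp_id, "SSP1-2.6")
  expect_equal(d1$term, "basic")

  # generator-known closed form on a noise-free pyramid: every cohort
  # count is base x growth^t x split fractions; demand is linear in it
  cfg0 <- generator_config(seed = 12, years = 2011:2012, noise_cv = 0,
                           growth = 0)
  pp0 <- gen_population_pyramid(cfg0)
  pyr0 <- term_average(pp0$regional, c(2011, 2012))
  s_one <- uniform_structure("custom", c(cereals = 1, rep(0, 8)))
  got <- cohort_caloric_demand(pyr0, s_one, ft)
  expected <- cfg0$share * sum(cfg0$base_pop) * 1000 *
    ft$calf[ft$food == "cereals"]
  expect_equal(got[["cereals"]], expected, tolerance = 1e-9)
})

test_that("future gaps compare projected demand to frozen baseline production", {
  ft <- default_factor_table()
  cfg <- generator_config(seed = 13, years = 2011:2060)
  pp <- gen_population_pyramid(cfg)
  its <- gen_intake_tables(cfg)
  prod <- gen_production_table(generator_config(seed = 13))
  pa <- production_account(prod[prod$year == 2020, ], ft, year = 2020)
  pyr <- term_average(pp$regional, c(2011, 2030))
  acc <- project_demand(pyr, its$S2, ft)
  fg <- future_gap(acc, pa)
  expect_s3_class(fg, "gap_report")
  expect_equal(fg$gap_pct[fg$level == "total"],
               gap_percent(acc$tcd_kcal, pa$tcp_kcal), tolerance = 1e-12)

  # demand exactly at baseline production balances; doubling it gives 100%
  expect_equal(gap_percent(pa$tcp_kcal, pa$tcp_kcal), 0)
  expect_equal(gap_percent(2 * pa$tcp_kcal, pa$tcp_kcal), 100)
})

test_that("growth rates between terms are identical across age-invariant structures", {
  ft <- default_factor_table()
  cfg <- generator_config(seed = 14, years = 2011:2060)
  pp <- gen_population_pyramid(cfg)
  its <- gen_intake_tables(cfg)
  basic <- term_average(pp$regional, c(2011, 2030))
  mid <- term_average(pp$regional, c(2041, 2060))
  g <- sapply(its[c("S1", "S2")], function(s) {
    demand_account(mid, s, ft)$tcd_kcal /
      demand_account(basic, s, ft)$tcd_kcal
  })
  expect_equal(g[["S1"]], g[["S2"]], tolerance = 1e-9)
})

test_that("scenario specs validate windows and read from YAML", {
  sc <- scenario_spec("SSP1-2.6")
  expect_equal(sc$windows$basic, c(2011, 2030))
  expect_equal(sc$windows$mid, c(2041, 2060))
  expect_equal(sc$baseline_year, 2020)
  expect_error(scenario_spec("SSP9"), "arg")
  expect_error(scenario_spec("SSP2-4.5", windows = list(basic = c(2030, 2011))),
               "inclusive")

  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("ssp_id: SSP5-8.5", "baseline_year: 2010", "windows:",
               "  basic: [2011, 2030]", "  near: [2021, 2040]"), path)
  sc2 <- read_scenario_spec(path)
  expect_equal(sc2$ssp_id, "SSP5-8.5")
  expect_equal(sc2$baseline_year, 2010)
  expect_equal(sc2$windows$near, c(2021, 2040))
})
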