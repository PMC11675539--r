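# shared builders for the test suite; everything is generated in code

# a pyramid with a single (age, sex, residence) cell
tiny_pyramid <- function(count, age = "18-49", sex = "female",
                         residence = "urban", year = 2020) {
  population_pyramid(data.frame(
    year = year, age_stage = age, sex = sex, residence = residence,
    count = count, stringsAsFactors = FALSE
  ))
}

# a full 9-stage x 2-sex x 2-residence pyramid with given counts
full_pyramid <- function(counts, year = 2020) {
  grid <- expand.grid(year = year, age_stage = age_stages(),
                      sex = c("female", "male"),
                      residence = c("urban", "rural"),
                      stringsAsFactors = FALSE)
  grid$count <- counts
  population_pyramid(grid)
}

# age-invariant structure: one kg/person/year value per food
uniform_structure <- function(id, kg) {
  dietary_structure(id, data.frame(food = food_names(),
                                   kg_per_person_year = unname(kg),
                                   stringsAsFactors = FALSE))
}

# a random but valid factor table
random_factor_table <- function() {
  ep1 <- runif(9, 0.1, 0.8)
  ep2 <- runif(9, 0, 1 - ep1) * 0.9
  ep3 <- pmax(0, runif(9, 0.9, 1) - ep1 - ep2)
  factor_table(data.frame(
    food = food_names(),
    cf = runif(9, 0.3, 1.2),
    calf = runif(9, 0.2, 4),
    ep_carb = ep1, ep_protein = ep2, ep_fat = ep3,
    stringsAsFactors = FALSE
  ))
}
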