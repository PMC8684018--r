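# Small in-code record sets shared across tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

# n persons in one survey band/race, both sexes, all four factors drawn
# from the scenario defaults; deterministic under `seed`.
one_band_records <- function(n_per_sex = 200, seed = 7) {
  cfg <- scenario_config(
    seed = seed, n_per_stratum = n_per_sex,
    prev_bands = "18-24", races = "nh_white"
  )
  simulate_records(cfg)
}

# four fixed red-meat consumers, unit weights (the hand-enumerable case)
four_redmeat_records <- function(consumption = c(10, 50, 80, 120),
                                 weight = rep(1, length(consumption))) {
  tibble::tibble(
    person_id = seq_along(consumption),
    age_band = "25-34", sex = "men", race = "nh_white",
    weight = weight, factor = "red_meat", consumption = consumption
  )
}

# a population where every person sits exactly one published increment
# beyond the guideline for every factor (closed-form PAFs)
one_increment_records <- function(n = 50) {
  cons <- c(red_meat = 60 + 100, processed_meat = 0 + 50,
            fiber = 28 - 10, calcium = 1000 - 200)
  tidyr::expand_grid(
    person_id = seq_len(n),
    age_band = c("18-24", "25-34", "35-44", "45-54", "55-64", "60-69"),
    sex = c("men", "women"),
    race = c("nh_white", "nh_black"),
    factor = names(cons)
  ) |>
    dplyr::mutate(
      weight = 1,
      consumption = unname(cons[factor]),
      person_id = paste(person_id, age_band, sex, race, sep = "_")
    )
}

expect_no_issue <- function(report) {
  testthat::expect_equal(nrow(report), 0)
}
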