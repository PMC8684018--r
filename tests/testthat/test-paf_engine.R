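make_dist <- function(factor, medians, prevalence, lower = NULL,
                      upper = NULL) {
  k <- length(medians)
  tibble::tibble(
    factor = factor, age_band = "all", sex = "persons", race = "all",
    category_index = seq_len(k),
    lower = lower %||% c(0, medians[-1] - 1),
    upper = upper %||% c(medians[-1] - 1, Inf),
    median = medians, prevalence = prevalence
  )
}

test_that("excess relative risk follows the exponential dose response", {
  expect_equal(err(0.01, 0), 0)
  expect_equal(err(0.0030, 50), exp(0.15) - 1)
  # at one full increment the ERR recovers RR - 1 exactly
  expect_equal(err(log(1.28) / 100, 100), 0.28, tolerance = 1e-12)
  expect_equal(err(0, 500), 0)
  expect_error(err(0.01, -5), class = "dietpaf_computation_error")
})

test_that("single-factor PAF matches direct evaluation of the formula", {
  # three categories, doses 0 / 20 / 60 above the 60 g/day reference
  d <- make_dist("red_meat", medians = c(30, 80, 120),
                 prevalence = c(0.5, 0.25, 0.25),
                 lower = c(0, 60, 100), upper = c(60, 100, Inf))
  rg <- 0.0025
  s <- 0.25 * (exp(rg * 20) - 1) + 0.25 * (exp(rg * 60) - 1)
  expect_equal(paf_single(d, rg), s / (1 + s), tolerance = 1e-12)

  # all compliant -> PAF 0
  d0 <- make_dist("red_meat", medians = c(10, 40),
                  prevalence = c(0.5, 0.5),
                  lower = c(0, 20), upper = c(20, 60))
  expect_equal(paf_single(d0, rg), 0)

  # single category with ERR = 1 -> PAF = 1/2
  d1 <- make_dist("red_meat", medians = 160, prevalence = 1,
                  lower = 60, upper = Inf)
  expect_equal(paf_single(d1, log(2) / 100), 0.5, tolerance = 1e-12)
})

test_that("PAF is bounded and strictly monotone in slope, dose and mass", {
  set.seed(42)
  for (i in 1:20) {
    p_non <- runif(1, 0.05, 0.9)
    d <- make_dist("red_meat",
                   medians = c(30, 60 + runif(1, 5, 200)),
                   prevalence = c(1 - p_non, p_non),
                   lower = c(0, 60), upper = c(60, Inf))
    rg <- runif(1, 1e-4, 5e-3)
    paf <- paf_single(d, rg)
    expect_gte(paf, 0)
    expect_lt(paf, 1)
    expect_gt(paf_single(d, rg * 1.5), paf)            # more slope
    d_dose <- dplyr::mutate(d, median = median + c(0, 50))
    expect_gt(paf_single(d_dose, rg), paf)             # more dose
    d_mass <- dplyr::mutate(
      d, prevalence = prevalence + c(-0.04, 0.04))
    expect_gt(paf_single(d_mass, rg), paf)             # more exposed mass
  }
})

test_that("latency pairing shifts age bands and carries the oldest forward", {
  prev <- c("18-24", "25-34", "35-44", "45-54", "55-64", "60-69")
  inc <- c("25-34", "35-44", "45-54", "55-64", "65-69", "70+")
  map <- pair_latency(prev, inc, offset = 10)
  expect_equal(map$prev_band[map$inc_band == "35-44"], "25-34")
  expect_equal(map$prev_band[map$inc_band == "25-34"], "18-24")
  expect_equal(map$prev_band[map$inc_band == "65-69"], "55-64")
  expect_equal(map$prev_band[map$inc_band == "70+"], "60-69")
  # every incidence band has exactly one source (totality)
  expect_setequal(map$inc_band, inc)
  expect_false(any(is.na(map$prev_band)))

  ident <- pair_latency(prev, prev, offset = 0)
  expect_equal(ident$prev_band, ident$inc_band)

  expect_error(pair_latency(c("18-24", "25-34"), c("80-89"), offset = 10),
               class = "dietpaf_config_error")
})

test_that("excess cases multiply paired PAFs into counts, never guessing", {
  map <- pair_latency(c("18-24", "25-34"), c("25-34", "35-44"), offset = 10)
  pafs <- tibble::tibble(prev_band = c("18-24", "25-34"),
                         paf = c(0.10, 0.20))
  counts <- tibble::tibble(age_band = c("25-34", "35-44"),
                           count = c(100, 50))
  ec <- excess_cases(pafs, counts, map)
  expect_equal(ec$excess_cases, c(10, 10))
  expect_equal(sum(ec$excess_cases), 20)

  # zero counts: zero excess, PAF still reported
  ec0 <- excess_cases(pafs, dplyr::mutate(counts, count = 0), map)
  expect_equal(ec0$excess_cases, c(0, 0))
  expect_equal(ec0$paf, c(0.10, 0.20))

  # a count cell the map cannot reach is an error
  expect_error(
    excess_cases(pafs, tibble::tibble(age_band = "95-99", count = 5), map),
    class = "dietpaf_config_error"
  )
  # a missing PAF is an error, not zero
  expect_error(
    excess_cases(pafs[1, ], counts, map),
    class = "dietpaf_computation_error"
  )
})

test_that("age aggregation is case-weighted and conserves excess", {
  bands <- tibble::tibble(paf = c(0.10, 0.20),
                          case_count = c(100, 100),
                          excess_cases = c(10, 20))
  agg <- aggregate_age_weighted(bands)
  expect_equal(agg$paf, 0.15)
  expect_equal(agg$excess_cases, agg$paf * agg$case_count)

  one <- aggregate_age_weighted(bands[1, ])
  expect_equal(one$paf, 0.10)

  # equal PAFs aggregate to the same PAF under any weights
  same <- tibble::tibble(paf = 0.07, case_count = c(13, 999, 40))
  same$excess_cases <- same$paf * same$case_count
  expect_equal(aggregate_age_weighted(same)$paf, 0.07)

  expect_error(aggregate_age_weighted(bands[0, ]),
               class = "dietpaf_computation_error")
})

test_that("factors combine additively in excess cases", {
  fac <- tibble::tibble(
    factor = c("red_meat", "processed_meat", "fiber", "calcium"),
    paf = c(0.038, 0.099, 0.123, 0.080),
    case_count = 10000,
    excess_cases = paf * 10000
  )
  all <- combine_factors(fac)
  expect_equal(all$factor, "all_factors")
  expect_equal(all$paf, sum(fac$paf), tolerance = 1e-12)
  expect_equal(all$excess_cases, sum(fac$excess_cases))

  expect_equal(combine_factors(fac[1, ])$paf, fac$paf[1])

  # additive overflow warns rather than truncating
  big <- dplyr::mutate(fac, paf = 0.3, excess_cases = 3000)
  expect_warning(res <- combine_factors(big), ">= 1")
  expect_equal(res$paf, 1.2, tolerance = 1e-12)

  # complement-multiplicative alternative stays below 1
  comp <- combine_factors(big, mode = "complement")
  expect_lt(comp$paf, 1)
  expect_equal(comp$paf, 1 - (1 - 0.3)^4, tolerance = 1e-12)

  expect_error(
    combine_factors(dplyr::mutate(fac, case_count = c(1, 2, 3, 4) * 100)),
    class = "dietpaf_computation_error"
  )
})

test_that("all-cancer scope swaps the denominator, keeping the numerator", {
  crc <- tibble::tibble(factor = "all_factors", site_scope = "colorectal",
                        paf = 0.34, case_count = 10082,
                        excess_cases = 3428)
  allc <- allcancer_scope(crc, 103408)
  expect_equal(allc$excess_cases, 3428)
  expect_equal(allc$case_count, 103408)
  expect_equal(paf_percent(allc$paf), 3.3)

  zero <- allcancer_scope(dplyr::mutate(crc, excess_cases = 0, paf = 0),
                          103408)
  expect_equal(zero$paf, 0)

  expect_error(allcancer_scope(crc, 5000), class = "dietpaf_data_error")
})
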