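test_that("identical config and seed give byte-identical simulations", {
  cfg <- scenario_config(seed = 99, n_per_stratum = 30,
                         races = c("nh_white", "nh_black"))
  r1 <- simulate_records(cfg)
  r2 <- simulate_records(cfg)
  expect_identical(r1, r2)
  s1 <- simulate_incidence(cfg, r1)
  s2 <- simulate_incidence(cfg, r2)
  expect_identical(s1, s2)
  # a different seed actually changes the draws
  r3 <- simulate_records(scenario_config(seed = 100, n_per_stratum = 30,
                                         races = c("nh_white", "nh_black")))
  expect_false(identical(r1$consumption, r3$consumption))
})

test_that("simulated non-adherence recovers the analytic mixture tails", {
  cfg <- scenario_config(seed = 2024, n_per_stratum = 5000,
                         prev_bands = "18-24", races = "nh_white")
  recs <- simulate_records(cfg)   # 10,000 persons pooled over both sexes
  rec <- default_recommendations()
  n <- 10000
  for (fac in c("red_meat", "processed_meat", "fiber", "calcium")) {
    cs <- cfg$consumption[cfg$consumption$factor == fac, ]
    rrow <- rec[rec$factor == fac, ]
    p <- true_nonadherence(cs$pi0, cs$meanlog, cs$sdlog,
                           rrow$reference, rrow$comparator)
    phat <- adherence_prevalence(recs, fac, list())
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(phat - p), 3 * se + 1e-12)
  }
})

test_that("a population of never-consumers is fully compliant", {
  spec <- default_consumption_spec()
  spec$pi0[spec$factor == "processed_meat"] <- 1
  cfg <- scenario_config(seed = 3, n_per_stratum = 200,
                         consumption = spec,
                         prev_bands = "18-24", races = "nh_white")
  recs <- simulate_records(cfg)
  expect_equal(adherence_prevalence(recs, "processed_meat", list()), 0)
})

test_that("true AF has its closed form at one full increment", {
  # everyone 100 g/day over the red-meat limit: AF = (RR-1)/RR = 0.21875
  recs <- four_redmeat_records(consumption = rep(160, 8))
  rg <- rg_from_rr(data.frame(factor = "red_meat", rr = 1.28,
                              increment = 100, direction = "detrimental"))
  expect_equal(true_af(recs, rg), 0.28 / 1.28, tolerance = 1e-12)
  # fully compliant population: AF = 0
  ok <- four_redmeat_records(consumption = rep(30, 4))
  expect_equal(true_af(ok, rg), 0)
})

test_that("categorical PAF converges to the enumerated oracle", {
  cfg <- scenario_config(seed = 8, n_per_stratum = 5000,
                         prev_bands = "18-24", races = "nh_white")
  recs <- simulate_records(cfg)
  rg_tab <- rg_from_rr(table1_risk())
  for (fac in c("red_meat", "fiber")) {
    rg <- rg_tab[rg_tab$factor == fac & rg_tab$sex_stratum == "persons", ]
    oracle <- true_af(recs[recs$factor == fac, ], rg)
    errs <- vapply(
      list(scheme_quantile(2), scheme_quantile(5), scheme_quantile(20),
           scheme_distinct()),
      function(sch) {
        d <- build_distribution(recs, fac, list(), scheme = sch)
        abs(paf_single(d, rg$rg) - oracle)
      },
      numeric(1)
    )
    # refinement shrinks the error; full refinement is within 0.1 pp
    expect_lt(errs[4], errs[1] + 1e-12)
    expect_lt(errs[4], 0.001)
  }
})

test_that("case allocation is expectation-proportional and consistent", {
  # ties broken by position: the first 0.4 remainder takes the spare case
  expect_identical(dietpaf:::largest_remainder(c(1.4, 1.4, 1.2)),
                   c(2L, 1L, 1L))
  expect_identical(dietpaf:::largest_remainder(c(0, 0, 0)), c(0L, 0L, 0L))
  set.seed(4)
  x <- runif(20) * 10
  expect_equal(sum(dietpaf:::largest_remainder(x)), round(sum(x)))

  cfg <- scenario_config(seed = 12, n_per_stratum = 40,
                         races = c("nh_white", "hispanic"),
                         baseline_cases = 25, allcancer_multiplier = 10)
  sim <- simulate_incidence(cfg)
  inc <- sim$incidence
  expect_true(all(inc$count >= 0))
  expect_no_issue(validate_marginals(inc))
  # all-cancer counts dominate colorectal cell-by-cell
  wide <- tidyr::pivot_wider(inc, names_from = "site_group",
                             values_from = "count")
  expect_true(all(wide$all_excl_bcc_scc >= wide$colorectal))
  # diet raises counts above baseline wherever some exposure exists
  crc <- inc[inc$site_group == "colorectal" & inc$sex != "persons" &
               inc$race != "all", ]
  expect_true(all(crc$count >= cfg$baseline_cases))
  expect_true(all(sim$true_af$true_af >= 0 & sim$true_af$true_af < 1))
})

test_that("bernoulli allocation and weight heterogeneity are exercised", {
  cfg <- scenario_config(seed = 21, n_per_stratum = 60,
                         races = "nh_white", weight_sdlog = 0.5,
                         allocation = "bernoulli")
  recs <- simulate_records(cfg)
  expect_gt(stats::sd(recs$weight), 0)
  sim <- simulate_incidence(cfg, recs)
  expect_true(all(sim$incidence$count >= 0))
})

test_that("scenario files round-trip through YAML", {
  skip_if_not_installed("yaml")
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 77",
    "n_per_stratum: 25",
    "baseline_cases: 12",
    "races: [nh_white]",
    "prev_bands: ['18-24', '25-34']",
    "inc_bands: ['25-34', '35-44']",
    "consumption:",
    "  - {factor: red_meat, pi0: 0.2, meanlog: 4.0, sdlog: 0.7}",
    "  - {factor: processed_meat, pi0: 0.2, meanlog: 3.4, sdlog: 0.8}",
    "  - {factor: fiber, pi0: 0.0, meanlog: 2.8, sdlog: 0.5}",
    "  - {factor: calcium, pi0: 0.0, meanlog: 6.7, sdlog: 0.5}"
  ), tmp)
  cfg <- read_scenario(tmp)
  expect_equal(cfg$seed, 77L)
  expect_equal(nrow(simulate_records(cfg)),
               25 * 2 * 1 * 2 * 4)  # n x sexes x races x bands x factors
})
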