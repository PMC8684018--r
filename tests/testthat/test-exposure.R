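test_that("fixed-bin distributions match hand enumeration", {
  recs <- four_redmeat_records()
  d <- build_distribution(recs, "red_meat", list(sex = "men"),
                          scheme = scheme_fixed(c(60, 100)))
  expect_equal(d$prevalence, c(0.5, 0.25, 0.25))
  expect_equal(d$median, c(30, 80, 120))
  expect_equal(d$lower, c(0, 60, 100))
  expect_equal(d$upper, c(60, 100, Inf))

  # weights shift prevalence, not support
  w <- four_redmeat_records(consumption = c(40, 80), weight = c(3, 1))
  dw <- build_distribution(w, "red_meat", list(sex = "men"),
                           scheme = scheme_fixed(60))
  expect_equal(dw$prevalence, c(0.75, 0.25))
})

test_that("consumption exactly at a maximum-type reference is compliant", {
  recs <- four_redmeat_records(consumption = c(10, 60, 80, 120))
  d <- build_distribution(recs, "red_meat", list(sex = "men"),
                          scheme = scheme_fixed(c(60, 100)))
  # the 60 g/day record sits in the compliant bin, not [60, 100)
  expect_equal(d$prevalence[d$lower == 0], 0.5)
  expect_equal(
    adherence_prevalence(recs, "red_meat", list(sex = "men")), 0.5
  )
})

test_that("quantile scheme puts compliant mass in category 1 and tiles", {
  recs <- one_band_records(n_per_sex = 300)
  for (fac in c("red_meat", "processed_meat", "fiber", "calcium")) {
    d <- build_distribution(recs, fac, list(), scheme = scheme_quantile(5))
    expect_lte(nrow(d), 5)
    expect_equal(sum(d$prevalence), 1, tolerance = 1e-12)
    # category bounds tile the axis: sorted, each upper meets the next lower
    s <- d[order(d$lower), ]
    if (nrow(s) > 1) {
      expect_equal(utils::head(s$upper, -1), s$lower[-1])
    }
    # category 1 is the compliant class: zero modelled dose
    expect_equal(gx(d$median[1], default_recommendations(), fac), 0)
  }
})

test_that("a fully compliant stratum collapses to one category", {
  recs <- four_redmeat_records(consumption = c(5, 10, 20, 55))
  d <- build_distribution(recs, "red_meat", list(sex = "men"))
  expect_equal(nrow(d), 1)
  expect_equal(d$prevalence, 1)
})

test_that("modelled dose is the clamped distance to the reference", {
  rec <- default_recommendations()
  expect_equal(gx(120, rec, "red_meat"), 60)
  expect_equal(gx(28, rec, "fiber"), 0)
  # over-adherence confers no modelled excess risk
  expect_equal(gx(35, rec, "fiber"), 0)
  expect_equal(gx(25, rec, "processed_meat"), 25)
  expect_equal(gx(c(800, 1000, 1300), rec, "calcium"), c(200, 0, 0))
})

test_that("non-adherence prevalence counts strict guideline violations", {
  recs <- four_redmeat_records()
  expect_equal(adherence_prevalence(recs, "red_meat", list(sex = "men")),
               0.5)

  pm <- four_redmeat_records(consumption = c(0, 0, 25))
  pm$factor <- "processed_meat"
  expect_equal(adherence_prevalence(pm, "processed_meat",
                                    list(sex = "men")), 1 / 3)

  ok <- four_redmeat_records(consumption = c(5, 10))
  expect_equal(adherence_prevalence(ok, "red_meat", list(sex = "men")), 0)
})

test_that("adherence equals non-compliant category mass when bins align", {
  set.seed(11)
  rec <- default_recommendations()
  for (i in 1:5) {
    recs <- one_band_records(n_per_sex = 80, seed = 100 + i)
    for (fac in c("red_meat", "fiber")) {
      ref <- rec$reference[rec$factor == fac]
      d <- build_distribution(recs, fac, list(),
                              scheme = scheme_fixed(c(ref / 2, ref,
                                                      ref * 2)))
      non <- gx(d$median, rec, fac) > 0
      expect_equal(
        sum(d$prevalence[non]),
        adherence_prevalence(recs, fac, list()),
        tolerance = 1e-12
      )
    }
  }
})

test_that("empty strata raise an explicit error, never silent zeros", {
  recs <- four_redmeat_records()
  expect_error(
    build_distribution(recs, "red_meat", list(sex = "women")),
    class = "dietpaf_data_error"
  )
  expect_error(
    adherence_prevalence(recs, "fiber", list(sex = "men")),
    class = "dietpaf_data_error"
  )
})

test_that("exposure tables round-trip through CSV losslessly", {
  recs <- one_band_records(n_per_sex = 120)
  d <- build_distribution(recs, "calcium", list(),
                          scheme = scheme_quantile(5))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_exposure_table(d, tmp)
  back <- load_exposure_table(tmp)
  expect_equal(as.data.frame(back), as.data.frame(d), tolerance = 1e-12)

  bad <- dplyr::mutate(d, prevalence = prevalence * 1.2)
  readr::write_csv(bad, tmp)
  expect_error(load_exposure_table(tmp), "sum to 1")
})

test_that("the shipped prevalence fixture carries the published cells", {
  tab <- readr::read_csv(paf_fixture("table2_adherence.csv"),
                         show_col_types = FALSE)
  expect_equal(tab, table2_adherence(), ignore_attr = TRUE)
  cell <- function(race, sex, fac) {
    tab$not_meeting_pct[tab$race == race & tab$sex == sex &
                          tab$factor == fac]
  }
  expect_equal(cell("all", "persons", "red_meat"), 52.7)
  expect_equal(cell("all", "persons", "fiber"), 92.0)
  expect_equal(cell("nh_black", "women", "fiber"), 98.3)
  expect_equal(cell("hispanic", "men", "processed_meat"), 84.9)
})

test_that("weighted median matches stats::median at unit weights", {
  expect_equal(weighted_median(c(1, 2, 3, 4)), 2.5)
  expect_equal(weighted_median(c(4, 1, 3, 2)), 2.5)
  expect_equal(weighted_median(c(1, 2, 3)), 2)
  set.seed(9)
  for (i in 1:10) {
    x <- runif(sample(3:20, 1)) * 100
    expect_equal(weighted_median(x), stats::median(x))
  }
  # weights move the split point; ties resolve deterministically
  expect_equal(weighted_median(c(10, 20), c(1, 3)), 20)
  expect_equal(weighted_median(c(10, 20), c(3, 1)), 10)
  expect_equal(weighted_median(5), 5)
})
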