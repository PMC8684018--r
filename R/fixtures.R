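# Published input and result tables for the Texas 2015 diet-and-cancer
# burden analysis, transcribed as code so every fixture is plain text and
# regenerable. These are the values the acceptance checks replay.

#' Published colorectal-cancer relative risks for the four dietary factors
#'
#' One RR per factor and sex stratum, each reported per a dose increment
#' (red meat per 100 g/day, processed meat per 50 g/day, fiber per
#' 10 g/day, calcium per 200 mg/day). `ci_includes_null` marks estimates
#' whose published confidence interval spans 1; they are used as point
#' estimates regardless.
#'
#' @return validated risk tibble (12 rows).
#' @export
table1_risk <- function() {
  risk <- tibble(
    factor = rep(DIET_FACTORS, each = 3),
    sex_stratum = rep(SEX_LEVELS, times = 4),
    site = "colorectal",
    rr = c(1.28, 1.02, 1.12,
           1.11, 1.18, 1.16,
           0.89, 0.91, 0.93,
           0.93, 0.93, 0.94),
    increment = rep(c(100, 50, 10, 200), each = 3),
    unit = rep(c("g_per_day", "g_per_day", "g_per_day", "mg_per_day"),
               each = 3),
    direction = rep(c("detrimental", "detrimental", "protective",
                      "protective"), each = 3),
    ci_includes_null = c(TRUE, TRUE, TRUE,
                         TRUE, TRUE, FALSE,
                         FALSE, FALSE, TRUE,
                         FALSE, FALSE, FALSE)
  )
  validate_risk_table(risk)
}

#' Published per-unit risk slopes (four-decimal report values)
#'
#' The printed Rg column accompanying [table1_risk()]: risk per g/day
#' (meats, fiber) or per mg/day (calcium), rounded to four decimals.
#'
#' @return tibble with `factor`, `sex_stratum`, `rg_printed`.
#' @export
table1_rg_printed <- function() {
  tibble(
    factor = rep(DIET_FACTORS, each = 3),
    sex_stratum = rep(SEX_LEVELS, times = 4),
    rg_printed = c(0.0025, 0.0002, 0.0011,
                   0.0021, 0.0033, 0.0030,
                   0.0117, 0.0094, 0.0073,
                   0.0004, 0.0004, 0.0003)
  )
}

#' Published prevalence of adults not meeting dietary recommendations
#'
#' Percentage of Americans aged 18 and over not adhering to the guideline
#' for each factor, by sex and race/ethnicity (survey-weighted 24-hour
#' dietary recall; meats from the 2009-2010 cycle, fiber and calcium from
#' 2005-2006).
#'
#' @return tibble with `race`, `sex`, `factor`, `not_meeting_pct`.
#' @export
table2_adherence <- function() {
  races <- c("all", "nh_white", "nh_black", "hispanic", "other")
  cells <- c(
    # men: rm, pm, fiber, ca; women; persons — one row block per race
    59.9, 88.1, 88.0, 53.4,  45.4, 83.9, 95.6, 71.7,  52.7, 86.0, 92.0, 63.0,
    63.9, 91.6, 87.8, 49.5,  48.7, 85.9, 95.6, 69.3,  56.4, 88.8, 91.9, 59.9,
    49.0, 86.6, 96.4, 67.4,  37.6, 86.7, 98.3, 86.6,  42.9, 86.6, 97.5, 78.2,
    52.8, 84.9, 79.9, 63.6,  40.8, 79.8, 92.9, 69.0,  47.3, 82.5, 86.6, 66.4,
    53.8, 62.5, 89.3, 57.2,  36.6, 67.9, 94.0, 74.6,  44.9, 65.3, 91.7, 66.2
  )
  tibble(
    race = rep(races, each = 12),
    sex = rep(rep(SEX_LEVELS, each = 4), times = 5),
    factor = rep(DIET_FACTORS, times = 15),
    not_meeting_pct = cells
  )
}

#' Published age-weighted PAFs and excess cases, Texas 2015
#'
#' Colorectal-cancer PAF (%), all-cancer PAF (%) and excess cases per
#' dietary factor (and all factors combined), by sex and race/ethnicity,
#' for Texan adults aged 25 and over. All-cancer figures exclude basal-
#' and squamous-cell skin carcinomas.
#'
#' @return tibble with `race`, `sex`, `factor`, `crc_paf_pct`,
#'   `allcancer_paf_pct`, `excess_cases`.
#' @export
table3_results <- function() {
  blocks <- list(
    all = list(
      men     = c(6.5, 0.7, 365,  9.0, 1.0, 505,  12.3, 1.3, 695,
                  6.6, 0.7, 370,  34.4, 3.8, 1935),
      women   = c(0.3, 0.0, 14,  11.1, 1.0, 497,  12.1, 1.0, 541,
                  9.9, 0.8, 441,  33.5, 2.9, 1493),
      persons = c(3.8, 0.4, 379,  9.9, 1.0, 1002,  12.3, 1.2, 1236,
                  8.0, 0.8, 811,  34.0, 3.3, 3428)
    ),
    nh_white = list(
      men     = c(6.8, 0.7, 223,  9.4, 0.9, 308,  12.1, 1.2, 393,
                  5.8, 0.6, 190,  34.2, 3.4, 1114),
      women   = c(0.3, 0.0, 9,  11.3, 0.9, 300,  12.0, 1.0, 317,
                  9.3, 0.8, 248,  32.9, 2.7, 874),
      persons = c(3.9, 0.4, 232,  10.3, 0.9, 608,  12.0, 1.1, 711,
                  7.4, 0.7, 438,  33.6, 3.1, 1989)
    ),
    nh_black = list(
      men     = c(5.8, 0.7, 41,  9.5, 1.1, 68,  14.9, 1.8, 106,
                  9.5, 1.1, 68,  39.7, 4.7, 283),
      women   = c(0.2, 0.0, 1,  12.7, 1.3, 79,  13.8, 1.4, 86,
                  12.9, 1.3, 81,  39.6, 4.1, 248),
      persons = c(3.2, 0.4, 43,  11.0, 1.2, 147,  14.3, 1.6, 192,
                  11.1, 1.2, 149,  39.6, 4.4, 531)
    ),
    hispanic = list(
      men     = c(5.2, 0.7, 78,  7.4, 1.0, 112,  11.5, 1.6, 173,
                  9.8, 1.4, 148,  34.0, 4.8, 511),
      women   = c(0.3, 0.0, 3,  10.4, 0.9, 107,  11.6, 1.0, 119,
                  10.2, 0.9, 105,  32.5, 2.8, 334),
      persons = c(3.2, 0.4, 81,  8.7, 1.0, 219,  11.6, 1.2, 292,
                  10.0, 1.1, 253,  33.4, 3.7, 845)
    ),
    other = list(
      men     = c(5.3, 0.5, 8,  4.0, 0.4, 6,  12.4, 1.1, 18,
                  7.2, 0.6, 11,  28.9, 2.5, 43),
      women   = c(0.1, 0.0, 0,  6.6, 0.5, 10,  11.4, 1.0, 17,
                  10.9, 0.9, 17,  28.9, 2.4, 44),
      persons = c(2.6, 0.2, 8,  5.3, 0.5, 16,  11.9, 1.0, 36,
                  9.1, 0.8, 27,  28.9, 2.5, 87)
    )
  )
  factors <- c(DIET_FACTORS, "all_factors")
  rows <- list()
  for (race in names(blocks)) {
    for (sex in names(blocks[[race]])) {
      v <- matrix(blocks[[race]][[sex]], ncol = 3, byrow = TRUE)
      rows[[paste(race, sex)]] <- tibble(
        race = race, sex = sex, factor = factors,
        crc_paf_pct = v[, 1], allcancer_paf_pct = v[, 2],
        excess_cases = as.integer(v[, 3])
      )
    }
  }
  bind_rows(rows)
}

#' Published Texas 2015 all-cancer case counts, adults aged 25 and over
#'
#' Marginal counts of new invasive cancers excluding basal- and
#' squamous-cell skin carcinomas: the overall total, sex totals, and
#' race/ethnicity totals. Age-band-stratified counts and colorectal counts
#' by stratum were not published; tests use synthetic ones.
#'
#' @return validated incidence tibble (marginals only, age band `25+`).
#' @export
texas2015_counts <- function() {
  inc <- tibble(
    site_group = "all_excl_bcc_scc",
    age_band = "25+",
    sex = c("men", "women", "persons",
            "persons", "persons", "persons", "persons"),
    race = c("all", "all", "all",
             "nh_white", "nh_black", "hispanic", "other"),
    count = c(51472L, 51936L, 103408L,
              65214L, 12020L, 22642L, 3532L)
  )
  validate_incidence(inc)
}

#' Write the bundled published tables as CSV fixtures
#'
#' Writes `risk_table1.csv`, `table2_adherence.csv`, `table3_results.csv`,
#' and `texas2015_counts.csv` into `outdir`. These are the files shipped
#' under the package's `extdata/` directory.
#'
#' @param outdir output directory (created if missing).
#' @return character vector of the written paths, invisibly.
#' @export
make_fixtures <- function(outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    risk = file.path(outdir, "risk_table1.csv"),
    adherence = file.path(outdir, "table2_adherence.csv"),
    results = file.path(outdir, "table3_results.csv"),
    counts = file.path(outdir, "texas2015_counts.csv")
  )
  write_risk_table(table1_risk(), paths["risk"])
  readr::write_csv(table2_adherence(), paths["adherence"])
  readr::write_csv(table3_results(), paths["results"])
  write_incidence(texas2015_counts(), paths["counts"])
  invisible(paths)
}
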