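# End-to-end orchestration: records -> exposure distributions -> per-band
# PAFs -> latency-paired excess cases -> age-weighted, per-factor and
# all-factors results on both site scopes.

# Age-band count series for one (site, sex, race) stratum, deriving pooled
# cells by summing concrete ones when the table does not carry marginals.
counts_for <- function(inc, site_group, sex, race) {
  inc <- inc[inc$site_group == site_group, ]
  direct <- inc[inc$sex == sex & inc$race == race, ]
  if (nrow(direct) > 0) {
    return(direct[, c("age_band", "count")])
  }
  sexes <- if (sex == "persons") c("men", "women") else sex
  races <- if (race == "all") setdiff(RACE_LEVELS, "all") else race
  part <- inc[inc$sex %in% sexes & inc$race %in% races, ]
  if (nrow(part) == 0) {
    paf_data_error(sprintf(
      "no %s counts for stratum (sex=%s, race=%s)", site_group, sex, race
    ))
  }
  part |>
    group_by(.data$age_band) |>
    summarise(count = sum(.data$count), .groups = "drop")
}

#' Run the attributable-burden pipeline
#'
#' For every dietary factor and every (sex, race) reporting stratum:
#' build per-survey-age-band exposure distributions from the records, apply
#' the per-unit risk slope from the risk table (sex-specific RRs for sex
#' rows, persons RRs for pooled rows under the default policy), compute
#' Levin PAFs, pair them with registry counts via the latency map, and
#' aggregate age-weighted. Factor results are then combined additively into
#' an all-factors row and re-expressed against the all-cancer denominator.
#'
#' @param records diet records (tibble or CSV path,
#'   `person_id,age_band,sex,race,weight,factor,consumption`).
#' @param risk risk table (tibble or CSV path).
#' @param incidence count table (tibble or CSV path) holding both the
#'   `colorectal` and `all_excl_bcc_scc` site groups.
#' @param rec recommendations table.
#' @param scheme exposure category scheme (see [scheme_quantile()]).
#' @param offset latency years between survey and registry age bands.
#' @param rr_policy `"sex_specific"` (men/women rows use their own RR,
#'   persons rows the persons RR) or `"persons_only"`.
#' @param combination all-factors combination mode, see
#'   [combine_factors()].
#' @param sexes,races reporting strata; defaults cover men, women, persons
#'   and every race present plus the pooled `all`.
#' @param out_dir when given, results, a Table-3-style grid, and a
#'   provenance log are written there (deterministic content: reruns on
#'   identical inputs are byte-identical).
#' @return list with `results` (tidy tibble: one row per factor (incl.
#'   `all_factors`) x site scope x sex x race), `by_age_band` (per-band
#'   detail), `table3` (wide render), `log` (provenance list).
#' @export
run_pipeline <- function(records, risk, incidence,
                         rec = default_recommendations(),
                         scheme = scheme_quantile(5),
                         offset = 10,
                         rr_policy = c("sex_specific", "persons_only"),
                         combination = c("additive", "complement"),
                         sexes = SEX_LEVELS,
                         races = NULL,
                         out_dir = NULL) {
  rr_policy <- match.arg(rr_policy)
  combination <- match.arg(combination)
  prov <- list(package = "dietpaf",
               version = as.character(utils::packageVersion("dietpaf")),
               rr_policy = rr_policy, combination = combination,
               offset = offset, scheme = unclass(scheme))
  input_hash <- function(x, name) {
    if (is.character(x) && length(x) == 1) {
      prov$inputs[[name]] <<- list(path = x,
                                   md5 = unname(tools::md5sum(x)))
    } else {
      prov$inputs[[name]] <<- list(path = NA_character_, md5 = "in-memory")
    }
  }
  input_hash(records, "records")
  input_hash(risk, "risk")
  input_hash(incidence, "incidence")
  if (is.character(records)) records <- load_records(records)
  if (is.character(risk)) risk <- load_risk_table(risk)
  if (is.character(incidence)) incidence <- load_incidence(incidence)
  records <- validate_records(records)
  risk <- validate_risk_table(risk)
  incidence <- validate_incidence(incidence)
  rec <- validate_recommendations(rec)
  if (is.null(races)) {
    races <- c(sort(unique(records$race)), "all")
  }
  rg_all <- rg_from_rr(risk)
  prev_bands <- order_age_bands(unique(records$age_band))

  detail <- list()
  rows <- list()
  for (sex in sexes) {
    rg_sex <- if (rr_policy == "persons_only") "persons" else sex
    for (race in races) {
      crc_counts <- counts_for(incidence, "colorectal", sex, race)
      lmap <- pair_latency(prev_bands, crc_counts$age_band, offset = offset)
      total_cancers <- sum(counts_for(incidence, "all_excl_bcc_scc",
                                      sex, race)$count)
      fac_rows <- list()
      for (fac in DIET_FACTORS) {
        rg_row <- rg_all[rg_all$factor == fac &
                           rg_all$sex_stratum == rg_sex, ]
        if (nrow(rg_row) != 1) {
          paf_computation_error(sprintf(
            "no risk estimate for factor '%s', sex stratum '%s'",
            fac, rg_sex
          ))
        }
        pafs <- vapply(prev_bands, function(band) {
          d <- build_distribution(records, fac,
                                  list(age_band = band, sex = sex,
                                       race = race),
                                  rec = rec, scheme = scheme)
          paf_single(d, rg_row$rg, rec)
        }, numeric(1))
        paf_tbl <- tibble(prev_band = prev_bands, paf = unname(pafs))
        ec <- excess_cases(paf_tbl, crc_counts, lmap)
        detail[[length(detail) + 1L]] <- mutate(
          ec, factor = fac, sex = sex, race = race, .before = 1
        )
        agg <- aggregate_age_weighted(ec)
        fac_rows[[fac]] <- mutate(agg, factor = fac, .before = 1)
      }
      fac_tbl <- bind_rows(fac_rows)
      all_tbl <- combine_factors(fac_tbl, mode = combination)
      both <- bind_rows(fac_tbl, all_tbl) |>
        mutate(site_scope = "colorectal", sex = sex, race = race)
      allscope <- bind_rows(lapply(seq_len(nrow(both)), function(i) {
        allcancer_scope(both[i, ], total_cancers)
      }))
      rows[[length(rows) + 1L]] <- bind_rows(both, allscope)
    }
  }
  results <- bind_rows(rows) |>
    mutate(paf_percent = paf_percent(.data$paf)) |>
    select(all_of(c("factor", "site_scope", "sex", "race", "paf",
                    "paf_percent", "excess_cases", "case_count")))
  out <- list(results = results, by_age_band = bind_rows(detail),
              table3 = render_table3(results), log = prov)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

#' Read long-format diet records from CSV
#'
#' Schema: `person_id,age_band,sex,race,weight,factor,consumption`.
#'
#' @param path CSV path.
#' @return validated records tibble.
#' @export
load_records <- function(path) {
  if (!file.exists(path)) {
    paf_config_error(sprintf("records file not found: %s", path))
  }
  validate_records(readr::read_csv(
    path,
    col_types = readr::cols(
      person_id = readr::col_character(),
      age_band = readr::col_character(),
      sex = readr::col_character(),
      race = readr::col_character(),
      weight = readr::col_double(),
      factor = readr::col_character(),
      consumption = readr::col_double()
    )
  ))
}

#' Render results as a wide burden-table grid
#'
#' One row per (race, sex); per dietary factor (and the all-factors
#' combination) two columns: the colorectal PAF percentage and the
#' all-cancer cell formatted `"PAF% (excess cases)"`. Strata absent from
#' `results` render as empty strings, never as zeros.
#'
#' @param results tidy results tibble from [run_pipeline()] (or any tibble
#'   with `factor,site_scope,sex,race,paf,excess_cases`).
#' @return wide tibble of formatted strings.
#' @export
render_table3 <- function(results) {
  results <- as_tibble(results)
  require_columns(results,
                  c("factor", "site_scope", "sex", "race", "paf",
                    "excess_cases"),
                  "results")
  factors <- c(DIET_FACTORS, "all_factors")
  races <- intersect(RACE_LEVELS[c(5, 1:4)], unique(results$race))
  sexes <- intersect(SEX_LEVELS, unique(results$sex))
  grid <- list()
  for (race in races) {
    for (sex in sexes) {
      row <- list(race = race, sex = sex)
      for (fac in factors) {
        crc <- results[results$factor == fac & results$sex == sex &
                         results$race == race &
                         results$site_scope == "colorectal", ]
        allc <- results[results$factor == fac & results$sex == sex &
                          results$race == race &
                          results$site_scope == "all_excl_bcc_scc", ]
        row[[paste0(fac, "_crc_paf")]] <-
          if (nrow(crc) == 1) format_paf_cell(crc$paf) else ""
        row[[paste0(fac, "_all")]] <-
          if (nrow(allc) == 1) {
            format_paf_cell(allc$paf, allc$excess_cases)
          } else ""
      }
      grid[[paste(race, sex)]] <- as_tibble(row)
    }
  }
  if (length(grid) == 0) {
    # header-only grid
    cols <- c("race", "sex",
              as.vector(rbind(paste0(factors, "_crc_paf"),
                              paste0(factors, "_all"))))
    return(as_tibble(setNames(
      lapply(cols, function(x) character(0)), cols)))
  }
  bind_rows(grid)
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- out$results |>
    mutate(excess_cases_rounded =
             as.integer(round_half_up(.data$excess_cases, 0)))
  readr::write_csv(
    res[, c("factor", "site_scope", "sex", "race", "paf_percent",
            "excess_cases", "excess_cases_rounded", "case_count")],
    file.path(out_dir, "results.csv")
  )
  readr::write_csv(out$by_age_band, file.path(out_dir, "results_by_age.csv"))
  readr::write_csv(out$table3, file.path(out_dir, "table3.csv"))
  jsonlite::write_json(
    list(log = out$log,
         summary = res[res$factor == "all_factors", ]),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(out_dir)
}
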