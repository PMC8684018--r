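#' Excess relative risk at a modelled dose
#'
#' On the log-linear dose-response scale, a category with dose `G_x`
#' (excess consumption or intake deficit, already clamped at zero by
#' [gx()]) carries relative risk `exp(Rg * G_x)`; its excess relative risk
#' is \deqn{ERR_x = e^{R_g G_x} - 1.} At a full published increment the ERR
#' recovers `RR - 1` exactly.
#'
#' @param rg per-unit log-risk slope (scalar or vector).
#' @param gx non-negative dose in factor units.
#' @return excess relative risk, `>= 0` whenever `rg >= 0`.
#' @export
err <- function(rg, gx) {
  if (any(!is.finite(gx)) || any(gx < 0)) {
    paf_computation_error("err: gx must be finite and >= 0 (clamp upstream)")
  }
  exp(rg * gx) - 1
}

#' Population attributable fraction for one factor in one stratum
#'
#' Levin-type PAF over exposure categories:
#' \deqn{PAF = \frac{\sum_x p_x ERR_x}{1 + \sum_x p_x ERR_x}}
#' with `p_x` the category prevalences of `dist` and `ERR_x` from [err()]
#' at dose [gx()] relative to the guideline reference. Full precision is
#' returned; round at report time.
#'
#' @param dist a single-stratum exposure distribution (one factor, one
#'   `(age_band, sex, race)` cell) as built by [build_distribution()].
#' @param rg either a scalar slope or a one-row slope table carrying a
#'   `factor` column (checked against `dist`).
#' @param rec recommendations table or single row for the factor.
#' @return scalar PAF in `[0, 1)` when all `ERR_x >= 0`.
#' @export
paf_single <- function(dist, rg, rec = default_recommendations()) {
  dist <- validate_exposure_table(dist)
  fac <- unique(dist$factor)
  key <- unique(dist[, c("factor", "age_band", "sex", "race")])
  if (length(fac) != 1 || nrow(key) != 1) {
    paf_computation_error(
      "paf_single expects a single (factor, stratum) distribution")
  }
  if (is.data.frame(rg)) {
    if (!fac %in% rg$factor) {
      paf_computation_error(sprintf(
        "slope table has no row for factor '%s'", fac))
    }
    rg <- rg$rg[rg$factor == fac][1]
  }
  row <- rec_for_factor(rec, fac)
  s <- sum(dist$prevalence * err(rg, gx(dist$median, row)))
  s / (1 + s)
}

#' Pair exposure-prevalence age bands with incidence age bands
#'
#' Builds the latency map: each incidence age band is sourced from the
#' prevalence band `offset` years younger (default 10, the assumed lag
#' between dietary exposure and cancer diagnosis). Two boundary rules
#' mirror how survey bands are published: the youngest incidence band falls
#' back to the youngest prevalence band when the shifted target is below
#' the survey's age floor, and an open-ended oldest incidence band takes
#' the oldest prevalence band (carry-forward, e.g. prevalence 60-69 applied
#' to incidence >= 70). `offset = 0` is the identity mapping on matching
#' bands.
#'
#' @param prev_bands character labels of prevalence age bands.
#' @param inc_bands character labels of incidence age bands.
#' @param offset latency in years (non-negative integer).
#' @return tibble with columns `inc_band`, `prev_band`, ordered by
#'   incidence age.
#' @export
#' @examples
#' pair_latency(c("18-24", "25-34", "35-44", "45-54", "55-64", "60-69"),
#'              c("25-34", "35-44", "45-54", "55-64", "65-69", "70+"))
pair_latency <- function(prev_bands, inc_bands, offset = 10) {
  if (offset < 0) paf_config_error("latency offset must be >= 0")
  pb <- parse_age_bands(unique(prev_bands))
  pb <- pb[order(pb$lower, pb$upper), ]
  ib <- parse_age_bands(unique(inc_bands))
  ib <- ib[order(ib$lower, ib$upper), ]
  orphans <- character(0)
  src <- vapply(seq_len(nrow(ib)), function(i) {
    target <- ib$lower[i] - offset
    exact <- which(pb$lower == target)
    if (length(exact) > 0) return(pb$band[max(exact)])
    containing <- which(pb$lower <= target & target <= pb$upper)
    if (length(containing) > 0) return(pb$band[max(containing)])
    if (target < min(pb$lower)) return(pb$band[1])       # youngest fallback
    if (is.infinite(ib$upper[i])) return(pb$band[nrow(pb)])  # carry-forward
    orphans <<- c(orphans, ib$band[i])
    NA_character_
  }, character(1))
  if (length(orphans) > 0) {
    paf_config_error(sprintf(
      "latency pairing: no prevalence band reaches incidence band(s) %s at offset %d",
      paste(orphans, collapse = ", "), offset
    ))
  }
  tibble(inc_band = ib$band, prev_band = src)
}

#' Excess cases per incidence age band
#'
#' Multiplies each incidence band's case count by the PAF of its
#' latency-paired prevalence band. Missing count cells are an error, never
#' an implicit zero; a zero count is legal and yields zero excess with the
#' PAF still reported.
#'
#' @param paf_by_ageband tibble with columns `prev_band` (or `age_band`)
#'   and `paf`.
#' @param counts_by_ageband tibble with columns `age_band`, `count`
#'   (incidence-side bands).
#' @param latency_map output of [pair_latency()] covering every incidence
#'   band present in `counts_by_ageband`.
#' @return tibble per incidence band with `paf`, `case_count`,
#'   `excess_cases` (unrounded).
#' @export
excess_cases <- function(paf_by_ageband, counts_by_ageband, latency_map) {
  paf_by_ageband <- as_tibble(paf_by_ageband)
  if (!"prev_band" %in% names(paf_by_ageband)) {
    require_columns(paf_by_ageband, c("age_band", "paf"), "PAF table")
    paf_by_ageband <- dplyr::rename(paf_by_ageband,
                                    prev_band = "age_band")
  }
  require_columns(counts_by_ageband, c("age_band", "count"), "count table")
  counts <- as_tibble(counts_by_ageband)
  uncovered <- setdiff(counts$age_band, latency_map$inc_band)
  if (length(uncovered) > 0) {
    paf_config_error(sprintf(
      "latency map does not cover incidence band(s): %s",
      paste(uncovered, collapse = ", ")
    ))
  }
  joined <- counts |>
    left_join(latency_map, by = c(age_band = "inc_band")) |>
    left_join(paf_by_ageband[, c("prev_band", "paf")], by = "prev_band")
  if (any(is.na(joined$paf))) {
    paf_computation_error(sprintf(
      "no PAF available for prevalence band(s): %s",
      paste(unique(joined$prev_band[is.na(joined$paf)]), collapse = ", ")
    ))
  }
  if (any(is.na(joined$count))) {
    paf_data_error("missing case count cell (never treated as zero)")
  }
  mutate(joined,
         case_count = .data$count,
         excess_cases = .data$paf * .data$count)[
    , c("age_band", "prev_band", "paf", "case_count", "excess_cases")]
}

#' Case-weighted (age-weighted) aggregation of PAFs
#'
#' Aggregates per-age-band results into one stratum result with weights
#' equal to case counts: the aggregate PAF is total excess over total
#' cases, so the identity `excess = PAF * cases` survives aggregation.
#'
#' @param results tibble with columns `paf`, `case_count`, `excess_cases`
#'   (one row per age band of a common factor/sex/race/site scope).
#' @return one-row tibble with aggregate `paf`, `case_count`,
#'   `excess_cases`.
#' @export
aggregate_age_weighted <- function(results) {
  results <- as_tibble(results)
  require_columns(results, c("paf", "case_count", "excess_cases"),
                  "age-band results")
  if (nrow(results) == 0) {
    paf_computation_error("aggregate_age_weighted: no age-band results")
  }
  total_cases <- sum(results$case_count)
  total_excess <- sum(results$excess_cases)
  tibble(
    paf = if (total_cases > 0) total_excess / total_cases else 0,
    case_count = total_cases,
    excess_cases = total_excess
  )
}

#' Combine factor-specific results into an all-factors result
#'
#' Excess cases attributable to the individual dietary factors are summed
#' over a common denominator; the combined PAF is the summed excess over
#' the case count, equivalently the sum of the factor PAFs. Additive
#' combination can exceed one when factor PAFs are large; a warning is
#' attached rather than truncating. A complement-multiplicative
#' alternative, `1 - prod(1 - PAF_f)`, is available for sensitivity
#' analysis; it assumes independently acting exposures and is NOT how the
#' bundled burden tables were produced.
#'
#' @param results tibble with one row per factor: `factor`, `paf`,
#'   `case_count`, `excess_cases`, sharing a single denominator.
#' @param mode `"additive"` (default) or `"complement"`.
#' @return one-row tibble with `factor = "all_factors"`.
#' @export
combine_factors <- function(results, mode = c("additive", "complement")) {
  mode <- match.arg(mode)
  results <- as_tibble(results)
  require_columns(results, c("factor", "paf", "case_count", "excess_cases"),
                  "factor results")
  if (nrow(results) == 0) {
    paf_computation_error("combine_factors: empty input")
  }
  if (any(duplicated(results$factor))) {
    paf_computation_error("combine_factors: duplicated factor rows")
  }
  cc <- unique(results$case_count)
  if (length(cc) != 1) {
    paf_computation_error(
      "combine_factors: results do not share a common case-count denominator")
  }
  if (mode == "additive") {
    excess <- sum(results$excess_cases)
    paf <- if (cc > 0) excess / cc else sum(results$paf)
  } else {
    paf <- 1 - prod(1 - results$paf)
    excess <- paf * cc
  }
  if (paf >= 1) {
    warn(sprintf(
      "combined all-factors PAF is %.3f (>= 1): additive excess exceeds the denominator",
      paf
    ))
  }
  tibble(factor = "all_factors", paf = paf, case_count = cc,
         excess_cases = excess)
}

#' Re-express colorectal excess cases against the all-cancer denominator
#'
#' Keeps the excess-case numerator and swaps the denominator from the
#' site-specific count to the count of all incident cancers (excluding
#' basal- and squamous-cell skin carcinomas), giving the share of the total
#' cancer burden attributable to the exposure.
#'
#' @param result one-row result with `excess_cases` over a colorectal
#'   denominator.
#' @param total_cancers all-cancer case count for the same stratum.
#' @return the result row with `site_scope = "all_excl_bcc_scc"`, `paf` and
#'   `case_count` rescaled.
#' @export
allcancer_scope <- function(result, total_cancers) {
  result <- as_tibble(result)
  require_columns(result, c("excess_cases", "case_count"), "scope input")
  if (nrow(result) != 1) {
    paf_computation_error("allcancer_scope expects a single result row")
  }
  if (total_cancers < result$case_count) {
    paf_data_error(sprintf(
      "all-cancer count (%s) below site-group count (%s)",
      format(total_cancers), format(result$case_count)
    ))
  }
  result$case_count <- total_cancers
  result$paf <- if (total_cancers > 0) {
    result$excess_cases / total_cancers
  } else 0
  result$site_scope <- "all_excl_bcc_scc"
  result
}

#' Format a PAF as a report percentage
#'
#' One decimal place, half up — the convention of the bundled burden
#' tables. Excess cases are summed at full precision and rounded to the
#' nearest integer only here.
#'
#' @param paf fraction in `[0, 1]` (or above for additive combinations).
#' @param excess_cases unrounded excess cases (optional).
#' @return `paf_percent()` a numeric percentage; `format_paf_cell()` a
#'   string `"P.P (N)"`.
#' @export
paf_percent <- function(paf) round_half_up(100 * paf, 1)

#' @rdname paf_percent
#' @export
format_paf_cell <- function(paf, excess_cases = NULL) {
  pct <- sprintf("%.1f", paf_percent(paf))
  if (is.null(excess_cases)) return(pct)
  sprintf("%s (%d)", pct, as.integer(round_half_up(excess_cases, 0)))
}
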