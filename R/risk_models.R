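#' Validate a table of published relative-risk estimates
#'
#' A risk table holds one published relative risk per dietary factor, sex
#' stratum, and cancer site group. Each RR is reported per a dose increment
#' (e.g. per 100 g/day of red meat, per 200 mg/day of calcium) and is flagged
#' as detrimental (excess consumption raises risk) or protective (a deficit
#' relative to the guideline raises risk). Estimates whose reported
#' confidence interval spans the null are kept as point estimates; the
#' `ci_includes_null` flag travels as metadata only and never alters the
#' arithmetic.
#'
#' @param risk data frame with columns `factor`, `sex_stratum`, `site`,
#'   `rr`, `increment`, `unit`, `direction`, `ci_includes_null`.
#' @return the validated tibble, invisibly classed as input was.
#' @export
validate_risk_table <- function(risk) {
  require_columns(
    risk,
    c("factor", "sex_stratum", "site", "rr", "increment", "unit",
      "direction", "ci_includes_null"),
    "risk table"
  )
  risk <- as_tibble(risk)
  match_vocab(risk$factor, DIET_FACTORS, "factor", "risk table")
  match_vocab(risk$sex_stratum, SEX_LEVELS, "sex_stratum", "risk table")
  match_vocab(risk$unit, UNIT_LEVELS, "unit", "risk table")
  match_vocab(risk$direction, DIRECTION_LEVELS, "direction", "risk table")
  if (any(!is.finite(risk$rr)) || any(risk$rr <= 0)) {
    paf_data_error("risk table: rr must be finite and > 0")
  }
  if (any(!is.finite(risk$increment)) || any(risk$increment <= 0)) {
    paf_data_error("risk table: increment must be finite and > 0")
  }
  key <- paste(risk$factor, risk$sex_stratum, risk$site, sep = "/")
  dup <- unique(key[duplicated(key)])
  if (length(dup) > 0) {
    paf_data_error(sprintf(
      "risk table: duplicated (factor, sex_stratum, site) key(s): %s",
      paste(dup, collapse = ", ")
    ))
  }
  flagged <- risk$direction == "detrimental" & risk$rr < 1
  if (any(flagged)) {
    warn(sprintf(
      "risk table: detrimental factor(s) with RR < 1 accepted as-is: %s",
      paste(unique(risk$factor[flagged]), collapse = ", ")
    ))
  }
  risk
}

#' Convert published relative risks to per-unit log-risk slopes
#'
#' A relative risk reported per increment `x` of daily consumption is placed
#' on a continuous log-linear dose-response scale:
#' \deqn{R_g = \ln(RR)/x} for a detrimental factor (risk per unit of excess
#' consumption per day) and \deqn{R_g = \ln(1/RR)/x} for a protective factor
#' (risk per unit of daily deficit below the guideline). `Rg` is then in
#' risk per g/day (meats, fiber) or per mg/day (calcium), matching the unit
#' carried on the input row. A null RR of exactly 1 maps to a slope of 0.
#'
#' Full precision is retained; round only at report time (conventionally
#' four decimals, half up, via [round_half_up()]).
#'
#' @param risk a validated risk table (see [validate_risk_table()]), or any
#'   data frame with `rr`, `increment`, `direction` columns.
#' @return tibble with the identifying columns plus `rg`.
#' @export
#' @examples
#' rg_from_rr(data.frame(rr = 1.28, increment = 100,
#'                       direction = "detrimental"))$rg  # ln(1.28)/100
rg_from_rr <- function(risk) {
  require_columns(risk, c("rr", "increment", "direction"), "risk input")
  match_vocab(risk$direction, DIRECTION_LEVELS, "direction", "risk input")
  if (any(!is.finite(risk$rr)) || any(risk$rr <= 0)) {
    paf_data_error("rg_from_rr: rr must be finite and > 0")
  }
  if (any(!is.finite(risk$increment)) || any(risk$increment <= 0)) {
    paf_data_error("rg_from_rr: increment must be finite and > 0")
  }
  out <- as_tibble(risk)
  out$rg <- ifelse(
    out$direction == "detrimental",
    log(out$rr) / out$increment,
    log(1 / out$rr) / out$increment
  )
  keep <- intersect(
    c("factor", "sex_stratum", "site", "unit", "direction", "rg",
      "ci_includes_null"),
    names(out)
  )
  out[, keep]
}

#' Reconstruct a relative risk from a per-unit slope
#'
#' Inverse of [rg_from_rr()] at the same increment; used for round-trip
#' checks.
#'
#' @param rg per-unit log-risk slope.
#' @param increment dose increment the RR was reported per.
#' @param direction `"detrimental"` or `"protective"`.
#' @return relative risk per increment.
#' @export
rr_from_rg <- function(rg, increment, direction) {
  match_vocab(direction, DIRECTION_LEVELS, "direction", "rr_from_rg")
  ifelse(direction == "detrimental",
         exp(rg * increment),
         exp(-rg * increment))
}

#' Read a risk table from CSV
#'
#' Expected columns:
#' `factor,sex_stratum,site,rr,increment,unit,direction,ci_includes_null`.
#' Rows are validated (see [validate_risk_table()]); duplicated keys and
#' unknown labels are rejected with the offending key named.
#'
#' @param path CSV file path.
#' @return validated tibble of risk estimates (possibly zero rows).
#' @export
load_risk_table <- function(path) {
  if (!file.exists(path)) {
    paf_config_error(sprintf("risk table file not found: %s", path))
  }
  risk <- readr::read_csv(
    path,
    col_types = readr::cols(
      factor = readr::col_character(),
      sex_stratum = readr::col_character(),
      site = readr::col_character(),
      rr = readr::col_double(),
      increment = readr::col_double(),
      unit = readr::col_character(),
      direction = readr::col_character(),
      ci_includes_null = readr::col_logical()
    )
  )
  validate_risk_table(risk)
}

#' Write a risk table to CSV
#'
#' @param risk validated risk table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_risk_table <- function(risk, path) {
  risk <- validate_risk_table(risk)
  risk <- arrange(
    risk,
    match(.data$factor, DIET_FACTORS),
    match(.data$sex_stratum, SEX_LEVELS),
    .data$site
  )
  readr::write_csv(risk, path)
  invisible(path)
}
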