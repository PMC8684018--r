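#' Is an ICD-O-3 topography code colorectal?
#'
#' Colorectal cancers are defined by SEER site-recode topography major
#' groups C18 (colon), C19 (rectosigmoid junction), and C20 (rectum);
#' sub-sites (e.g. `C18.7`) are included.
#'
#' @param site_code character vector of topography codes matching
#'   `C<dd>` or `C<dd>.<d>`.
#' @return logical vector.
#' @export
#' @examples
#' is_colorectal(c("C18.7", "C20", "C16.0"))
is_colorectal <- function(site_code) {
  site_code <- toupper(trimws(as.character(site_code)))
  ok <- grepl("^C[0-9]{2}(\\.[0-9]+)?$", site_code)
  if (any(!ok)) {
    paf_data_error(sprintf(
      "malformed ICD-O-3 topography code(s): %s",
      paste(unique(site_code[!ok]), collapse = ", ")
    ))
  }
  substr(site_code, 1, 3) %in% c("C18", "C19", "C20")
}

validate_incidence <- function(inc) {
  require_columns(inc, c("site_group", "age_band", "sex", "race", "count"),
                  "incidence table")
  inc <- as_tibble(inc)
  match_vocab(inc$site_group, SITE_GROUPS, "site_group", "incidence table")
  match_vocab(inc$sex, SEX_LEVELS, "sex", "incidence table")
  match_vocab(inc$race, RACE_LEVELS, "race", "incidence table")
  if (any(!is.finite(inc$count)) || any(inc$count < 0) ||
      any(inc$count != floor(inc$count))) {
    paf_data_error("incidence table: counts must be non-negative integers")
  }
  key <- paste(inc$site_group, inc$age_band, inc$sex, inc$race, sep = "/")
  if (anyDuplicated(key)) {
    paf_data_error(sprintf(
      "incidence table: duplicated cell(s): %s",
      paste(unique(key[duplicated(key)]), collapse = ", ")
    ))
  }
  parse_age_bands(unique(inc$age_band))  # fail loudly on unparseable bands
  inc$count <- as.integer(inc$count)
  inc
}

#' Read a stratified cancer-count table
#'
#' CSV schema: `site_group,age_band,sex,race,count` with `site_group` in
#' `colorectal` / `all_excl_bcc_scc`. Counts must be non-negative integers;
#' duplicated cells are rejected. Alternatively a per-site-code table
#' (`site_code,age_band,sex,race,count`) may be given with
#' `from_site_codes = TRUE`, in which case colorectal counts are derived by
#' summing codes C18-C20 via [is_colorectal()].
#'
#' @param path CSV path.
#' @param from_site_codes derive the colorectal site group from raw
#'   topography codes.
#' @return validated incidence tibble.
#' @export
load_incidence <- function(path, from_site_codes = FALSE) {
  if (!file.exists(path)) {
    paf_config_error(sprintf("incidence file not found: %s", path))
  }
  if (from_site_codes) {
    raw <- readr::read_csv(
      path,
      col_types = readr::cols(
        site_code = readr::col_character(),
        age_band = readr::col_character(),
        sex = readr::col_character(),
        race = readr::col_character(),
        count = readr::col_double()
      )
    )
    inc <- raw |>
      filter(is_colorectal(.data$site_code)) |>
      group_by(.data$age_band, .data$sex, .data$race) |>
      summarise(count = sum(.data$count), .groups = "drop") |>
      mutate(site_group = "colorectal", .before = 1)
  } else {
    inc <- readr::read_csv(
      path,
      col_types = readr::cols(
        site_group = readr::col_character(),
        age_band = readr::col_character(),
        sex = readr::col_character(),
        race = readr::col_character(),
        count = readr::col_double()
      )
    )
  }
  validate_incidence(inc)
}

#' Write an incidence table with a canonical row order
#'
#' @param inc validated incidence tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_incidence <- function(inc, path) {
  inc <- validate_incidence(inc)
  info <- parse_age_bands(inc$age_band)
  inc <- inc[order(match(inc$site_group, SITE_GROUPS), info$lower,
                   match(inc$sex, SEX_LEVELS),
                   match(inc$race, RACE_LEVELS)), ]
  readr::write_csv(inc, path)
  invisible(path)
}

#' Check marginal consistency of an incidence table
#'
#' Where a table supplies both marginals and components — `persons`
#' alongside `men`/`women`, or `all` races alongside race groups — the
#' marginals must equal the component sums cell-by-cell. Inconsistencies
#' are reported (and raised as warnings); with `strict = TRUE` any
#' inconsistency is an error.
#'
#' @param inc validated incidence tibble.
#' @param strict escalate inconsistencies to an error.
#' @return tibble of inconsistent cells (zero rows when consistent),
#'   invisibly.
#' @export
validate_marginals <- function(inc, strict = FALSE) {
  inc <- validate_incidence(inc)
  issues <- list()

  sexes <- inc |>
    filter(.data$sex %in% c("men", "women")) |>
    group_by(.data$site_group, .data$age_band, .data$race) |>
    summarise(sum_parts = sum(.data$count), n_parts = n(),
              .groups = "drop") |>
    filter(.data$n_parts == 2) |>
    inner_join(
      filter(inc, .data$sex == "persons"),
      by = c("site_group", "age_band", "race")
    ) |>
    filter(.data$sum_parts != .data$count)
  if (nrow(sexes) > 0) {
    issues$sex <- mutate(sexes, check = "men + women != persons")
  }

  races <- inc |>
    filter(.data$race != "all") |>
    group_by(.data$site_group, .data$age_band, .data$sex) |>
    summarise(sum_parts = sum(.data$count), n_parts = n(),
              .groups = "drop") |>
    filter(.data$n_parts == length(setdiff(RACE_LEVELS, "all"))) |>
    inner_join(
      filter(inc, .data$race == "all"),
      by = c("site_group", "age_band", "sex")
    ) |>
    filter(.data$sum_parts != .data$count)
  if (nrow(races) > 0) {
    issues$race <- mutate(races, check = "race groups != all-races total")
  }

  report <- bind_rows(issues)
  if (nrow(report) > 0) {
    msg <- sprintf(
      "incidence marginals inconsistent in %d cell(s), e.g. %s/%s: %s (parts %d vs marginal %d)",
      nrow(report), report$site_group[1], report$age_band[1],
      report$check[1], report$sum_parts[1], report$count[1]
    )
    if (strict) paf_data_error(msg) else warn(msg)
  }
  invisible(report)
}
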