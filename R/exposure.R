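#' Guideline reference levels for the four dietary factors
#'
#' Defaults follow the dietary-guideline thresholds used in the bundled
#' analysis: red meat at most 60 g/day, processed meat 0 g/day (any
#' consumption is non-compliant), fiber at least 28 g/day, calcium at least
#' 1000 mg/day. `comparator = "maximum"` marks factors where consumption
#' above the reference is harmful; `"minimum"` marks intakes where falling
#' below it is insufficient. Consumption exactly at the reference counts as
#' compliant in both cases.
#'
#' @return tibble with columns `factor`, `reference`, `comparator`, `unit`.
#' @export
default_recommendations <- function() {
  tibble(
    factor = DIET_FACTORS,
    reference = c(60, 0, 28, 1000),
    comparator = c("maximum", "maximum", "minimum", "minimum"),
    unit = c("g_per_day", "g_per_day", "g_per_day", "mg_per_day")
  )
}

validate_recommendations <- function(rec) {
  require_columns(rec, c("factor", "reference", "comparator", "unit"),
                  "recommendations")
  rec <- as_tibble(rec)
  match_vocab(rec$factor, DIET_FACTORS, "factor", "recommendations")
  match_vocab(rec$comparator, COMPARATOR_LEVELS, "comparator",
              "recommendations")
  match_vocab(rec$unit, UNIT_LEVELS, "unit", "recommendations")
  if (any(duplicated(rec$factor))) {
    paf_data_error("recommendations: one row per factor required")
  }
  if (any(!is.finite(rec$reference)) || any(rec$reference < 0)) {
    paf_data_error("recommendations: reference must be finite and >= 0")
  }
  rec
}

rec_for_factor <- function(rec, factor) {
  rec <- validate_recommendations(rec)
  row <- rec[rec$factor == factor, ]
  if (nrow(row) != 1) {
    paf_config_error(sprintf("no recommendation for factor '%s'", factor))
  }
  row
}

validate_records <- function(records) {
  require_columns(
    records,
    c("person_id", "age_band", "sex", "race", "weight", "factor",
      "consumption"),
    "diet records"
  )
  records <- as_tibble(records)
  match_vocab(records$sex, setdiff(SEX_LEVELS, "persons"), "sex",
              "diet records")
  match_vocab(records$race, setdiff(RACE_LEVELS, "all"), "race",
              "diet records")
  match_vocab(records$factor, DIET_FACTORS, "factor", "diet records")
  if (any(!is.finite(records$consumption)) || any(records$consumption < 0)) {
    paf_data_error("diet records: consumption must be finite and >= 0")
  }
  if (any(!is.finite(records$weight)) || any(records$weight <= 0)) {
    paf_data_error("diet records: weights must be finite and > 0")
  }
  records
}

# Select the records of one factor within a stratum. sex = "persons" pools
# both sexes and race = "all" pools all races: pooled strata are computed
# from pooled records, never by averaging sub-stratum summaries.
stratum_records <- function(records, factor, stratum) {
  records <- validate_records(records)
  sex <- stratum$sex %||% "persons"
  race <- stratum$race %||% "all"
  age_band <- stratum$age_band %||% NULL
  sel <- records$factor == factor
  if (!identical(sex, "persons")) sel <- sel & records$sex == sex
  if (!identical(race, "all")) sel <- sel & records$race == race
  if (!is.null(age_band)) sel <- sel & records$age_band %in% age_band
  out <- records[sel, ]
  if (nrow(out) == 0) {
    paf_data_error(sprintf(
      "no diet records for factor '%s' in stratum (age_band=%s, sex=%s, race=%s)",
      factor, paste(age_band %||% "any", collapse = "|"), sex, race
    ))
  }
  out
}

# Non-compliant means strictly beyond the reference: consumption exactly at
# a maximum-type reference (<= ref allowed) or a minimum-type reference
# (>= ref required) is compliant.
is_noncompliant <- function(consumption, reference, comparator) {
  if (comparator == "maximum") consumption > reference
  else consumption < reference
}

#' Category scheme constructors
#'
#' `scheme_quantile(k)` (the default, `k = 5`) makes category 1 the
#' compliant stratum and splits the non-compliant consumption range into
#' `k - 1` weighted quantile classes, so boundaries always include the
#' reference level. `scheme_fixed(breaks)` uses fixed half-open bins
#' `[lower, upper)` over the non-negative axis — supply breaks including the
#' reference as an interior boundary to mimic a published categorisation.
#' `scheme_distinct()` gives every distinct consumption value its own
#' category, the full refinement under which the categorical PAF equals the
#' enumerated individual-level attributable fraction.
#'
#' @param k total number of categories (compliant + `k - 1` quantile bins).
#' @param breaks increasing numeric vector of interior bin edges; bins are
#'   `[0, breaks[1]), [breaks[1], breaks[2]), ..., [breaks[last], Inf)`.
#' @return a scheme object consumed by [build_distribution()].
#' @export
scheme_quantile <- function(k = 5) {
  if (k < 1) paf_config_error("scheme_quantile: k must be >= 1")
  structure(list(type = "quantile", k = as.integer(k)),
            class = "dietpaf_scheme")
}

#' @rdname scheme_quantile
#' @export
scheme_fixed <- function(breaks) {
  breaks <- sort(unique(as.numeric(breaks)))
  if (any(!is.finite(breaks)) || any(breaks < 0)) {
    paf_config_error("scheme_fixed: breaks must be finite and >= 0")
  }
  structure(list(type = "fixed", breaks = breaks), class = "dietpaf_scheme")
}

#' @rdname scheme_quantile
#' @export
scheme_distinct <- function() {
  structure(list(type = "distinct"), class = "dietpaf_scheme")
}

# Weighted quantile (lower-type edge rule for deterministic binning).
weighted_quantile_lower <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]
  w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) {
    x[which(cw >= p - sqrt(.Machine$double.eps))[1]]
  }, numeric(1))
}

#' Build a per-stratum exposure-category distribution
#'
#' Summarises individual consumption records for one factor and stratum into
#' ordered exposure categories with survey-weight prevalences `p_x`, bounds,
#' and weighted median consumption. Prevalences sum to one.
#' Category 1 under the default quantile scheme is the compliant class
#' (`G_x = 0` downstream); fixed-bin schemes classify by half-open
#' `[lower, upper)` intervals, except that a boundary equal to a
#' maximum-type reference level is kept on the compliant side (consumption
#' exactly at the reference is compliant).
#'
#' @param records long-format diet records
#'   (`person_id,age_band,sex,race,weight,factor,consumption`).
#' @param factor one of `red_meat`, `processed_meat`, `fiber`, `calcium`.
#' @param stratum list with any of `age_band`, `sex`, `race`; `sex =
#'   "persons"` pools both sexes, `race = "all"` pools races, a missing
#'   `age_band` pools all ages.
#' @param rec recommendations table (defaults to
#'   [default_recommendations()]).
#' @param scheme a [scheme_quantile()], [scheme_fixed()] or
#'   [scheme_distinct()] object.
#' @return tibble with columns `factor`, `age_band`, `sex`, `race`,
#'   `category_index`, `lower`, `upper`, `median`, `prevalence`.
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   person_id = 1:4, age_band = "25-34", sex = "men", race = "nh_white",
#'   weight = 1, factor = "red_meat", consumption = c(10, 50, 80, 120)
#' )
#' build_distribution(recs, "red_meat", list(sex = "men"),
#'                    scheme = scheme_fixed(c(60, 100)))
build_distribution <- function(records, factor, stratum = list(),
                               rec = default_recommendations(),
                               scheme = scheme_quantile(5)) {
  if (!inherits(scheme, "dietpaf_scheme")) {
    paf_config_error("scheme must be built with scheme_quantile/fixed/distinct")
  }
  row <- rec_for_factor(rec, factor)
  recs <- stratum_records(records, factor, stratum)
  x <- recs$consumption
  w <- recs$weight

  if (scheme$type == "fixed") {
    edges <- c(0, scheme$breaks[scheme$breaks > 0], Inf)
    idx <- findInterval(x, edges, rightmost.closed = FALSE)
    # keep consumption exactly at a maximum-type reference compliant when
    # the reference is one of the bin edges
    if (row$comparator == "maximum" && row$reference %in% edges) {
      at_ref <- x == row$reference
      idx[at_ref] <- findInterval(row$reference, edges) - 1L
      idx[at_ref & idx < 1L] <- 1L
    }
    cats <- tibble(
      category_index = seq_len(length(edges) - 1),
      lower = edges[-length(edges)],
      upper = edges[-1]
    )
  } else if (scheme$type == "distinct") {
    vals <- sort(unique(x))
    edges <- c(vals, Inf)
    idx <- match(x, vals)
    cats <- tibble(
      category_index = seq_along(vals),
      lower = vals,
      upper = edges[-1]
    )
  } else { # quantile: compliant class + k-1 quantile classes of the rest
    non <- is_noncompliant(x, row$reference, row$comparator)
    k_non <- scheme$k - 1L
    compliant <- if (row$comparator == "maximum") {
      tibble(category_index = 1L, lower = 0, upper = row$reference)
    } else {
      tibble(category_index = 1L, lower = row$reference, upper = Inf)
    }
    if (scheme$k == 1L) {
      # single catch-all category (degenerate but legal)
      idx <- rep(1L, length(x))
      cats <- tibble(category_index = 1L, lower = 0, upper = Inf)
    } else if (!any(non)) {
      idx <- rep(1L, length(x))
      cats <- compliant
    } else {
      idx <- integer(length(x))
      idx[!non] <- 1L
      xn <- x[non]
      wn <- w[non]
      qs <- weighted_quantile_lower(xn, wn, seq_len(k_non - 1) / k_non)
      qs <- unique(qs[qs > min(xn) & qs < max(xn)])
      if (row$comparator == "maximum") {
        # non-compliant range is (reference, Inf); bins (edge_i, edge_{i+1}]
        edges_non <- c(row$reference, qs, Inf)
        sub <- findInterval(xn, edges_non, left.open = TRUE)
      } else {
        # non-compliant range is [0, reference); bins [edge_i, edge_{i+1})
        edges_non <- sort(unique(c(0, qs, row$reference)))
        sub <- findInterval(xn, edges_non, rightmost.closed = FALSE)
      }
      idx[non] <- 1L + sub
      cats_non <- tibble(
        category_index = 1L + seq_len(length(edges_non) - 1),
        lower = edges_non[-length(edges_non)],
        upper = edges_non[-1]
      )
      cats <- bind_rows(compliant, cats_non)
    }
  }

  agg <- tibble(category_index = idx, consumption = x, weight = w) |>
    group_by(.data$category_index) |>
    summarise(
      median = weighted_median(.data$consumption, .data$weight),
      prevalence = sum(.data$weight),
      .groups = "drop"
    )
  agg$prevalence <- agg$prevalence / sum(w)
  out <- inner_join(cats, agg, by = "category_index") |>
    arrange(.data$category_index)
  out <- mutate(
    out,
    factor = factor,
    age_band = paste(stratum$age_band %||% "all", collapse = "|"),
    sex = stratum$sex %||% "persons",
    race = stratum$race %||% "all",
    .before = 1
  )
  stopifnot(abs(sum(out$prevalence) - 1) < 1e-9)
  out
}

#' Excess (or deficit) consumption of a category relative to the guideline
#'
#' For a detrimental factor the modelled dose is the category's median
#' consumption above the reference level, `max(0, median - reference)`; for
#' a protective intake it is the deficit below it, `max(0, reference -
#' median)`. Compliant categories — and over-adherent ones — get `G_x = 0`:
#' exceeding a minimum-type guideline confers no modelled benefit beyond
#' compliance.
#'
#' @param median category median consumption (vectorised).
#' @param rec a single recommendation row (`factor,reference,comparator,unit`)
#'   or a full recommendations table plus `factor`.
#' @param factor needed when `rec` has several rows.
#' @return non-negative dose `G_x` in factor units.
#' @export
gx <- function(median, rec, factor = NULL) {
  if (nrow(rec) > 1) {
    if (is.null(factor)) {
      paf_config_error("gx: supply factor when rec has multiple rows")
    }
    rec <- rec_for_factor(rec, factor)
  }
  if (any(!is.finite(median))) paf_data_error("gx: undefined category median")
  if (rec$comparator == "maximum") {
    pmax(0, median - rec$reference)
  } else {
    pmax(0, rec$reference - median)
  }
}

#' Prevalence of non-adherence to a dietary recommendation
#'
#' Weight fraction of a stratum's records with consumption strictly above a
#' maximum-type reference or strictly below a minimum-type reference.
#' When category bounds align with the reference this equals the summed
#' prevalence of the non-compliant categories of [build_distribution()].
#'
#' @inheritParams build_distribution
#' @return scalar in `[0, 1]`.
#' @export
adherence_prevalence <- function(records, factor, stratum = list(),
                                 rec = default_recommendations()) {
  row <- rec_for_factor(rec, factor)
  recs <- stratum_records(records, factor, stratum)
  non <- is_noncompliant(recs$consumption, row$reference, row$comparator)
  sum(recs$weight[non]) / sum(recs$weight)
}

#' Read/write exposure-distribution tables
#'
#' CSV schema:
#' `factor,age_band,sex,race,category_index,lower,upper,median,prevalence`
#' (`upper` may be `Inf`). On load, prevalences must sum to one within each
#' `(factor, age_band, sex, race)` group. Written values carry full double
#' precision, so a write/load round trip is lossless.
#'
#' @param path CSV path.
#' @param dists exposure-distribution tibble.
#' @return `load_exposure_table()` a validated tibble;
#'   `write_exposure_table()` the path, invisibly.
#' @export
load_exposure_table <- function(path) {
  if (!file.exists(path)) {
    paf_config_error(sprintf("exposure table file not found: %s", path))
  }
  d <- readr::read_csv(
    path,
    col_types = readr::cols(
      factor = readr::col_character(),
      age_band = readr::col_character(),
      sex = readr::col_character(),
      race = readr::col_character(),
      category_index = readr::col_integer(),
      lower = readr::col_double(),
      upper = readr::col_double(),
      median = readr::col_double(),
      prevalence = readr::col_double()
    )
  )
  validate_exposure_table(d)
}

#' @rdname load_exposure_table
#' @export
write_exposure_table <- function(dists, path) {
  dists <- validate_exposure_table(dists)
  readr::write_csv(dists, path)
  invisible(path)
}

#' @rdname load_exposure_table
#' @export
validate_exposure_table <- function(dists) {
  require_columns(
    dists,
    c("factor", "age_band", "sex", "race", "category_index", "lower",
      "upper", "median", "prevalence"),
    "exposure table"
  )
  dists <- as_tibble(dists)
  match_vocab(dists$factor, DIET_FACTORS, "factor", "exposure table")
  match_vocab(dists$sex, SEX_LEVELS, "sex", "exposure table")
  match_vocab(dists$race, RACE_LEVELS, "race", "exposure table")
  if (any(dists$prevalence < 0) || any(dists$prevalence > 1)) {
    paf_data_error("exposure table: prevalence outside [0, 1]")
  }
  sums <- dists |>
    group_by(.data$factor, .data$age_band, .data$sex, .data$race) |>
    summarise(s = sum(.data$prevalence), .groups = "drop")
  bad <- sums[abs(sums$s - 1) > 1e-6, ]
  if (nrow(bad) > 0) {
    paf_data_error(sprintf(
      "exposure table: prevalences do not sum to 1 for %s",
      paste(sprintf("(%s,%s,%s,%s): %.6f", bad$factor, bad$age_band,
                    bad$sex, bad$race, bad$s), collapse = "; ")
    ))
  }
  dists
}
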