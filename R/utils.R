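#' @importFrom rlang abort warn .data %||%
#' @importFrom dplyr filter mutate select arrange group_by summarise ungroup
#'   left_join inner_join anti_join bind_rows distinct pull across all_of n
#' @importFrom tibble tibble as_tibble
#' @importFrom stats plnorm qlnorm rbinom rlnorm runif setNames
#' @importFrom utils head tail
NULL

# Controlled vocabularies shared across the pipeline.
DIET_FACTORS <- c("red_meat", "processed_meat", "fiber", "calcium")
SEX_LEVELS <- c("men", "women", "persons")
RACE_LEVELS <- c("nh_white", "nh_black", "hispanic", "other", "all")
SITE_GROUPS <- c("colorectal", "all_excl_bcc_scc")
UNIT_LEVELS <- c("g_per_day", "mg_per_day")
DIRECTION_LEVELS <- c("detrimental", "protective")
COMPARATOR_LEVELS <- c("maximum", "minimum")

#' Round half away from zero at a fixed number of decimals
#'
#' Report-facing rounding used throughout: `round()` in R rounds half to
#' even, whereas published epidemiological tables conventionally round half
#' up. Applied only when formatting results; all internal arithmetic keeps
#' full double precision.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(2.5, 3.5, -2.5), 0)   # 3, 4, -3 (round() gives 2, 4, -2)
#' round_half_up(0.00315, 4)             # 0.0032
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# Condition constructors: distinct classes so callers (and the command-line
# wrapper) can map failures to configuration vs data vs computation.
paf_config_error <- function(msg, ...) {
  abort(msg, class = "dietpaf_config_error", ...)
}
paf_data_error <- function(msg, ...) {
  abort(msg, class = "dietpaf_data_error", ...)
}
paf_computation_error <- function(msg, ...) {
  abort(msg, class = "dietpaf_computation_error", ...)
}

match_vocab <- function(x, vocab, what, where = "input") {
  bad <- setdiff(unique(x), vocab)
  if (length(bad) > 0) {
    paf_data_error(sprintf(
      "Unknown %s value(s) in %s: %s (expected one of %s)",
      what, where, paste(bad, collapse = ", "), paste(vocab, collapse = ", ")
    ))
  }
  x
}

require_columns <- function(df, cols, where) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    paf_data_error(sprintf(
      "%s is missing required column(s): %s",
      where, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

#' Parse age-band labels
#'
#' Accepts closed bands written `"25-34"` (en dash also tolerated) and
#' open-ended bands written `"70+"` or `">=70"`. Returns one row per label
#' with numeric `lower` and `upper` (`Inf` for open-ended).
#'
#' @param bands character vector of band labels.
#' @return tibble with columns `band`, `lower`, `upper`.
#' @export
parse_age_bands <- function(bands) {
  bands <- as.character(bands)
  norm <- gsub("–|—", "-", bands)
  norm <- gsub("≥", ">=", norm)
  lower <- rep(NA_real_, length(norm))
  upper <- rep(NA_real_, length(norm))
  closed <- grepl("^\\s*\\d+\\s*-\\s*\\d+\\s*$", norm)
  open <- grepl("^\\s*(>=\\s*\\d+|\\d+\\s*\\+)\\s*$", norm)
  if (any(!closed & !open)) {
    paf_config_error(sprintf(
      "Unparseable age band label(s): %s",
      paste(unique(bands[!closed & !open]), collapse = ", ")
    ))
  }
  lower[closed] <- as.numeric(sub("-.*$", "", trimws(norm[closed])))
  upper[closed] <- as.numeric(sub("^.*-", "", trimws(norm[closed])))
  lower[open] <- as.numeric(gsub("[^0-9]", "", norm[open]))
  upper[open] <- Inf
  if (any(upper < lower)) {
    paf_config_error("Age band with upper bound below lower bound.")
  }
  tibble(band = bands, lower = lower, upper = upper)
}

order_age_bands <- function(bands) {
  info <- parse_age_bands(unique(bands))
  info$band[order(info$lower, info$upper)]
}

#' Weighted median
#'
#' The smallest value whose cumulative weight fraction reaches one half;
#' when a value's cumulative fraction lands exactly on one half (as in an
#' even unit-weight sample) the midpoint with the next larger value is
#' taken, so unit weights reproduce [stats::median()]. Deterministic under
#' ties; used for category medians so that repeated runs and permuted
#' inputs give identical distributions.
#'
#' @param x numeric values.
#' @param w positive weights (recycled scalar allowed).
#' @return scalar weighted median.
#' @export
weighted_median <- function(x, w = rep(1, length(x))) {
  if (length(x) == 0) paf_computation_error("weighted median of zero values")
  if (length(w) == 1) w <- rep(w, length(x))
  if (any(!is.finite(x)) || any(!is.finite(w)) || any(w <= 0)) {
    paf_data_error("weighted median needs finite values and positive weights")
  }
  o <- order(x)
  x <- x[o]
  w <- w[o]
  cw <- cumsum(w) / sum(w)
  eps <- sqrt(.Machine$double.eps)
  i <- which(cw >= 0.5 - eps)[1]
  if (abs(cw[i] - 0.5) < eps && i < length(x)) {
    (x[i] + x[i + 1]) / 2
  } else {
    x[i]
  }
}

#' Path to a bundled fixture file
#'
#' @param name file name under the package's `extdata` directory; with no
#'   argument, lists the available fixtures.
#' @return a file path, or a character vector of file names.
#' @export
paf_fixture <- function(name = NULL) {
  if (is.null(name)) {
    return(dir(system.file("extdata", package = "dietpaf")))
  }
  path <- system.file("extdata", name, package = "dietpaf")
  if (identical(path, "")) {
    paf_config_error(sprintf("No bundled fixture named '%s'", name))
  }
  path
}
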