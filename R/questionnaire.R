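# Scoring of the two questionnaires: the abridged sports nutrition
# knowledge questionnaire (A-NSKQ, 35 multiple-choice items: 11 general
# nutrition, 24 sports nutrition) and the short-form international physical
# activity questionnaire (IPAQ-SF: days and minutes/day of vigorous,
# moderate and walking activity plus sitting time).

ANSKQ_N_ITEMS <- 35L
ANSKQ_GNK_ITEMS <- 1:11
ANSKQ_SNK_ITEMS <- 12:35

anskq_item_cols <- function() sprintf("q%02d", seq_len(ANSKQ_N_ITEMS))

#' Placeholder A-NSKQ answer key
#'
#' The instrument's items and key are copyrighted and not redistributable,
#' so the package ships a synthetic placeholder key (cycling a/b/c/d over
#' the 35 items). Supply the licensed key to [score_anskq()] for real data;
#' scoring logic is independent of the key content.
#'
#' @return Character vector of 35 option letters.
#' @export
default_answer_key <- function() {
  rep(c("a", "b", "c", "d"), length.out = ANSKQ_N_ITEMS)
}

#' Score the A-NSKQ
#'
#' Percentage of correct answers in the general (GNK, items 1-11) and
#' sports (SNK, items 12-35) subsections and overall (TNK). Unanswered
#' items (`NA` or `""`) count as incorrect: the percentage denominator is
#' fixed by the instrument. TNK is by construction the 11/24-weighted
#' combination of the subsection percentages.
#'
#' @param data Data frame with columns `id` and `q01`...`q35` (selected
#'   option letter, or `NA`/blank if unanswered).
#' @param key Answer key, 35 option letters (default
#'   [default_answer_key()]).
#' @return A tibble with `id`, `gnk_pct`, `snk_pct`, `tnk_pct`, `nk_band`.
#' @export
score_anskq <- function(data, key = default_answer_key()) {
  cols <- anskq_item_cols()
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(sprintf("A-NSKQ data must have 35 item columns; missing: %s",
                  paste(missing, collapse = ", ")))
  }
  if (length(key) != ANSKQ_N_ITEMS) abort("Answer key must have 35 entries.")
  ans <- as.matrix(data[cols])
  correct <- sweep(ans, 2, key, function(a, k) !is.na(a) & a != "" & a == k)
  gnk <- rowSums(correct[, ANSKQ_GNK_ITEMS, drop = FALSE])
  snk <- rowSums(correct[, ANSKQ_SNK_ITEMS, drop = FALSE])
  gnk_pct <- 100 * gnk / length(ANSKQ_GNK_ITEMS)
  snk_pct <- 100 * snk / length(ANSKQ_SNK_ITEMS)
  tnk_pct <- 100 * (gnk + snk) / ANSKQ_N_ITEMS
  tibble::tibble(
    id = data$id, gnk_pct = gnk_pct, snk_pct = snk_pct, tnk_pct = tnk_pct,
    nk_band = classify_nk(tnk_pct)
  )
}

#' Nutrition-knowledge band
#'
#' Bands a percentage-correct score as poor / average / good / excellent.
#' The published integer bands (0-49, 50-65, 66-75, 76-100) are implemented
#' as the half-open partition \[0,50), \[50,66), \[66,76), \[76,100\] so
#' that non-integer scores are covered without gaps.
#'
#' @param score_pct Score in \[0, 100\].
#' @return Factor with levels poor < average < good < excellent.
#' @export
#' @examples
#' classify_nk(c(45.7, 52.6, 70, 90))
classify_nk <- function(score_pct) {
  if (any(score_pct < 0 | score_pct > 100, na.rm = TRUE)) {
    abort("Nutrition-knowledge scores must be in [0, 100].")
  }
  cut(score_pct, breaks = c(0, 50, 66, 76, 100),
      labels = c("poor", "average", "good", "excellent"),
      right = FALSE, include.lowest = TRUE, ordered_result = TRUE)
}

ipaq_cols <- function() {
  c("vig_days", "vig_min", "mod_days", "mod_min", "walk_days", "walk_min")
}

#' Clean IPAQ-SF records
#'
#' Applies the instrument's cleaning rules before scoring: any activity
#' domain reported at under 10 min/day is re-coded to zero minutes
#' (sessions that short carry no health benefit and are excluded by the
#' scoring protocol), and records whose summed daily activity minutes
#' exceed 960 (16 h/day) are flagged as outliers for exclusion. The
#' official 180-min/day per-domain truncation is available behind
#' `truncate_180` and is off by default. Cleaning is idempotent.
#'
#' @param data Data frame with columns `vig_days`, `vig_min`, `mod_days`,
#'   `mod_min`, `walk_days`, `walk_min` (and optionally `sit_min`).
#' @param truncate_180 Truncate each domain's minutes/day at 180 before the
#'   outlier check (default FALSE).
#' @return The input with minutes re-coded and a logical `excluded` column
#'   appended (outlier flag).
#' @export
ipaq_clean <- function(data, truncate_180 = FALSE) {
  need <- setdiff(ipaq_cols(), names(data))
  if (length(need)) {
    abort(sprintf("IPAQ data missing column(s): %s", paste(need, collapse = ", ")))
  }
  data <- tibble::as_tibble(data)
  for (cl in c("vig_min", "mod_min", "walk_min")) {
    x <- data[[cl]]
    if (any(x < 0, na.rm = TRUE)) abort(sprintf("'%s' has negative minutes.", cl))
    x[!is.na(x) & x < 10] <- 0
    if (truncate_180) x <- pmin(x, 180)
    data[[cl]] <- x
  }
  daily <- data$vig_min + data$mod_min + data$walk_min
  data$excluded <- !is.na(daily) & daily > 960
  data
}

#' MET-minutes per week from a cleaned IPAQ-SF record
#'
#' Weighted energy-expenditure score per domain: walking 3.3 MET, moderate
#' 4.0 MET, vigorous 8.0 MET; each domain contributes
#' weight x days/week x min/day, and the total physical-activity-level
#' score is their sum.
#'
#' @param data Cleaned IPAQ data frame (see [ipaq_clean()]).
#' @return The input with `met_walk`, `met_mod`, `met_vig`, `met_total`
#'   appended (MET-min/week).
#' @export
ipaq_met_minutes <- function(data) {
  neg <- c(ipaq_cols())[vapply(ipaq_cols(), function(cl)
    any(data[[cl]] < 0, na.rm = TRUE), logical(1))]
  if (length(neg)) abort(sprintf("Negative IPAQ value(s) in: %s",
                                 paste(neg, collapse = ", ")))
  dplyr::mutate(
    tibble::as_tibble(data),
    met_walk = 3.3 * .data$walk_days * .data$walk_min,
    met_mod = 4.0 * .data$mod_days * .data$mod_min,
    met_vig = 8.0 * .data$vig_days * .data$vig_min,
    met_total = .data$met_walk + .data$met_mod + .data$met_vig
  )
}

#' IPAQ-SF activity category
#'
#' Categorical physical activity level from a cleaned, scored record:
#' \describe{
#'   \item{high}{vigorous activity on >= 3 days with total >= 1500
#'     MET-min/week, or activity on >= 7 days (any combination) with total
#'     >= 3000 MET-min/week;}
#'   \item{moderate}{>= 3 days of vigorous activity of >= 20 min/day, or
#'     >= 5 days of moderate activity or walking of >= 30 min/day, or
#'     >= 5 days of any combination with total >= 600 MET-min/week;}
#'   \item{low}{otherwise.}
#' }
#'
#' @param data Data frame that has been through [ipaq_clean()] and
#'   [ipaq_met_minutes()] (needs the day/minute columns, `met_total` and
#'   `excluded`).
#' @param na_excluded Return `NA` for excluded records instead of erroring
#'   (default FALSE: an excluded record is an error to score).
#' @return Factor with levels low < moderate < high.
#' @export
ipaq_category <- function(data, na_excluded = FALSE) {
  if (!"met_total" %in% names(data)) {
    abort("Run ipaq_met_minutes() before ipaq_category().")
  }
  excl <- data$excluded %||% rep(FALSE, nrow(data))
  if (any(excl) && !na_excluded) {
    abort(sprintf("%d record(s) are flagged as outliers (excluded); score them with na_excluded = TRUE to get NA.",
                  sum(excl)))
  }
  days_any <- data$vig_days + data$mod_days + data$walk_days
  high <- (data$vig_days >= 3 & data$met_total >= 1500) |
    (days_any >= 7 & data$met_total >= 3000)
  moderate <- (data$vig_days >= 3 & data$vig_min >= 20) |
    (data$mod_days >= 5 & data$mod_min >= 30) |
    (data$walk_days >= 5 & data$walk_min >= 30) |
    (days_any >= 5 & data$met_total >= 600)
  out <- factor(ifelse(high, "high", ifelse(moderate, "moderate", "low")),
                levels = c("low", "moderate", "high"), ordered = TRUE)
  out[excl] <- NA
  out
}

#' Weekly energy expenditure from MET-minutes
#'
#' IPAQ convention: kcal/week = MET-min/week x body mass (kg) / 60. The
#' source instrument reports kcal without printing a formula; this is the
#' standard conversion and is flagged as such in report metadata.
#'
#' @param met_total MET-min/week.
#' @param body_mass_kg Body mass in kg; `NA` yields `NA` (kcal is omitted,
#'   never defaulted).
#' @return kcal/week.
#' @export
#' @examples
#' ipaq_kcal(600, 60)
ipaq_kcal <- function(met_total, body_mass_kg) {
  if (any(met_total < 0 | (!is.na(body_mass_kg) & body_mass_kg <= 0), na.rm = TRUE)) {
    abort("MET-minutes must be >= 0 and body mass > 0.")
  }
  met_total * body_mass_kg / 60
}

#' Score IPAQ-SF records end to end
#'
#' Cleaning, MET-minute conversion, categorisation and (when body mass is
#' available) kcal/week, in one call.
#'
#' @param data IPAQ data frame with `id` and the day/minute columns;
#'   optionally `body_mass_kg` (or pass `body_mass`).
#' @param body_mass Optional numeric vector of body masses (kg) aligned
#'   with rows; overrides a `body_mass_kg` column.
#' @param truncate_180 See [ipaq_clean()].
#' @return A tibble with `id`, `met_walk`, `met_mod`, `met_vig`,
#'   `met_total`, `kcal_week`, `pal_category`, `excluded`. Excluded records
#'   keep their scores but have `pal_category = NA`.
#' @export
score_ipaq <- function(data, body_mass = NULL, truncate_180 = FALSE) {
  scored <- ipaq_met_minutes(ipaq_clean(data, truncate_180 = truncate_180))
  mass <- body_mass %||%
    (if ("body_mass_kg" %in% names(scored)) scored$body_mass_kg) %||%
    rep(NA_real_, nrow(scored))
  tibble::tibble(
    id = scored$id,
    met_walk = scored$met_walk, met_mod = scored$met_mod,
    met_vig = scored$met_vig, met_total = scored$met_total,
    kcal_week = ipaq_kcal(scored$met_total, mass),
    pal_category = ipaq_category(scored, na_excluded = TRUE),
    excluded = scored$excluded
  )
}
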