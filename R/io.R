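# Cohort CSV input: schema definition, reading, validation and joining.

#' Cohort CSV schemas
#'
#' Column names (exact, in order) of the three cohort CSV files.
#'
#' @param which `"anthro"`, `"anskq"` or `"ipaq"`.
#' @return Character vector of column names.
#' @export
cohort_cols <- function(which = c("anthro", "anskq", "ipaq")) {
  which <- match.arg(which)
  switch(which,
    anthro = c(
      "id", "sex", "ranking", "age_y", "op_years", "otf_days_wk", "otq_h_wk",
      "mass_kg", "stature_cm", "sitting_height_cm", "arm_span_cm",
      "sf_pectoral_mm", "sf_triceps_mm", "sf_subscapular_mm", "sf_biceps_mm",
      "sf_suprailiac_mm", "sf_supraspinale_mm", "sf_abdominal_mm",
      "sf_front_thigh_mm", "sf_calf_mm",
      "g_neck_cm", "g_relaxed_arm_cm", "g_flexed_arm_cm", "g_chest_cm",
      "g_waist_cm", "g_hip_cm", "g_mid_thigh_cm", "g_calf_cm", "g_ankle_cm",
      "b_humerus_cm", "b_bistyloid_cm", "b_femur_cm", "b_bimalleolar_cm"
    ),
    anskq = c("id", anskq_item_cols()),
    ipaq = c("id", "vig_days", "vig_min", "mod_days", "mod_min",
             "walk_days", "walk_min", "sit_min")
  )
}

read_schema_csv <- function(path, which) {
  cols <- cohort_cols(which)
  ct <- switch(which,
    anskq = readr::cols(id = readr::col_character(),
                        .default = readr::col_character()),
    anthro = readr::cols(id = readr::col_character(),
                         sex = readr::col_character(),
                         ranking = readr::col_character(),
                         .default = readr::col_double()),
    ipaq = readr::cols(id = readr::col_character(),
                       .default = readr::col_double())
  )
  data <- readr::read_csv(path, col_types = ct, progress = FALSE)
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(sprintf("%s file '%s' is missing column(s): %s",
                  which, path, paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(data$id)) {
    abort(sprintf("%s file '%s' has duplicate id(s): %s", which, path,
                  paste(unique(data$id[duplicated(data$id)]), collapse = ", ")))
  }
  data[cols]
}

#' Read and join a cohort from CSV files
#'
#' Reads the anthropometric file (required) and the questionnaire files
#' (optional), validates, and joins on `id`. Anthropometric rows failing a
#' hard validation rule are dropped with a warning naming the row and rule;
#' soft physiologic-range findings are reported but kept. Athletes missing
#' from a questionnaire file keep `NA` in that file's fields (outer join on
#' the anthropometric ids), with a warning.
#'
#' @param anthro Path to the anthropometric CSV (see [cohort_cols()]), or a
#'   `synthetic_cohort` object (in which case the questionnaire paths are
#'   ignored and the in-memory tables are joined directly).
#' @param anskq,ipaq Optional paths to the questionnaire CSVs.
#' @return A joined tibble, one row per valid athlete; the validation-issue
#'   table is attached as attribute `"issues"`.
#' @export
read_cohort <- function(anthro, anskq = NULL, ipaq = NULL) {
  if (inherits(anthro, "synthetic_cohort")) {
    return(join_cohort(anthro$anthro, anthro$anskq, anthro$ipaq))
  }
  a <- read_schema_csv(anthro, "anthro")
  k <- if (!is.null(anskq)) read_schema_csv(anskq, "anskq")
  p <- if (!is.null(ipaq)) read_schema_csv(ipaq, "ipaq")
  join_cohort(a, k, p)
}

join_cohort <- function(a, k = NULL, p = NULL) {
  issues <- validate_profiles(a)
  hard <- issues[issues$severity == "error", ]
  if (nrow(hard)) {
    warn(paste0("Dropping ", length(unique(hard$row)), " invalid athlete row(s):\n",
                paste(sprintf("  row %d (%s): %s %s", hard$row, hard$id,
                              hard$column, hard$rule), collapse = "\n")))
    a <- a[-unique(hard$row), , drop = FALSE]
  }
  soft <- issues[issues$severity == "warning", ]
  if (nrow(soft)) {
    inform(sprintf("%d soft validation finding(s) (kept); see attr(, 'issues').",
                   nrow(soft)))
  }
  out <- a
  for (extra in list(k, p)) {
    if (is.null(extra)) next
    miss <- setdiff(out$id, extra$id)
    if (length(miss)) {
      warn(sprintf("%d athlete id(s) missing from a questionnaire file; fields set NA: %s",
                   length(miss), paste(miss, collapse = ", ")))
    }
    orphan <- setdiff(extra$id, out$id)
    if (length(orphan)) {
      warn(sprintf("%d questionnaire id(s) with no anthropometric record (ignored): %s",
                   length(orphan), paste(orphan, collapse = ", ")))
    }
    out <- dplyr::left_join(out, extra, by = "id")
  }
  attr(out, "issues") <- issues
  out
}
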