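# Study-report assembly: the full pipeline in fixed stage order
# (derive -> somatotype -> score -> describe -> compare -> correlate),
# producing a serialisable report mirroring the descriptive-table /
# correlation-table structure of a cross-sectional cohort study.

#' Build a full study report
#'
#' Runs the whole pipeline on a joined cohort: body-composition derivation,
#' somatotyping, questionnaire scoring, per-group descriptives (mean and
#' SD of every study variable), group-mean somatotype classification,
#' dispersion block (per-group SDM/SAM around the group mean somatotype;
#' per-sex elite vs non-elite SDD/SAD between mean somatotypes), the
#' statistics block ([compare_groups()]), per-sex Pearson correlations, and
#' the design block (Cochran n for the configured population and achieved
#' omnibus power at the realised N). With a single-sex cohort the sex and
#' interaction effects cannot be estimated; the comparison block is skipped
#' and an explicit notice recorded.
#'
#' All values are carried at full precision; rounding happens only in
#' [write_report()].
#'
#' @param data Joined cohort tibble from [read_cohort()], or a
#'   `synthetic_cohort`.
#' @param equation_bd_male,equation_bd_female,fat_conversion,equation_bone
#'   Equation-registry ids for the body-composition chain.
#' @param truncate_180 Apply the per-domain 180-min IPAQ truncation rule.
#' @param compare_vars Variables for the statistics block; defaults to the
#'   main derived study variables.
#' @param correlate_vars Variables for the per-sex correlation block.
#' @param population,z,p_hom,margin Design-block inputs for
#'   [cochran_sample_size()] (population of licensed athletes, z quantile,
#'   assumed homogeneity proportion, error margin).
#' @param effect_f,alpha,groups Design-block inputs for [anova_power()].
#' @param seed Seed for Monte-Carlo normality p-values.
#' @return An object of class `study_report`: a list with elements `data`
#'   (the fully derived athlete table), `descriptives`, `classification`,
#'   `dispersion`, `comparison` (`kin_comparison` or `NULL`),
#'   `correlations`, `design`, `meta`.
#' @export
build_report <- function(data,
                         equation_bd_male = "male_athlete_7sf",
                         equation_bd_female = "female_athlete_4sf",
                         fat_conversion = "siri",
                         equation_bone = "vondobeln_rocha",
                         truncate_180 = FALSE,
                         compare_vars = NULL,
                         correlate_vars = NULL,
                         population = 2500, z = 1.96, p_hom = 0.8, margin = 0.10,
                         effect_f = 0.4, alpha = 0.05, groups = 4,
                         seed = KIN_DEFAULT_SEED) {
  if (inherits(data, "synthetic_cohort")) data <- read_cohort(data)
  if (length(unique(data$ranking)) < 2) {
    abort("build_report() needs at least 2 groups (elite and non_elite).")
  }
  notes <- character()

  # stage 1-2: derive body composition, somatotype
  derived <- add_somatotype(add_body_composition(
    data, equation_bd_male, equation_bd_female, fat_conversion, equation_bone
  ))

  # stage 3: questionnaire scores (when the item/diary columns are present)
  if (all(anskq_item_cols() %in% names(derived))) {
    nk <- score_anskq(derived)
    derived <- dplyr::left_join(derived, nk, by = "id")
  } else notes <- c(notes, "A-NSKQ items absent; nutrition-knowledge block skipped.")
  if (all(ipaq_cols() %in% names(derived))) {
    pal <- score_ipaq(derived, body_mass = derived$mass_kg,
                      truncate_180 = truncate_180)
    derived <- dplyr::left_join(derived, pal, by = "id")
    n_excl <- sum(pal$excluded, na.rm = TRUE)
    if (n_excl) notes <- c(notes, sprintf(
      "%d record(s) excluded from activity scoring by the 960-min/day outlier rule.", n_excl))
  } else notes <- c(notes, "IPAQ fields absent; physical-activity block skipped.")

  # stage 4: descriptives
  num_vars <- setdiff(names(derived)[vapply(derived, is.numeric, logical(1))],
                      c("chart_x", "chart_y"))
  descriptives <- derived |>
    dplyr::group_by(.data$sex, .data$ranking) |>
    dplyr::summarise(dplyr::across(
      dplyr::all_of(num_vars),
      list(mean = ~mean(.x, na.rm = TRUE), sd = ~sd(.x, na.rm = TRUE))
    ), n = dplyr::n(), .groups = "drop") |>
    tidyr::pivot_longer(-c("sex", "ranking", "n"),
                        names_to = c("variable", ".value"),
                        names_pattern = "(.*)_(mean|sd)$")

  # group-mean somatotypes, their classification, and dispersion
  group_soma <- derived |>
    dplyr::group_by(.data$sex, .data$ranking) |>
    dplyr::summarise(endo = mean(.data$endo), meso = mean(.data$meso),
                     ecto = mean(.data$ecto), .groups = "drop")
  classification <- dplyr::mutate(
    group_soma,
    category = classify_somatotype(.data$endo, .data$meso, .data$ecto)
  )
  within_disp <- derived |>
    dplyr::group_by(.data$sex, .data$ranking) |>
    dplyr::group_modify(~somatotype_dispersion(.x)) |>
    dplyr::ungroup() |>
    dplyr::select("sex", "ranking", "n", "sdm", "sam")
  between <- group_soma |>
    tidyr::pivot_wider(names_from = "ranking",
                       values_from = c("endo", "meso", "ecto")) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      sdd_elite_vs_non_elite = {
        a <- somatochart_xy(.data$endo_elite, .data$meso_elite, .data$ecto_elite)
        b <- somatochart_xy(.data$endo_non_elite, .data$meso_non_elite,
                            .data$ecto_non_elite)
        sdd(a$x, a$y, b$x, b$y)
      },
      sad_elite_vs_non_elite = sad(.data$endo_elite, .data$meso_elite,
                                   .data$ecto_elite, .data$endo_non_elite,
                                   .data$meso_non_elite, .data$ecto_non_elite)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("sex", "sdd_elite_vs_non_elite", "sad_elite_vs_non_elite")

  # stage 5: comparison
  default_cmp <- intersect(
    c("age_y", "otf_days_wk", "otq_h_wk", "mass_kg", "stature_cm", "bmi",
      "percent_body_fat", "bone_mass_kg", "muscle_mass_kg",
      "endo", "meso", "ecto", "gnk_pct", "snk_pct", "tnk_pct",
      "met_total", "kcal_week"),
    names(derived)
  )
  compare_vars <- compare_vars %||% default_cmp
  comparison <- NULL
  if (length(unique(derived$sex)) < 2) {
    notes <- c(notes, "Single-sex cohort: sex and interaction effects omitted.")
  } else {
    comparison <- compare_groups(derived, compare_vars, alpha = alpha, seed = seed)
  }

  # stage 6: per-sex correlations
  correlate_vars <- correlate_vars %||% intersect(
    c("age_y", "otf_days_wk", "otq_h_wk", "percent_body_fat", "bone_mass_kg",
      "muscle_mass_kg", "bmi", "endo", "meso", "ecto",
      "gnk_pct", "snk_pct", "tnk_pct", "met_total", "kcal_week"),
    names(derived)
  )
  correlations <- lapply(split(derived, derived$sex), function(d) {
    keep <- correlate_vars[vapply(correlate_vars, function(v) {
      x <- d[[v]]
      sum(complete.cases(x)) >= 3 && sd(x, na.rm = TRUE) > 0
    }, logical(1))]
    if (length(keep) < 2) return(NULL)
    pearson_matrix(d, keep)
  })

  design <- tibble::tibble(
    cochran_n = cochran_sample_size(population, z, p_hom, margin),
    achieved_power = anova_power(effect_f, alpha, groups, nrow(derived)),
    total_n = nrow(derived)
  )

  structure(list(
    data = derived, descriptives = descriptives,
    classification = classification,
    dispersion = list(within_group = within_disp, between_ranking = between),
    comparison = comparison, correlations = correlations, design = design,
    meta = list(
      n = nrow(derived), notes = notes, seed = seed,
      equation_ids = c(bd_male = equation_bd_male,
                       bd_female = equation_bd_female,
                       fat = fat_conversion, bone = equation_bone),
      kcal_formula = "MET-min/week * body mass (kg) / 60"
    )
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Study report: %d athletes\n", x$meta$n))
  print(x$classification)
  if (!is.null(x$comparison)) print(glance(x$comparison))
  for (nt in x$meta$notes) cat("note:", nt, "\n")
  invisible(x)
}

#' Serialise a study report to JSON
#'
#' Writes the report blocks as JSON. Rounding (default 1 decimal place, the
#' presentation convention of kinanthropometry tables) is applied at
#' serialisation only; the in-memory report keeps full precision.
#'
#' @param report A `study_report`.
#' @param path Output file path.
#' @param round Digits to round numeric values to, or `NULL` for none.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, round = 1) {
  blocks <- list(
    n = report$meta$n,
    descriptives = report$descriptives,
    classification = report$classification,
    dispersion = list(
      within_group = report$dispersion$within_group,
      between_ranking = report$dispersion$between_ranking
    ),
    statistics = if (!is.null(report$comparison)) report$comparison$effects,
    posthoc = if (!is.null(report$comparison)) report$comparison$posthoc,
    correlations = lapply(report$correlations,
                          function(cc) if (!is.null(cc)) cc$pairs),
    design = report$design,
    notes = report$meta$notes,
    kcal_formula = report$meta$kcal_formula
  )
  if (!is.null(round)) blocks <- round_rec(blocks, round)
  jsonlite::write_json(blocks, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

round_rec <- function(x, digits) {
  if (is.list(x)) {
    x[] <- lapply(x, round_rec, digits)
    x
  } else if (is.double(x)) round(x, digits) else x
}

#' Per-group mean-and-SD summary of selected variables
#'
#' Descriptive helper matching the "mean +/- SD by sex and ranking" layout
#' of cohort tables.
#'
#' @param data Data frame with `sex` and `ranking`.
#' @param vars Character vector of numeric columns to summarise.
#' @return A tibble: `sex`, `ranking`, `n`, `variable`, `mean`, `sd`.
#' @export
describe_groups <- function(data, vars) {
  data |>
    dplyr::group_by(.data$sex, .data$ranking) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(vars),
                                   list(mean = ~mean(.x, na.rm = TRUE),
                                        sd = ~sd(.x, na.rm = TRUE))),
                     n = dplyr::n(), .groups = "drop") |>
    tidyr::pivot_longer(-c("sex", "ranking", "n"),
                        names_to = c("variable", ".value"),
                        names_pattern = "(.*)_(mean|sd)$")
}
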