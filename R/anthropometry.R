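# Body-composition arithmetic on ISAK anthropometric profiles.

#' Body mass index
#'
#' @param body_mass_kg Body mass in kg.
#' @param stature_cm Stature in cm.
#' @return BMI in kg/m^2.
#' @export
#' @examples
#' bmi(65.0, 175.1)
bmi <- function(body_mass_kg, stature_cm) {
  check_positive(body_mass_kg, "body_mass_kg")
  check_positive(stature_cm, "stature_cm")
  body_mass_kg / (stature_cm / 100)^2
}

#' Skinfold-corrected girth
#'
#' Limb girths entering somatotype and muscle-mass equations are corrected
#' for the overlying skinfold. Two conventions exist: the Heath-Carter
#' convention subtracts the skinfold converted to cm; the muscle-mass
#' (circumference-model) convention subtracts pi times the skinfold in cm,
#' treating the fold as a double layer around a circular limb.
#'
#' @param girth_cm Girth in cm.
#' @param skinfold_mm Skinfold at the site in mm.
#' @param mode `"heath_carter"` (girth - sf/10) or `"lee"` (girth - pi*sf/10).
#' @return Corrected girth in cm.
#' @export
#' @examples
#' corrected_girth(29.1, 7.0, "heath_carter")
#' corrected_girth(27.3, 7.0, "lee")
corrected_girth <- function(girth_cm, skinfold_mm, mode = c("heath_carter", "lee")) {
  mode <- match.arg(mode)
  out <- switch(mode,
    heath_carter = girth_cm - skinfold_mm / 10,
    lee = girth_cm - pi * skinfold_mm / 10
  )
  if (any(out < 0, na.rm = TRUE)) {
    abort("Corrected girth is negative: skinfold correction exceeds the girth.")
  }
  out
}

#' Body density from skinfolds
#'
#' Evaluates a registered skinfold body-density equation on each row of a
#' data frame holding the athlete schema columns. The default entries are a
#' linear male-athlete 7-skinfold equation and a log-linear female-athlete
#' 4-skinfold equation; both are swappable via the registry because the
#' sex-specific athlete equations in use differ between laboratories.
#'
#' @param data Data frame with the skinfold columns the equation needs
#'   (`sf_*_mm`) and, if `equation_male`/`equation_female` both apply, a
#'   `sex` column coded `"M"`/`"F"`.
#' @param equation_male,equation_female Registry ids used for male and
#'   female rows respectively.
#' @return Numeric vector of body densities (g/cm^3), one per row.
#' @seealso [equation_registry()], [percent_body_fat()]
#' @export
body_density <- function(data, equation_male = "male_athlete_7sf",
                         equation_female = "female_athlete_4sf") {
  em <- get_equation(equation_male, "body_density")
  ef <- get_equation(equation_female, "body_density")
  if (!"sex" %in% names(data)) {
    abort("body_density() needs a 'sex' column coded 'M'/'F'.")
  }
  check_sex(data$sex)
  out <- rep(NA_real_, nrow(data))
  m <- data$sex == "M"
  if (any(m)) out[m] <- em$fn(data[m, , drop = FALSE])
  if (any(!m)) out[!m] <- ef$fn(data[!m, , drop = FALSE])
  bad <- !is.na(out) & (out < 0.98 | out > 1.12)
  if (any(bad)) {
    warn(sprintf("%d body-density value(s) outside the physiologic range [0.98, 1.12].",
                 sum(bad)))
  }
  out
}

#' Percent body fat from body density
#'
#' @param bd Body density in g/cm^3, within \[0.98, 1.12\].
#' @param conversion Registry id of the density-to-fat conversion
#'   (default `"siri"`).
#' @return Percent body fat.
#' @export
#' @examples
#' percent_body_fat(1.07844)
percent_body_fat <- function(bd, conversion = "siri") {
  entry <- get_equation(conversion, "fat_conversion")
  if (any(bd < 0.98 | bd > 1.12, na.rm = TRUE)) {
    abort("Body density outside [0.98, 1.12] g/cm^3.")
  }
  entry$fn(bd)
}

#' Skeletal (bone) mass from breadths
#'
#' @param stature_cm Stature in cm.
#' @param bistyloid_cm Wrist (bistyloid) breadth in cm.
#' @param femur_cm Biepicondylar femur breadth in cm.
#' @param equation Registry id (default `"vondobeln_rocha"`).
#' @return Bone mass in kg.
#' @export
#' @examples
#' bone_mass(175.1, 5.5, 9.8)
bone_mass <- function(stature_cm, bistyloid_cm, femur_cm,
                      equation = "vondobeln_rocha") {
  entry <- get_equation(equation, "bone_mass")
  check_positive(stature_cm, "stature_cm")
  check_positive(bistyloid_cm, "bistyloid_cm")
  check_positive(femur_cm, "femur_cm")
  entry$fn(tibble::tibble(stature_cm = stature_cm,
                          b_bistyloid_cm = bistyloid_cm,
                          b_femur_cm = femur_cm))
}

#' Skeletal muscle mass (anthropometric circumference model)
#'
#' Total-body skeletal muscle mass from stature, age, sex and three
#' skinfold-corrected limb girths (arm, mid-thigh, calf), using the
#' circumference-model prediction equation of Lee and colleagues. Girths are
#' corrected in "lee" mode (girth minus pi times the skinfold in cm).
#'
#' @param stature_cm Stature in cm.
#' @param age_y Age in years.
#' @param sex `"M"` or `"F"` (the model adds 2.4 kg for males).
#' @param relaxed_arm_girth_cm,triceps_sf_mm Arm girth (cm) and triceps
#'   skinfold (mm).
#' @param mid_thigh_girth_cm,front_thigh_sf_mm Mid-thigh girth and front
#'   thigh skinfold.
#' @param calf_girth_cm,calf_sf_mm Calf girth and medial calf skinfold.
#' @param race_coeff Ethnicity adjustment term in kg; defaults to 0.
#' @return Skeletal muscle mass in kg.
#' @export
#' @examples
#' muscle_mass_lee(175.1, 24.3, "M", 27.3, 7.0, 51.0, 9.2, 37.2, 5.9)
muscle_mass_lee <- function(stature_cm, age_y, sex,
                            relaxed_arm_girth_cm, triceps_sf_mm,
                            mid_thigh_girth_cm, front_thigh_sf_mm,
                            calf_girth_cm, calf_sf_mm, race_coeff = 0) {
  check_sex(sex)
  cag <- corrected_girth(relaxed_arm_girth_cm, triceps_sf_mm, "lee")
  ctg <- corrected_girth(mid_thigh_girth_cm, front_thigh_sf_mm, "lee")
  ccg <- corrected_girth(calf_girth_cm, calf_sf_mm, "lee")
  sex_term <- ifelse(sex == "M", 1, 0)
  (stature_cm / 100) * (0.00744 * cag^2 + 0.00088 * ctg^2 + 0.00441 * ccg^2) +
    2.4 * sex_term - 0.048 * age_y + race_coeff + 7.8
}

#' Technical error of measurement
#'
#' Absolute and relative TEM over paired repeated measurements of the same
#' variable: TEM = sqrt(sum(d^2) / (2n)) over the paired differences d;
#' relative TEM expresses it as a percentage of the grand mean.
#'
#' @param first,second Numeric vectors of equal length (the two measurement
#'   passes), n >= 2.
#' @return A one-row tibble with columns `n`, `tem` (variable units) and
#'   `tem_pct` (relative TEM, %).
#' @export
#' @examples
#' tem(c(10, 8), c(12, 8))
tem <- function(first, second) {
  if (length(first) != length(second)) {
    abort("The two measurement passes must have equal length.")
  }
  if (length(first) < 2) abort("TEM needs at least 2 paired observations.")
  d <- first - second
  abs_tem <- sqrt(sum(d^2) / (2 * length(d)))
  grand <- mean(c(first, second))
  tibble::tibble(n = length(d), tem = abs_tem, tem_pct = 100 * abs_tem / grand)
}

#' Derive body composition for a cohort
#'
#' Adds BMI, body density, percent body fat, bone mass and skeletal muscle
#' mass columns to an athlete data frame in the cohort CSV schema. Internal
#' precision is kept full; round only at reporting.
#'
#' @param data Athlete data frame (see [cohort_cols()]).
#' @param equation_bd_male,equation_bd_female,fat_conversion,equation_bone
#'   Registry ids for the pluggable steps.
#' @param race_coeff Ethnicity term passed to [muscle_mass_lee()].
#' @return The input with columns `bmi`, `body_density_gcc`,
#'   `percent_body_fat`, `bone_mass_kg`, `muscle_mass_kg` appended; the ids
#'   of the equations used are attached as the `"equation_ids"` attribute.
#' @export
add_body_composition <- function(data,
                                 equation_bd_male = "male_athlete_7sf",
                                 equation_bd_female = "female_athlete_4sf",
                                 fat_conversion = "siri",
                                 equation_bone = "vondobeln_rocha",
                                 race_coeff = 0) {
  data <- tibble::as_tibble(data)
  bd <- body_density(data, equation_bd_male, equation_bd_female)
  out <- dplyr::mutate(
    data,
    bmi = bmi(.data$mass_kg, .data$stature_cm),
    body_density_gcc = bd,
    percent_body_fat = percent_body_fat(bd, fat_conversion),
    bone_mass_kg = bone_mass(.data$stature_cm, .data$b_bistyloid_cm,
                             .data$b_femur_cm, equation_bone),
    muscle_mass_kg = muscle_mass_lee(
      .data$stature_cm, .data$age_y, .data$sex,
      .data$g_relaxed_arm_cm, .data$sf_triceps_mm,
      .data$g_mid_thigh_cm, .data$sf_front_thigh_mm,
      .data$g_calf_cm, .data$sf_calf_mm, race_coeff = race_coeff
    )
  )
  over <- !is.na(out$bone_mass_kg) & !is.na(out$muscle_mass_kg) &
    (out$bone_mass_kg + out$muscle_mass_kg >= out$mass_kg)
  if (any(over)) {
    warn(sprintf("%d athlete(s) with bone + muscle mass >= body mass; check inputs.",
                 sum(over)))
  }
  attr(out, "equation_ids") <- c(
    bd_male = equation_bd_male, bd_female = equation_bd_female,
    fat = fat_conversion, bone = equation_bone
  )
  out
}

# -- validation helpers ------------------------------------------------------

check_positive <- function(x, name) {
  if (any(!is.na(x) & x <= 0)) {
    abort(sprintf("'%s' must be strictly positive.", name))
  }
  invisible(x)
}

check_sex <- function(sex) {
  if (any(!sex %in% c("M", "F"))) abort("'sex' must be coded 'M' or 'F'.")
  invisible(sex)
}

#' Validate anthropometric profiles
#'
#' Hard rules (rejection): non-positive measurements, malformed sex/ranking
#' codes. Soft rules (warning only): stature outside \[100, 230\] cm,
#' skinfolds outside \[1, 80\] mm — athlete populations include extreme but
#' valid values, so physiologic range checks never reject.
#'
#' @param data Athlete data frame in the cohort CSV schema.
#' @return A tibble of issues with columns `row`, `id`, `column`, `rule`,
#'   `severity` (`"error"` or `"warning"`); zero rows when clean.
#' @export
validate_profiles <- function(data) {
  issues <- list()
  note <- function(rows, column, rule, severity) {
    if (!length(rows)) return()
    issues[[length(issues) + 1L]] <<- tibble::tibble(
      row = rows,
      id = as.character(data$id[rows] %||% NA_character_),
      column = column, rule = rule, severity = severity
    )
  }
  num_cols <- intersect(setdiff(cohort_cols("anthro"),
                                c("id", "sex", "ranking")), names(data))
  for (cl in num_cols) {
    x <- data[[cl]]
    note(which(!is.na(x) & x <= 0), cl, "must be strictly positive", "error")
  }
  if ("sex" %in% names(data)) {
    note(which(!data$sex %in% c("M", "F")), "sex", "must be 'M' or 'F'", "error")
  }
  if ("ranking" %in% names(data)) {
    note(which(!data$ranking %in% c("elite", "non_elite")), "ranking",
         "must be 'elite' or 'non_elite'", "error")
  }
  if ("stature_cm" %in% names(data)) {
    x <- data$stature_cm
    note(which(!is.na(x) & x > 0 & (x < 100 | x > 230)), "stature_cm",
         "outside physiologic range [100, 230] cm", "warning")
  }
  for (cl in grep("^sf_", num_cols, value = TRUE)) {
    x <- data[[cl]]
    note(which(!is.na(x) & x > 0 & (x < 1 | x > 80)), cl,
         "outside physiologic range [1, 80] mm", "warning")
  }
  if (length(issues)) dplyr::bind_rows(issues) else {
    tibble::tibble(row = integer(), id = character(), column = character(),
                   rule = character(), severity = character())
  }
}
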