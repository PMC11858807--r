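# Pluggable equation registry.
#
# The body-density, fat-conversion and bone-mass steps of a skinfold
# body-composition chain are all "choose your published equation" steps:
# different studies cite different sources and the choice materially changes
# %BF and bone-mass output. Entries are therefore keyed by a string id and
# swappable at call time without code change. Each entry is a function of a
# data frame holding the athlete CSV schema columns (see [cohort_cols()]),
# returning one value per row.

.kin_registry <- new.env(parent = emptyenv())

#' Register a body-composition equation
#'
#' Adds (or replaces) an entry in the equation registry used by
#' [body_density()], [percent_body_fat()] and [bone_mass()].
#'
#' @param id Character key for the entry.
#' @param type One of `"body_density"`, `"fat_conversion"`, `"bone_mass"`.
#' @param fn For `body_density` and `bone_mass`: a function of a data frame
#'   with the athlete schema columns, returning a numeric vector (one value
#'   per row). For `fat_conversion`: a function of a body-density vector
#'   (g/cm^3) returning percent body fat.
#' @param sex Optional sex the entry is intended for (`"M"`, `"F"` or `NA`
#'   for either); informational only.
#' @param description One-line description of the equation.
#' @return The id, invisibly.
#' @export
register_equation <- function(id, type = c("body_density", "fat_conversion", "bone_mass"),
                              fn, sex = NA_character_, description = "") {
  type <- match.arg(type)
  stopifnot(is.character(id), length(id) == 1L, is.function(fn))
  assign(id, list(id = id, type = type, fn = fn, sex = sex,
                  description = description), envir = .kin_registry)
  invisible(id)
}

#' List registered equations
#'
#' @return A tibble with columns `id`, `type`, `sex`, `description`.
#' @export
#' @examples
#' equation_registry()
equation_registry <- function() {
  entries <- lapply(ls(.kin_registry), get, envir = .kin_registry)
  tibble::tibble(
    id = vapply(entries, `[[`, "", "id"),
    type = vapply(entries, `[[`, "", "type"),
    sex = vapply(entries, `[[`, "", "sex"),
    description = vapply(entries, `[[`, "", "description")
  )
}

get_equation <- function(id, type) {
  if (!exists(id, envir = .kin_registry, inherits = FALSE)) {
    abort(sprintf("Unknown equation id '%s'; see equation_registry().", id))
  }
  entry <- get(id, envir = .kin_registry)
  if (entry$type != type) {
    abort(sprintf("Equation '%s' has type '%s', not '%s'.", id, entry$type, type))
  }
  entry
}

need_cols <- function(data, cols, id) {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(sprintf("Equation '%s' needs missing column(s): %s",
                  id, paste(missing, collapse = ", ")))
  }
}

# -- default entries ---------------------------------------------------------

# Male-athlete density from the sum of seven skinfolds (mm):
# triceps, subscapular, biceps, supraspinale, abdominal, front thigh, calf.
register_equation(
  "male_athlete_7sf", "body_density",
  function(data) {
    need_cols(data, c("sf_triceps_mm", "sf_subscapular_mm", "sf_biceps_mm",
                      "sf_supraspinale_mm", "sf_abdominal_mm",
                      "sf_front_thigh_mm", "sf_calf_mm"), "male_athlete_7sf")
    s7 <- data$sf_triceps_mm + data$sf_subscapular_mm + data$sf_biceps_mm +
      data$sf_supraspinale_mm + data$sf_abdominal_mm +
      data$sf_front_thigh_mm + data$sf_calf_mm
    1.0988 - 0.0004 * s7
  },
  sex = "M",
  description = "Linear male-athlete density on the sum of 7 skinfolds"
)

# Female-athlete density from log10 of the sum of four skinfolds (mm):
# triceps, subscapular, supraspinale, calf.
register_equation(
  "female_athlete_4sf", "body_density",
  function(data) {
    need_cols(data, c("sf_triceps_mm", "sf_subscapular_mm",
                      "sf_supraspinale_mm", "sf_calf_mm"), "female_athlete_4sf")
    s4 <- data$sf_triceps_mm + data$sf_subscapular_mm +
      data$sf_supraspinale_mm + data$sf_calf_mm
    1.20953 - 0.08294 * log10(s4)
  },
  sex = "F",
  description = "Log-linear female-athlete density on the sum of 4 skinfolds"
)

# Siri two-compartment density-to-fat conversion; the classic zero point is
# %BF = 0 at BD = 1.10 g/cm^3.
register_equation(
  "siri", "fat_conversion",
  function(bd) 495 / bd - 450,
  description = "Siri: %BF = 495/BD - 450"
)

# Brozek alternate conversion, kept as a registry alternative.
register_equation(
  "brozek", "fat_conversion",
  function(bd) 457 / bd - 414.2,
  description = "Brozek: %BF = 457/BD - 414.2"
)

# von Dobeln-type skeletal (bone) mass from stature, wrist (bistyloid) and
# femur breadths, all converted to metres.
register_equation(
  "vondobeln_rocha", "bone_mass",
  function(data) {
    need_cols(data, c("stature_cm", "b_bistyloid_cm", "b_femur_cm"),
              "vondobeln_rocha")
    h <- data$stature_cm / 100
    r <- data$b_bistyloid_cm / 100
    f <- data$b_femur_cm / 100
    3.02 * (h^2 * r * f * 400)^0.712
  },
  description = "Bone mass 3.02*(h^2*wrist*femur*400)^0.712, inputs in m"
)
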