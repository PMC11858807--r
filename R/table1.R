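# Published group summaries of the orienteering athlete cohort that the
# synthetic generator and the worked examples are parameterised from.

#' Published group means and SDs for the orienteering cohort
#'
#' Mean and standard deviation of every raw study variable for the four
#' groups (elite/non-elite x male/female) of the orienteering athlete
#' cohort, as printed in the source study's descriptive table. These are
#' the default generating parameters of [table1_default_specs()] and the
#' inputs of the package's worked desk-scale examples (group-mean
#' somatotypes, muscle mass, dispersion distances, nutrition-knowledge
#' weighting).
#'
#' Derived quantities (BMI, %BF, somatotype components, MET scores) are
#' listed for reference but are never generator inputs.
#'
#' @return A tibble with columns `variable`, `sex` (`"M"`/`"F"`),
#'   `ranking` (`"elite"`/`"non_elite"`), `mean`, `sd` (`NA` where the
#'   source prints a single value).
#' @export
table1_group_means <- function() {
  g <- function(sex, ranking, ...) {
    v <- c(...)
    nm <- names(v)
    tibble::tibble(variable = nm[seq(1, length(v), 2)],
                   sex = sex, ranking = ranking,
                   mean = unname(v[seq(1, length(v), 2)]),
                   sd = unname(v[seq(2, length(v), 2)]))
  }
  # each entry: variable = mean, variable = sd (pairs)
  em <- g("M", "elite",
    age_y = 24.3, age_y = 5.0, op_years = 12.1, op_years = 6.2,
    otf_days_wk = 6.1, otf_days_wk = 1.3, otq_h_wk = 8.8, otq_h_wk = 4.0,
    mass_kg = 65.0, mass_kg = 5.5, stature_cm = 175.1, stature_cm = 6.0,
    sitting_height_cm = 103.0, sitting_height_cm = 18.7,
    arm_span_cm = 176.1, arm_span_cm = 6.2,
    sf_pectoral_mm = 6.4, sf_pectoral_mm = 3.4,
    sf_triceps_mm = 7.0, sf_triceps_mm = 2.8,
    sf_subscapular_mm = 8.4, sf_subscapular_mm = 2.6,
    sf_biceps_mm = 3.3, sf_biceps_mm = 1.0,
    sf_suprailiac_mm = 11.0, sf_suprailiac_mm = 7.1,
    sf_supraspinale_mm = 7.0, sf_supraspinale_mm = 3.7,
    sf_abdominal_mm = 10.1, sf_abdominal_mm = 6.4,
    sf_front_thigh_mm = 9.2, sf_front_thigh_mm = 3.2,
    sf_calf_mm = 5.9, sf_calf_mm = 2.7,
    g_neck_cm = 35.1, g_neck_cm = 1.8,
    g_relaxed_arm_cm = 27.3, g_relaxed_arm_cm = 2.4,
    g_flexed_arm_cm = 29.1, g_flexed_arm_cm = 2.3,
    g_chest_cm = 90.3, g_chest_cm = 4.5,
    g_waist_cm = 74.2, g_waist_cm = 5.6,
    g_hip_cm = 91.2, g_hip_cm = 3.4,
    g_mid_thigh_cm = 51.0, g_mid_thigh_cm = 3.1,
    g_calf_cm = 37.2, g_calf_cm = 2.1,
    g_ankle_cm = 22.2, g_ankle_cm = 0.9,
    endo = 2.1, endo = 0.9, meso = 4.4, meso = 1.3, ecto = 3.3, ecto = 1.2,
    gnk_pct = 57.3, gnk_pct = 19.4, snk_pct = 40.4, snk_pct = 15.5,
    tnk_pct = 45.7, tnk_pct = 14.3,
    met_min_wk = 4451.3, met_min_wk = 2299.4,
    kcal_wk = 4948.8, kcal_wk = 2520.0,
    body_fat_pct = 8.4, body_fat_pct = 2.2,
    bone_mass_kg = 8.7, bone_mass_kg = 0.8,
    muscle_mass_kg = 30.5, muscle_mass_kg = 2.0,
    bmi = 21.3, bmi = 2.2)
  nm <- g("M", "non_elite",
    age_y = 37.2, age_y = 14.6, op_years = 11.6, op_years = 7.6,
    otf_days_wk = 3.6, otf_days_wk = 2.1, otq_h_wk = 5.5, otq_h_wk = 5.2,
    mass_kg = 71.5, mass_kg = 14.2, stature_cm = 174.0, stature_cm = 8.8,
    sitting_height_cm = 122.0, sitting_height_cm = 13.6,
    arm_span_cm = 183.2, arm_span_cm = 27.0,
    sf_pectoral_mm = 10.9, sf_pectoral_mm = 9.0,
    sf_triceps_mm = 9.2, sf_triceps_mm = 4.4,
    sf_subscapular_mm = 12.1, sf_subscapular_mm = 8.2,
    sf_biceps_mm = 3.9, sf_biceps_mm = 1.6,
    sf_suprailiac_mm = 15.0, sf_suprailiac_mm = 8.7,
    sf_supraspinale_mm = 9.9, sf_supraspinale_mm = 7.8,
    sf_abdominal_mm = 16.8, sf_abdominal_mm = 9.7,
    sf_front_thigh_mm = 10.6, sf_front_thigh_mm = 5.8,
    sf_calf_mm = 5.7, sf_calf_mm = 2.5,
    g_neck_cm = 37.2, g_neck_cm = 3.0,
    g_relaxed_arm_cm = 28.8, g_relaxed_arm_cm = 3.3,
    g_flexed_arm_cm = 30.1, g_flexed_arm_cm = 3.1,
    g_chest_cm = 96.4, g_chest_cm = 8.5,
    g_waist_cm = 84.2, g_waist_cm = 12.1,
    g_hip_cm = 95.7, g_hip_cm = 8.2,
    g_mid_thigh_cm = 51.1, g_mid_thigh_cm = 3.8,
    g_calf_cm = 37.4, g_calf_cm = 2.8,
    g_ankle_cm = 22.6, g_ankle_cm = 1.8,
    endo = 2.9, endo = 1.8, meso = 4.5, meso = 1.4, ecto = 2.4, ecto = 1.7,
    gnk_pct = 49.2, gnk_pct = 13.3, snk_pct = 26.7, snk_pct = 15.8,
    tnk_pct = 33.8, tnk_pct = 13.8,
    met_min_wk = 3727.7, met_min_wk = 3014.7,
    kcal_wk = 4281.1, kcal_wk = 2815.8,
    body_fat_pct = 11.3, body_fat_pct = 4.8,
    bone_mass_kg = 8.6, bone_mass_kg = 1.3,
    muscle_mass_kg = 30.4, muscle_mass_kg = 3.4,
    bmi = 23.6, bmi = 4.1)
  ef <- g("F", "elite",
    age_y = 25.5, age_y = 6.4, op_years = 11.3, op_years = 5.3,
    otf_days_wk = 4.9, otf_days_wk = 1.6, otq_h_wk = 7.7, otq_h_wk = 4.3,
    mass_kg = 59.5, mass_kg = 7.7, stature_cm = 168.1, stature_cm = 6.5,
    sitting_height_cm = 100.5, sitting_height_cm = 20.2,
    arm_span_cm = 168.2, arm_span_cm = 5.8,
    sf_pectoral_mm = 8.7, sf_pectoral_mm = 4.4,
    sf_triceps_mm = 15.2, sf_triceps_mm = 5.2,
    sf_subscapular_mm = 9.2, sf_subscapular_mm = 2.7,
    sf_biceps_mm = 5.3, sf_biceps_mm = 2.3,
    sf_suprailiac_mm = 15.7, sf_suprailiac_mm = 7.3,
    sf_supraspinale_mm = 8.1, sf_supraspinale_mm = 3.4,
    sf_abdominal_mm = 13.0, sf_abdominal_mm = 6.0,
    sf_front_thigh_mm = 23.5, sf_front_thigh_mm = 8.5,
    sf_calf_mm = 13.4, sf_calf_mm = 6.7,
    g_neck_cm = 30.6, g_neck_cm = 1.6,
    g_relaxed_arm_cm = 25.8, g_relaxed_arm_cm = 1.9,
    g_flexed_arm_cm = 26.7, g_flexed_arm_cm = 1.4,
    g_chest_cm = 85.5, g_chest_cm = 4.4,
    g_waist_cm = 67.2, g_waist_cm = 4.5,
    g_hip_cm = 93.4, g_hip_cm = 10.5,
    g_mid_thigh_cm = 50.3, g_mid_thigh_cm = 3.2,
    g_calf_cm = 35.5, g_calf_cm = 2.7,
    g_ankle_cm = 21.8, g_ankle_cm = 2.5,
    endo = 3.3, endo = 1.1, meso = 3.5, meso = 0.9, ecto = 3.0, ecto = 1.0,
    gnk_pct = 63.6, gnk_pct = 19.6, snk_pct = 47.5, snk_pct = 14.0,
    tnk_pct = 52.6, tnk_pct = 13.4,
    met_min_wk = 4249.5, met_min_wk = 2346.8,
    kcal_wk = 4242.3, kcal_wk = 1900.7,
    body_fat_pct = 17.6, body_fat_pct = 6.2,
    bone_mass_kg = 7.3, bone_mass_kg = 1.1,
    muscle_mass_kg = 22.1, muscle_mass_kg = 1.9,
    bmi = 21.0, bmi = 1.9)
  nf <- g("F", "non_elite",
    age_y = 41.7, age_y = 10.3, op_years = 11.3, op_years = 9.6,
    otf_days_wk = 3.0, otf_days_wk = 2.2, otq_h_wk = 4.2, otq_h_wk = 3.3,
    mass_kg = 60.6, mass_kg = 8.5, stature_cm = 161.3, stature_cm = 11.7,
    sitting_height_cm = 114.0, sitting_height_cm = 20.3,
    arm_span_cm = 163.6, arm_span_cm = 7.6,
    sf_pectoral_mm = 7.9, sf_pectoral_mm = 5.7,
    sf_triceps_mm = 15.8, sf_triceps_mm = 4.9,
    sf_subscapular_mm = 11.5, sf_subscapular_mm = 5.0,
    sf_biceps_mm = 5.6, sf_biceps_mm = 2.4,
    sf_suprailiac_mm = 15.4, sf_suprailiac_mm = 5.2,
    sf_supraspinale_mm = 9.6, sf_supraspinale_mm = 4.0,
    sf_abdominal_mm = 16.3, sf_abdominal_mm = 6.2,
    sf_front_thigh_mm = 21.5, sf_front_thigh_mm = 7.3,
    sf_calf_mm = 11.5, sf_calf_mm = 4.6,
    g_neck_cm = 31.6, g_neck_cm = 2.0,
    g_relaxed_arm_cm = 27.0, g_relaxed_arm_cm = 2.8,
    g_flexed_arm_cm = 27.3, g_flexed_arm_cm = 2.1,
    g_chest_cm = 88.6, g_chest_cm = 6.4,
    g_waist_cm = 74.0, g_waist_cm = 7.4,
    g_hip_cm = 96.0, g_hip_cm = 7.1,
    g_mid_thigh_cm = 49.2, g_mid_thigh_cm = 3.5,
    g_calf_cm = 36.0, g_calf_cm = 2.0,
    g_ankle_cm = 21.5, g_ankle_cm = 1.1,
    endo = 3.9, endo = 1.2, meso = 4.7, meso = 1.6, ecto = 1.9, ecto = 1.2,
    gnk_pct = 54.5, gnk_pct = 12.1, snk_pct = 35.4, snk_pct = 15.7,
    tnk_pct = 41.4, tnk_pct = 13.1,
    met_min_wk = 3941.2, met_min_wk = 2487.7,
    kcal_wk = 4100.2, kcal_wk = 2486.1,
    body_fat_pct = 17.9, body_fat_pct = 3.9,
    bone_mass_kg = 7.2, bone_mass_kg = 1.0,
    muscle_mass_kg = 21.7, muscle_mass_kg = 2.3,
    bmi = 23.4, bmi = 3.7)
  dplyr::bind_rows(em, nm, ef, nf)
}

#' Published group sizes
#'
#' @return A tibble with `sex`, `ranking`, `n` for the four study groups
#'   (13/17 males, 10/18 females; total 58).
#' @export
table1_group_sizes <- function() {
  tibble::tibble(
    sex = c("M", "M", "F", "F"),
    ranking = c("elite", "non_elite", "elite", "non_elite"),
    n = c(13L, 17L, 10L, 18L)
  )
}

table1_value <- function(tab, variable, sex, ranking) {
  tab$mean[tab$variable == variable & tab$sex == sex & tab$ranking == ranking]
}
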