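# Shared fixtures, all generated in code.

# the four published group-mean somatotypes (endo, meso, ecto)
soma_means <- function() {
  tibble::tribble(
    ~sex, ~ranking, ~endo, ~meso, ~ecto,
    "M", "elite", 2.1, 4.4, 3.3,
    "M", "non_elite", 2.9, 4.5, 2.4,
    "F", "elite", 3.3, 3.5, 3.0,
    "F", "non_elite", 3.9, 4.7, 1.9
  )
}

# default specs with every group shrunk/grown to n
specs_with_n <- function(n) {
  lapply(table1_default_specs(), function(s) {
    s$n <- as.integer(n)
    s
  })
}

# small full cohort joined into one table
tiny_cohort <- function(n = 8, seed = 42) {
  suppressMessages(read_cohort(generate_cohort(specs_with_n(n), seed = seed)))
}

# one-row anthro tibble with the elite-male group means (schema columns)
elite_male_profile <- function() {
  tibble::tibble(
    id = "EM001", sex = "M", ranking = "elite",
    age_y = 24.3, op_years = 12.1, otf_days_wk = 6.1, otq_h_wk = 8.8,
    mass_kg = 65.0, stature_cm = 175.1, sitting_height_cm = 103.0,
    arm_span_cm = 176.1,
    sf_pectoral_mm = 6.4, sf_triceps_mm = 7.0, sf_subscapular_mm = 8.4,
    sf_biceps_mm = 3.3, sf_suprailiac_mm = 11.0, sf_supraspinale_mm = 7.0,
    sf_abdominal_mm = 10.1, sf_front_thigh_mm = 9.2, sf_calf_mm = 5.9,
    g_neck_cm = 35.1, g_relaxed_arm_cm = 27.3, g_flexed_arm_cm = 29.1,
    g_chest_cm = 90.3, g_waist_cm = 74.2, g_hip_cm = 91.2,
    g_mid_thigh_cm = 51.0, g_calf_cm = 37.2, g_ankle_cm = 22.2,
    b_humerus_cm = 7.0, b_bistyloid_cm = 5.5, b_femur_cm = 9.5,
    b_bimalleolar_cm = 7.2
  )
}

# unbalanced 2x2 fixture with known effects for ANOVA oracles
unbalanced_fixture <- function(seed = 11) {
  withr::with_seed(seed, {
    grid <- expand.grid(sex = c("M", "F"), ranking = c("elite", "non_elite"),
                        stringsAsFactors = FALSE)
    ns <- c(7, 12, 9, 15)
    d <- do.call(rbind, lapply(seq_len(4), function(i) {
      data.frame(sex = grid$sex[i], ranking = grid$ranking[i],
                 y = rnorm(ns[i], mean = 10 + 2 * (grid$sex[i] == "M") +
                             1.5 * (grid$ranking[i] == "elite") +
                             1 * (grid$sex[i] == "M") * (grid$ranking[i] == "elite"),
                           sd = 2))
    }))
    tibble::as_tibble(d)
  })
}

# brute-force Type-III SS: RSS(model without the effect's columns) - RSS(full),
# under sum-to-zero contrasts
oracle_type3_ss <- function(y, fa, fb) {
  fa <- factor(fa); fb <- factor(fb)
  X <- stats::model.matrix(~ A * B, data.frame(A = fa, B = fb),
                           contrasts.arg = list(A = "contr.sum", B = "contr.sum"))
  asg <- attr(X, "assign")  # 0 intercept, 1 A, 2 B, 3 A:B
  rss <- function(cols) {
    fit <- stats::lm.fit(X[, cols, drop = FALSE], y)
    sum(fit$residuals^2)
  }
  full <- rss(seq_len(ncol(X)))
  ss <- vapply(1:3, function(k) rss(which(asg != k)) - full, numeric(1))
  list(ss = ss, ss_err = full, df_err = length(y) - ncol(X))
}
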