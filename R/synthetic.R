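# Seeded synthetic athlete cohorts.
#
# Real athlete anthropometry is rarely depositable, so every pipeline stage
# is exercised on generated cohorts with the statistical structure the
# analysis assumes: four groups (elite/non-elite x male/female), raw
# measurements driven by three correlated latent factors (frame size,
# adiposity, muscularity), questionnaire items as per-item Bernoulli draws,
# and activity diaries calibrated so group MET-min/week means match the
# configured targets. Only raw inputs are generated — BMI, somatotype, MET
# scores etc. are always derived downstream, so tests exercise the real
# arithmetic rather than a circular shortcut.

# factor loadings per generated variable; 0 = independent residual only
kin_loadings <- function() {
  c(
    mass_kg = 0.80, stature_cm = 0.85, sitting_height_cm = 0.60,
    arm_span_cm = 0.85,
    b_humerus_cm = 0.70, b_bistyloid_cm = 0.70, b_femur_cm = 0.70,
    b_bimalleolar_cm = 0.70,
    sf_pectoral_mm = 0.80, sf_triceps_mm = 0.80, sf_subscapular_mm = 0.80,
    sf_biceps_mm = 0.80, sf_suprailiac_mm = 0.80, sf_supraspinale_mm = 0.80,
    sf_abdominal_mm = 0.80, sf_front_thigh_mm = 0.80, sf_calf_mm = 0.80,
    g_waist_cm = 0.50, g_hip_cm = 0.50,
    g_neck_cm = 0.60, g_relaxed_arm_cm = 0.60, g_flexed_arm_cm = 0.60,
    g_chest_cm = 0.60, g_mid_thigh_cm = 0.60, g_calf_cm = 0.60,
    g_ankle_cm = 0.60
  )
}

kin_factor_of <- function() {
  c(
    mass_kg = "frame", stature_cm = "frame", sitting_height_cm = "frame",
    arm_span_cm = "frame",
    b_humerus_cm = "frame", b_bistyloid_cm = "frame", b_femur_cm = "frame",
    b_bimalleolar_cm = "frame",
    sf_pectoral_mm = "adiposity", sf_triceps_mm = "adiposity",
    sf_subscapular_mm = "adiposity", sf_biceps_mm = "adiposity",
    sf_suprailiac_mm = "adiposity", sf_supraspinale_mm = "adiposity",
    sf_abdominal_mm = "adiposity", sf_front_thigh_mm = "adiposity",
    sf_calf_mm = "adiposity",
    g_waist_cm = "adiposity", g_hip_cm = "adiposity",
    g_neck_cm = "muscularity", g_relaxed_arm_cm = "muscularity",
    g_flexed_arm_cm = "muscularity", g_chest_cm = "muscularity",
    g_mid_thigh_cm = "muscularity", g_calf_cm = "muscularity",
    g_ankle_cm = "muscularity"
  )
}

# generation bounds (resampling truncation)
kin_bounds <- function(variable) {
  if (grepl("^sf_", variable)) return(c(1, 80))
  switch(variable,
    stature_cm = c(100, 230), mass_kg = c(35, 150),
    sitting_height_cm = c(60, 145), arm_span_cm = c(120, 235),
    age_y = c(16, 80), op_years = c(0.2, 60),
    otf_days_wk = c(0, 7), otq_h_wk = c(0.25, 45),
    vig_days = c(0, 7), mod_days = c(0, 7), walk_days = c(0, 7),
    vig_min = c(0, 400), mod_min = c(0, 400), walk_min = c(0, 400),
    sit_min = c(0, 960),
    b_humerus_cm = c(4, 12), b_bistyloid_cm = c(3, 9),
    b_femur_cm = c(6, 14), b_bimalleolar_cm = c(4, 11),
    c(1, 300)  # remaining girths: broad positive range
  )
}

#' Specify one synthetic group
#'
#' A group specification holds everything needed to generate raw records
#' for one sex x ranking cell: sample size, mean and SD for every raw input
#' variable, per-item correct-answer probabilities for the two
#' nutrition-knowledge subsections, and the latent correlation knobs
#' linking frame size to adiposity and muscularity.
#'
#' @param sex `"M"` or `"F"`.
#' @param ranking `"elite"` or `"non_elite"`.
#' @param n Number of athletes (>= 1).
#' @param vars Named list or data frame mapping each raw variable to
#'   `c(mean, sd)`; SDs must be >= 0.
#' @param gnk_prob,snk_prob Per-item probability of a correct answer in the
#'   general (items 1-11) and sports (items 12-35) subsections.
#' @param size_adiposity_rho,size_muscularity_rho Correlations between the
#'   frame-size latent and the adiposity / muscularity latents.
#' @return An object of class `group_spec`.
#' @export
group_spec <- function(sex, ranking, n, vars, gnk_prob, snk_prob,
                       size_adiposity_rho = 0.3, size_muscularity_rho = 0.4) {
  check_sex(sex)
  stopifnot(ranking %in% c("elite", "non_elite"), n >= 1)
  if (is.data.frame(vars)) {
    vt <- tibble::as_tibble(vars)
  } else {
    vt <- tibble::tibble(
      variable = names(vars),
      mean = vapply(vars, `[`, numeric(1), 1),
      sd = vapply(vars, `[`, numeric(1), 2)
    )
  }
  if (any(vt$sd < 0)) abort("Variable SDs must be >= 0.")
  if (gnk_prob < 0 || gnk_prob > 1 || snk_prob < 0 || snk_prob > 1) {
    abort("Item probabilities must be in [0, 1].")
  }
  if (abs(size_adiposity_rho) + abs(size_muscularity_rho) >= 1.4) {
    abort("Latent correlations too large for a valid correlation matrix.")
  }
  structure(list(
    sex = sex, ranking = ranking, n = as.integer(n), vars = vt,
    gnk_prob = gnk_prob, snk_prob = snk_prob,
    size_adiposity_rho = size_adiposity_rho,
    size_muscularity_rho = size_muscularity_rho
  ), class = "group_spec")
}

#' Default group specifications from the published cohort table
#'
#' Four `group_spec`s parameterised by the published descriptive table of
#' the orienteering cohort: the printed group sizes (13/17 elite/non-elite
#' males, 10/18 females) and every printed raw-variable mean and SD.
#' Derived variables (BMI, %BF, somatotype, MET totals) are never generator
#' inputs. Two kinds of parameters are not printed and get documented
#' defaults: bone breadths (sex-specific plausible means, SD 0.3-0.5 cm)
#' and the activity-diary day/minute structure — day-count means are fixed
#' at 3.5 / 3.5 / 5.0 d/wk (vigorous/moderate/walking) and the minutes/day
#' means are solved per group so the implied MET-min/week mean equals the
#' printed group mean. GNK/SNK item probabilities are the printed subsection
#' percentages divided by 100.
#'
#' @return A list of four `group_spec` objects.
#' @export
table1_default_specs <- function() {
  tab <- table1_group_means()
  sizes <- table1_group_sizes()
  gen_vars <- c("age_y", "op_years", "otf_days_wk", "otq_h_wk", "mass_kg",
                "stature_cm", "sitting_height_cm", "arm_span_cm",
                grep("^sf_|^g_", unique(tab$variable), value = TRUE))
  breadths <- list(
    M = list(b_humerus_cm = c(7.0, 0.4), b_bistyloid_cm = c(5.5, 0.3),
             b_femur_cm = c(9.5, 0.5), b_bimalleolar_cm = c(7.2, 0.4)),
    F = list(b_humerus_cm = c(6.3, 0.4), b_bistyloid_cm = c(5.0, 0.3),
             b_femur_cm = c(8.8, 0.5), b_bimalleolar_cm = c(6.6, 0.4))
  )
  day_means <- c(vig_days = 3.5, mod_days = 3.5, walk_days = 5.0)
  met_weight <- 8.0 * day_means[["vig_days"]] + 4.0 * day_means[["mod_days"]] +
    3.3 * day_means[["walk_days"]]
  purrr::pmap(sizes, function(sex, ranking, n) {
    sub <- tab[tab$sex == sex & tab$ranking == ranking, ]
    vars <- setNames(
      lapply(gen_vars, function(v) c(sub$mean[sub$variable == v],
                                     sub$sd[sub$variable == v])),
      gen_vars
    )
    vars <- c(vars, breadths[[sex]])
    met_target <- sub$mean[sub$variable == "met_min_wk"]
    min_mean <- met_target / met_weight
    vars <- c(vars, list(
      vig_days = c(day_means[["vig_days"]], 1.5),
      mod_days = c(day_means[["mod_days"]], 1.5),
      walk_days = c(day_means[["walk_days"]], 1.5),
      vig_min = c(min_mean, 0.35 * min_mean),
      mod_min = c(min_mean, 0.35 * min_mean),
      walk_min = c(min_mean, 0.35 * min_mean),
      sit_min = c(420, 120)
    ))
    group_spec(
      sex = sex, ranking = ranking, n = n, vars = vars,
      gnk_prob = sub$mean[sub$variable == "gnk_pct"] / 100,
      snk_prob = sub$mean[sub$variable == "snk_pct"] / 100
    )
  })
}

# mean of a normal(mu, sd) truncated to [a, b]
trunc_norm_mean <- function(mu, sd, a, b) {
  al <- (a - mu) / sd
  be <- (b - mu) / sd
  z <- pnorm(be) - pnorm(al)
  mu + sd * (stats::dnorm(al) - stats::dnorm(be)) / z
}

# underlying mu such that the truncated mean equals `target`
solve_trunc_mu <- function(target, sd, a, b) {
  if (sd == 0) return(target)
  f <- function(mu) trunc_norm_mean(mu, sd, a, b) - target
  lo <- target - 4 * sd; hi <- target + 4 * sd
  if (f(lo) > 0 || f(hi) < 0) return(target)  # target not attainable; use as-is
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

# One variable for n athletes. The loading-weighted latent plus an
# independent residual gives a standard-normal score per athlete; mapping
# it through the inverse CDF of the location-adjusted truncated normal
# gives a draw whose marginal is exactly that truncated normal (the same
# distribution resampling-to-bounds would give, never a clipped one) with
# mean exactly `target_mean`, while athletes keep their latent ranks.
draw_variable <- function(n, target_mean, sd, bounds, loading, latent) {
  if (sd == 0) return(rep(target_mean, n))
  mu <- solve_trunc_mu(target_mean, sd, bounds[1], bounds[2])
  z <- loading * latent + sqrt(1 - loading^2) * rnorm(n)
  pa <- pnorm(bounds[1], mu, sd)
  pb <- pnorm(bounds[2], mu, sd)
  qnorm(pa + pnorm(z) * (pb - pa), mu, sd)
}

#' Generate a synthetic athlete cohort
#'
#' Draws one record set per group specification: anthropometrics from the
#' three-factor latent model (frame size, adiposity, muscularity with the
#' configured inter-factor correlations; each variable is mean + sd times a
#' loading-weighted latent plus an independent residual, truncated to its
#' generation bounds by resampling with a mean-preserving location
#' adjustment), questionnaire items as independent Bernoulli draws at the
#' group probabilities, and activity diaries from truncated normals. The
#' same (specs, seed) pair regenerates the cohort exactly; the caller's RNG
#' state is untouched.
#'
#' @param specs List of [group_spec()] objects (default
#'   [table1_default_specs()]).
#' @param seed Integer seed.
#' @param answer_key A-NSKQ key used to encode correct answers (default
#'   [default_answer_key()]).
#' @return An object of class `synthetic_cohort`: a list with tibbles
#'   `anthro`, `anskq`, `ipaq` (the three cohort CSV schemas) and a
#'   `provenance` list (`seed`, `spec_hash`).
#' @export
generate_cohort <- function(specs = table1_default_specs(),
                            seed = KIN_DEFAULT_SEED,
                            answer_key = default_answer_key()) {
  stopifnot(length(specs) >= 1, all(vapply(specs, inherits, TRUE, "group_spec")))
  with_preserved_seed(seed, {
    parts <- lapply(seq_along(specs), function(gi) generate_group(specs[[gi]], gi, answer_key))
    cohort <- list(
      anthro = dplyr::bind_rows(lapply(parts, `[[`, "anthro")),
      anskq = dplyr::bind_rows(lapply(parts, `[[`, "anskq")),
      ipaq = dplyr::bind_rows(lapply(parts, `[[`, "ipaq")),
      provenance = list(seed = as.integer(seed), spec_hash = rlang::hash(specs))
    )
    structure(cohort, class = "synthetic_cohort")
  })
}

generate_group <- function(spec, group_index, answer_key) {
  n <- spec$n
  sigma <- matrix(c(
    1, spec$size_adiposity_rho, spec$size_muscularity_rho,
    spec$size_adiposity_rho, 1, 0,
    spec$size_muscularity_rho, 0, 1
  ), 3, 3, dimnames = list(NULL, c("frame", "adiposity", "muscularity")))
  latents <- matrix(rnorm(n * 3), n, 3) %*% chol(sigma)
  colnames(latents) <- c("frame", "adiposity", "muscularity")

  loadings <- kin_loadings()
  factor_of <- kin_factor_of()
  vt <- spec$vars
  draws <- setNames(vector("list", nrow(vt)), vt$variable)
  for (i in seq_len(nrow(vt))) {
    v <- vt$variable[i]
    lam <- loadings[v] %|na|% 0
    lat <- if (lam > 0) latents[, factor_of[[v]]] else rep(0, n)
    draws[[v]] <- draw_variable(n, vt$mean[i], vt$sd[i], kin_bounds(v), lam, lat)
  }
  for (v in c("vig_days", "mod_days", "walk_days")) {
    if (!is.null(draws[[v]])) draws[[v]] <- round(draws[[v]])
  }

  id <- sprintf("%s%s%03d", ifelse(spec$ranking == "elite", "E", "N"),
                spec$sex, seq_len(n))
  anthro <- tibble::as_tibble(c(
    list(id = id, sex = rep(spec$sex, n), ranking = rep(spec$ranking, n)),
    draws[intersect(cohort_cols("anthro"), names(draws))]
  ))[, cohort_cols("anthro")]

  options <- c("a", "b", "c", "d")
  probs <- c(rep(spec$gnk_prob, length(ANSKQ_GNK_ITEMS)),
             rep(spec$snk_prob, length(ANSKQ_SNK_ITEMS)))
  items <- lapply(seq_len(ANSKQ_N_ITEMS), function(j) {
    correct <- rbinom(n, 1, probs[j]) == 1
    wrong <- sample(setdiff(options, answer_key[j]), n, replace = TRUE)
    ifelse(correct, answer_key[j], wrong)
  })
  anskq <- tibble::as_tibble(c(list(id = id), setNames(items, anskq_item_cols())))

  ipaq <- tibble::tibble(
    id = id,
    vig_days = draws$vig_days, vig_min = draws$vig_min,
    mod_days = draws$mod_days, mod_min = draws$mod_min,
    walk_days = draws$walk_days, walk_min = draws$walk_min,
    sit_min = draws$sit_min
  )
  list(anthro = anthro, anskq = anskq, ipaq = ipaq)
}

`%|na|%` <- function(x, y) if (length(x) == 0 || is.na(x)) y else unname(x)

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d athletes (seed %d, spec hash %s)\n",
              nrow(x$anthro), x$provenance$seed, x$provenance$spec_hash))
  print(dplyr::count(x$anthro, .data$sex, .data$ranking))
  invisible(x)
}

#' Write a cohort to CSV files
#'
#' Emits the three cohort CSVs (`anthro.csv`, `anskq.csv`, `ipaq.csv`) in
#' the exact schemas read back by [read_cohort()].
#'
#' @param cohort A `synthetic_cohort` (or any list with `anthro`, `anskq`,
#'   `ipaq` tibbles).
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(anthro = file.path(dir, "anthro.csv"),
             anskq = file.path(dir, "anskq.csv"),
             ipaq = file.path(dir, "ipaq.csv"))
  readr::write_csv(cohort$anthro, paths["anthro"])
  readr::write_csv(cohort$anskq, paths["anskq"])
  readr::write_csv(cohort$ipaq, paths["ipaq"])
  invisible(paths)
}
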