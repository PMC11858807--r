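test_that("normality gate accepts normal and rejects exponential samples", {
  withr::with_seed(21, {
    x_norm <- rnorm(5000)
    x_exp <- rexp(5000)
  })
  r1 <- ks_normality(x_norm, n_sim = 200)
  expect_equal(r1$decision, "normal")
  r2 <- ks_normality(x_exp, n_sim = 200)
  expect_equal(r2$decision, "non_normal")
  expect_lt(r2$p_value, 0.01)
  expect_equal(ks_normality(rep(3, 10))$decision, "non_normal")
  expect_error(ks_normality(1:3), "at least 4")
})

test_that("the KS statistic agrees with the reference Lilliefors implementation", {
  withr::with_seed(4, x <- rgamma(80, 2))
  ours <- ks_normality(x, n_sim = 100)
  ref <- nortest::lillie.test(x)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
})

test_that("normality test restores the caller's RNG state", {
  withr::with_seed(99, {
    x <- rnorm(50)
    before <- .Random.seed
    ks_normality(x)
    expect_identical(.Random.seed, before)
  })
})

test_that("Type-III ANOVA is null on flat data and exact on additive data", {
  d <- tidyr::expand_grid(sex = c("M", "F"), ranking = c("elite", "non_elite"),
                          rep = 1:5)
  d$y <- 10
  d$y <- d$y + rep(c(0.001, -0.001), length.out = nrow(d))  # tie-free jitter
  fit <- anova_two_way_type3(d, y)
  expect_true(all(fit$effects$eta_sq_p < 0.05))
  # exact additivity: interaction SS is zero
  d2 <- tidyr::expand_grid(sex = c("M", "F"), ranking = c("elite", "non_elite"),
                           rep = 1:4)
  d2$y <- 10 + 2 * (d2$sex == "M") + 3 * (d2$ranking == "elite") + 0.1 * d2$rep
  fit2 <- anova_two_way_type3(d2, y)
  expect_equal(fit2$effects$ss[fit2$effects$term == "interaction"], 0,
               tolerance = 1e-20)
})

test_that("Type-III sums of squares equal the model-comparison oracle", {
  d <- unbalanced_fixture()
  fit <- anova_two_way_type3(d, y)
  oracle <- oracle_type3_ss(d$y, d$sex, d$ranking)
  expect_equal(fit$effects$ss, oracle$ss, tolerance = 1e-8)
  expect_equal(fit$effects$ss_error[1], oracle$ss_err, tolerance = 1e-8)
  expect_equal(fit$effects$eta_sq_p,
               oracle$ss / (oracle$ss + oracle$ss_err), tolerance = 1e-8)
})

test_that("partial eta-squared on balanced data equals the classical SS ratio", {
  d <- tidyr::expand_grid(sex = c("M", "F"), ranking = c("elite", "non_elite"),
                          rep = 1:10)
  withr::with_seed(13, {
    d$y <- 5 + 1.5 * (d$sex == "M") + 0.8 * (d$ranking == "elite") + rnorm(nrow(d))
  })
  fit <- anova_two_way_type3(d, y)
  # balanced: Type-III SS coincide with the sequential decomposition
  a1 <- anova(lm(y ~ sex * ranking, d))
  expect_equal(fit$effects$ss, a1$`Sum Sq`[1:3], tolerance = 1e-8)
  expect_equal(fit$effects$eta_sq_p,
               a1$`Sum Sq`[1:3] / (a1$`Sum Sq`[1:3] + a1$`Sum Sq`[4]),
               tolerance = 1e-8)
})

test_that("empty cells are reported by name", {
  d <- unbalanced_fixture()
  d <- d[!(d$sex == "F" & d$ranking == "elite"), ]
  expect_error(anova_two_way_type3(d, y), "F:elite")
})

test_that("ART alignment sums to zero within every level of the other effects", {
  d <- tidyr::expand_grid(sex = c("M", "F"), ranking = c("elite", "non_elite"),
                          rep = 1:6)
  withr::with_seed(31, d$y <- rexp(nrow(d)) + 2 * (d$sex == "M"))
  for (eff in c("sex", "ranking", "interaction")) {
    al <- art_align(d$y, d$sex, d$ranking, eff)
    others <- setdiff(c("sex", "ranking"), eff)
    if (eff == "interaction") others <- c("sex", "ranking")
    for (other in others) {
      sums <- as.vector(tapply(al, d[[other]], sum))
      expect_equal(sums, rep(0, length(sums)), tolerance = 1e-9)
    }
  }
})

test_that("ART is quiet under the null and matches parametric decisions under monotone maps", {
  d <- tidyr::expand_grid(sex = c("M", "F"), ranking = c("elite", "non_elite"),
                          rep = 1:10)
  withr::with_seed(77, d$y <- rnorm(nrow(d)))
  fit <- art_anova(d, y)
  expect_true(all(fit$effects$p > 0.05))
  # additive data, exp-transformed: the rank-based sex decision agrees with
  # the parametric decision on the untransformed scale
  d2 <- tidyr::expand_grid(sex = c("M", "F"), ranking = c("elite", "non_elite"),
                           rep = 1:40)
  withr::with_seed(78, {
    d2$y <- 1 + 0.8 * (d2$sex == "M") + 0.5 * (d2$ranking == "elite") +
      rnorm(nrow(d2), sd = 0.6)
  })
  par_p <- tidy(anova_two_way_type3(d2, y))
  d2$y_exp <- exp(d2$y)
  art_p <- tidy(art_anova(d2, y_exp))
  expect_equal(art_p$p[art_p$term == "sex"] <= 0.05,
               par_p$p[par_p$term == "sex"] <= 0.05)
})

test_that("Bonferroni post hoc multiplies and caps the Welch p-values", {
  d <- tibble::tibble(g = rep(c("a", "b", "c"), each = 6),
                      y = rep(c(1, 1, 1), each = 6) + rep(c(0.01, -0.01), 9))
  ph <- posthoc_pairwise_bonferroni(d, y, g)
  expect_equal(ph$p_adj, rep(1, 3))  # identical groups
  withr::with_seed(55, {
    d2 <- tibble::tibble(g = rep(c("a", "b", "c", "d"), each = 8),
                         y = rnorm(32) + rep(c(0, 0.5, 1, 1.5), each = 8))
  })
  ph2 <- posthoc_pairwise_bonferroni(d2, y, g)
  expect_equal(nrow(ph2), 6)
  expect_equal(ph2$p_adj, pmin(1, 6 * ph2$p_raw))
  ph3 <- posthoc_pairwise_bonferroni(d2, y, g, m = 12)
  expect_equal(ph3$p_adj, pmin(1, 12 * ph3$p_raw))
  d3 <- tibble::tibble(g = c("a", "b", "b"), y = 1:3)
  expect_error(posthoc_pairwise_bonferroni(d3, y, g), "at least 2 obs")
})

test_that("Pearson matrix recovers known correlations with consistent labels", {
  withr::with_seed(10, {
    x <- rnorm(200)
    d <- tibble::tibble(x = x, same = x, neg = -x, noise = rnorm(200))
  })
  cm <- tidy(pearson_matrix(d))
  expect_equal(cm$r[cm$var1 == "x" & cm$var2 == "same"], 1)
  expect_equal(cm$r[cm$var1 == "x" & cm$var2 == "neg"], -1)
  expect_equal(cm$label, r_effect_label(cm$r))
  # sampling oracle: bivariate normal with rho = 0.5 at n = 10000
  withr::with_seed(12, {
    z <- rnorm(10000)
    d2 <- tibble::tibble(a = z, b = 0.5 * z + sqrt(0.75) * rnorm(10000))
  })
  cm2 <- tidy(pearson_matrix(d2))
  expect_equal(unname(cm2$r), 0.5, tolerance = 0.04)
  expect_error(pearson_matrix(tibble::tibble(a = rep(1, 10), b = rnorm(10))),
               "Zero variance")
})

test_that("effect-size bands match their published thresholds", {
  expect_equal(effect_size_label(c(0.005, 0.01, 0.059, 0.06, 0.139, 0.14, 0.9)),
               c("below-small", "small", "small", "medium", "medium",
                 "large", "large"))
  expect_error(effect_size_label(1.2), "\\[0, 1\\]")
  expect_equal(r_effect_label(c(0.05, -0.1, 0.3, -0.49, 0.5, -0.9)),
               c("below-small", "small", "medium", "medium", "large", "large"))
  expect_error(r_effect_label(1.5), "\\[-1, 1\\]")
})

test_that("Cochran sample size reproduces the design numbers", {
  expect_equal(cochran_sample_size(2500, 1.96, 0.8, 0.10), 61L)
  expect_equal(cochran_sample_size(Inf, 1.96, 0.5, 0.05), 385L)
  expect_equal(cochran_sample_size(Inf, 1.96, 0.5, 50), 1L)
  expect_error(cochran_sample_size(margin = 0), "margin")
  expect_error(cochran_sample_size(p = 1, margin = 0.1), "'p'")
  # monotone: shrinking the margin and moving p toward 0.5 never shrink n
  margins <- c(0.2, 0.1, 0.05, 0.02)
  ns <- vapply(margins, function(m) cochran_sample_size(Inf, 1.96, 0.5, m),
               integer(1))
  expect_true(all(diff(ns) >= 0))
  ps <- c(0.05, 0.2, 0.35, 0.5)
  ns2 <- vapply(ps, function(p) cochran_sample_size(Inf, 1.96, p, 0.05),
                integer(1))
  expect_true(all(diff(ns2) >= 0))
})

test_that("noncentral-F power matches the design values and is monotone", {
  expect_equal(anova_power(0, 0.05, 4, 58), 0.05, tolerance = 1e-10)
  expect_equal(round(anova_power(0.4, 0.05, 4, 58), 1), 0.7)
  expect_equal(anova_power(0.4, 0.05, 4, 72), 0.80, tolerance = 0.005)
  ns <- seq(20, 200, by = 20)
  pw <- vapply(ns, function(n) anova_power(0.4, 0.05, 4, n), numeric(1))
  expect_true(all(diff(pw) > 0))
  fs <- seq(0.1, 0.8, by = 0.1)
  pw2 <- vapply(fs, function(f) anova_power(f, 0.05, 4, 58), numeric(1))
  expect_true(all(diff(pw2) > 0))
  expect_error(anova_power(0.4, 0.05, 4, 4), "exceed")
})

test_that("compare_groups gates methods, honours overrides, triggers post hoc", {
  d <- tiny_cohort(n = 12, seed = 2)
  d <- suppressWarnings(add_somatotype(add_body_composition(d)))
  cmp <- compare_groups(d, c("mass_kg", "endo", "sf_triceps_mm"))
  eff <- tidy(cmp)
  expect_equal(nrow(eff), 9)  # 3 variables x 3 effects
  expect_true(all(eff$method %in% c("anova_type3", "art_anova")))
  expect_true(all(eff$eta_sq_p >= 0 & eff$eta_sq_p <= 1))
  # post hoc appears exactly for variables with significant interaction
  sig_int <- unique(eff$variable[eff$term == "interaction" & eff$p <= 0.05])
  expect_identical(sort(as.character(names(cmp$posthoc))), sort(sig_int))
  cmp2 <- compare_groups(d, "mass_kg", method_override = c(mass_kg = "art_anova"))
  expect_equal(unique(tidy(cmp2)$method), "art_anova")
  g <- glance(cmp)
  expect_equal(g$n_variables, 3L)
  expect_error(compare_groups(d, "not_a_column"), "not in data")
})
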