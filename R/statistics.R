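# Inference layer for 2 x 2 (sex x ranking) athlete cohorts: normality
# gate, Type-III two-way ANOVA or aligned-rank-transform (ART) ANOVA with
# partial eta-squared, Bonferroni pairwise post hoc, Pearson correlations
# with effect-size labels, and the design-stage sample-size/power
# utilities.

KIN_DEFAULT_SEED <- 20230714L

#' Lilliefors-corrected Kolmogorov-Smirnov normality test
#'
#' KS test of normality with mean and SD estimated from the sample. Because
#' estimating the parameters makes the naive KS p-value anticonservative,
#' the null distribution of the statistic is obtained by seeded Monte-Carlo
#' simulation (Lilliefors correction): `n_sim` standard-normal samples of
#' the same size are drawn, each standardised by its own estimates, and the
#' p-value is the (add-one) proportion of simulated statistics at least as
#' large as the observed one.
#'
#' @param x Numeric sample, n >= 4.
#' @param alpha Decision level (default 0.05).
#' @param n_sim Monte-Carlo replicates (default 400).
#' @param seed Seed for the simulation (default 20230714); the caller's RNG
#'   state is restored afterwards.
#' @return A one-row tibble: `n`, `statistic`, `p_value`, `decision`
#'   (`"normal"` / `"non_normal"`).
#' @export
ks_normality <- function(x, alpha = 0.05, n_sim = 400, seed = KIN_DEFAULT_SEED) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4) abort("ks_normality() needs at least 4 observations.")
  if (sd(x) == 0) {
    return(tibble::tibble(n = n, statistic = Inf, p_value = 0,
                          decision = "non_normal"))
  }
  d_obs <- lillie_stat(x)
  d_null <- with_preserved_seed(seed, {
    vapply(seq_len(n_sim), function(i) lillie_stat(rnorm(n)), numeric(1))
  })
  p <- (1 + sum(d_null >= d_obs)) / (n_sim + 1)
  tibble::tibble(n = n, statistic = d_obs, p_value = p,
                 decision = if (p <= alpha) "non_normal" else "normal")
}

# KS distance of a sample from the normal with sample-estimated parameters.
lillie_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  p <- pnorm(z)
  max(seq_len(n) / n - p, p - (seq_len(n) - 1) / n)
}

with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

check_cells <- function(sex, ranking) {
  tab <- table(sex, ranking)
  if (any(tab < 2)) {
    bad <- which(tab < 2, arr.ind = TRUE)
    abort(sprintf("Cell %s:%s has fewer than 2 observations.",
                  rownames(tab)[bad[1, 1]], colnames(tab)[bad[1, 2]]))
  }
  invisible(tab)
}

effects_tbl <- function(ss, df, ss_err, df_err, terms) {
  ms_err <- ss_err / df_err
  f <- (ss / df) / ms_err
  p <- pf(f, df, df_err, lower.tail = FALSE)
  eta <- ss / (ss + ss_err)
  tibble::tibble(term = terms, df = df, ss = ss, ss_error = ss_err,
                 F = f, p = p, eta_sq_p = eta,
                 label = effect_size_label(eta))
}

# Type-III sums of squares for y ~ A*B under sum-to-zero contrasts,
# via car::Anova on an lm fit.
type3_fit <- function(values, sex, ranking) {
  d <- data.frame(y = values,
                  A = factor(sex), B = factor(ranking))
  fit <- lm(y ~ A * B, data = d,
            contrasts = list(A = "contr.sum", B = "contr.sum"))
  a3 <- car::Anova(fit, type = 3)
  idx <- match(c("A", "B", "A:B"), rownames(a3))
  list(ss = a3[["Sum Sq"]][idx], df = a3[["Df"]][idx],
       ss_err = a3[["Sum Sq"]][rownames(a3) == "Residuals"],
       df_err = a3[["Df"]][rownames(a3) == "Residuals"])
}

#' Two-way Type-III ANOVA with partial eta-squared
#'
#' Fits `values ~ sex * ranking` under sum-to-zero contrasts and reports
#' Type-III (partial) sums of squares per effect — the convention under
#' which Type-III tests are standard, and the one that matters for the
#' unbalanced group sizes typical of athlete cohorts. Partial eta-squared
#' is SS_effect / (SS_effect + SS_error).
#'
#' @param data Data frame.
#' @param values Column (tidy-eval) holding the response.
#' @param sex,ranking Factor columns (tidy-eval); defaults `sex`, `ranking`.
#' @return An object of class `kin_anova`; its `effects` element is a
#'   tibble with `term` (sex, ranking, interaction), `df`, `F`, `p`,
#'   `eta_sq_p`, `label`. Use [tidy()] to extract it.
#' @export
anova_two_way_type3 <- function(data, values, sex = sex, ranking = ranking) {
  y <- dplyr::pull(data, {{ values }})
  fa <- dplyr::pull(data, {{ sex }})
  fb <- dplyr::pull(data, {{ ranking }})
  ok <- complete.cases(y, fa, fb)
  y <- y[ok]; fa <- factor(fa[ok]); fb <- factor(fb[ok])
  check_cells(fa, fb)
  t3 <- type3_fit(y, fa, fb)
  structure(list(
    method = "anova_type3",
    effects = effects_tbl(t3$ss, t3$df, t3$ss_err, t3$df_err,
                          c("sex", "ranking", "interaction")),
    n = length(y)
  ), class = "kin_anova")
}

#' Align a response for one effect of a 2 x 2 factorial (ART step)
#'
#' The alignment step of the aligned rank transform: the response is
#' stripped of every estimated effect except the one of interest, using
#' unweighted cell-mean estimates. For effect A the aligned response is the
#' cell residual plus A's estimated main effect, and analogously for B and
#' the interaction. On balanced data the aligned responses sum to zero
#' within every level of every other effect.
#'
#' @param values Numeric response.
#' @param sex,ranking Factors.
#' @param effect `"sex"`, `"ranking"` or `"interaction"`.
#' @return Numeric vector of aligned responses.
#' @export
art_align <- function(values, sex, ranking,
                      effect = c("sex", "ranking", "interaction")) {
  effect <- match.arg(effect)
  fa <- factor(sex); fb <- factor(ranking)
  cell <- tapply(values, list(fa, fb), mean)
  a_eff <- rowMeans(cell) - mean(cell)
  b_eff <- colMeans(cell) - mean(cell)
  mu_cell <- cell[cbind(as.integer(fa), as.integer(fb))]
  resid <- values - mu_cell
  est <- switch(effect,
    sex = a_eff[as.integer(fa)],
    ranking = b_eff[as.integer(fb)],
    interaction = mu_cell - a_eff[as.integer(fa)] - b_eff[as.integer(fb)] -
      mean(cell)
  )
  resid + est
}

#' Aligned-rank-transform (ART) two-way ANOVA
#'
#' Nonparametric factorial inference for non-normal responses: for each
#' effect (sex, ranking, interaction) the response is aligned for that
#' effect ([art_align()]), mid-ranked, and the full Type-III factorial
#' ANOVA is run on the ranks; only the effect of interest is read from each
#' rank model. Partial eta-squared is computed on the rank-model sums of
#' squares.
#'
#' @inheritParams anova_two_way_type3
#' @return An object of class `kin_anova` with `method = "art_anova"`.
#' @export
art_anova <- function(data, values, sex = sex, ranking = ranking) {
  y <- dplyr::pull(data, {{ values }})
  fa <- dplyr::pull(data, {{ sex }})
  fb <- dplyr::pull(data, {{ ranking }})
  ok <- complete.cases(y, fa, fb)
  y <- y[ok]; fa <- factor(fa[ok]); fb <- factor(fb[ok])
  check_cells(fa, fb)
  terms <- c("sex", "ranking", "interaction")
  rows <- lapply(seq_along(terms), function(i) {
    aligned <- art_align(y, fa, fb, terms[i])
    r <- rank(aligned)  # mid-ranks for ties
    t3 <- type3_fit(r, fa, fb)
    effects_tbl(t3$ss[i], t3$df[i], t3$ss_err, t3$df_err, terms[i])
  })
  structure(list(method = "art_anova", effects = dplyr::bind_rows(rows),
                 n = length(y)), class = "kin_anova")
}

#' @export
print.kin_anova <- function(x, ...) {
  cat(sprintf("%s (n = %d)\n", x$method, x$n))
  print(x$effects)
  invisible(x)
}

#' @rdname anova_two_way_type3
#' @param x A `kin_anova` object.
#' @param ... Unused.
#' @method tidy kin_anova
#' @export
tidy.kin_anova <- function(x, ...) x$effects

#' Welch pairwise t-tests with Bonferroni correction
#'
#' All pairwise comparisons between group levels using unequal-variance
#' (Welch) t-tests; adjusted p is min(1, m * p) with `m` the number of
#' comparisons (by default the number of pairs).
#'
#' @param data Data frame.
#' @param values Response column (tidy-eval).
#' @param group Grouping column (tidy-eval).
#' @param m Number of comparisons for the correction; defaults to the
#'   number of pairs tested.
#' @return A tibble: `group1`, `group2`, `estimate` (mean difference), `t`,
#'   `df`, `p_raw`, `p_adj`.
#' @export
posthoc_pairwise_bonferroni <- function(data, values, group, m = NULL) {
  y <- dplyr::pull(data, {{ values }})
  g <- factor(dplyr::pull(data, {{ group }}))
  ok <- complete.cases(y, g)
  y <- y[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2) abort("Post hoc needs at least 2 groups.")
  if (any(table(g) < 2)) abort("Every group needs at least 2 observations.")
  pairs <- combn(levels(g), 2)
  m <- m %||% ncol(pairs)
  res <- apply(pairs, 2, function(pr) {
    tt <- t.test(y[g == pr[1]], y[g == pr[2]], var.equal = FALSE)
    c(estimate = unname(diff(rev(tt$estimate))), t = unname(tt$statistic),
      df = unname(tt$parameter), p_raw = tt$p.value)
  })
  tibble::tibble(
    group1 = pairs[1, ], group2 = pairs[2, ],
    estimate = res["estimate", ], t = res["t", ], df = res["df", ],
    p_raw = res["p_raw", ], p_adj = pmin(1, m * res["p_raw", ])
  )
}

#' Pearson correlation matrix with effect-size labels
#'
#' Pairwise Pearson correlations over a set of variables on complete cases
#' per pair, with two-sided p-values and the conventional small/medium/
#' large labels at |r| thresholds 0.10 / 0.30 / 0.50.
#'
#' @param data Data frame.
#' @param vars Character vector of numeric column names; default all
#'   numeric columns.
#' @return An object of class `kin_correlation`; [tidy()] returns the pair
#'   table (`var1`, `var2`, `n`, `r`, `p`, `label`).
#' @export
pearson_matrix <- function(data, vars = NULL) {
  vars <- vars %||% names(data)[vapply(data, is.numeric, logical(1))]
  if (length(vars) < 2) abort("pearson_matrix() needs at least 2 variables.")
  pairs <- combn(vars, 2)
  rows <- apply(pairs, 2, function(pr) {
    x <- data[[pr[1]]]; y <- data[[pr[2]]]
    ok <- complete.cases(x, y)
    if (sum(ok) < 3) abort(sprintf("Pair %s/%s has fewer than 3 complete cases.",
                                   pr[1], pr[2]))
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      abort(sprintf("Zero variance in pair %s/%s.", pr[1], pr[2]))
    }
    ct <- cor.test(x[ok], y[ok], method = "pearson")
    c(n = sum(ok), r = unname(ct$estimate), p = ct$p.value)
  })
  tbl <- tibble::tibble(
    var1 = pairs[1, ], var2 = pairs[2, ],
    n = as.integer(rows["n", ]), r = rows["r", ], p = rows["p", ],
    label = r_effect_label(rows["r", ])
  )
  structure(list(pairs = tbl, vars = vars), class = "kin_correlation")
}

#' @export
print.kin_correlation <- function(x, ...) {
  cat(sprintf("Pearson correlations over %d variables\n", length(x$vars)))
  print(x$pairs)
  invisible(x)
}

#' @rdname pearson_matrix
#' @param x A `kin_correlation` object.
#' @param ... Unused.
#' @method tidy kin_correlation
#' @export
tidy.kin_correlation <- function(x, ...) x$pairs

#' Effect-size label for partial eta-squared
#'
#' Bands: below-small < 0.01 <= small < 0.06 <= medium < 0.14 <= large.
#'
#' @param eta_sq_p Partial eta-squared value(s) in \[0, 1\].
#' @return Character vector of labels.
#' @export
#' @examples
#' effect_size_label(c(0.005, 0.01, 0.06, 0.14))
effect_size_label <- function(eta_sq_p) {
  if (any(eta_sq_p < 0 | eta_sq_p > 1, na.rm = TRUE)) {
    abort("Partial eta-squared must be in [0, 1].")
  }
  ifelse(eta_sq_p >= 0.14, "large",
         ifelse(eta_sq_p >= 0.06, "medium",
                ifelse(eta_sq_p >= 0.01, "small", "below-small")))
}

#' Effect-size label for a Pearson correlation
#'
#' |r| thresholds 0.10 / 0.30 / 0.50 for small / medium / large.
#'
#' @param r Correlation coefficient(s) in \[-1, 1\].
#' @return Character vector of labels.
#' @export
r_effect_label <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) abort("r must be in [-1, 1].")
  a <- abs(r)
  ifelse(a >= 0.50, "large",
         ifelse(a >= 0.30, "medium",
                ifelse(a >= 0.10, "small", "below-small")))
}

#' Cochran sample size
#'
#' Required sample size for estimating a proportion: n0 = z^2 p (1-p) /
#' margin^2, optionally with the finite-population correction
#' n = n0 / (1 + (n0 - 1)/N); the result is rounded up.
#'
#' @param population Population size N (may be `Inf`).
#' @param z Standard-normal quantile (1.96 for 95% confidence).
#' @param p Assumed population proportion, in (0, 1).
#' @param margin Absolute error margin, > 0 (e.g. 0.10 for +/-10%).
#' @param fpc Apply the finite-population correction (default: whenever
#'   `population` is finite).
#' @return Required n (integer, ceiling).
#' @export
#' @examples
#' cochran_sample_size(2500, 1.96, 0.8, 0.10)  # 61
cochran_sample_size <- function(population = Inf, z = 1.96, p = 0.5, margin,
                                fpc = is.finite(population)) {
  if (margin <= 0) abort("'margin' must be > 0.")
  if (p <= 0 || p >= 1) abort("'p' must be in (0, 1).")
  n0 <- z^2 * p * (1 - p) / margin^2
  n <- if (fpc) n0 / (1 + (n0 - 1) / population) else n0
  as.integer(max(1, ceiling(n)))
}

#' Power of a one-way omnibus F test
#'
#' Power of the omnibus ANOVA for `groups` groups and `total_n` subjects at
#' effect size f (Cohen), via the noncentral F distribution: lambda =
#' f^2 N, df1 = groups - 1, df2 = N - groups. Exact power is returned;
#' rounding conventions are left to the caller.
#'
#' @param effect_f Cohen's f.
#' @param alpha Significance level.
#' @param groups Number of groups.
#' @param total_n Total sample size N (> groups).
#' @return Power in \[0, 1\].
#' @export
#' @examples
#' anova_power(0.4, 0.05, 4, 58)
anova_power <- function(effect_f, alpha = 0.05, groups, total_n) {
  if (total_n <= groups) abort("'total_n' must exceed 'groups'.")
  df1 <- groups - 1
  df2 <- total_n - groups
  lambda <- effect_f^2 * total_n
  pf(qf(1 - alpha, df1, df2), df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' Compare variables across sex and ranking
#'
#' The per-variable inference pipeline: a Lilliefors-corrected KS normality
#' gate picks Type-III two-way ANOVA (normal) or ART ANOVA (non-normal) for
#' each variable; when the sex-ranking interaction is significant at
#' `alpha`, Bonferroni-corrected Welch pairwise t-tests over the four
#' sex-ranking cells are attached. The gate can be pinned per variable via
#' `method_override` — reproducing a published table can require pinning
#' borderline gates.
#'
#' @param data Data frame with `sex`, `ranking` and the variables.
#' @param vars Character vector of variable (column) names to test.
#' @param alpha Significance level for the gate and the post hoc trigger.
#' @param method_override Named character vector mapping variable names to
#'   `"anova_type3"` or `"art_anova"` to bypass the gate.
#' @param seed Seed for the Monte-Carlo normality p-values.
#' @return An object of class `kin_comparison`: [tidy()] gives one row per
#'   variable x effect (`variable`, `method`, `normality_p`, `term`, `df`,
#'   `F`, `p`, `eta_sq_p`, `label`); `$posthoc` is a named list of pairwise
#'   tables for variables with a significant interaction; [glance()]
#'   summarises.
#' @export
compare_groups <- function(data, vars, alpha = 0.05, method_override = NULL,
                           seed = KIN_DEFAULT_SEED) {
  stopifnot(all(c("sex", "ranking") %in% names(data)))
  missing <- setdiff(vars, names(data))
  if (length(missing)) abort(sprintf("Variable(s) not in data: %s",
                                     paste(missing, collapse = ", ")))
  posthoc <- list()
  rows <- lapply(vars, function(v) {
    y <- data[[v]]
    ksr <- ks_normality(y, alpha = alpha, seed = seed)
    pinned <- if (!is.null(method_override) && v %in% names(method_override)) {
      unname(method_override[[v]])
    }
    method <- pinned %||%
      (if (ksr$decision == "normal") "anova_type3" else "art_anova")
    fit <- if (method == "anova_type3") {
      anova_two_way_type3(data, !!rlang::sym(v))
    } else {
      art_anova(data, !!rlang::sym(v))
    }
    eff <- fit$effects
    int_p <- eff$p[eff$term == "interaction"]
    if (isTRUE(int_p <= alpha)) {
      d2 <- dplyr::mutate(data, .cell = paste(.data$sex, .data$ranking, sep = ":"))
      posthoc[[v]] <<- posthoc_pairwise_bonferroni(d2, !!rlang::sym(v), .data$.cell)
    }
    dplyr::mutate(eff, variable = v, method = method,
                  normality_p = ksr$p_value, .before = 1)
  })
  structure(list(effects = dplyr::bind_rows(rows), posthoc = posthoc,
                 alpha = alpha, n = nrow(data)), class = "kin_comparison")
}

#' @export
print.kin_comparison <- function(x, ...) {
  cat(sprintf("Group comparison over %d variable(s), n = %d\n",
              length(unique(x$effects$variable)), x$n))
  print(x$effects)
  if (length(x$posthoc)) {
    cat("Post hoc (Bonferroni pairwise) for:",
        paste(names(x$posthoc), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname compare_groups
#' @param x A `kin_comparison` object.
#' @param ... Unused.
#' @method tidy kin_comparison
#' @export
tidy.kin_comparison <- function(x, ...) x$effects

#' @rdname compare_groups
#' @method glance kin_comparison
#' @export
glance.kin_comparison <- function(x, ...) {
  eff <- x$effects
  tibble::tibble(
    n = x$n,
    n_variables = length(unique(eff$variable)),
    n_art = length(unique(eff$variable[eff$method == "art_anova"])),
    n_anova = length(unique(eff$variable[eff$method == "anova_type3"])),
    n_significant_effects = sum(eff$p <= x$alpha),
    n_posthoc = length(x$posthoc)
  )
}
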