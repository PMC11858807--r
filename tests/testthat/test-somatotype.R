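test_that("endomorphy matches hand arithmetic with and without height correction", {
  expect_equal(round(endomorphy(7.0, 8.4, 7.0, stature_cm = 175.1), 2), 2.13)
  expect_equal(round(endomorphy(7.0, 8.4, 7.0, height_correct = FALSE), 2), 2.21)
  expect_equal(endomorphy(15.2, 9.2, 8.1, stature_cm = 168.1), 3.37,
               tolerance = 1e-3)
  expect_error(endomorphy(7, 8, 7, stature_cm = -1), "positive")
  expect_error(endomorphy(7, 8, 7), "stature")
})

test_that("mesomorphy matches hand arithmetic and applies the 0.1 floor", {
  expect_equal(mesomorphy(7.0, 9.5, 29.1, 7.0, 37.2, 5.9, 175.1), 4.51,
               tolerance = 1e-3)
  expect_equal(mesomorphy(6.5, 9.0, 27.0, 15.0, 35.0, 12.0, 165.0), 4.11,
               tolerance = 1e-3)
  # tall enough stature drives the linear form negative; score floors at 0.1
  expect_equal(mesomorphy(6.5, 9.0, 27.0, 15.0, 35.0, 12.0, 220.0), 0.1)
})

test_that("ectomorphy applies the HWR piecewise rule with >= on the upper branch", {
  expect_equal(ectomorphy(90, 160), 0.1)  # HWR 35.7, bottom branch
  expect_equal(ectomorphy(65.0, 175.1), 3.30, tolerance = 1e-3)
  expect_equal(ectomorphy(59.5, 168.1), 2.94, tolerance = 1e-3)
  # boundary: mass chosen so HWR is exactly 40.75 -> upper branch 1.249
  stature <- 170
  mass_at <- (stature / 40.75)^3
  expect_equal(ectomorphy(mass_at, stature), 0.732 * 40.75 - 28.58,
               tolerance = 1e-9)
  expect_equal(ectomorphy(mass_at, stature), 1.249, tolerance = 1e-6)
  # just below the boundary the middle branch applies (1.237 at the limit)
  mass_below <- (stature / 40.749)^3
  expect_equal(ectomorphy(mass_below, stature), 0.463 * 40.749 - 17.63,
               tolerance = 1e-6)
})

test_that("somatotype components are always at least 0.1", {
  d <- tiny_cohort(n = 12)
  out <- add_somatotype(d)
  expect_true(all(out$endo >= 0.1))
  expect_true(all(out$meso >= 0.1))
  expect_true(all(out$ecto >= 0.1))
})

test_that("elite-male mean profile rounds to the published endomorphy/ectomorphy", {
  out <- add_somatotype(elite_male_profile())
  expect_equal(round(out$endo, 1), 2.1)
  expect_equal(round(out$ecto, 1), 3.3)
})

test_that("somatochart coordinates are exact and round-trip", {
  expect_equal(somatochart_xy(4, 4, 4), tibble::tibble(x = 0, y = 0))
  expect_equal(somatochart_xy(2.1, 4.4, 3.3), tibble::tibble(x = 1.2, y = 3.4))
  expect_equal(somatochart_xy(3.9, 4.7, 1.9), tibble::tibble(x = -2.0, y = 3.6))
  # (x, y) plus the endo+ecto sum determine the somatotype again
  withr::with_seed(5, {
    endo <- runif(20, 1, 8); meso <- runif(20, 1, 8); ecto <- runif(20, 1, 8)
    xy <- somatochart_xy(endo, meso, ecto)
    s <- endo + ecto
    expect_equal((s - xy$x) / 2, endo)
    expect_equal((s + xy$x) / 2, ecto)
    expect_equal((xy$y + s) / 2, meso)
  })
})

test_that("dispersion and attitudinal distances match the printed-mean oracles", {
  sm <- soma_means()
  xy <- somatochart_xy(sm$endo, sm$meso, sm$ecto)
  f <- which(sm$sex == "F"); m <- which(sm$sex == "M")
  expect_equal(sdd(xy$x[f[1]], xy$y[f[1]], xy$x[f[2]], xy$y[f[2]]), 4.13,
               tolerance = 1e-3)
  expect_equal(sdd(xy$x[m[1]], xy$y[m[1]], xy$x[m[2]], xy$y[m[2]]), 2.96,
               tolerance = 1e-3)
  expect_equal(sad(3.3, 3.5, 3.0, 3.9, 4.7, 1.9), 1.735, tolerance = 1e-3)
  expect_equal(sad(2.1, 4.4, 3.3, 2.9, 4.5, 2.4), 1.208, tolerance = 1e-3)
  expect_equal(sdd(1, 2, 1, 2), 0)
  expect_equal(sad(3, 4, 5, 3, 4, 5), 0)
})

test_that("sdm and sam are plain means of the individual distances", {
  # two points at chart distance 2 and 4 from the origin reference
  expect_equal(sdm(c(0, 0), c(2, 4), 0, 0), 3.0)
  # collinear points at distances 1, 1, 4
  expect_equal(sdm(c(0, 0, 0), c(1, -1, 4), 0, 0), 2.0)
  expect_equal(sdm(c(1, 1), c(2, 2), 1, 2), 0)
  expect_equal(sam(c(3, 3), c(4, 4), c(5, 5), ref = c(3, 4, 5)), 0)
  # symmetric pair about the reference at SAD 1.5 each
  expect_equal(sam(c(2.5, 5.5), c(4, 4), c(5, 5), ref = c(4, 4, 5)), 1.5)
  # brute-force oracle on a random list
  withr::with_seed(9, {
    e <- runif(15, 1, 7); m <- runif(15, 1, 7); c2 <- runif(15, 1, 7)
    ref <- c(mean(e), mean(m), mean(c2))
    brute <- mean(sqrt((e - ref[1])^2 + (m - ref[2])^2 + (c2 - ref[3])^2))
    expect_equal(sam(e, m, c2), brute)
    xy <- somatochart_xy(e, m, c2)
    rxy <- somatochart_xy(ref[1], ref[2], ref[3])
    brute_sdm <- mean(sqrt(3 * (xy$x - rxy$x)^2 + (xy$y - rxy$y)^2))
    expect_equal(sdm(xy$x, xy$y, rxy$x, rxy$y), brute_sdm)
  })
  expect_error(sdm(numeric(0), numeric(0)), "non-empty")
  expect_error(sam(numeric(0), numeric(0), numeric(0)), "non-empty")
})

test_that("sdd and sad satisfy the metric axioms on random triples", {
  withr::with_seed(17, {
    for (i in 1:50) {
      p <- matrix(runif(9, 0.5, 8), 3, 3)  # three somatotypes
      xy <- somatochart_xy(p[, 1], p[, 2], p[, 3])
      dab <- sdd(xy$x[1], xy$y[1], xy$x[2], xy$y[2])
      dba <- sdd(xy$x[2], xy$y[2], xy$x[1], xy$y[1])
      dac <- sdd(xy$x[1], xy$y[1], xy$x[3], xy$y[3])
      dbc <- sdd(xy$x[2], xy$y[2], xy$x[3], xy$y[3])
      expect_equal(dab, dba)
      expect_gte(dac + dbc + 1e-12, dab)
      expect_equal(sdd(xy$x[1], xy$y[1], xy$x[1], xy$y[1]), 0)
      # identity in chart coordinates relates exactly to the X weighting
      expect_equal(dab^2 - (xy$y[1] - xy$y[2])^2, 3 * (xy$x[1] - xy$x[2])^2)
      aab <- sad(p[1, 1], p[1, 2], p[1, 3], p[2, 1], p[2, 2], p[2, 3])
      aba <- sad(p[2, 1], p[2, 2], p[2, 3], p[1, 1], p[1, 2], p[1, 3])
      aac <- sad(p[1, 1], p[1, 2], p[1, 3], p[3, 1], p[3, 2], p[3, 3])
      abc <- sad(p[2, 1], p[2, 2], p[2, 3], p[3, 1], p[3, 2], p[3, 3])
      expect_equal(aab, aba)
      expect_gte(aac + abc + 1e-12, aab)
    }
  })
})

test_that("classification reproduces the four published group labels", {
  sm <- soma_means()
  labels <- classify_somatotype(sm$endo, sm$meso, sm$ecto)
  expect_equal(labels, c("ectomorphic mesomorph", "balanced mesomorph",
                         "central", "endomorphic mesomorph"))
})

test_that("classification covers edge, balanced and tie cases deterministically", {
  expect_equal(classify_somatotype(4, 4, 4), "central")
  expect_equal(classify_somatotype(3.3, 3.5, 3.0), "central")  # precedence
  expect_equal(classify_somatotype(5.0, 5.0, 2.0), "endomorph-mesomorph")
  expect_equal(classify_somatotype(2.0, 5.0, 4.8), "mesomorph-ectomorph")
  expect_equal(classify_somatotype(5.0, 2.0, 4.7), "endomorph-ectomorph")
  expect_equal(classify_somatotype(6.0, 2.0, 2.3), "balanced endomorph")
  expect_equal(classify_somatotype(2.0, 2.2, 6.0), "balanced ectomorph")
  expect_equal(classify_somatotype(5.5, 3.9, 1.5), "mesomorphic endomorph")
  expect_equal(classify_somatotype(1.5, 3.9, 5.5), "mesomorphic ectomorph")
  expect_equal(classify_somatotype(4.0, 1.5, 5.5), "endomorphic ectomorph")
  # exact three-way spread with a tie on top resolves to the edge category
  expect_equal(classify_somatotype(5.0, 3.0, 5.0), "endomorph-ectomorph")
})

test_that("dispersion summary means equal the means of the per-individual lists", {
  d <- add_somatotype(tiny_cohort(n = 10))
  ds <- somatotype_dispersion(d)
  expect_equal(ds$sdm, mean(ds$sdd[[1]]))
  expect_equal(ds$sam, mean(ds$sad[[1]]))
  expect_true(all(ds$sdd[[1]] >= 0) && all(ds$sad[[1]] >= 0))
  # explicit reference overrides the mean somatotype
  ds0 <- somatotype_dispersion(d, ref = c(4, 4, 4))
  expect_equal(ds0$ref_endo, 4)
})

test_that("somatochart export table carries the contract columns", {
  d <- add_somatotype(tiny_cohort(n = 4))
  tab <- somatochart_table(d)
  expect_named(tab, c("id", "endo", "meso", "ecto", "x", "y", "category"))
  expect_equal(tab$x, d$chart_x)
})
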