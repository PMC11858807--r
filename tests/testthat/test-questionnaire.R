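# build an A-NSKQ response tibble with the requested number of correct
# answers per section (remaining items wrong, or NA if unanswered = TRUE)
anskq_fixture <- function(n_gnk, n_snk, unanswered = FALSE,
                          key = default_answer_key()) {
  wrong <- ifelse(key == "a", "b", "a")
  ans <- if (unanswered) rep(NA_character_, 35) else wrong
  if (n_gnk > 0) ans[1:n_gnk] <- key[1:n_gnk]
  if (n_snk > 0) ans[12:(11 + n_snk)] <- key[12:(11 + n_snk)]
  tibble::as_tibble(c(list(id = "x"), stats::setNames(as.list(ans),
                                                      sprintf("q%02d", 1:35))))
}

test_that("A-NSKQ scoring computes section and total percentages", {
  s <- score_anskq(anskq_fixture(11, 24))
  expect_equal(c(s$gnk_pct, s$snk_pct, s$tnk_pct), c(100, 100, 100))
  s <- score_anskq(anskq_fixture(11, 0))
  expect_equal(s$gnk_pct, 100)
  expect_equal(s$snk_pct, 0)
  expect_equal(s$tnk_pct, 31.43, tolerance = 1e-3)
  s <- score_anskq(anskq_fixture(6, 10))
  expect_equal(s$gnk_pct, 54.55, tolerance = 1e-3)
  expect_equal(s$snk_pct, 41.67, tolerance = 1e-3)
  expect_equal(s$tnk_pct, 45.71, tolerance = 1e-3)
})

test_that("unanswered items count as incorrect and item count is enforced", {
  s <- score_anskq(anskq_fixture(3, 5, unanswered = TRUE))
  expect_equal(s$gnk_pct, 100 * 3 / 11)
  expect_equal(s$snk_pct, 100 * 5 / 24)
  expect_error(score_anskq(dplyr::select(anskq_fixture(1, 1), -q35)),
               "35 item")
  expect_error(score_anskq(anskq_fixture(1, 1), key = c("a", "b")), "35")
})

test_that("total score is always the 11/24-weighted section combination", {
  withr::with_seed(3, {
    for (i in 1:20) {
      s <- score_anskq(anskq_fixture(sample(0:11, 1), sample(0:24, 1)))
      expect_equal(s$tnk_pct, (11 * s$gnk_pct + 24 * s$snk_pct) / 35)
    }
  })
})

test_that("knowledge bands partition [0, 100] as half-open intervals", {
  expect_equal(as.character(classify_nk(45.7)), "poor")
  expect_equal(as.character(classify_nk(0)), "poor")
  expect_equal(as.character(classify_nk(100)), "excellent")
  expect_equal(as.character(classify_nk(65.9)), "average")
  expect_equal(as.character(classify_nk(c(49.9, 50, 65.9, 66, 75.9, 76))),
               c("poor", "average", "average", "good", "good", "excellent"))
  # no gaps or overlaps over a fine grid
  grid <- seq(0, 100, by = 0.1)
  expect_false(anyNA(classify_nk(grid)))
  expect_error(classify_nk(101), "0, 100")
})

ipaq_row <- function(vd = 0, vm = 0, md = 0, mm = 0, wd = 0, wm = 0, sit = 300) {
  tibble::tibble(id = "x", vig_days = vd, vig_min = vm, mod_days = md,
                 mod_min = mm, walk_days = wd, walk_min = wm, sit_min = sit)
}

test_that("IPAQ cleaning recodes short sessions and flags 960-min outliers", {
  r <- ipaq_clean(ipaq_row(wd = 5, wm = 9))
  expect_equal(r$walk_min, 0)
  expect_false(r$excluded)
  r <- ipaq_clean(ipaq_row(vd = 3, vm = 400, md = 3, mm = 400, wd = 3, wm = 200))
  expect_true(r$excluded)
  r <- ipaq_clean(ipaq_row())
  expect_equal(unlist(r[c("vig_min", "mod_min", "walk_min")], use.names = FALSE),
               c(0, 0, 0))
  expect_false(r$excluded)
  # 180-min truncation only behind the flag
  r <- ipaq_clean(ipaq_row(vd = 2, vm = 200), truncate_180 = TRUE)
  expect_equal(r$vig_min, 180)
  expect_equal(ipaq_clean(ipaq_row(vd = 2, vm = 200))$vig_min, 200)
  expect_error(ipaq_clean(ipaq_row(vd = 1, vm = -5)), "negative")
})

test_that("IPAQ cleaning is idempotent", {
  withr::with_seed(8, {
    d <- tibble::tibble(
      id = sprintf("a%d", 1:30),
      vig_days = sample(0:7, 30, TRUE), vig_min = runif(30, 0, 500),
      mod_days = sample(0:7, 30, TRUE), mod_min = runif(30, 0, 500),
      walk_days = sample(0:7, 30, TRUE), walk_min = runif(30, 0, 500),
      sit_min = runif(30, 0, 900)
    )
    once <- ipaq_clean(d)
    expect_identical(ipaq_clean(once), once)
  })
})

test_that("MET-minute conversion applies the 3.3/4.0/8.0 weights", {
  s <- ipaq_met_minutes(ipaq_clean(ipaq_row()))
  expect_equal(s$met_total, 0)
  s <- ipaq_met_minutes(ipaq_clean(ipaq_row(vd = 3, vm = 30, wd = 5, wm = 30)))
  expect_equal(s$met_vig, 720)
  expect_equal(s$met_walk, 495)
  expect_equal(s$met_total, 1215)
  s <- ipaq_met_minutes(ipaq_clean(ipaq_row(md = 5, mm = 30)))
  expect_equal(s$met_total, 600)
})

test_that("activity categories follow the official criteria", {
  cat_of <- function(...) {
    as.character(ipaq_category(ipaq_met_minutes(ipaq_clean(ipaq_row(...)))))
  }
  expect_equal(cat_of(vd = 3, vm = 63), "high")        # 1512 MET on 3 vigorous days
  expect_equal(cat_of(md = 5, mm = 30), "moderate")    # 600 MET on 5 days
  expect_equal(cat_of(wd = 2, wm = 15), "low")
  expect_equal(cat_of(vd = 3, vm = 20), "moderate")    # 20-min vigorous rule
  expect_equal(cat_of(vd = 4, vm = 100, md = 3, mm = 60), "high")  # 7 days, 3920 MET
})

test_that("excluded records error unless NA is requested", {
  big <- ipaq_met_minutes(ipaq_clean(ipaq_row(vd = 5, vm = 500, md = 5, mm = 500)))
  expect_error(ipaq_category(big), "outlier")
  expect_true(is.na(ipaq_category(big, na_excluded = TRUE)))
})

test_that("raising activity never lowers the category", {
  base_args <- list(vd = 2, vm = 25, md = 4, mm = 25, wd = 4, wm = 25)
  score_cat <- function(args) {
    ipaq_category(ipaq_met_minutes(ipaq_clean(do.call(ipaq_row, args))))
  }
  base_cat <- score_cat(base_args)
  for (fld in c("vd", "vm", "md", "mm", "wd", "wm")) {
    for (bump in c(1, 5, 40)) {
      args <- base_args
      cap <- if (fld %in% c("vd", "md", "wd")) 7 else 900 / 3
      args[[fld]] <- min(args[[fld]] + bump, cap)
      expect_gte(as.integer(score_cat(args)), as.integer(base_cat))
    }
  }
})

test_that("kcal conversion follows MET-min x kg / 60 and omits missing mass", {
  expect_equal(ipaq_kcal(600, 60), 600)
  expect_equal(ipaq_kcal(4451.3, 65.0), 4822.2, tolerance = 1e-4)
  expect_equal(ipaq_kcal(0, 70), 0)
  expect_true(is.na(ipaq_kcal(1000, NA)))
  expect_error(ipaq_kcal(-1, 60), ">= 0")
})

test_that("score_ipaq assembles the full scored table", {
  d <- dplyr::bind_rows(ipaq_row(vd = 3, vm = 63), ipaq_row(wd = 2, wm = 15))
  d$id <- c("a", "b")
  s <- score_ipaq(d, body_mass = c(65, 60))
  expect_named(s, c("id", "met_walk", "met_mod", "met_vig", "met_total",
                    "kcal_week", "pal_category", "excluded"))
  expect_equal(as.character(s$pal_category), c("high", "low"))
  expect_equal(s$kcal_week[1], 1512 * 65 / 60)
})
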