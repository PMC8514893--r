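test_that("pooled t-test matches hand evaluation and degenerate limits", {
  g1 <- group_summary("experimental", 19.55, 1.72, 30)
  g2 <- group_summary("control", 28.82, 2.16, 30)
  tt <- t_test_from_summary(g1, g2)
  expect_equal(tt$df, 58)
  expect_equal(tt$t, -18.38861, tolerance = 1e-5)
  expect_lt(tt$p_two_sided, 1e-10)
  # identical summaries
  same <- t_test_from_summary(g1, g1)
  expect_equal(same$t, 0)
  expect_equal(same$p_two_sided, 1)
  # zero-variance limits
  a <- group_summary("a", 1, 0, 5); b <- group_summary("b", 2, 0, 5)
  z <- t_test_from_summary(a, b)
  expect_equal(z$p_two_sided, 0)
  expect_equal(t_test_from_summary(a, a)$p_two_sided, 1)
  expect_error(group_summary("x", 1, -1, 5), ">= 0")
  expect_error(group_summary("x", 1, 1, 1), ">= 2")
})

test_that("summary t-test agrees with t.test on moment-matched samples", {
  # oracle: rescale a fixed sample to the exact mean/SD, then run the
  # classical test on the reconstructed data
  make_sample <- function(mean, sd, n, seed) {
    set.seed(seed)
    x <- rnorm(n)
    mean + sd * (x - mean(x)) / sd(x)
  }
  cases <- list(c(5.1, 1.2, 12, 3.9, 2.0, 17), c(0.4, 0.1, 8, 0.6, 0.2, 9),
                c(100, 15, 30, 92, 14, 30))
  for (cs in cases) {
    x <- make_sample(cs[1], cs[2], cs[3], 1)
    y <- make_sample(cs[4], cs[5], cs[6], 2)
    for (variant in c("pooled", "welch")) {
      ours <- t_test_from_summary(
        group_summary("x", cs[1], cs[2], cs[3]),
        group_summary("y", cs[4], cs[5], cs[6]), variant = variant)
      ref <- stats::t.test(x, y, var.equal = variant == "pooled")
      expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-8)
      expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-8)
      expect_equal(ours$p_two_sided, ref$p.value, tolerance = 1e-8)
    }
  }
})

test_that("pooled t with equal n and equal SDs reduces to the textbook form", {
  g1 <- group_summary("a", 10, 2, 20)
  g2 <- group_summary("b", 11.5, 2, 20)
  tt <- t_test_from_summary(g1, g2)
  expect_equal(tt$t, (10 - 11.5) / (2 * sqrt(2 / 20)), tolerance = 1e-12)
})

test_that("rate_percent rounds half away from zero", {
  expect_identical(rate_percent(count_pair(6, 98)), 6L)
  expect_identical(rate_percent(count_pair(9, 95)), 9L)
  expect_identical(rate_percent(count_pair(0, 50)), 0L)
  expect_identical(rate_percent(count_pair(1, 200)), 1L)   # 0.5 -> 1
  expect_identical(rate_percent(count_pair(3, 200)), 2L)   # 1.5 -> 2
  expect_error(count_pair(5, 0), ">= 1")
  expect_error(count_pair(7, 6), "in \\[0, total\\]")
  # complementary rates sum to 100 when the split is exact
  expect_identical(rate_percent(count_pair(25, 100)) +
                     rate_percent(count_pair(75, 100)), 100L)
  s <- rate_percent(count_pair(6, 98)) + rate_percent(count_pair(92, 98))
  expect_true(s %in% 99:101)
})

test_that("2x2 chi-square matches the closed form and chisq.test", {
  flat <- chi_square_2x2(10, 10, 10, 10)
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p, 1)
  g <- chi_square_2x2(24, 6, 22, 8)
  expect_equal(g$chi2, 60 * (24 * 8 - 6 * 22)^2 / (30 * 30 * 46 * 14),
               tolerance = 1e-12)
  # cross-check both variants against stats::chisq.test
  set.seed(8)
  for (i in 1:8) {
    m <- matrix(sample(1:30, 4, replace = TRUE), 2, 2)
    ours_n <- chi_square_2x2(m)
    ours_y <- chi_square_2x2(m, correction = "yates")
    ref_n <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    ref_y <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
    expect_equal(ours_n$chi2, unname(ref_n$statistic), tolerance = 1e-10)
    expect_equal(ours_n$p, ref_n$p.value, tolerance = 1e-10)
    expect_equal(ours_y$chi2, unname(ref_y$statistic), tolerance = 1e-10)
  }
  expect_warning(zres <- chi_square_2x2(0, 0, 5, 5), "marginal")
  expect_equal(zres$p, 1)
})

test_that("chi-square is transpose-invariant and monotone in |ad - bc|", {
  m <- matrix(c(12, 7, 5, 14), 2, 2)
  expect_equal(chi_square_2x2(m)$chi2, chi_square_2x2(t(m))$chi2)
  # fixed margins (19, 19, 17, 21): slide mass along the diagonal
  chis <- vapply(6:12, function(a)
    chi_square_2x2(a, 19 - a, 17 - a, 2 + a)$chi2, numeric(1))
  dets <- vapply(6:12, function(a) abs(a * (2 + a) - (19 - a) * (17 - a)),
                 numeric(1))
  expect_identical(order(chis), order(dets))
})

test_that("chi-square p-value is consistent with a permutation oracle", {
  # condition on the margins: hypergeometric draw of cell a
  a <- 18; b <- 12; c <- 9; d <- 21
  obs <- chi_square_2x2(a, b, c, d)
  set.seed(9)
  n_draw <- 1e5
  a_sim <- stats::rhyper(n_draw, m = a + b, n = c + d, k = a + c)
  chi_sim <- vapply(a_sim, function(ai)
    chi_square_2x2(ai, (a + b) - ai, (a + c) - ai,
                   (c + d) - ((a + c) - ai))$chi2, numeric(1))
  p_mc <- mean(chi_sim >= obs$chi2 - 1e-12)
  # the asymptotic p should sit near the exact conditional tail
  expect_lt(abs(p_mc - obs$p), 0.03)
})

test_that("the packaged clinical report recomputes every comparison", {
  rep <- reproduce_report()
  expect_true(all(c("section", "comparison", "statistic", "p", "claim",
                    "flag") %in% names(rep)))
  expect_equal(nrow(rep), 21 + 6 + 1)
  # key hormone/anxiety/quality-of-life rows are consistent with P < 0.05
  for (lbl in c("acth_t4", "cortisol_t5", "sas_t5",
                "qol_physical_function")) {
    row <- rep[rep$comparison == lbl, ]
    expect_lt(row$p, 0.05)
    expect_identical(row$flag, "consistent")
  }
  # baseline rows are consistent with P > 0.05
  for (lbl in c("age_years", "tumor_size_cm", "male")) {
    expect_identical(rep$flag[rep$comparison == lbl], "consistent")
  }
  # necrosis rates match the printed integers
  nec <- rep[rep$comparison == "focal_necrosis", ]
  expect_identical(nec$rate_exp, 6L)
  expect_identical(nec$rate_ctl, 9L)
  # compliance counts are reported, not forced: flags may be discrepant,
  # but every row must carry a finite recomputed p
  expect_true(all(is.finite(rep$p)))
})

test_that("malformed fixtures raise schema errors naming the problem", {
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(continuous = list()), bad, auto_unbox = TRUE)
  expect_error(reproduce_report(bad), "missing section")
  bad2 <- tempfile(fileext = ".json")
  jsonlite::write_json(
    list(continuous = data.frame(section = "s", label = "x"),
         counts = data.frame(), lesions = list()),
    bad2, auto_unbox = TRUE)
  expect_error(reproduce_report(bad2), "lacks column")
})
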