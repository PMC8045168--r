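test_that("group summaries use the n-1 standard deviation", {
  g <- summarize_group(c(1, 2, 3))
  expect_equal(g$mean, 2)
  expect_equal(g$sd, 1)
  expect_equal(summarize_group(rep(4.2, 10))$sd, 0)
  expect_error(summarize_group(1), "at least 2")
  expect_error(summarize_group(c(1, NA, 3)), "finite")
})

test_that("combining the published sex groups reproduces the printed All rows", {
  # lateral screw length: male 43.26 +/- 4.64, female 35.20 +/- 4.28
  all <- pooled_mean_sd(c(43.26, 4.64, 50), c(35.20, 4.28, 50))
  expect_equal(round(all$mean, 2), 39.23)
  expect_equal(round(all$sd, 2), 6.01)
  # medial screw diameter: male 5.69 +/- 0.81, female 3.73 +/- 0.67
  all2 <- pooled_mean_sd(c(5.69, 0.81, 50), c(3.73, 0.67, 50))
  expect_equal(round(all2$mean, 2), 4.71)
  expect_equal(round(all2$sd, 2), 1.23)
  # two identical groups: SD contracts by sqrt((2n-2)/(2n-1))
  g <- pooled_mean_sd(c(10, 2, 8), c(10, 2, 8))
  expect_equal(g$mean, 10)
  expect_equal(g$sd, 2 * sqrt(14 / 15), tolerance = 1e-12)
})

test_that("summary pooling is exact for any split of raw data", {
  withr::local_seed(31)
  for (k in 1:50) {
    x <- stats::rnorm(sample(10:60, 1), mean = stats::runif(1, -5, 50),
                      sd = stats::runif(1, 0.1, 9))
    cut <- sample(2:(length(x) - 2), 1)
    combined <- pooled_mean_sd(summarize_group(x[1:cut]),
                               summarize_group(x[-(1:cut)]))
    expect_equal(combined$mean, mean(x), tolerance = 1e-12)
    expect_equal(combined$sd, stats::sd(x), tolerance = 1e-12)
  }
})

test_that("pooled t from the printed summaries matches the published t rows", {
  # medial length: printed t = 10.478
  tt <- t_from_summary(c(50.79, 4.33, 50), c(41.87, 4.19, 50))
  expect_equal(tt$t, 10.478, tolerance = 0.01 * 10.478)
  expect_equal(tt$df, 98)
  expect_lt(tt$p, 0.001)
  # equal means give t = 0; hand-checked small case gives t = 1, df = 2
  expect_equal(t_from_summary(c(5, 1, 10), c(5, 2, 12))$t, 0)
  hand <- t_from_summary(c(1, 1, 2), c(0, 1, 2))
  expect_equal(hand$t, 1)
  expect_equal(hand$df, 2)
  # zero-variance edge cases
  expect_equal(t_from_summary(c(3, 0, 5), c(3, 0, 5))$t, 0)
  expect_true(is.infinite(t_from_summary(c(4, 0, 5), c(3, 0, 5))$t))
})

test_that("t_from_data equals the summary route and stats::t.test", {
  withr::local_seed(17)
  for (k in 1:20) {
    x1 <- stats::rnorm(sample(3:30, 1), 2, 1.5)
    x2 <- stats::rnorm(sample(3:30, 1), 2.4, 0.8)
    td <- t_from_data(x1, x2)
    ts <- t_from_summary(summarize_group(x1), summarize_group(x2))
    expect_equal(td$t, ts$t, tolerance = 1e-12)
    ref <- stats::t.test(x1, x2, var.equal = TRUE)
    expect_equal(td$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(td$p, ref$p.value, tolerance = 1e-10)
    refw <- stats::t.test(x1, x2)
    tw <- t_from_data(x1, x2, method = "welch")
    expect_equal(tw$t, unname(refw$statistic), tolerance = 1e-10)
    expect_equal(tw$df, unname(refw$parameter), tolerance = 1e-8)
    # exchangeability within groups
    expect_equal(t_from_data(sample(x1), x2)$t, td$t, tolerance = 1e-12)
  }
})

fake_cohort <- function(n = 12, delta = 0, seed = 5) {
  withr::local_seed(seed)
  sex <- rep(c("M", "F"), each = n / 2)
  eff <- ifelse(sex == "M", delta, 0)
  tibble::tibble(
    subject = sprintf("s%02d", 1:n), sex = sex,
    ms_length = stats::rnorm(n, 45 + 2 * eff, 4),
    ms_diameter = stats::rnorm(n, 4 + eff, 0.7),
    ls_length = stats::rnorm(n, 40 + 2 * eff, 4),
    ls_diameter = stats::rnorm(n, 4.5 + eff, 0.7),
    L1 = stats::rnorm(n, 7, 1.5), L2 = stats::rnorm(n, 6, 1.5),
    L3 = stats::rnorm(n, 17, 2), L4 = stats::rnorm(n, 6, 1.5),
    alpha = stats::rnorm(n, 14, 5), beta = abs(stats::rnorm(n, 7, 5)))
}

test_that("build_tables lays out the three comparison tables", {
  tb <- build_tables(fake_cohort())
  expect_named(tb, c("medial", "lateral", "angles", "raw"))
  expect_equal(tb$medial$Group, c("All", "Male", "Female", "t", "P"))
  expect_equal(names(tb$lateral),
               c("Group", "Length (mm)", "Diameter (mm)", "L3 (mm)",
                 "L4 (mm)"))
  expect_match(tb$medial$`Length (mm)`[1], "^[0-9.]+ ± [0-9.]+$")
  # deterministic: same cohort, same tables
  expect_identical(build_tables(fake_cohort()), tb)
  # raw layer carries full-precision tests
  expect_s3_class(tb$raw$ms_length$test, "t_test_result")
  expect_error(build_tables(fake_cohort()[1:6, ]), "both sexes")
})

test_that("p-value formatting follows the 0.000 convention", {
  expect_equal(acroplan:::format_p(0.0004), "0.000")
  expect_equal(acroplan:::format_p(0.0006), "0.001")
  expect_equal(acroplan:::format_p(0.291), "0.291")
})

test_that("reference checks flag exactly the inconsistent printed cells", {
  rc <- reference_checks()
  cons <- rc[rc$consistent, ]
  expect_true(all(abs(cons$t - cons$printed_t) / abs(cons$printed_t) < 0.01))
  # the flagged cells genuinely fail to reproduce
  l1 <- rc[rc$variable == "L1", ]
  expect_gt(abs(l1$t - l1$printed_t), 1)
  len <- rc[rc$table == "medial" & rc$variable == "length", ]
  expect_gt(abs(len$all_mean - len$printed_all_mean), 1)
})
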