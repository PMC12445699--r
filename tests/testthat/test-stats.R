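test_that("summary statistics and box descriptors are exact", {
  s <- summarize_sample(c(1, 2, 3, 4, 5))
  expect_equal(s$mean, 3)
  expect_equal(s$sd, sqrt(2.5))
  expect_equal(s$box$median, 3)
  s2 <- summarize_sample(c(1, 1, 1))
  expect_equal(s2$sd, 0)
  expect_identical(length(s2$box$outliers), 0L)
  expect_error(summarize_sample(numeric()), "empty")
})

test_that("box stats agree with a naive type-7 quantile implementation", {
  naive_q <- function(x, p) {
    x <- sort(x); n <- length(x)
    h <- (n - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
  }
  set.seed(14)
  for (i in 1:10) {
    x <- stats::rnorm(sample(5:60, 1))
    b <- box_stats(x)
    expect_equal(b$q1, naive_q(x, 0.25))
    expect_equal(b$median, naive_q(x, 0.5))
    expect_equal(b$q3, naive_q(x, 0.75))
    fence <- c(b$q1 - 1.5 * b$iqr, b$q3 + 1.5 * b$iqr)
    expect_true(b$whisker_low >= fence[1] && b$whisker_high <= fence[2])
    expect_setequal(b$outliers, x[x < fence[1] | x > fence[2]])
  }
})

test_that("group comparisons are two-sided and symmetric", {
  x <- c(1, 2, 3, 4, 5, 6)
  t0 <- compare_groups(x, x, "two_tailed_t")
  expect_equal(t0$statistic, 0)
  w0 <- compare_groups(x, x, "wilcoxon_rank_sum")
  expect_gt(w0$p_value, 0.9)
  set.seed(15)
  a <- stats::rnorm(30, 22.9, 2); b <- stats::rnorm(30, 24.5, 2)
  for (m in c("two_tailed_t", "wilcoxon_rank_sum")) {
    pab <- compare_groups(a, b, m)$p_value
    pba <- compare_groups(b, a, m)$p_value
    expect_equal(pab, pba)
  }
  expect_error(compare_groups(1:2, 1:5), "at least 3")
  expect_error(compare_groups(1:5, 1:4, "wilcoxon_signed_rank"),
               "equal group sizes")
})

test_that("the t-test separates 22.9 from 24.5 pN at n = 90", {
  set.seed(16)
  hits <- sum(vapply(1:100, function(i) {
    a <- stats::rnorm(90, 22.9, 2); b <- stats::rnorm(90, 24.5, 2)
    compare_groups(a, b, "two_tailed_t")$p_value < 0.05
  }, logical(1)))
  expect_gte(hits, 95)
})

test_that("paired signed-rank p-value matches exact enumeration", {
  set.seed(19)
  x <- stats::rnorm(10)
  d <- stats::runif(10, 0.5, 1.5)  # distinct positive shifts (no ties)
  r <- compare_groups(x + d, x, "wilcoxon_signed_rank")
  # all differences positive: the most extreme of 2^10 sign patterns,
  # two-sided
  expect_equal(r$p_value, 2 / 2^10, tolerance = 1e-12)
})

test_that("bootstrap CIs are seeded, sane and degenerate-aware", {
  ci <- bootstrap_ci(mean, rep(3, 50))
  expect_identical(as.numeric(ci), c(3, 3))
  expect_true(attr(ci, "degenerate"))
  set.seed(17)
  x <- stats::rbinom(500, 1, 0.6)
  ci2 <- bootstrap_ci(mean, x, B = 2000, seed = 2)
  width <- ci2[2] - ci2[1]
  expect_lt(abs(width - 2 * 1.96 * sqrt(0.6 * 0.4 / 500)) / 0.0859, 0.30)
  ci3 <- bootstrap_ci(mean, x, B = 2000, seed = 2)
  expect_identical(as.numeric(ci2), as.numeric(ci3))
  expect_error(bootstrap_ci(mean, x, B = 50), "at least 200")
})

test_that("bootstrap coverage is near nominal for the mean", {
  set.seed(18)
  cover <- mean(vapply(1:300, function(i) {
    x <- stats::rnorm(150, 10, 2)
    ci <- bootstrap_ci(mean, x, B = 500, seed = i)
    ci[1] <= 10 && 10 <= ci[2]
  }, logical(1)))
  expect_gte(cover, 0.92)
  expect_lte(cover, 0.975)
})

test_that("reports are complete, deterministic and round-trip stable", {
  an <- simulate_and_analyze("h33_tetra", 6, seed = 8)
  rep1 <- build_report(list(h33_tetra = an), seed = 8)
  expect_identical(rep1$schema_version, "1.0")
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_report(rep1, f1)
  write_report(rep1, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_report(f1)
  expect_identical(back$schema_version, "1.0")
  # identical analysis run -> byte-identical report
  an2 <- simulate_and_analyze("h33_tetra", 6, seed = 8)
  f3 <- tempfile(fileext = ".json")
  write_report(build_report(list(h33_tetra = an2), seed = 8), f3)
  expect_identical(readLines(f1), readLines(f3))
  # empty input stays valid with explicit nulls
  rep0 <- build_report(list())
  expect_true(is.null(rep0$comparisons))
  f0 <- tempfile(fileext = ".json")
  write_report(rep0, f0)
  expect_silent(read_report(f0))
})
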