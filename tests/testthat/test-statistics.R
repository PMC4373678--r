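test_that("standard errors of skewness and kurtosis match closed forms", {
  expect_equal(round(ses(86), 4), 0.2597)
  expect_equal(round(sek(86), 4), 0.5139)
  expect_equal(ses(10), sqrt(540 / 1144))
  expect_equal(sek(10), 2 * sqrt(540 / 1144) * sqrt(99 / 105))
  # asymptotics: ses ~ sqrt(6/n)
  expect_equal(ses(1e6) * sqrt(1e6 / 6), 1, tolerance = 1e-4)
  expect_true(all(sek(4:100) > ses(4:100)))
  expect_error(ses(2), "n >= 3")
  expect_error(sek(3), "n >= 4")
})

test_that("describe_distribution reproduces the catalogue moments", {
  cat86 <- table1_dataset()
  s <- describe_distribution(cat86$total)
  expect_equal(s$n, 86L)
  expect_equal(round(s$mean, 1), 4.4)
  expect_equal(round(s$sd, 1), 1.6)
  expect_equal(s$ses, ses(86))
  expect_equal(s$sek, sek(86))
  expect_true(s$p_value >= 0 && s$p_value <= 1)
})

test_that("symmetric samples have zero skewness and K2 = Z2^2", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  s <- describe_distribution(x)
  expect_equal(s$skewness, 0)
  expect_equal(s$z_skew, 0)
  expect_equal(s$k2, s$z_kurt^2)
})

test_that("omnibus K2 agrees with an independent reference to 1e-6", {
  # frozen reference values computed with an independent implementation
  # of the same published transforms (scipy.stats.normaltest) on these
  # exact deterministic samples
  set.seed(4242)
  x <- round(rnorm(100), 6)
  s <- describe_distribution(x)
  expect_equal(s$k2, 1.3988151670, tolerance = 1e-9)
  expect_equal(s$p_value, 0.4968795763, tolerance = 1e-9)
  expect_equal(s$z_skew, 1.0305636451, tolerance = 1e-9)
  expect_equal(s$z_kurt, -0.5803048684, tolerance = 1e-9)

  set.seed(77)
  y <- round(rexp(60), 6)
  sy <- describe_distribution(y)
  expect_equal(sy$k2, 31.0139663473, tolerance = 1e-9)
  expect_equal(sy$p_value, 1.84247997627e-07, tolerance = 1e-6)
})

test_that("moment statistics are invariant under positive affine maps", {
  set.seed(5)
  x <- rnorm(40)
  a <- describe_distribution(x)
  b <- describe_distribution(2.5 * x + 7)
  for (f in c("skewness", "kurtosis", "k2", "p_value"))
    expect_equal(a[[f]], b[[f]])
})

test_that("describe_distribution rejects degenerate input", {
  expect_error(describe_distribution(rep(3, 20)), "constant")
  expect_error(describe_distribution(1:7), "n >= 8")
})

test_that("integer histogram tallies the catalogue totals", {
  cat86 <- table1_dataset()
  h <- score_histogram(cat86$total, 0, 11)
  expect_equal(h$count, c(1L, 3L, 6L, 14L, 17L, 19L, 20L, 6L, 0L, 0L, 0L, 0L))
  expect_equal(sum(h$count), 86L)
  expect_equal(score_histogram(integer(), 0, 11)$count, rep(0L, 12))
  expect_error(score_histogram(c(1, 12), 0, 11), "range")
  expect_error(score_histogram(1.5, 0, 11), "integer")
})

test_that("gaussian fit recovers exact and noisy synthetic histograms", {
  x <- 0:11
  y <- 20 * exp(-(x - 4.7)^2 / (2 * 1.7^2))
  f <- fit_gaussian(y, x)
  expect_equal(f$amplitude, 20, tolerance = 1e-6)
  expect_equal(f$mean, 4.7, tolerance = 1e-6)
  expect_equal(f$sd, 1.7, tolerance = 1e-6)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  expect_equal(f$df, 9L)

  # Poisson noise around a known curve: recovered mean within 3 SE
  set.seed(31)
  yn <- rpois(12, y)
  fn <- fit_gaussian(yn, x)
  expect_lt(abs(fn$mean - 4.7), 3 * fn$se[["mean"]])
  # residual identity
  expect_equal(fn$sy_x, sqrt(fn$ss_res / fn$df))

  expect_error(fit_gaussian(rep(0, 12), x), "all-zero")
  expect_error(fit_gaussian(c(1, 2, 3), 1:3), "4 points")
})

test_that("the catalogue histogram fit reproduces the reference values", {
  cat86 <- table1_dataset()
  h <- score_histogram(cat86$total, 0, 11)
  f <- fit_gaussian(h$count, h$center)
  expect_equal(round(f$amplitude, 2), 20.74)
  expect_equal(round(f$mean, 3), 4.686)
  expect_equal(round(f$sd, 3), 1.682)
  expect_equal(f$df, 9L)
  expect_equal(round(f$r_squared, 4), 0.9355)
  expect_equal(round(f$ss_res, 1), 45.9)
  expect_equal(round(f$sy_x, 3), 2.258)
  expect_equal(round(unname(f$se), c(3, 2, 4)), c(1.602, 0.15, 0.1501))
  expect_equal(f$ci95["mu", ], c(lower = 4.347, upper = 5.025),
               tolerance = 5e-4)
  expect_equal(f$ci95["sigma", ], c(lower = 1.342, upper = 2.021),
               tolerance = 5e-4)
})

test_that("spearman rho matches brute-force ranking on all small inputs", {
  r <- spearman_test(1:6, c(2, 4, 6, 8, 10, 12))
  expect_equal(r$rho, 1)
  expect_equal(r$p_value, 0)
  expect_equal(spearman_test(1:6, 6:1)$rho, -1)

  # hand-ranked tie case
  x <- c(1, 2, 2, 3); y <- c(2, 1, 3, 4)
  expect_equal(spearman_test(x, y)$rho, brute_spearman(x, y))

  # exhaustive: every pair of 4-vectors over {1,2,3} with rank variance
  vals <- as.matrix(expand.grid(rep(list(1:3), 4)))
  vals <- vals[apply(vals, 1, function(v) length(unique(v)) > 1), ]
  set.seed(8)
  idx <- cbind(sample(nrow(vals), 400, TRUE), sample(nrow(vals), 400, TRUE))
  for (k in seq_len(nrow(idx))) {
    x <- vals[idx[k, 1], ]; y <- vals[idx[k, 2], ]
    expect_equal(spearman_test(x, y)$rho, brute_spearman(x, y))
  }

  expect_error(spearman_test(1:3, 1:4), "length")
  expect_error(spearman_test(c(1, 1, 1), 1:3), "variance")
})

test_that("spearman p-values: t approximation and exact permutation", {
  set.seed(21)
  x <- rnorm(30); y <- x + rnorm(30)
  r <- spearman_test(x, y)
  # cross-check rho against the stock implementation
  expect_equal(r$rho, unname(cor(x, y, method = "spearman")))
  tstat <- r$rho * sqrt(28 / (1 - r$rho^2))
  expect_equal(r$p_value, 2 * pt(-abs(tstat), 28))

  # exact enumeration on a small sample is close to the t approximation
  xs <- c(3, 1, 4, 1, 5, 9)
  ys <- c(2, 7, 1, 8, 2, 8)
  ex <- spearman_test(xs, ys, exact = TRUE)
  expect_equal(ex$method, "exact permutation")
  expect_true(ex$p_value >= 0 && ex$p_value <= 1)
  # a perfect small correlation has the minimal attainable exact p
  expect_equal(spearman_test(1:5, 2:6, exact = TRUE)$p_value, 2 / factorial(5))
  expect_error(spearman_test(rnorm(9), rnorm(9), exact = TRUE), "n <= 8")
})
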