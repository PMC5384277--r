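test_that("paired t test matches hand computation and the base oracle", {
  expect_equal(paired_t(1:5, 1:5), list(t = 0, p = 1, df = 4,
                                        mean_diff = 0,
                                        degenerate = TRUE))
  r <- paired_t(c(1, 2, 3), c(2, 3, 5))
  expect_equal(r$t, 4)
  expect_equal(r$p, 0.05719096, tolerance = 1e-6)
  set.seed(9)
  x <- rnorm(20); y <- rnorm(20, 0.3)
  ref <- stats::t.test(y, x, paired = TRUE)
  mine <- paired_t(x, y)
  expect_equal(mine$t, unname(ref$statistic))
  expect_equal(mine$p, ref$p.value)
  expect_error(paired_t(1:3, 1:4), "unequal")
})

test_that("paired t test holds its nominal type-I error rate", {
  set.seed(2)
  rej <- mean(replicate(1000, paired_t(rnorm(30), rnorm(30))$p < 0.05))
  expect_gte(rej, 0.04)
  expect_lte(rej, 0.06)
})

test_that("step-down correction: basics, bounds and order invariance", {
  expect_equal(holm_correct(0.03), 0.03)
  expect_equal(holm_correct(numeric(0)), numeric(0))
  expect_error(holm_correct(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(4)
  for (k in 1:5) {
    p <- runif(sample(3:12, 1))
    h <- holm_correct(p)
    expect_equal(h, stats::p.adjust(p, "holm"))  # independent oracle
    expect_true(all(h >= p - 1e-15))
    expect_true(all(h <= pmin(1, length(p) * p) + 1e-15))
    o <- sample(length(p))
    expect_equal(holm_correct(p[o]), h[o])       # order invariance
  }
})

test_that("step-down correction reproduces the reference table of nine", {
  raw <- c(0.677, 0.009, 0.053, 0.006, 0.003, 0.000, 0.822, 0.006, 0.005)
  printed <- c(1.000, 0.036, 0.159, 0.036, 0.024, 0.000, 1.000, 0.036,
               0.036)
  got <- holm_correct(raw)
  expect_equal(got[2], 0.036)   # raw 0.009
  expect_equal(got[3], 0.159)   # raw 0.053
  expect_equal(got[7], 1.000)   # raw 0.822, capped after monotonicity
  # eight of nine cells agree exactly; the raw-0.005 cell differs by
  # 0.001 (0.035 vs 0.036), attributable to rounding of the raw inputs
  expect_true(all(abs(got - printed) <= 0.001 + 1e-12))
  expect_equal(sum(abs(got - printed) < 1e-12), 8)
})

test_that("Pearson correlation: exact lines, oracle match, MC recovery", {
  x <- c(1, 2, 4, 7)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
  set.seed(5)
  a <- rnorm(25); b <- rnorm(25)
  ref <- stats::cor.test(a, b)
  mine <- pearson_r(a, b)
  expect_equal(mine$r, unname(ref$estimate))
  expect_equal(mine$p, ref$p.value)
  set.seed(3)
  rho <- 0.79
  rh <- replicate(2000, {
    x <- rnorm(30); y <- rho * x + sqrt(1 - rho^2) * rnorm(30)
    pearson_r(x, y)$r
  })
  expect_equal(mean(rh), rho, tolerance = 0.03 / rho)
})

test_that("Dahlberg method error: formula cases and scale equivariance", {
  expect_equal(dahlberg_me(c(3, 4), c(3, 4)), 0)
  expect_equal(dahlberg_me(5, 3), sqrt(2))
  expect_equal(dahlberg_me(c(1, 0), c(0, 1)), sqrt(2 / 4))
  set.seed(6)
  a <- rnorm(40); b <- rnorm(40)
  expect_equal(dahlberg_me(3.5 * a, 3.5 * b), 3.5 * dahlberg_me(a, b))
  expect_error(dahlberg_me(1:3, 1:4), "unequal")
})

test_that("ICC(3,1): perfect agreement, variance components, null", {
  m <- cbind(1:10, 1:10)
  expect_equal(icc_consistency(m), 1)
  set.seed(1)
  n <- 2000
  obj <- rnorm(n, 0, 10)
  r <- cbind(obj + rnorm(n), obj + rnorm(n))
  expect_equal(icc_consistency(r), 100 / 101, tolerance = 0.01)
  r0 <- cbind(rnorm(n), rnorm(n))
  expect_lt(abs(icc_consistency(r0)), 0.05)
  expect_error(icc_consistency(cbind(rep(1, 5), rep(1, 5))), "degenerate")
})

test_that("cohort-level paired tests and correlations assemble correctly", {
  set.seed(8)
  n <- 24
  tab <- data.frame(case = 1:n, ice = rtrunc <- abs(rnorm(n, 6.8, 1.7)))
  tab$V_or_t1 <- rnorm(n, 20, 3)
  tab$V_or_t2 <- tab$V_or_t1 - 0.9 * tab$ice + rnorm(n, 0, 0.5)
  tab$dP_max_t1 <- rnorm(n, 33, 5)
  tab$dP_max_t2 <- tab$dP_max_t1 + 3 * tab$ice + rnorm(n, 0, 2)
  tests <- cohort_paired_tests(tab)
  expect_setequal(tests$variable, c("V_or", "dP_max"))
  expect_true(all(tests$p_corrected >= tests$p))
  expect_true(tests$significant[tests$variable == "dP_max"])
  cors <- cohort_correlations(tab, dp_vars = "dP_max",
                              covar_vars = "V_or")
  expect_equal(nrow(cors), 2)
  r_ice <- cors$r[cors$covariate == "ice"]
  expect_gt(r_ice, 0.5)  # built-in positive coupling with retraction
})
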