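test_that("cohort sampling edge cases and determinism", {
  expect_identical(sample_cohort(cohort_params(), 0), list())
  expect_error(sample_cohort(cohort_params(), -1), "n must be")
  c1 <- sample_cohort(cohort_params(), 5, seed = 7)
  c2 <- sample_cohort(cohort_params(), 5, seed = 7)
  expect_identical(c1, c2)
  c3 <- sample_cohort(cohort_params(), 5, seed = 8)
  expect_false(identical(c1, c3))
})

test_that("retraction mapping narrows monotonically with ice", {
  pre <- reference_pre_spec()
  ices <- seq(0, 12, by = 1.5)
  posts <- lapply(ices, function(i) apply_retraction(pre, i,
                                                     noise = FALSE))
  a_min <- vapply(posts, function(p) p$a_min, numeric(1))
  v_or <- vapply(posts, function(p) p$regions[[2]]$volume, numeric(1))
  v_hy <- vapply(posts, function(p) p$regions[[3]]$volume, numeric(1))
  expect_true(all(diff(a_min) <= 1e-12))
  expect_true(all(diff(v_or) <= 1e-12))
  expect_true(all(diff(v_hy) <= 1e-12))
  # zero retraction leaves volumes and a_min unchanged
  p0 <- posts[[1]]
  expect_equal(p0$a_min, pre$a_min)
  expect_equal(p0$regions[[2]]$volume, pre$regions[[2]]$volume)
})

test_that("cohort marginals recover configured means at n = 10000", {
  p <- cohort_params()
  cs <- sample_cohort(p, 10000, seed = 123)
  get <- function(f) vapply(cs, f, numeric(1))
  v_or <- get(function(c) c$pre$regions[[2]]$volume)
  v_hy <- get(function(c) c$pre$regions[[3]]$volume)
  a_min <- get(function(c) c$pre$a_min)
  ice <- get(function(c) c$ice)
  v_na_pre <- get(function(c) c$pre$regions[[1]]$volume)
  v_na_post <- get(function(c) c$post$regions[[1]]$volume)
  n <- length(cs)
  within3se <- function(x, mu, sd0) abs(mean(x) - mu) < 3 * sd0 / sqrt(n)
  expect_true(within3se(v_or, p$mean[["v_or"]], p$sd[["v_or"]]))
  expect_true(within3se(v_hy, p$mean[["v_hy"]], p$sd[["v_hy"]]))
  expect_true(within3se(a_min, p$mean[["a_min"]], p$sd[["a_min"]]))
  expect_true(within3se(ice, p$mean[["ice"]], p$sd[["ice"]]))
  # nasopharynx unchanged in expectation
  d <- v_na_post - v_na_pre
  expect_lt(abs(mean(d)), 3 * stats::sd(d) / sqrt(n))
  # positivity from truncation
  expect_true(all(a_min > 0) && all(v_or > 0) && all(ice >= 0))
})

test_that("double-measurement emulation reproduces the configured ME", {
  p <- cohort_params()
  tab <- data.frame(case = 1:4000,
                    dP_max_t1 = rep(30, 4000),
                    A_min_t1 = rep(2.2, 4000),
                    ice = rep(6.8, 4000))
  set.seed(11)
  m <- measure_cohort(tab, p)
  s <- m$sessions
  me_hat <- function(v) {
    d <- s[s$variable == v, ]
    dahlberg_me(d$session1, d$session2)
  }
  expect_equal(me_hat("dP_max_t1"), p$me_pressure, tolerance = 0.05)
  expect_equal(me_hat("ice"), p$me_ice, tolerance = 0.05)
  # averages stay unbiased
  expect_equal(mean(m$averaged$dP_max_t1), 30, tolerance = 0.01)
})
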