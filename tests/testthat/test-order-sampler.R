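test_that("elementary split/merge step satisfies detailed balance", {
  # empirical visit frequencies of a long chain match the enumerated
  # single-series posterior
  set.seed(7)
  y <- matrix(c(0.2, 0.1, -1.2, -0.9, -1.0), 1L)
  k <- ou_kernel(y, ou_hyper())
  orders <- enumerate_orders(5L)
  keys <- vapply(orders, format_order, character(1L))
  lm <- vapply(orders, function(o) k$series_lm(1L, as.integer(o)),
               numeric(1L))
  post <- exp(lm - max(lm))
  post <- post / sum(post)
  names(post) <- keys
  visits <- stats::setNames(numeric(length(keys)), keys)
  ord <- make_order(5L)
  for (it in 1:30000) {
    ord <- single_order_step(k, 1L, ord, q = 0.5)
    key <- format_order(ord)
    visits[key] <- visits[key] + 1
  }
  emp <- visits / sum(visits)
  expect_lt(0.5 * sum(abs(emp - post[names(emp)])), 0.02)
})

test_that("flat likelihood makes the elementary chain uniform over orders", {
  set.seed(31)
  flat <- list(type = "flat", n = 1L, T = 4L, additive = FALSE,
               series_lm = function(i, sizes) 0)
  keys <- vapply(enumerate_orders(4L), format_order, character(1L))
  visits <- stats::setNames(numeric(length(keys)), keys)
  ord <- make_order(4L)
  for (it in 1:16000) {
    ord <- single_order_step(flat, 1L, ord, q = 0.5)
    key <- format_order(ord)
    visits[key] <- visits[key] + 1
  }
  expect_gt(stats::chisq.test(visits)$p.value, 1e-4)
})

test_that("T = 1 orders admit no moves", {
  k <- ou_kernel(matrix(0.5, 1L, 1L), ou_hyper())
  expect_equal(as.integer(single_order_step(k, 1L, make_order(1L))), 1L)
  expect_equal(as.integer(sample_order_posterior(k, 1L, L = 3L)), 1L)
})

test_that("sweep draws converge to the single-series posterior", {
  set.seed(17)
  y <- matrix(c(1.1, 0.9, 1.2, -1.0, -1.2, -0.8), 1L)
  k <- ou_kernel(y, ou_hyper())
  orders <- enumerate_orders(6L)
  keys <- vapply(orders, format_order, character(1L))
  lm <- vapply(orders, function(o) k$series_lm(1L, as.integer(o)),
               numeric(1L))
  post <- exp(lm - max(lm))
  post <- post / sum(post)
  draws <- replicate(4000, format_order(sample_order_posterior(k, 1L,
                                                               L = 25L)))
  emp <- as.numeric(table(factor(draws, levels = keys))) / length(draws)
  expect_lt(0.5 * sum(abs(emp - post)), 0.04)
  # modal draw carries the true change point (strong two-regime signal)
  expect_equal(names(which.max(table(draws))), "3,3")
})

test_that("sample_order_posterior is reproducible from the seed", {
  dat <- ts_scenario_dataset(1L)
  k <- ou_kernel(dat$y, ou_hyper())
  set.seed(5)
  o1 <- sample_order_posterior(k, 3L, L = 5L)
  set.seed(5)
  o2 <- sample_order_posterior(k, 3L, L = 5L)
  expect_identical(as.integer(o1), as.integer(o2))
})

test_that("uniform-IS normalizer is exact for a constant kernel", {
  flat <- list(type = "flat", n = 1L, T = 6L, additive = FALSE,
               series_lm = function(i, sizes) -3.25)
  set.seed(1)
  for (B in c(1L, 7L, 50L)) {
    expect_equal(estimate_log_normalizer(flat, 1L, B), -3.25,
                 tolerance = 1e-12)
  }
})

test_that("uniform-IS normalizer converges to the enumerated value", {
  set.seed(23)
  y <- matrix(stats::rnorm(6L, sd = 0.6), 1L)
  k <- ou_kernel(y, ou_hyper())
  truth <- enumerated_normalizers(k)[1L]
  # natural-scale unbiasedness: mean of exp over replicates within 3 sigma
  reps <- replicate(200, exp(estimate_log_normalizer(k, 1L, 200L)))
  se <- stats::sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - exp(truth)), 3 * se)
  # variance shrinks roughly like 1/B
  v <- vapply(c(100L, 1000L), function(B) {
    stats::var(replicate(60, exp(estimate_log_normalizer(k, 1L, B))))
  }, numeric(1L))
  expect_gt(v[1L] / v[2L], 3)
})

test_that("calibrated normalizer matches enumeration at small T", {
  set.seed(29)
  for (T in c(5L, 8L)) {
    y <- matrix(cumsum(stats::rnorm(T, sd = 0.5)), 1L)
    k <- ou_kernel(y, ou_hyper())
    truth <- enumerated_normalizers(k)[1L]
    est <- replicate(10, normalizer_table(k, draws = 30L, depth = 10L)[1L])
    expect_lt(abs(mean(est) - truth), 0.5)
  }
})

test_that("log_psi with exact normalizers is a proper mixture density", {
  set.seed(37)
  y <- rbind(stats::rnorm(5L), stats::rnorm(5L))
  k <- ou_kernel(y, ou_hyper())
  nt <- enumerated_normalizers(k)
  lp <- vapply(enumerate_orders(5L), function(o) log_psi(k, o, nt),
               numeric(1L))
  expect_equal(sum(exp(lp)), 1, tolerance = 1e-10)
  # n = 1 reduces to the single-series posterior
  k1 <- ou_kernel(y[1L, , drop = FALSE], ou_hyper())
  nt1 <- enumerated_normalizers(k1)
  o <- make_order(c(2L, 3L))
  expect_equal(log_psi(k1, o, nt1),
               k1$series_lm(1L, as.integer(o)) - 4 * log(2) - nt1[[1L]])
  # permuting the series leaves the mixture unchanged
  k_swap <- ou_kernel(y[c(2L, 1L), ], ou_hyper())
  nt_swap <- enumerated_normalizers(k_swap)
  expect_equal(log_psi(k, o, nt), log_psi(k_swap, o, nt_swap),
               tolerance = 1e-10)
})

test_that("sample_psi draws match the psi density (small T)", {
  set.seed(41)
  y <- rbind(c(0.5, 0.6, -0.4, -0.5), c(-0.2, 0.3, 0.1, 0.0))
  k <- ou_kernel(y, ou_hyper())
  nt <- enumerated_normalizers(k)
  keys <- vapply(enumerate_orders(4L), format_order, character(1L))
  lp <- vapply(enumerate_orders(4L), function(o) log_psi(k, o, nt),
               numeric(1L))
  draws <- replicate(8000, format_order(sample_psi(k, L = 15L)))
  emp <- as.numeric(table(factor(draws, levels = keys))) / length(draws)
  expect_lt(0.5 * sum(abs(emp - exp(lp))), 0.03)
})
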