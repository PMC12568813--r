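test_that("SIR integration honors the analytic decoupled solution", {
  cfg <- epi_config(xi = 0.2, grid_step = 0.25)
  tr <- integrate_sir(rep(0, 30L), cfg, I0 = 0.01)
  expect_equal(tr$S, rep(1, nrow(tr)), tolerance = 1e-12)
  # Runge-Kutta error accumulates relatively over the 30-day horizon
  expect_equal(tr$I, 0.01 * exp(-0.2 * tr$time), tolerance = 1e-5)
})

test_that("constant-beta trajectories satisfy the SIR first integral", {
  cfg <- epi_config(xi = 1 / 8, grid_step = 0.05)
  beta <- 0.3
  tr <- integrate_sir(rep(beta, 80L), cfg, I0 = 0.001)
  # S(t) = exp(-(beta/xi) R(t)) along the trajectory
  expect_lt(max(abs(tr$S - exp(-(beta / cfg$xi) * tr$R))), 1e-6)
  # conservation to integrator tolerance, S non-increasing, R non-decreasing
  expect_lt(max(abs(tr$S + tr$I + tr$R - (1 + 0.001))), 1e-8)
  expect_true(all(diff(tr$S) <= 1e-12))
  expect_true(all(diff(tr$R) >= -1e-12))
})

test_that("integrate_sir rejects bad inputs", {
  cfg <- epi_config()
  expect_error(integrate_sir(c(0.1, NA), cfg, 0.01), "finite")
  expect_error(integrate_sir(rep(0.1, 5L), cfg, 1.5), "I0")
  expect_error(epi_config(grid_step = 0.3), "divide")
})

test_that("DSA pmf is proper and refines to the continuous density", {
  cfg <- epi_config(xi = 1 / 8, grid_step = 0.5)
  beta <- rep(c(0.3, 0.1), each = 30L)
  lp <- dsa_log_pmf(beta, cfg, I0 = 0.002)
  expect_equal(sum(exp(lp)), 1, tolerance = 1e-12)
  # trapezoid integral of beta S I / (1 - S(T)) approaches 1 as the grid
  # refines
  for (h in c(0.5, 0.1)) {
    cfg_h <- epi_config(xi = 1 / 8, grid_step = h)
    tr <- integrate_sir(beta, cfg_h, 0.002)
    bgrid <- beta[pmin(floor(tr$time) + 1L, length(beta))]
    f <- bgrid * tr$S * tr$I / (1 - tr$S[nrow(tr)])
    integ <- sum((f[-1L] + f[-length(f)]) / 2 * diff(tr$time))
    expect_equal(integ, 1, tolerance = 5 * h)
  }
  # degenerate epidemic: beta = 0 means no infections
  expect_error(dsa_log_pmf(rep(0, 10L), cfg, 0.001), "degenerate")
})

test_that("doubling I0 shifts the infection-time pmf mode earlier", {
  cfg <- epi_config(xi = 1 / 8, grid_step = 0.5)
  beta <- rep(0.3, 100L)
  m1 <- which.max(dsa_log_pmf(beta, cfg, 0.001))
  m2 <- which.max(dsa_log_pmf(beta, cfg, 0.002))
  expect_lt(m2, m1)
})

test_that("epi marginal with one draw is the plug-in likelihood", {
  set.seed(83)
  counts <- matrix(c(5L, 12L, 8L, 3L), 1L)
  cfg <- epi_config(mc_draws = 1L, grid_step = 1)
  k <- epi_kernel(counts, cfg, I0 = 0.002, seed = 99L)
  # reproduce the single draw by hand from the kernel's CRN stream
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(99L)
  u <- matrix(stats::runif(4L), 1L)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  b <- stats::qgamma(u[1L, 1L], 4, rate = 10)  # one block -> start-day column
  lp <- dsa_log_pmf(rep(b, 4L), cfg, 0.002)
  expect_equal(k$series_lm(1L, 4L), sum(counts[1L, ] * lp),
               tolerance = 1e-10)
})

test_that("epi marginal is deterministic given the CRN seed and cached", {
  set.seed(5)
  counts <- matrix(rpois(20L, 30), 2L)
  cfg <- epi_config(mc_draws = 50L, grid_step = 1)
  k1 <- epi_kernel(counts, cfg, I0 = 0.002, seed = 11L)
  k2 <- epi_kernel(counts, cfg, I0 = 0.002, seed = 11L)
  o <- c(4L, 6L)
  set.seed(1); v1 <- k1$series_lm(1L, o)
  set.seed(2); v2 <- k2$series_lm(1L, o)
  expect_identical(v1, v2)
  expect_identical(v1, k1$series_lm(1L, o))  # cache hit
})

test_that("Monte-Carlo marginal is consistent across MC sizes", {
  set.seed(7)
  counts <- matrix(rpois(30L, 40), 1L)
  est <- vapply(1:8, function(s) {
    cfg <- epi_config(mc_draws = 10000L, grid_step = 1)
    k <- epi_kernel(counts, cfg, I0 = 0.002, seed = 1000L + s)
    k$series_lm(1L, c(10L, 20L))
  }, numeric(1L))
  cfg_big <- epi_config(mc_draws = 100000L, grid_step = 1)
  kb <- epi_kernel(counts, cfg_big, I0 = 0.002, seed = 77L)
  big <- kb$series_lm(1L, c(10L, 20L))
  se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - big), 3 * se + 0.05)
})

test_that("true two-block orders beat the no-change order on average", {
  set.seed(29)
  cfg <- epi_config(mc_draws = 300L, grid_step = 1)
  wins <- 0L
  for (r in 1:10) {
    sched <- rep(c(0.25, 0.1), each = 30L)
    counts <- gillespie_sir(50000L, 50L, sched, 1 / 8, 60L)
    counts <- subsample_infections(counts, 0.2)
    k <- epi_kernel(matrix(counts, 1L), cfg, I0 = 0.001, seed = 400L + r)
    if (k$series_lm(1L, c(30L, 30L)) > k$series_lm(1L, 60L)) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})

test_that("I0 Metropolis chain recovers the truth within a factor of 3", {
  set.seed(31)
  sched <- rep(c(0.3, 0.1), each = 40L)
  counts <- gillespie_sir(100000L, 100L, sched, 1 / 8, 80L)  # I0 = 0.001
  counts <- subsample_infections(counts, 0.2)
  cfg <- epi_config(mc_draws = 100L, grid_step = 1, I0_proposal_sd = 0.6)
  k <- epi_kernel(matrix(counts, 1L), cfg, seed = 51L)
  chain <- numeric(300L)
  for (it in seq_along(chain)) {
    k$i0_step(1L, c(40L, 40L))
    chain[it] <- k$get_I0()[1L]
  }
  med <- stats::median(chain[101:300])
  expect_gt(med, 0.001 / 3)
  expect_lt(med, 0.001 * 3)
})

test_that("Gillespie simulation conserves the population", {
  set.seed(37)
  counts <- gillespie_sir(5000L, 10L, rep(0.3, 50L), 1 / 8, 50L)
  expect_equal(attr(counts, "final_S") + attr(counts, "final_I") +
                 attr(counts, "final_R"), 5010)
  expect_equal(5000 - attr(counts, "final_S"), sum(counts))
  # beta = 0: no infections ever
  z <- gillespie_sir(1000L, 5L, rep(0, 20L), 1 / 8, 20L)
  expect_true(all(z == 0L))
  # seed reproducibility
  set.seed(4); a <- gillespie_sir(2000L, 5L, rep(0.25, 30L), 1 / 8, 30L)
  set.seed(4); b <- gillespie_sir(2000L, 5L, rep(0.25, 30L), 1 / 8, 30L)
  expect_identical(as.integer(a), as.integer(b))
})

test_that("Gillespie mean incidence tracks the ODE limit at the peak", {
  set.seed(41)
  sched <- rep(0.35, 60L)
  nrep <- 20L
  inc <- matrix(0L, nrep, 60L)
  for (r in seq_len(nrep)) {
    inc[r, ] <- gillespie_sir(100000L, 100L, sched, 1 / 8, 60L)
  }
  cfg <- epi_config(xi = 1 / 8, grid_step = 0.25)
  tr <- integrate_sir(sched, cfg, I0 = 0.001)
  Sd <- tr$S[1 + 4 * (0:60)]
  ode_inc <- 100000 * (-diff(Sd))
  peak <- which.max(ode_inc)
  se <- stats::sd(inc[, peak]) / sqrt(nrep)
  expect_lt(abs(mean(inc[, peak]) - ode_inc[peak]), 3 * se)
})

test_that("subsampling is exact hypergeometric thinning", {
  counts <- c(10L, 0L, 25L, 5L)
  expect_identical(subsample_infections(counts, 1), counts)
  set.seed(43)
  th <- subsample_infections(counts, 0.2)
  expect_equal(sum(th), round(0.2 * sum(counts)))
  expect_true(all(th <= counts))
  # empirical per-day mean over repeated thinnings: 0.2 * counts within 3 se
  reps <- replicate(200, subsample_infections(counts, 0.2))
  for (d in seq_along(counts)) {
    se <- stats::sd(reps[d, ]) / sqrt(200)
    expect_lt(abs(mean(reps[d, ]) - 0.2 * counts[d]), 3 * se + 1e-9)
  }
})
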