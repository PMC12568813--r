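# SIR dynamical-survival-analysis kernel: piecewise-constant infection rate,
# Monte-Carlo marginalization of the block rates, Metropolis update of the
# initial infected fraction, and the Doob-Gillespie simulator.

#' Epidemic kernel configuration
#'
#' Settings of the SIR dynamical-survival-analysis likelihood. The recovery
#' rate \eqn{\xi} is fixed and shared across series; the block-specific
#' infection rates are i.i.d. Gamma(`beta_shape`, `beta_rate`) under the
#' prior and marginalized by Monte Carlo with `mc_draws` draws; the initial
#' infected fraction \eqn{I_0} carries a uniform prior on
#' (`I0_prior_low`, `I0_prior_high`) and a logit-scale Gaussian random-walk
#' Metropolis update of scale `I0_proposal_sd`.
#'
#' Defaults: \eqn{\xi = 1/8} per day and a Gamma(4, 10) infection-rate prior
#' (mean 0.4/day) suit synthetic SIR incidence; `grid_step` is the
#' Runge-Kutta step in days and must divide one day.
#'
#' @param xi recovery rate (1/days, > 0).
#' @param beta_shape,beta_rate Gamma prior parameters of each block rate.
#' @param mc_draws Monte-Carlo sample size for the rate marginalization.
#' @param mc_proposal Monte-Carlo sample size used only while *constructing*
#'   order proposals (the depth-`L` chain inside the informed proposal);
#'   defaults to `min(100, mc_draws)`. Proposal densities and acceptance
#'   ratios always use the full `mc_draws` marginal, so this trades proposal
#'   quality (not correctness of the target) for speed.
#' @param grid_step ODE integration step in days (must divide 1).
#' @param I0_prior_low,I0_prior_high bounds of the uniform prior on I0,
#'   within (0, 1).
#' @param I0_proposal_sd random-walk scale on the logit of the rescaled I0.
#' @return object of class `"cp_epi_config"`.
#' @export
epi_config <- function(xi = 1 / 8, beta_shape = 4, beta_rate = 10,
                       mc_draws = 1000L, mc_proposal = NULL,
                       grid_step = 0.5,
                       I0_prior_low = 1e-6, I0_prior_high = 0.05,
                       I0_proposal_sd = 0.5) {
  if (is.null(mc_proposal)) mc_proposal <- min(100L, as.integer(mc_draws))
  stopifnot(xi > 0, beta_shape > 0, beta_rate > 0, mc_draws >= 1L,
            mc_proposal >= 1L, mc_proposal <= mc_draws,
            grid_step > 0, I0_prior_low > 0, I0_prior_high > I0_prior_low,
            I0_prior_high < 1, I0_proposal_sd > 0)
  spd <- 1 / grid_step
  if (abs(spd - round(spd)) > 1e-9) {
    stop("grid_step must divide one day (e.g. 1, 0.5, 0.25)", call. = FALSE)
  }
  structure(list(xi = xi, beta_shape = beta_shape, beta_rate = beta_rate,
                 mc_draws = as.integer(mc_draws),
                 mc_proposal = as.integer(mc_proposal),
                 grid_step = grid_step,
                 steps_per_day = as.integer(round(spd)),
                 I0_prior_low = I0_prior_low, I0_prior_high = I0_prior_high,
                 I0_proposal_sd = I0_proposal_sd),
            class = "cp_epi_config")
}

#' Integrate the SIR ordinary differential equations
#'
#' Fourth-order Runge-Kutta solution of
#' \eqn{S' = -\beta(t) S I,\; I' = \beta(t) S I - \xi I,\; R' = \xi I}
#' with \eqn{S(0) = 1, I(0) = I_0, R(0) = 0} and \eqn{\beta} piecewise
#' constant by calendar day. Mass conservation \eqn{S + I + R = 1 + I_0}
#' holds exactly by construction (R is recovered from it), and \eqn{S} is
#' non-increasing.
#'
#' @param beta_per_day positive rates, one per day; the horizon is
#'   `length(beta_per_day)` days.
#' @param config an [epi_config()] (supplies `xi` and the grid step).
#' @param I0 initial infected fraction in (0, 1).
#' @return a data frame of class `"cp_sir_trajectory"` with columns `time`,
#'   `S`, `I`, `R` on the integration grid.
#' @export
integrate_sir <- function(beta_per_day, config, I0) {
  stopifnot(inherits(config, "cp_epi_config"))
  if (any(!is.finite(beta_per_day)) || any(beta_per_day < 0)) {
    stop("beta must be finite and non-negative", call. = FALSE)
  }
  if (I0 <= 0 || I0 >= 1) stop("I0 must lie in (0, 1)", call. = FALSE)
  m <- sir_rk4_cpp(as.numeric(beta_per_day), config$xi, I0,
                   config$steps_per_day)
  out <- data.frame(time = m[, 1L], S = m[, 2L], I = m[, 3L], R = m[, 4L])
  class(out) <- c("cp_sir_trajectory", "data.frame")
  out
}

#' Discrete-day DSA log-pmf of infection times
#'
#' The dynamical-survival-analysis density of a random individual's
#' infection day, \eqn{f_T(t) \propto \beta(t) S(t) I(t)}, is evaluated at
#' the integer days `1..T` on the Runge-Kutta solution and renormalized so
#' the discrete masses sum to one (so the result is a proper pmf regardless
#' of grid step, and the continuous normalization \eqn{1 - S(T)} cancels).
#'
#' @inheritParams integrate_sir
#' @return numeric vector of log-probabilities over days `1..T`; their
#'   exponentials sum to 1.
#' @export
dsa_log_pmf <- function(beta_per_day, config, I0) {
  stopifnot(inherits(config, "cp_epi_config"))
  traj <- integrate_sir(beta_per_day, config, I0)
  T <- length(beta_per_day)
  spd <- config$steps_per_day
  idx <- 1L + spd * seq_len(T)   # rows at integer days 1..T
  S_T <- traj$S[length(traj$S)]
  if (S_T >= 1 - 1e-12) {
    stop("degenerate epidemic: no infections occur (S(T) = 1)",
         call. = FALSE)
  }
  logf <- log(beta_per_day) + log(traj$S[idx]) + log(traj$I[idx])
  logf - logsumexp(logf)
}

#' Epidemic kernel handle bound to incidence data
#'
#' Builds the dynamical-survival-analysis marginal likelihood for a matrix
#' of daily incidence counts. For a series and an order, the block-specific
#' infection rates are drawn `mc_draws` times from their Gamma prior, each
#' draw's multinomial log-likelihood \eqn{\sum_t y_t \log f(t)} is computed
#' on the Runge-Kutta solution, and the Monte-Carlo average is assembled by
#' log-sum-exp. Common random numbers -- one fixed uniform array per series,
#' transformed through the Gamma quantile function block by block -- make the
#' marginal a fixed (if noisy) function of the order during a whole run, as
#' the pseudo-marginal interpretation requires; marginals are cached by
#' (order, I0) key.
#'
#' @param counts matrix of non-negative daily counts, one row per series.
#' @param config an [epi_config()].
#' @param I0 initial infected fractions: scalar or length-n vector (chain
#'   state, updated by [update_I0()]); defaults to the geometric midpoint of
#'   the prior bounds.
#' @param seed integer seed of the dedicated common-random-numbers stream
#'   (independent of the sampler's stream).
#' @return a kernel handle (list) with fields `n`, `T`, `additive = FALSE`,
#'   closures `series_lm(i, sizes)`, `i0_step(i, sizes)` and `get_I0()`.
#' @export
epi_kernel <- function(counts, config = epi_config(), I0 = NULL,
                       seed = 171717L) {
  counts <- as.matrix(counts)
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must be non-negative with no missing values", call. = FALSE)
  }
  n <- nrow(counts); T <- ncol(counts)
  if (is.null(I0)) {
    I0 <- sqrt(config$I0_prior_low * config$I0_prior_high)
  }
  i0 <- rep_len(as.numeric(I0), n)
  stopifnot(all(i0 > config$I0_prior_low), all(i0 < config$I0_prior_high))
  MC <- config$mc_draws
  # dedicated CRN stream: draw the uniform arrays without disturbing the
  # sampler's RNG state
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  U <- lapply(seq_len(n), function(i) matrix(stats::runif(MC * T), MC, T))
  if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
  state <- new.env(parent = emptyenv())
  state$i0 <- i0
  state$cache <- lapply(seq_len(n), function(i) new.env(parent = emptyenv()))
  state$bcache <- lapply(seq_len(n), function(i) new.env(parent = emptyenv()))

  # Gamma quantiles of the CRN uniforms: the full MC x T matrix is computed
  # once per series on first use; the likelihood reads only the first m
  # columns (one per block), so all block counts share it
  block_draws <- function(i) {
    hit <- state$bcache[[i]]$full
    if (!is.null(hit)) return(hit)
    val <- matrix(stats::qgamma(U[[i]], shape = config$beta_shape,
                                rate = config$beta_rate), nrow = MC)
    state$bcache[[i]]$full <- val
    val
  }
  compute_lm <- function(i, sizes, I0_i, mc_use = -1L) {
    ll <- epi_loglik_mc_cpp(block_draws(i), as.integer(sizes), counts[i, ],
                            config$xi, I0_i, config$steps_per_day,
                            as.integer(mc_use))
    out <- logsumexp(ll) - log(length(ll))
    if (!is.finite(out)) {
      stop("degenerate epidemic: all Monte-Carlo draws have zero likelihood",
           call. = FALSE)
    }
    out
  }
  series_lm <- function(i, sizes) {
    I0_i <- state$i0[i]
    key <- paste0(order_key(sizes), "@", sprintf("%.15g", I0_i))
    env <- state$cache[[i]]
    hit <- env[[key]]
    if (!is.null(hit)) return(hit)
    val <- compute_lm(i, sizes, I0_i)
    env[[key]] <- val
    val
  }
  # reduced-draw marginal (first mc_proposal CRN rows) used only inside the
  # informed proposal's order chain
  MCp <- config$mc_proposal
  proposal_lm <- if (MCp < MC) {
    function(i, sizes) compute_lm(i, sizes, state$i0[i], mc_use = MCp)
  } else {
    NULL
  }
  i0_step <- function(i, sizes) {
    lo <- config$I0_prior_low; hi <- config$I0_prior_high
    u_cur <- (state$i0[i] - lo) / (hi - lo)
    z_cur <- stats::qlogis(u_cur)
    z_new <- z_cur + stats::rnorm(1L, 0, config$I0_proposal_sd)
    u_new <- stats::plogis(z_new)
    I0_new <- lo + (hi - lo) * u_new
    lm_cur <- series_lm(i, sizes)
    key_new <- paste0(order_key(sizes), "@", sprintf("%.15g", I0_new))
    lm_new <- compute_lm(i, sizes, I0_new)
    # uniform prior; Jacobian of the logit reparameterization
    log_acc <- lm_new - lm_cur +
      log(u_new * (1 - u_new)) - log(u_cur * (1 - u_cur))
    if (log(stats::runif(1L)) < log_acc) {
      state$i0[i] <- I0_new
      state$cache[[i]][[key_new]] <- lm_new
      lm_new
    } else {
      lm_cur
    }
  }
  list(type = "sir", n = n, T = T, additive = FALSE, config = config,
       counts = counts, series_lm = series_lm, proposal_lm = proposal_lm,
       i0_step = i0_step, get_I0 = function() state$i0)
}

#' One Metropolis-Hastings update of a series' initial infected fraction
#'
#' Gaussian random walk on the logit of the prior-rescaled \eqn{I_0},
#' targeting the product of the Monte-Carlo marginal likelihood (under the
#' series' current order) and the uniform prior. The kernel's internal
#' \eqn{I_0} state is updated in place.
#'
#' @param kernel an [epi_kernel()].
#' @param i series index.
#' @param order the series' current `"cp_order"` (its cluster's order).
#' @return the accepted (or retained) \eqn{I_0} value, invisibly alongside
#'   the kernel state update.
#' @export
update_I0 <- function(kernel, i, order) {
  stopifnot(identical(kernel$type, "sir"))
  kernel$i0_step(i, as.integer(order))
  kernel$get_I0()[i]
}

#' Doob-Gillespie simulation of daily SIR incidence
#'
#' Exact stochastic simulation of the Markov SIR jump process with infection
#' propensity \eqn{\beta(t) X_S X_I / S_0} and recovery propensity
#' \eqn{\xi X_I}; \eqn{\beta} is piecewise constant by calendar day. The
#' total count \eqn{X_S + X_I + X_R} is conserved throughout. Uses R's RNG,
#' so results are reproducible under `set.seed()`.
#'
#' @param S0 initial susceptible count (>= 1).
#' @param I0_count initial infected count (>= 1).
#' @param beta_schedule per-day infection rates (per-contact scale, matching
#'   the ODE limit).
#' @param xi recovery rate (1/days).
#' @param horizon number of days simulated.
#' @return integer vector of daily counts of infection events, length
#'   `horizon`, with attributes `final_S`, `final_I`, `final_R` (compartment
#'   counts when the simulation stopped; their sum always equals
#'   `S0 + I0_count`).
#' @export
gillespie_sir <- function(S0, I0_count, beta_schedule, xi, horizon) {
  stopifnot(S0 >= 1L, I0_count >= 1L, xi >= 0, horizon >= 1L)
  if (any(!is.finite(beta_schedule)) || any(beta_schedule < 0)) {
    stop("beta schedule must be finite and non-negative", call. = FALSE)
  }
  gillespie_sir_cpp(as.integer(S0), as.integer(I0_count),
                    as.numeric(beta_schedule), xi, as.integer(horizon))
}

#' Subsample infection events
#'
#' Hypergeometric thinning of the pooled infection times: exactly
#' `round(fraction * total)` events are retained by sampling without
#' replacement, then reallocated to their original days. (Dynamical survival
#' analysis only needs a random subset of infection times.)
#'
#' @param counts integer vector of daily counts.
#' @param fraction retention fraction in (0, 1].
#' @return integer vector of thinned daily counts, same length.
#' @export
subsample_infections <- function(counts, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  counts <- as.integer(counts)
  total <- sum(counts)
  keep <- round(fraction * total)
  if (keep >= total) return(counts)
  if (keep == 0L) return(integer(length(counts)))
  pooled <- rep.int(seq_along(counts), counts)
  kept <- pooled[sample.int(total, keep)]
  tabulate(kept, nbins = length(counts))
}
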