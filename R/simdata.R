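# Synthetic-data generators: the three-group AR/OU scenario and a
# three-group Gillespie SIR scenario, plus small smoothing utilities.

# Data-generating parameters of the real-valued synthetic study: 10 series,
# T = 300, three clusters with shared change times but series-specific local
# levels/variances.
ts_scenario <- list(
  gamma = 0.1,
  sizes = list(c(50L, 100L, 45L, 55L, 50L),
               c(40L, 50L, 45L, 45L, 30L, 90L),
               c(75L, 50L, 40L, 20L, 75L, 40L)),
  group = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L),
  mu = list(c(-0.25, -0.5, 0.5, 0, 0.5),
            c(0.1, 0.12, 0.14, 0.1, 0.13),
            c(0.45, -0.5, 0.5, 0, 0.5),
            c(0.5, -0.5, 0.5, 0.5, 0),
            c(-0.5, 0, 1, -0.1, 0.6, -0.2),
            c(0, 0.85, -0.15, 0.65, 0, 1),
            c(0.4, 0.4, -0.15, 0.5, 0, -0.65),
            c(-0.5, 0, 1, -0.1, 0.6, -0.2),
            c(0.5, 0.5, 1, 0.25, -0.5, 0.25),
            c(-0.5, 0, 0.5, -0.1, 0.6, -0.25)),
  eta = list(c(0.1, 0.12, 0.14, 0.1, 0.13),
             c(0.1, 0.12, 0.14, 0.1, 0.13),
             c(0.1, 0.12, 0.2, 0.12, 0.14),
             c(0.1, 0.12, 0.09, 0.24, 0.15),
             c(0.14, 0.13, 0.17, 0.12, 0.14, 0.12),
             c(0.1, 0.24, 0.14, 0.15, 0.12, 0.13),
             c(0.22, 0.12, 0.1, 0.13, 0.14, 0.12),
             c(0.14, 0.13, 0.17, 0.12, 0.14, 0.12),
             c(0.12, 0.22, 0.15, 0.14, 0.17, 0.19),
             c(0.12, 0.13, 0.15, 0.12, 0.15, 0.18)))

#' Three-group AR/OU synthetic dataset
#'
#' Generates the standard real-valued benchmark: 10 series observed at
#' T = 300 times, in three clusters sharing change times (true orders with
#' block sizes `50,100,45,55,50`, `40,50,45,45,30,90` and `75,50,40,20,75,40`
#' for series 1-4, 5-7 and 8-10 respectively) but series-specific block
#' levels and variances; each block is generated independently by
#' [simulate_ar_block()] with \eqn{\gamma = 0.1}.
#'
#' @param seed integer seed; the output is reproducible byte for byte.
#' @return list with elements `y` (10 x 300 matrix, rownames `series_1..10`),
#'   `truth` (a [cluster_state()] holding the generating partition and
#'   orders), and `scenario` (the generating parameters).
#' @export
ts_scenario_dataset <- function(seed = 1L) {
  set.seed(seed)
  sc <- ts_scenario
  n <- length(sc$group)
  T <- sum(sc$sizes[[1L]])
  y <- matrix(NA_real_, n, T,
              dimnames = list(paste0("series_", seq_len(n)), NULL))
  for (i in seq_len(n)) {
    sizes <- sc$sizes[[sc$group[i]]]
    blocks <- lapply(seq_along(sizes), function(j) {
      simulate_ar_block(sc$mu[[i]][j], sc$eta[[i]][j], sc$gamma, sizes[j])
    })
    y[i, ] <- unlist(blocks)
  }
  truth <- cluster_state(sc$group,
                         lapply(sc$sizes, function(s) make_order(s, T)))
  list(y = y, truth = truth, scenario = sc)
}

#' Default epidemic scenario specification
#'
#' Ten populations in three groups sharing change times of the daily
#' infection rate: group 1 (populations 1-4) experiences two large spreads;
#' groups 2 (5-7) and 3 (8-10) a single large spread each, with different
#' change points. Simulation runs over `horizon` days and the analysis
#' window keeps days `window[1]+1 .. window[2]` (default 11..150, T = 140).
#' All entries are overridable.
#'
#' @param S0 initial susceptible count per population.
#' @param xi shared recovery rate (1/days).
#' @param horizon simulated days.
#' @param window two integers: the analysis window keeps days
#'   `window[1]+1` to `window[2]`.
#' @param subsample_fraction fraction of infection times retained by
#'   [subsample_infections()].
#' @param change_days list (one per group) of day indices at which the
#'   infection rate changes (block starts after each listed day).
#' @param beta_values list (one per population) of block infection rates,
#'   lengths matching the group's block count.
#' @param I0_count initial infected count per population.
#' @return a `"cp_epi_scenario"` list.
#' @export
epi_scenario_spec <- function(S0 = 100000L, xi = 1 / 8, horizon = 200L,
                              window = c(10L, 150L),
                              subsample_fraction = 0.2,
                              change_days = list(c(35L, 75L, 105L),
                                                 c(55L, 90L),
                                                 c(25L, 60L)),
                              beta_values = list(
                                c(0.180, 0.105, 0.170, 0.100),
                                c(0.175, 0.110, 0.175, 0.100),
                                c(0.185, 0.100, 0.165, 0.105),
                                c(0.180, 0.108, 0.172, 0.098),
                                c(0.105, 0.185, 0.100),
                                c(0.102, 0.190, 0.105),
                                c(0.108, 0.180, 0.098),
                                c(0.105, 0.185, 0.100),
                                c(0.102, 0.192, 0.103),
                                c(0.108, 0.178, 0.098)),
                              I0_count = c(300L, 350L, 250L, 300L, 300L, 320L,
                                           280L, 300L, 340L, 260L)) {
  group <- c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L)
  for (i in seq_along(beta_values)) {
    stopifnot(length(beta_values[[i]]) ==
                length(change_days[[group[i]]]) + 1L)
  }
  structure(list(S0 = S0, xi = xi, horizon = as.integer(horizon),
                 window = as.integer(window),
                 subsample_fraction = subsample_fraction,
                 change_days = change_days, beta_values = beta_values,
                 I0_count = I0_count, group = group),
            class = "cp_epi_scenario")
}

# expand per-block rates + change days to a per-day schedule
epi_beta_schedule <- function(betas, change_days, horizon) {
  bounds <- c(0L, change_days, horizon)
  rep.int(betas, diff(bounds))
}

#' Three-group epidemic synthetic dataset
#'
#' Simulates each population with [gillespie_sir()] under its group's
#' piecewise-constant infection-rate schedule, trims the counts to the
#' analysis window, and applies the without-replacement infection-time
#' subsampling. The truth partition groups populations by shared change
#' days, with true orders expressed on the trimmed window.
#'
#' @param spec an [epi_scenario_spec()].
#' @param seed integer seed.
#' @return list with `counts` (10 x T matrix of thinned daily counts on the
#'   window), `raw_counts` (10 x horizon matrix before trimming/thinning),
#'   `truth` (a [cluster_state()]), and `spec`.
#' @export
epi_scenario_dataset <- function(spec = epi_scenario_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cp_epi_scenario"))
  set.seed(seed)
  n <- length(spec$beta_values)
  raw <- matrix(NA_integer_, n, spec$horizon,
                dimnames = list(paste0("pop_", seq_len(n)), NULL))
  for (i in seq_len(n)) {
    sched <- epi_beta_schedule(spec$beta_values[[i]],
                               spec$change_days[[spec$group[i]]],
                               spec$horizon)
    raw[i, ] <- gillespie_sir(spec$S0, spec$I0_count[i], sched, spec$xi,
                              spec$horizon)
  }
  lo <- spec$window[1L]; hi <- spec$window[2L]
  T <- hi - lo
  counts <- raw[, (lo + 1L):hi, drop = FALSE]
  for (i in seq_len(n)) {
    counts[i, ] <- subsample_infections(counts[i, ],
                                        spec$subsample_fraction)
  }
  # true orders on the trimmed window: a change at simulation day d is a new
  # block starting at window time d - lo + 1
  orders <- lapply(spec$change_days, function(cd) {
    cd_w <- cd[cd > lo & cd < hi] - lo
    make_order(diff(c(0L, cd_w, T)), T)
  })
  truth <- cluster_state(spec$group, orders)
  list(counts = counts, raw_counts = raw, truth = truth, spec = spec)
}

#' Rolling average of daily counts
#'
#' Centered moving-average smoother with edge truncation (the window shrinks
#' near the boundaries); `align = "trailing"` gives the trailing-window
#' variant common in epidemic reporting. Length is preserved.
#'
#' @param counts numeric vector.
#' @param window window width (>= 1), e.g. 7 for a weekly smoother.
#' @param align `"center"` (default) or `"trailing"`.
#' @return numeric vector, same length as `counts`.
#' @export
rolling_average <- function(counts, window = 7L, align = c("center",
                                                           "trailing")) {
  align <- match.arg(align)
  stopifnot(window >= 1L)
  n <- length(counts)
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(t) {
    if (align == "center") {
      lo <- max(1L, t - half)
      hi <- min(n, t + (window - 1L - half))
    } else {
      lo <- max(1L, t - window + 1L)
      hi <- t
    }
    mean(counts[lo:hi])
  }, numeric(1L))
}
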