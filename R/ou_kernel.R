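#' Ornstein-Uhlenbeck kernel hyperparameters
#'
#' Within a block the data follow a discretized Ornstein-Uhlenbeck (AR(1))
#' process with autocorrelation \eqn{\gamma = e^{-\alpha_{OU}}}, local level
#' \eqn{\mu} and stationary variance \eqn{\eta}. Conjugate priors
#' \eqn{\mu \mid \eta \sim N(0, \eta / c)} and
#' \eqn{1/\eta \sim \mathrm{Gamma}(a, b)} make the block marginal likelihood
#' available in closed form; the local parameters are never stored.
#'
#' Defaults \eqn{a = b = 1}, \eqn{c = 0.1}, \eqn{\gamma = 0.1} are the
#' standard weakly-informative choice for standardized series. \eqn{\gamma}
#' is fixed and shared across series; no inference is performed on it.
#'
#' @param gamma autocorrelation in `[0, 1)`.
#' @param a,b shape and rate of the Gamma prior on the noise precision.
#' @param c scale of the conditional Normal prior on the level.
#' @return object of class `"cp_ou_hyper"`.
#' @export
ou_hyper <- function(gamma = 0.1, a = 1, b = 1, c = 0.1) {
  if (!is.numeric(gamma) || gamma < 0 || gamma >= 1) {
    stop("gamma must lie in [0, 1)", call. = FALSE)
  }
  if (a <= 0 || b <= 0 || c <= 0) {
    stop("a, b, c must be positive", call. = FALSE)
  }
  structure(list(gamma = gamma, a = a, b = b, c = c), class = "cp_ou_hyper")
}

#' Closed-form OU block marginal likelihood
#'
#' Log marginal density of one contiguous block of observations under the
#' discretized OU model with \eqn{\mu, \eta} integrated out:
#' \deqn{\mathcal{M}(y \mid \gamma) =
#'   \frac{(2b(1-\gamma^2))^a \, \Gamma(n/2 + a)}{\pi^{n/2}\Gamma(a)}
#'   \left(\frac{c(1+\gamma)(1-\gamma^2)}{D}\right)^{1/2}
#'   \left(y^\top S y - \frac{(1-\gamma)(\Sigma y - \gamma \Sigma_{int} y)^2}{D}
#'         + 2b(1-\gamma^2)\right)^{-(n/2+a)},}
#' with \eqn{D = c + n - \gamma(n - c - 2)}, \eqn{S} the tridiagonal AR(1)
#' precision pattern (diagonal \eqn{1, 1+\gamma^2, \dots, 1+\gamma^2, 1},
#' off-diagonal \eqn{-\gamma}) and \eqn{\Sigma_{int}} the sum over the strictly
#' interior points of the block. Everything is computed in log space.
#'
#' @param block numeric vector, the block's observations (length >= 1).
#' @param hyper an [ou_hyper()].
#' @return log marginal density (scalar).
#' @export
ou_block_log_marginal <- function(block, hyper) {
  stopifnot(inherits(hyper, "cp_ou_hyper"))
  n <- length(block)
  if (n < 1L) stop("empty block", call. = FALSE)
  if (anyNA(block)) stop("block contains missing values", call. = FALSE)
  g <- hyper$gamma
  s_all <- sum(block)
  s_int <- if (n >= 3L) sum(block[2:(n - 1L)]) else 0
  ss <- sum(block^2)
  ss_int <- if (n >= 3L) sum(block[2:(n - 1L)]^2) else 0
  cross <- if (n >= 2L) sum(block[-n] * block[-1L]) else 0
  ySy <- ss + g^2 * ss_int - 2 * g * cross
  ou_lm_core(n, s_all, s_int, ySy, hyper)
}

# Shared core of the closed form, from sufficient statistics.
# Vectorized over blocks: n, s_all, s_int, ySy may be vectors.
# A singleton block has no autoregressive term, so its marginal is the plain
# Normal-Gamma predictive; the general formula reproduces it exactly when
# evaluated with gamma = 0, which is what we do for n = 1.
ou_lm_core <- function(n, s_all, s_int, ySy, hyper) {
  a <- hyper$a; b <- hyper$b; cc <- hyper$c
  g <- ifelse(n == 1L, 0, hyper$gamma)
  D <- cc + n - g * (n - cc - 2)
  quad <- ySy - (1 - g) * (s_all - g * s_int)^2 / D + 2 * b * (1 - g^2)
  a * log(2 * b * (1 - g^2)) + lgamma(n / 2 + a) - (n / 2) * log(pi) -
    lgamma(a) + 0.5 * (log(cc * (1 + g) * (1 - g^2)) - log(D)) -
    (n / 2 + a) * log(quad)
}

#' Series log marginal under an order (OU kernel)
#'
#' Sum of [ou_block_log_marginal()] over the blocks of `order`; the first
#' point of each block is treated as a fresh regime start (it does not
#' condition on the previous block).
#'
#' @param series numeric vector of length `order`'s `T`.
#' @param order a `"cp_order"`.
#' @param hyper an [ou_hyper()].
#' @return log marginal density (scalar).
#' @export
ou_series_log_marginal <- function(series, order, hyper) {
  sizes <- as.integer(order)
  if (length(series) != sum(sizes)) {
    stop("series length (", length(series), ") does not match order T (",
         sum(sizes), ")", call. = FALSE)
  }
  k <- ou_kernel(matrix(series, nrow = 1L), hyper)
  k$series_lm(1L, sizes)
}

#' OU kernel handle bound to a dataset
#'
#' Precomputes per-series prefix sums of \eqn{y}, \eqn{y^2} and
#' \eqn{y_t y_{t+1}} so that any block's sufficient statistics -- and hence
#' its closed-form marginal -- cost O(1), and a whole order costs O(blocks).
#' This is what makes split/merge moves on long series cheap.
#'
#' @param y numeric matrix, one row per series (no missing values).
#' @param hyper an [ou_hyper()].
#' @param standardize if `TRUE`, each series is marginally standardized
#'   (centered and scaled) before analysis.
#' @return a kernel handle (list) used by the samplers: fields `n`, `T`,
#'   `additive = TRUE`, and closures `block_lm(i, starts, ends)` (vectorized
#'   over blocks) and `series_lm(i, sizes)`.
#' @export
ou_kernel <- function(y, hyper = ou_hyper(), standardize = FALSE) {
  y <- as.matrix(y)
  if (anyNA(y)) stop("y contains missing values", call. = FALSE)
  if (standardize) y <- t(scale(t(y)))
  n <- nrow(y); T <- ncol(y)
  # prefix sums padded with a leading zero: P[, e + 1] - P[, s] = sum over s..e
  row_cumsum <- function(m) {
    out <- m
    for (i in seq_len(nrow(m))) out[i, ] <- cumsum(m[i, ])
    cbind(0, out)
  }
  P1 <- row_cumsum(y)
  P2 <- row_cumsum(y^2)
  PC <- if (T >= 2L) {
    row_cumsum(y[, -T, drop = FALSE] * y[, -1L, drop = FALSE])
  } else {
    matrix(0, n, 1L)
  }
  block_lm <- function(i, starts, ends) {
    len <- ends - starts + 1L
    s_all <- P1[i, ends + 1L] - P1[i, starts]
    s_int <- ifelse(len >= 3L, P1[i, ends] - P1[i, starts + 1L], 0)
    ss <- P2[i, ends + 1L] - P2[i, starts]
    ss_int <- ifelse(len >= 3L, P2[i, ends] - P2[i, starts + 1L], 0)
    cross <- ifelse(len >= 2L, PC[i, ends] - PC[i, starts], 0)
    g <- hyper$gamma
    ySy <- ss + g^2 * ss_int - 2 * g * cross
    ou_lm_core(len, s_all, s_int, ySy, hyper)
  }
  series_lm <- function(i, sizes) {
    ou_series_lm_cpp(P1[i, ], P2[i, ], PC[i, ], hyper$gamma, hyper$a,
                     hyper$b, hyper$c, as.integer(sizes))
  }
  list(type = "ou", n = n, T = T, additive = TRUE, hyper = hyper, y = y,
       P1 = P1, P2 = P2, PC = PC,
       block_lm = block_lm, series_lm = series_lm)
}

#' Simulate one AR(1)/OU block
#'
#' Generates a block of the discretized OU process: the first element is
#' drawn from the stationary law \eqn{N(\mu, \eta)} (a fresh regime start),
#' subsequent elements follow
#' \eqn{y_t = \gamma y_{t-1} + (1-\gamma)\mu + N(0, (1-\gamma^2)\eta)}, so
#' that every element has marginal variance \eqn{\eta} and lag-1
#' autocorrelation \eqn{\gamma}.
#'
#' @param mu local level.
#' @param eta stationary variance (> 0).
#' @param gamma autocorrelation in `[0, 1)`.
#' @param length block length (>= 1).
#' @return numeric vector of the simulated block.
#' @export
simulate_ar_block <- function(mu, eta, gamma, length) {
  stopifnot(length >= 1L, eta > 0, gamma >= 0, gamma < 1)
  y <- numeric(length)
  y[1L] <- mu + stats::rnorm(1L, 0, sqrt(eta))
  if (length > 1L) {
    innov <- stats::rnorm(length - 1L, 0, sqrt((1 - gamma^2) * eta))
    for (t in 2:length) {
      y[t] <- gamma * y[t - 1L] + (1 - gamma) * mu + innov[t - 1L]
    }
  }
  y
}
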