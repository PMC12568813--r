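#' Symmetric Dirichlet prior over the order mixture weights
#'
#' The mixture over the \eqn{2^{T-1}} orders carries Dirichlet-distributed
#' weights with common concentration \eqn{\alpha_r = \alpha}. The weights are
#' always marginalized analytically (Dirichlet-categorical), so only
#' \eqn{\alpha} and \eqn{T} are stored. The default \eqn{\alpha = 1} keeps
#' the prior tie probability non-negligible even for large \eqn{T}.
#'
#' @param alpha positive concentration parameter (default 1).
#' @param T number of time points (implying `2^(T-1)` mixture categories).
#' @return object of class `"cp_dirichlet"`.
#' @export
dirichlet_prior <- function(alpha = 1, T) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0) {
    stop("alpha must be a positive number", call. = FALSE)
  }
  T <- as.integer(T)
  if (is.na(T) || T < 1L) stop("T must be a positive integer", call. = FALSE)
  structure(
    list(alpha = alpha, T = T,
         # log alpha^+ = log(2^(T-1) * alpha), kept in log space: alpha^+
         # itself overflows double for T beyond ~1000
         log_alpha_plus = (T - 1) * log(2) + log(alpha)),
    class = "cp_dirichlet")
}

#' Prior probability that two series share an order
#'
#' Under the Dirichlet-categorical model the probability that two draws tie is
#' \deqn{P(X_2 = X_1) = \frac{\alpha + 1}{2^{T-1}\alpha + 1},}
#' which tends to 1 as \eqn{\alpha \to 0} and to \eqn{2^{-(T-1)}} as
#' \eqn{\alpha \to \infty}.
#'
#' @param prior a [dirichlet_prior()].
#' @return probability in `(2^-(T-1), 1]`.
#' @export
tie_probability <- function(prior) {
  stopifnot(inherits(prior, "cp_dirichlet"))
  a <- prior$alpha
  # log(2^(T-1)*alpha + 1), stable even when 2^(T-1) overflows double
  x <- prior$log_alpha_plus
  log_den <- max(x, 0) + log1p(exp(-abs(x)))
  exp(log1p(a) - log_den)
}

#' Collapsed Dirichlet-categorical allocation weight
#'
#' Log-probability that `n` series land in one *specific* assignment to the
#' given distinct orders, with the mixture weights integrated out:
#' \deqn{\frac{\Gamma(\alpha^+)}{\Gamma(\alpha^+ + n)}
#'       \prod_r \frac{\Gamma(\alpha_r + n_r)}{\Gamma(\alpha_r)},}
#' where \eqn{\alpha^+ = 2^{T-1}\alpha} and the product runs over occupied
#' categories only (empty ones contribute \eqn{\Gamma(\alpha)/\Gamma(\alpha)=1}).
#' The leading ratio is computed as \eqn{-\sum_{j=0}^{n-1}\log(\alpha^+ + j)},
#' exact for integer `n` and immune to the overflow of \eqn{\alpha^+} itself.
#'
#' @param cluster_sizes positive integers summing to `n`: the occupancy counts
#'   of the occupied orders.
#' @param prior a [dirichlet_prior()].
#' @param n number of series; defaults to `sum(cluster_sizes)`.
#' @return log-probability (scalar).
#' @export
log_allocation_weight <- function(cluster_sizes, prior,
                                  n = sum(cluster_sizes)) {
  stopifnot(inherits(prior, "cp_dirichlet"))
  sizes <- as.integer(cluster_sizes)
  if (any(sizes < 1L)) stop("cluster sizes must be positive", call. = FALSE)
  if (sum(sizes) != n) stop("cluster sizes must sum to n", call. = FALSE)
  lap <- prior$log_alpha_plus
  j <- seq_len(n) - 1
  # log(alpha^+ + j) = log(alpha^+) + log1p(j / alpha^+), stable for huge T
  lead <- -sum(lap + log1p(exp(log(pmax(j, 1e-300)) - lap)) * (j > 0))
  occ <- sum(lgamma(prior$alpha + sizes) - lgamma(prior$alpha))
  lead + occ
}
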