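# Independent oracles used across the suite.

# 2-D adaptive quadrature oracle for the OU block marginal: integrates the
# AR(1) likelihood against the Normal (level) and Gamma (noise precision)
# priors over (mu, tau), tau = 1 / variance.
ou_quadrature_oracle <- function(y, hyper) {
  g <- hyper$gamma
  a <- hyper$a
  b <- hyper$b
  cc <- hyper$c
  n <- length(y)
  f_mu <- function(mu, tau) {
    ll <- stats::dnorm(y[1L], mu, sqrt(1 / tau), log = TRUE)
    if (n > 1L) {
      for (t in 2:n) {
        ll <- ll + stats::dnorm(y[t], g * y[t - 1L] + (1 - g) * mu,
                                sqrt((1 - g^2) / tau), log = TRUE)
      }
    }
    exp(ll + stats::dnorm(mu, 0, sqrt(1 / (cc * tau)), log = TRUE))
  }
  inner <- function(tau) {
    vapply(tau, function(tv) {
      stats::integrate(function(m) vapply(m, f_mu, numeric(1L), tau = tv),
                       -Inf, Inf, rel.tol = 1e-10)$value *
        stats::dgamma(tv, a, rate = b)
    }, numeric(1L))
  }
  log(stats::integrate(inner, 0, Inf, rel.tol = 1e-9)$value)
}

# Exact per-series log normalizers by order enumeration (small T only).
enumerated_normalizers <- function(kernel) {
  orders <- enumerate_orders(kernel$T)
  lz <- vapply(seq_len(kernel$n), function(i) {
    lms <- vapply(orders, function(o) kernel$series_lm(i, as.integer(o)),
                  numeric(1L))
    m <- max(lms)
    m + log(sum(exp(lms - m))) - (kernel$T - 1) * log(2)
  }, numeric(1L))
  structure(lz, B = NA_integer_, class = "cp_normalizers")
}

# Canonical string for the set partition induced by a label vector.
partition_key <- function(lab) paste(match(lab, unique(lab)), collapse = "")

# Brute-force posterior over set partitions of n series: enumerate every
# assignment of series to the 2^(T-1) orders and accumulate Eq.-level
# collapsed weights (allocation weight x per-series marginals).
enumerated_partition_posterior <- function(kernel, prior) {
  orders <- enumerate_orders(kernel$T)
  R <- length(orders)
  n <- kernel$n
  M <- vapply(orders, function(o) {
    vapply(seq_len(n), function(i) kernel$series_lm(i, as.integer(o)),
           numeric(1L))
  }, numeric(n))           # n x R
  if (n == 1L) M <- matrix(M, 1L)
  grid <- do.call(expand.grid, rep(list(seq_len(R)), n))
  logw <- apply(grid, 1L, function(rr) {
    sizes <- as.integer(table(rr))
    log_allocation_weight(sizes, prior, n) +
      sum(M[cbind(seq_len(n), as.integer(rr))])
  })
  keys <- apply(grid, 1L, function(rr) partition_key(as.integer(rr)))
  mx <- max(logw)
  w <- exp(logw - mx)
  p <- tapply(w, keys, sum)
  p / sum(w)
}

total_variation <- function(p, q) {
  keys <- union(names(p), names(q))
  pv <- ifelse(keys %in% names(p), p[keys], 0)
  qv <- ifelse(keys %in% names(q), q[keys], 0)
  0.5 * sum(abs(pv - qv))
}

logsumexp_vec <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
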