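# Informed split-merge MCMC over the partition of series into clusters,
# each cluster carrying one shared order, targeting the collapsed posterior
# (Dirichlet-categorical allocation weight times block marginals).

#' Cluster state
#'
#' An assignment of `n` series to clusters together with one order per
#' non-empty cluster. Two series are clustered together exactly when they
#' carry the same latent order.
#'
#' @param assignment integer vector of cluster labels (values index
#'   `cluster_orders`).
#' @param cluster_orders list of `"cp_order"` objects, one per label in use.
#' @return object of class `"cp_cluster_state"`.
#' @export
cluster_state <- function(assignment, cluster_orders) {
  assignment <- as.integer(assignment)
  labs <- sort(unique(assignment))
  if (!all(labs %in% seq_along(cluster_orders))) {
    stop("every label must index an entry of cluster_orders", call. = FALSE)
  }
  Ts <- vapply(cluster_orders, function(o) sum(as.integer(o)), integer(1L))
  if (length(unique(Ts)) > 1L) {
    stop("all cluster orders must share the same T", call. = FALSE)
  }
  structure(list(assignment = assignment, cluster_orders = cluster_orders),
            class = "cp_cluster_state")
}

#' Sampler configuration
#'
#' @param M total MCMC iterations.
#' @param burn_in iterations discarded (must be `< M`).
#' @param q split probability of the order-level proposal (0 < q < 1).
#' @param L proposal depth: split/merge steps used when drawing an order from
#'   the informed proposal.
#' @param B importance-sample size for the normalization constants.
#' @param refresh if `TRUE`, add an order-refresh move each iteration (the
#'   partition is unchanged, one cluster's order is resampled; a mixing aid).
#' @param psi_correction if `TRUE` (default), acceptance ratios include the
#'   informed proposal's density [log_psi()], evaluated with the normalizer
#'   table -- the choice that makes the chain exactly invariant for the
#'   collapsed target when the normalizers are exact. If `FALSE`, the
#'   informed order draw is treated as symmetric and the ratio reduces to
#'   target and allocation terms; no normalizers are needed. This variant is
#'   not exactly invariant, but its bias is data-adaptive in a useful way: a
#'   fresh shared order drawn near the posterior mode recovers, for every
#'   compatible member, the gap between its current (posterior-typical)
#'   order and the mode, which is what lets common structure amalgamate at
#'   large `T`; see the methods vignette.
#' @param i0_updates if `TRUE` (default), the epidemic kernel's per-series
#'   initial-infected-fraction Metropolis step runs once per iteration;
#'   ignored by other kernels.
#' @param seed optional integer seed set at the start of [run_mcmc()].
#' @return object of class `"cp_sampler_config"`.
#' @export
sampler_config <- function(M = 5000L, burn_in = 2000L, q = 0.5, L = 25L,
                           B = 1000L, refresh = TRUE, psi_correction = TRUE,
                           i0_updates = TRUE, seed = NULL) {
  stopifnot(q > 0, q < 1, L >= 1L, B >= 1L, burn_in >= 0L, burn_in < M)
  structure(list(M = as.integer(M), burn_in = as.integer(burn_in), q = q,
                 L = as.integer(L), B = as.integer(B),
                 refresh = isTRUE(refresh),
                 psi_correction = isTRUE(psi_correction),
                 i0_updates = isTRUE(i0_updates), seed = seed),
            class = "cp_sampler_config")
}

#' Collapsed log target of a cluster state
#'
#' Log of the joint law of data and order assignment with mixture weights and
#' local parameters integrated out: the Dirichlet-categorical allocation
#' weight of the cluster sizes plus, for every series, its log marginal under
#' its cluster's order.
#'
#' @param state a [cluster_state()].
#' @param kernel a kernel handle ([ou_kernel()] or [epi_kernel()]).
#' @param prior a [dirichlet_prior()].
#' @return log density (scalar).
#' @export
log_target <- function(state, kernel, prior) {
  stopifnot(inherits(state, "cp_cluster_state"))
  asg <- state$assignment
  sizes <- as.integer(table(asg))
  lw <- log_allocation_weight(sizes, prior, n = length(asg))
  lik <- sum(vapply(seq_along(asg), function(i) {
    kernel$series_lm(i, as.integer(state$cluster_orders[[asg[i]]]))
  }, numeric(1L)))
  lw + lik
}

# ---- internal mutable chain state -------------------------------------------
# labels: integer vector length n; orders: list label -> integer sizes;
# slm: per-series log marginal under its cluster's order.

mc_new_label <- function(orders) {
  free <- which(vapply(orders, is.null, logical(1L)))
  if (length(free)) free[1L] else length(orders) + 1L
}

mc_alloc_delta <- function(prior, removed, added) {
  a <- prior$alpha
  sum(lgamma(a + added) - lgamma(a)) - sum(lgamma(a + removed) - lgamma(a))
}

# The partition is defined by equivalence classes of orders, so a valid
# state never holds the same order in two clusters (the collapsed target is
# zero there: such a labeled state double-counts a single configuration).
# Proposals that would create a duplicate are therefore rejected outright.
mc_order_keys <- function(chain, exclude = integer(0)) {
  labs <- setdiff(unique(chain$labels), exclude)
  vapply(labs, function(lb) order_key(chain$orders[[lb]]), character(1L))
}

# One split/merge MH step on the partition. Returns the updated state plus
# bookkeeping on the move performed.
mc_partition_step <- function(chain, kernel, prior, config, normalizers) {
  n <- kernel$n
  if (n < 2L) return(chain)
  pair <- sample.int(n, 2L)
  i <- pair[1L]; l <- pair[2L]
  labels <- chain$labels; orders <- chain$orders; slm <- chain$slm
  q <- config$q; L <- config$L
  if (labels[i] == labels[l]) {
    ## SPLIT: anchor i and l in two new clusters, allocate the rest uniformly
    c_old <- labels[i]
    members <- which(labels == c_old)
    s <- length(members)
    others <- setdiff(members, c(i, l))
    to_A <- c(i, others[stats::runif(length(others)) < 0.5])
    to_B <- setdiff(members, to_A)
    ord_A <- as.integer(sample_psi(kernel, L, q))
    ord_B <- as.integer(sample_psi(kernel, L, q))
    taken <- mc_order_keys(chain, exclude = c_old)
    if (order_key(ord_A) == order_key(ord_B) ||
        any(c(order_key(ord_A), order_key(ord_B)) %in% taken)) {
      chain$last_move <- c(move = "split", accepted = FALSE)
      return(chain)
    }
    use_psi <- !identical(config$psi_correction, FALSE)
    lpsi_A <- if (use_psi) log_psi(kernel, ord_A, normalizers) else 0
    lpsi_B <- if (use_psi) log_psi(kernel, ord_B, normalizers) else 0
    lpsi_old <- if (use_psi) log_psi(kernel, orders[[c_old]], normalizers)
                else 0
    lm_A <- vapply(to_A, function(m) kernel$series_lm(m, ord_A), numeric(1L))
    lm_B <- vapply(to_B, function(m) kernel$series_lm(m, ord_B), numeric(1L))
    d_alloc <- mc_alloc_delta(prior, removed = s,
                              added = c(length(to_A), length(to_B)))
    d_lik <- sum(lm_A) + sum(lm_B) - sum(slm[members])
    # forward: alloc prob 2^-(s-2) and two fresh psi draws; reverse: one
    log_acc <- d_alloc + d_lik + lpsi_old + (s - 2) * log(2) - lpsi_A - lpsi_B
    accepted <- log(stats::runif(1L)) < log_acc
    if (accepted) {
      orders[c_old] <- list(NULL)
      lab_A <- mc_new_label(orders)
      orders[[lab_A]] <- ord_A
      lab_B <- mc_new_label(orders)
      orders[[lab_B]] <- ord_B
      labels[to_A] <- lab_A
      labels[to_B] <- lab_B
      slm[to_A] <- lm_A
      slm[to_B] <- lm_B
      chain$labels <- labels; chain$orders <- orders; chain$slm <- slm
    }
    chain$last_move <- c(move = "split", accepted = accepted)
  } else {
    ## MERGE the two clusters, draw one fresh order from psi
    c_A <- labels[i]; c_B <- labels[l]
    mem_A <- which(labels == c_A); mem_B <- which(labels == c_B)
    s <- length(mem_A) + length(mem_B)
    ord_new <- as.integer(sample_psi(kernel, L, q))
    if (order_key(ord_new) %in% mc_order_keys(chain, exclude = c(c_A, c_B))) {
      chain$last_move <- c(move = "merge", accepted = FALSE)
      return(chain)
    }
    use_psi <- !identical(config$psi_correction, FALSE)
    lpsi_new <- if (use_psi) log_psi(kernel, ord_new, normalizers) else 0
    lpsi_A <- if (use_psi) log_psi(kernel, orders[[c_A]], normalizers) else 0
    lpsi_B <- if (use_psi) log_psi(kernel, orders[[c_B]], normalizers) else 0
    members <- c(mem_A, mem_B)
    lm_new <- vapply(members, function(m) kernel$series_lm(m, ord_new),
                     numeric(1L))
    d_alloc <- mc_alloc_delta(prior,
                              removed = c(length(mem_A), length(mem_B)),
                              added = s)
    d_lik <- sum(lm_new) - sum(slm[members])
    log_acc <- d_alloc + d_lik + lpsi_A + lpsi_B - (s - 2) * log(2) - lpsi_new
    accepted <- log(stats::runif(1L)) < log_acc
    if (accepted) {
      orders[c_B] <- list(NULL)
      orders[[c_A]] <- ord_new
      labels[mem_B] <- c_A
      slm[members] <- lm_new
      chain$labels <- labels; chain$orders <- orders; chain$slm <- slm
    }
    chain$last_move <- c(move = "merge", accepted = accepted)
  }
  chain
}

# Optional order-refresh move: resample one cluster's order from psi,
# partition unchanged.
mc_refresh_step <- function(chain, kernel, prior, config, normalizers) {
  labs <- sort(unique(chain$labels))
  cl <- labs[sample.int(length(labs), 1L)]
  members <- which(chain$labels == cl)
  ord_new <- as.integer(sample_psi(kernel, config$L, config$q))
  if (order_key(ord_new) %in% mc_order_keys(chain, exclude = cl)) {
    return(chain)
  }
  use_psi <- !identical(config$psi_correction, FALSE)
  lpsi_new <- if (use_psi) log_psi(kernel, ord_new, normalizers) else 0
  lpsi_old <- if (use_psi) log_psi(kernel, chain$orders[[cl]], normalizers)
              else 0
  lm_new <- vapply(members, function(m) kernel$series_lm(m, ord_new),
                   numeric(1L))
  log_acc <- sum(lm_new) - sum(chain$slm[members]) + lpsi_old - lpsi_new
  if (log(stats::runif(1L)) < log_acc) {
    chain$orders[[cl]] <- ord_new
    chain$slm[members] <- lm_new
  }
  chain
}

#' Run the cluster MCMC
#'
#' Initializes at the all-singleton partition with per-series informed orders
#' (depth-`L` draws from each series' own posterior), then iterates the
#' split/merge partition move, an optional order-refresh move, and -- for the
#' epidemic kernel -- one Metropolis-Hastings update of each series' initial
#' infected fraction per iteration. With `n = 1` only the order of the single
#' series is resampled, so the sampler doubles as a single-series
#' change-point detector.
#'
#' @param kernel a kernel handle ([ou_kernel()] or [epi_kernel()]).
#' @param prior a [dirichlet_prior()]; defaults to `alpha = 1`.
#' @param config a [sampler_config()].
#' @param normalizers optional [normalizer_table()]; computed here (with
#'   `config$B` draws) when missing.
#' @param progress if `TRUE`, log progress lines to standard error.
#' @return a `"cp_trace"`: post-burn-in snapshots with elements
#'   `assignment` (iterations x n matrix of cluster labels), `order_keys`
#'   (iterations x n character matrix, each series' cluster order as a
#'   block-size string), `log_target`, `acceptance` (move / accepted flags for
#'   all M iterations), `n`, `T` and the configuration.
#' @export
run_mcmc <- function(kernel, prior = dirichlet_prior(1, kernel$T),
                     config = sampler_config(), normalizers = NULL,
                     progress = FALSE) {
  stopifnot(inherits(config, "cp_sampler_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- kernel$n
  if (is.null(normalizers) && !identical(config$psi_correction, FALSE)) {
    normalizers <- normalizer_table(kernel, config$B)
  }
  # init: all singletons, informed per-series orders
  chain <- list(labels = seq_len(n),
                orders = vector("list", n),
                slm = numeric(n),
                last_move = c(move = "none", accepted = NA))
  # per-series informed draws; series whose draws coincide start co-clustered
  # (a valid state never holds one order in two clusters)
  init_keys <- character(0)
  for (i in seq_len(n)) {
    st <- psi_component_draw(kernel, i, config$L, config$q)
    k <- order_key(st$sizes)
    hit <- match(k, init_keys)
    if (is.na(hit)) {
      init_keys <- c(init_keys, k)
      lab <- length(init_keys)
      chain$orders[[lab]] <- st$sizes
    } else {
      lab <- hit
    }
    chain$labels[i] <- lab
    chain$slm[i] <- st$lm
  }
  chain$orders <- chain$orders[seq_along(init_keys)]
  keep <- config$M - config$burn_in
  assignment <- matrix(NA_integer_, keep, n)
  order_keys <- matrix(NA_character_, keep, n)
  lt <- numeric(keep)
  moves <- character(config$M)
  accepts <- logical(config$M)
  for (it in seq_len(config$M)) {
    if (n >= 2L) {
      chain <- mc_partition_step(chain, kernel, prior, config, normalizers)
      moves[it] <- chain$last_move[["move"]]
      accepts[it] <- as.logical(chain$last_move[["accepted"]])
    }
    if (config$refresh || n == 1L) {
      chain <- mc_refresh_step(chain, kernel, prior, config, normalizers)
    }
    if (identical(kernel$type, "sir") &&
        !identical(config$i0_updates, FALSE)) {
      for (i in seq_len(n)) {
        new_lm <- kernel$i0_step(i, chain$orders[[chain$labels[i]]])
        chain$slm[i] <- new_lm
      }
    }
    if (it > config$burn_in) {
      r <- it - config$burn_in
      assignment[r, ] <- chain$labels
      order_keys[r, ] <- vapply(chain$labels, function(lb) {
        order_key(chain$orders[[lb]])
      }, character(1L))
      csizes <- as.integer(table(chain$labels))
      lt[r] <- log_allocation_weight(csizes, prior, n) + sum(chain$slm)
    }
    if (progress && it %% 500L == 0L) {
      message(sprintf("iter %d/%d  k = %d  accept rate = %.2f", it, config$M,
                      length(unique(chain$labels)),
                      mean(accepts[seq_len(it)])))
    }
  }
  structure(list(assignment = assignment, order_keys = order_keys,
                 log_target = lt,
                 acceptance = data.frame(move = moves, accepted = accepts),
                 n = n, T = kernel$T, kernel_type = kernel$type,
                 config = config),
            class = "cp_trace")
}

#' @export
print.cp_trace <- function(x, ...) {
  cat("<cp_trace>", nrow(x$assignment), "retained iterations,", x$n,
      "series, T =", x$T, "(", x$kernel_type, "kernel )\n")
  k <- apply(x$assignment, 1L, function(r) length(unique(r)))
  cat("  clusters k: ", paste(names(table(k)), table(k), sep = ":",
                              collapse = "  "), "\n")
  invisible(x)
}
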