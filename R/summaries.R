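# Posterior summaries: Binder-loss point estimation, posterior similarity,
# and per-cluster change-point probability profiles.

#' Normalized Binder loss between two partitions
#'
#' The number of discordant pairs (together in one partition, apart in the
#' other, unit misclassification costs) divided by the number of pairs
#' \eqn{n(n-1)/2}, so the loss lies in `[0, 1]` and is comparable across `n`.
#'
#' @param p1,p2 partitions of the same `n` items, as label vectors (labels
#'   themselves are irrelevant, only the induced grouping matters).
#' @return loss in `[0, 1]`.
#' @examples
#' binder_loss(c(1, 1, 2), c(1, 2, 2))  # 2/3
#' @export
binder_loss <- function(p1, p2) {
  if (length(p1) != length(p2)) {
    stop("partitions must have the same length", call. = FALSE)
  }
  n <- length(p1)
  if (n < 2L) return(0)
  same1 <- outer(p1, p1, "==")
  same2 <- outer(p2, p2, "==")
  disc <- sum((same1 != same2)[upper.tri(same1)])
  disc / (n * (n - 1) / 2)
}

#' Posterior similarity matrix
#'
#' Entry (i, l) is the fraction of retained iterations in which series i and
#' l are co-clustered; symmetric with unit diagonal.
#'
#' @param trace a `"cp_trace"` from [run_mcmc()].
#' @return an `n x n` matrix of co-clustering frequencies.
#' @export
similarity_matrix <- function(trace) {
  stopifnot(inherits(trace, "cp_trace"))
  A <- trace$assignment
  if (nrow(A) == 0L) stop("empty trace", call. = FALSE)
  n <- ncol(A)
  S <- matrix(0, n, n)
  for (r in seq_len(nrow(A))) {
    S <- S + outer(A[r, ], A[r, ], "==")
  }
  S / nrow(A)
}

#' Binder point estimate of the latent partition
#'
#' Among the partitions visited by the chain, the one minimizing the expected
#' normalized Binder loss over the posterior sample (computable from the
#' similarity matrix); ties break by first occurrence, which also removes any
#' label-switching ambiguity.
#'
#' @param trace a `"cp_trace"` from [run_mcmc()].
#' @return a [cluster_state()]: the minimizing snapshot's assignment (labels
#'   renumbered by first appearance) and its cluster orders.
#' @export
point_estimate <- function(trace) {
  stopifnot(inherits(trace, "cp_trace"))
  A <- trace$assignment
  if (nrow(A) == 0L) stop("empty trace", call. = FALSE)
  n <- ncol(A)
  S <- similarity_matrix(trace)
  ut <- upper.tri(S)
  # expected loss of candidate partition lambda:
  # sum_{i<l} [ same_il (1 - S_il) + (1 - same_il) S_il ] / (n(n-1)/2)
  losses <- apply(A, 1L, function(lab) {
    same <- outer(lab, lab, "==")
    sum(ifelse(same[ut], 1 - S[ut], S[ut]))
  })
  best <- which.min(losses)  # first occurrence on ties
  lab <- A[best, ]
  canon <- match(lab, unique(lab))
  keys <- trace$order_keys[best, ]
  orders <- lapply(unique(lab), function(lb) {
    parse_order(keys[match(lb, lab)])
  })
  cluster_state(canon, orders)
}

#' Posterior change-point probabilities for one series
#'
#' For each time \eqn{t \in \{2, \dots, T\}}, the fraction of retained
#' iterations in which the order attached to the series' cluster has a change
#' point at \eqn{t} (a new block starting at \eqn{t}).
#'
#' @param trace a `"cp_trace"` from [run_mcmc()].
#' @param series series index in `1..n`.
#' @return numeric vector of length `T - 1`, named by times `2..T`.
#' @export
changepoint_probabilities <- function(trace, series) {
  stopifnot(inherits(trace, "cp_trace"))
  if (series < 1L || series > trace$n) {
    stop("series index out of range", call. = FALSE)
  }
  keys <- trace$order_keys[, series]
  if (length(keys) == 0L) stop("empty trace", call. = FALSE)
  T <- trace$T
  uk <- unique(keys)
  ind_by_key <- lapply(uk, function(k) order_to_indicators(parse_order(k)))
  counts <- numeric(max(T - 1L, 0L))
  tk <- table(keys)
  for (j in seq_along(uk)) {
    counts <- counts + ind_by_key[[j]] * as.numeric(tk[[uk[j]]])
  }
  p <- counts / length(keys)
  if (T > 1L) names(p) <- as.character(2:T)
  p
}

#' Full posterior summary
#'
#' Bundles the Binder point estimate, the posterior similarity matrix and the
#' per-cluster change-point probability profiles of the point estimate's
#' clusters.
#'
#' @param trace a `"cp_trace"` from [run_mcmc()].
#' @return a `"cp_summary"` list with elements `point_estimate`, `similarity`
#'   and `changepoint_prob` (one profile per cluster of the point estimate,
#'   computed from the first member series of each cluster).
#' @export
summarize_trace <- function(trace) {
  pe <- point_estimate(trace)
  S <- similarity_matrix(trace)
  labs <- sort(unique(pe$assignment))
  cp <- lapply(labs, function(lb) {
    changepoint_probabilities(trace, which(pe$assignment == lb)[1L])
  })
  names(cp) <- paste0("cluster_", labs)
  structure(list(point_estimate = pe, similarity = S, changepoint_prob = cp),
            class = "cp_summary")
}

#' @export
print.cp_summary <- function(x, ...) {
  k <- length(unique(x$point_estimate$assignment))
  cat("<cp_summary>", k, "clusters; assignment:",
      paste(x$point_estimate$assignment, collapse = " "), "\n")
  invisible(x)
}
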