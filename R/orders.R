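#' Random orders: contiguous partitions of the time axis
#'
#' A *random order* is a partition of the time indices \eqn{\{1, \dots, T\}}
#' into contiguous, increasing blocks. Each block is one regime of a time
#' series; the first index of every block after the first is a change point.
#' There are exactly \eqn{2^{T-1}} distinct orders of \eqn{T} times, in
#' bijection with the 0/1 change-indicator vector of length \eqn{T-1}
#' (indicator at position \eqn{t} marks a new block starting at \eqn{t+1}).
#'
#' Orders are stored as integer block-size vectors of class `"cp_order"`,
#' which keeps storage at O(number of blocks) and makes validation trivial.
#'
#' @param block_sizes positive integers summing to `T`.
#' @param T total number of time points. If missing, `sum(block_sizes)`.
#' @return An object of class `"cp_order"`: an integer vector of block sizes
#'   with attribute `T`.
#' @examples
#' make_order(c(2, 1))            # change point between times 2 and 3
#' order_to_indicators(make_order(c(2, 1)))   # c(0, 1)
#' @export
make_order <- function(block_sizes, T = sum(block_sizes)) {
  if (length(block_sizes) == 0L) {
    stop("an order needs at least one block", call. = FALSE)
  }
  bs <- as.integer(block_sizes)
  if (anyNA(bs) || any(bs < 1L)) {
    stop("block sizes must be positive integers", call. = FALSE)
  }
  if (sum(bs) != T) {
    stop("block sizes must sum to T (got sum ", sum(bs), ", T = ", T, ")",
         call. = FALSE)
  }
  structure(bs, T = as.integer(T), class = "cp_order")
}

#' @export
print.cp_order <- function(x, ...) {
  cat("<order> T =", attr(x, "T"), " blocks:", paste(unclass(x), collapse = ","),
      "\n")
  invisible(x)
}

#' @describeIn make_order change-indicator encoding: 0/1 vector of length
#'   `T - 1`, with a 1 at position `t` iff a new block starts at time `t + 1`.
#' @param order a `"cp_order"` object (or bare block-size vector).
#' @export
order_to_indicators <- function(order) {
  bs <- as.integer(order)
  T <- sum(bs)
  if (T == 1L) return(integer(0))
  ind <- integer(T - 1L)
  ends <- cumsum(bs)
  ind[ends[-length(ends)]] <- 1L
  ind
}

#' @describeIn make_order inverse of [order_to_indicators()].
#' @param indicators 0/1 vector of length `T - 1`.
#' @export
indicators_to_order <- function(indicators) {
  ind <- as.integer(indicators)
  if (anyNA(ind) || any(ind != 0L & ind != 1L)) {
    stop("indicators must be 0/1", call. = FALSE)
  }
  T <- length(ind) + 1L
  ends <- c(which(ind == 1L), T)
  make_order(diff(c(0L, ends)), T)
}

#' Enumerate all orders of T time points
#'
#' There are \eqn{2^{T-1}} orders; this walks all change-indicator vectors.
#' Guarded at `T <= 20` (beyond that the enumeration is astronomically large
#' and importance sampling is the intended tool).
#'
#' @param T number of time points (1 to 20).
#' @return list of `"cp_order"` objects, length `2^(T-1)`.
#' @export
enumerate_orders <- function(T) {
  T <- as.integer(T)
  if (T < 1L) stop("T must be >= 1", call. = FALSE)
  if (T > 20L) {
    stop("refusing to enumerate 2^(T-1) orders for T = ", T,
         " (> 20); use importance sampling instead", call. = FALSE)
  }
  if (T == 1L) return(list(make_order(1L)))
  n_ind <- T - 1L
  lapply(seq_len(2^n_ind) - 1L, function(code) {
    ind <- as.integer(intToBits(code))[seq_len(n_ind)]
    indicators_to_order(ind)
  })
}

#' Draw an order uniformly at random
#'
#' Each of the \eqn{2^{T-1}} orders has equal probability: the change
#' indicators are independent fair coins, so the number of blocks is
#' \eqn{1 + \mathrm{Binomial}(T-1, 1/2)}.
#'
#' @param T number of time points.
#' @return a `"cp_order"`.
#' @export
uniform_order <- function(T) {
  T <- as.integer(T)
  if (T < 1L) stop("T must be >= 1", call. = FALSE)
  if (T == 1L) return(make_order(1L))
  indicators_to_order(stats::rbinom(T - 1L, 1L, 0.5))
}

# Compact string key for an order ("2,1" style); used for caching and output.
order_key <- function(sizes) paste(as.integer(sizes), collapse = ",")

#' Serialize / parse orders
#'
#' Orders round-trip through a comma-separated block-size string (e.g.
#' `"50,100,45,55,50"`) and through a 0/1 indicator string; both appear in
#' output files.
#'
#' @param order a `"cp_order"`.
#' @export
format_order <- function(order) order_key(order)

#' @describeIn format_order parse a comma-separated block-size string.
#' @param x character scalar such as `"50,100,45,55,50"`.
#' @export
parse_order <- function(x) {
  make_order(as.integer(strsplit(x, ",", fixed = TRUE)[[1L]]))
}
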