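# File round-tripping: series/incidence CSVs, trace files, summary files,
# and run configuration.

fmt17 <- function(x) formatC(x, digits = 17, format = "g")

#' Read / write time-series and incidence matrices
#'
#' The on-disk format is a plain CSV with a header row of time labels and
#' one row per series, the series identifier in the first column. Incidence
#' files hold non-negative integers.
#'
#' @param path file path.
#' @param standardize if `TRUE`, marginally standardize each series after
#'   reading.
#' @return a numeric matrix with series identifiers as rownames.
#' @export
read_series_csv <- function(path, standardize = FALSE) {
  if (!file.exists(path)) stop("cannot read ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  y <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(y) <- "double"
  rownames(y) <- as.character(df[[1L]])
  if (anyNA(y)) stop("missing values in ", path, call. = FALSE)
  if (standardize) y <- t(scale(t(y)))
  y
}

#' @describeIn read_series_csv write a series matrix (17 significant digits,
#'   so write/read round-trips are exact for doubles).
#' @param y numeric matrix, one row per series.
#' @export
write_series_csv <- function(y, path) {
  y <- as.matrix(y)
  ids <- rownames(y)
  if (is.null(ids)) ids <- paste0("series_", seq_len(nrow(y)))
  df <- data.frame(id = ids,
                   matrix(vapply(y, fmt17, character(1L)), nrow(y)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("id", paste0("t", seq_len(ncol(y))))
  tmp <- paste0(path, ".tmp")
  utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' @describeIn read_series_csv read an incidence matrix (integer counts).
#' @export
read_incidence_csv <- function(path) {
  y <- read_series_csv(path)
  if (any(y < 0) || any(y != round(y))) {
    stop("incidence files must hold non-negative integer counts",
         call. = FALSE)
  }
  storage.mode(y) <- "integer"
  y
}

#' Write / read a trace file
#'
#' One row per retained iteration: the iteration index, the number of
#' clusters `k`, the assignment vector (`|`-separated), the per-cluster
#' order strings (`label:sizes` pairs, `;`-separated) and the log target.
#'
#' @param trace a `"cp_trace"`.
#' @param path file path.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "cp_trace"))
  A <- trace$assignment
  rows <- vapply(seq_len(nrow(A)), function(r) {
    lab <- A[r, ]
    keys <- trace$order_keys[r, ]
    ulab <- unique(lab)
    ostr <- paste(vapply(ulab, function(lb) {
      paste0(lb, ":", keys[match(lb, lab)])
    }, character(1L)), collapse = ";")
    paste(r, length(ulab), paste(lab, collapse = "|"), ostr,
          fmt17(trace$log_target[r]), sep = ",")
  }, character(1L))
  tmp <- paste0(path, ".tmp")
  writeLines(c("iteration,k,assignment,orders,log_target", rows), tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' @describeIn write_trace_csv read a trace file back into a `"cp_trace"`
#'   (metadata such as the kernel type is not recorded on disk).
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("empty trace file ", path, call. = FALSE)
  parts <- strsplit(lines[-1L], ",", fixed = TRUE)
  # orders field itself contains commas inside size strings, so re-join:
  # fields are iteration, k, assignment, orders..., log_target
  n_iter <- length(parts)
  asg_list <- vector("list", n_iter)
  key_list <- vector("list", n_iter)
  lt <- numeric(n_iter)
  for (r in seq_len(n_iter)) {
    p <- parts[[r]]
    lab <- as.integer(strsplit(p[3L], "|", fixed = TRUE)[[1L]])
    ostr <- paste(p[4:(length(p) - 1L)], collapse = ",")
    lt[r] <- as.numeric(p[length(p)])
    omap <- strsplit(strsplit(ostr, ";", fixed = TRUE)[[1L]], ":",
                     fixed = TRUE)
    keys <- character(max(lab))
    for (o in omap) keys[as.integer(o[1L])] <- o[2L]
    asg_list[[r]] <- lab
    key_list[[r]] <- keys[lab]
  }
  A <- do.call(rbind, asg_list)
  K <- do.call(rbind, key_list)
  T <- sum(as.integer(parse_order(K[1L, 1L])))
  structure(list(assignment = A, order_keys = K, log_target = lt,
                 acceptance = NULL, n = ncol(A), T = T,
                 kernel_type = "unknown", config = NULL),
            class = "cp_trace")
}

#' Write summary files
#'
#' Writes the point-estimate assignment, the posterior similarity matrix and
#' the per-cluster change-point probability profiles as CSVs under a common
#' prefix (`<prefix>_assignment.csv`, `<prefix>_similarity.csv`,
#' `<prefix>_changepoints.csv`).
#'
#' @param summary a `"cp_summary"` from [summarize_trace()].
#' @param prefix path prefix for the output files.
#' @return the three paths, invisibly.
#' @export
write_summary_files <- function(summary, prefix) {
  stopifnot(inherits(summary, "cp_summary"))
  pe <- summary$point_estimate
  p1 <- paste0(prefix, "_assignment.csv")
  labs <- pe$assignment
  ord <- vapply(labs, function(lb) format_order(pe$cluster_orders[[lb]]),
                character(1L))
  utils::write.csv(data.frame(series = seq_along(labs), cluster = labs,
                              order = ord),
                   p1, row.names = FALSE, quote = 3)
  p2 <- paste0(prefix, "_similarity.csv")
  utils::write.csv(summary$similarity, p2, row.names = FALSE)
  p3 <- paste0(prefix, "_changepoints.csv")
  cp <- summary$changepoint_prob
  df <- data.frame(time = as.integer(names(cp[[1L]])),
                   do.call(cbind, cp), check.names = FALSE)
  utils::write.csv(df, p3, row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2, p3))
}

#' Read a run-configuration file
#'
#' JSON (always available) or YAML (if the `yaml` package is installed) with
#' any of the keys understood by the command line: kernel settings,
#' Dirichlet `alpha`, and sampler settings. Flat key-value pairs; unknown
#' keys are rejected.
#'
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return a named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("cannot read ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is needed for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  allowed <- c("kernel", "gamma", "a", "b", "c", "alpha", "xi", "beta_shape",
               "beta_rate", "mc_draws", "grid_step", "iterations", "burn_in",
               "q", "L", "B", "refresh", "seed", "standardize", "window_low",
               "window_high")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  cfg
}
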