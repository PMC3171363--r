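#' Box-plot outlier detection on distances to the assigned center
#'
#' For every non-empty cluster, computes each member's Euclidean distance to
#' the cluster center, the Tukey quartiles of those distances (linear
#' interpolation between order statistics, `quantile(type = 7)`), and flags
#' members beyond the upper fence `Q3 + 1.5 * IQR` as outliers.  Distances
#' are non-negative and right-skewed, so only the upper fence flags; clusters
#' with fewer than four members are summarized but never flagged.
#'
#' @param points A [point_set()].
#' @param result A `feskm_result` (or any list with `assignments`, `centers`,
#'   `k`).
#' @return An object of class `outlier_report`: list with `records` (data
#'   frame `id`, `cluster`, `distance`, `is_outlier`), `clusters` (per-cluster
#'   data frame `cluster`, `n`, `q1`, `median`, `q3`, `iqr`, `upper_fence`,
#'   `n_outliers`) and `dead_centers`.
#' @export
distance_outliers <- function(points, result) {
  stopifnot(inherits(points, "pointset"))
  C <- center_matrix(result$centers)
  lab <- result$assignments
  check_labels(lab, points$n, nrow(C))
  distance <- sqrt(rowSums((points$coords - C[lab, , drop = FALSE])^2))
  live <- sort(unique(lab))
  is_outlier <- logical(points$n)
  rows <- lapply(live, function(j) {
    sel <- lab == j
    d <- distance[sel]
    q <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    fence <- q[3] + 1.5 * iqr
    flag <- if (sum(sel) >= 4L) d > fence else rep(FALSE, sum(sel))
    is_outlier[sel] <<- flag
    data.frame(cluster = j, n = sum(sel), q1 = q[1], median = q[2],
               q3 = q[3], iqr = iqr, upper_fence = fence,
               n_outliers = sum(flag))
  })
  structure(list(
    records = data.frame(id = points$ids, cluster = lab,
                         distance = distance, is_outlier = is_outlier),
    clusters = do.call(rbind, rows),
    dead_centers = setdiff(seq_len(nrow(C)), live)
  ), class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("<outlier report> %d clusters, %d flagged record(s)\n",
              nrow(x$clusters), sum(x$records$is_outlier)))
  invisible(x)
}

#' Benchmark the three methods over increasing fractions of the data
#'
#' For each fraction a seeded random subsample without replacement is drawn
#' (the same subsample for all three methods) and each method runs under the
#' given configuration; wall-clock runtime and the final MSE in dB are
#' recorded.  One record per method x fraction.  Runtimes are informational
#' — they depend on the machine — while the MSE column is deterministic
#' under a fixed seed.
#'
#' @param points A [point_set()].
#' @param config A [run_config()]; its `method` field is ignored (all three
#'   run).
#' @param fractions Percentages of the data to process, in (0, 100].
#'   Default `seq(10, 100, by = 10)`.
#' @param seed Seed for the subsample draws.
#' @param methods Methods to benchmark (default all three).
#' @return Data frame with columns `method`, `fraction`, `n_points`,
#'   `runtime_s`, `mse_db`, `seed`.
#' @export
run_benchmark <- function(points, config, fractions = seq(10, 100, by = 10),
                          seed = 1L,
                          methods = c("lloyd", "macqueen", "fes")) {
  stopifnot(inherits(points, "pointset"), inherits(config, "run_config"))
  if (any(fractions <= 0 | fractions > 100)) {
    stop("`fractions` must lie in (0, 100]", call. = FALSE)
  }
  out <- vector("list", length(fractions) * length(methods))
  r <- 0L
  for (fi in seq_along(fractions)) {
    f <- fractions[fi]
    n_f <- as.integer(round(f * points$n / 100))
    if (n_f < config$k) {
      stop(sprintf("fraction %g%% yields %d points, fewer than k = %d",
                   f, n_f, config$k), call. = FALSE)
    }
    idx <- with_seed(seed + fi, sample.int(points$n, n_f))
    sub <- point_set(points$coords[idx, , drop = FALSE],
                     ids = points$ids[idx], dim_names = points$dim_names)
    for (m in methods) {
      cfg <- config
      cfg$method <- m
      elapsed <- system.time(res <- run_clustering(sub, cfg))[["elapsed"]]
      r <- r + 1L
      out[[r]] <- data.frame(
        method = m, fraction = f, n_points = n_f, runtime_s = elapsed,
        mse_db = suppressWarnings(mse_db(sub, res$assignments, res$centers)),
        seed = seed)
    }
  }
  do.call(rbind, out)
}
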