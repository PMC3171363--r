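#' Run configuration for the k-means variants
#'
#' One configuration object drives all three methods so that comparisons
#' (benchmarks, oracle checks) run under identical settings.
#'
#' @param k Number of clusters (>= 1).
#' @param method One of `"fes"`, `"lloyd"`, `"macqueen"`.
#' @param eta0 Initial adaptation rate for the FES update, in (0, 1].
#'   Default 0.6: large enough for fast early movement, comfortably below a
#'   full replacement step.
#' @param epsilon Convergence tolerance on the maximum per-center Euclidean
#'   displacement within one epoch.  Default `1e-4` (coordinate units).
#' @param max_iter Maximum number of epochs (full passes over the data).
#'   Default 20.
#' @param seed Optional integer seed controlling center initialization and
#'   any presentation-order shuffling; the caller's RNG stream is restored
#'   afterwards.
#' @param shuffle Present records in a fresh random order every epoch
#'   (online methods only).  Default `FALSE`: dataset order.
#' @param leaf_size k-d tree leaf size used by [fes_kmeans()].
#' @param reseed_dead Relocate a center that finished an epoch with no
#'   members to the point farthest from its nearest center.  Default `FALSE`:
#'   dead centers are kept in place and reported.
#' @return An object of class `run_config`.
#' @export
run_config <- function(k, method = c("fes", "lloyd", "macqueen"), eta0 = 0.6,
                       epsilon = 1e-4, max_iter = 20, seed = NULL,
                       shuffle = FALSE, leaf_size = 10, reseed_dead = FALSE) {
  method <- match.arg(method)
  k <- stop_if_not_count(k, "k")
  max_iter <- stop_if_not_count(max_iter, "max_iter")
  leaf_size <- stop_if_not_count(leaf_size, "leaf_size")
  if (!is.numeric(eta0) || length(eta0) != 1L || eta0 <= 0 || eta0 > 1) {
    stop("`eta0` must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0) {
    stop("`epsilon` must be positive", call. = FALSE)
  }
  structure(list(k = k, method = method, eta0 = eta0, epsilon = epsilon,
                 max_iter = max_iter, seed = seed, shuffle = isTRUE(shuffle),
                 leaf_size = leaf_size, reseed_dead = isTRUE(reseed_dead)),
            class = "run_config")
}

center_matrix <- function(centers) {
  if (inherits(centers, "centerset")) return(centers$centers)
  C <- as.matrix(centers)
  storage.mode(C) <- "double"
  C
}

#' Initialize cluster centers from the data
#'
#' Draws `k` distinct records uniformly without replacement; centers start at
#' actual data locations.
#'
#' @param points A [point_set()].
#' @param k Number of centers, `1 <= k <= N`.
#' @param seed Optional seed for a reproducible draw.
#' @return An object of class `centerset`: list with `centers` (k x d
#'   matrix), `k` and `init_idx` (the sampled row indices).
#' @export
init_centers <- function(points, k, seed = NULL) {
  stopifnot(inherits(points, "pointset"))
  k <- stop_if_not_count(k, "k")
  if (k > points$n) stop("`k` cannot exceed the number of records",
                         call. = FALSE)
  idx <- with_seed(seed, sample.int(points$n, k))
  structure(list(centers = points$coords[idx, , drop = FALSE], k = k,
                 init_idx = idx),
            class = "centerset")
}

#' Mashor adaptation-rate update
#'
#' Advances the decaying learning-rate schedule
#' `eta <- eta / exp(1 / sqrt(cluster_count + iter))`, then increments the
#' epoch counter.  The rate starts large and decays toward a small steady
#' state: the decay factor tends to 1 as `iter` grows.
#'
#' @param state List with `eta` (current rate, positive), `iter` (epoch
#'   counter, starting at 1) and `cluster_count` (the number of clusters k).
#' @return The updated state.
#' @examples
#' mashor_eta_update(list(eta = 1, iter = 1, cluster_count = 10))$eta
#' @export
mashor_eta_update <- function(state) {
  if (!is.numeric(state$eta) || state$eta <= 0) {
    stop("`eta` must be positive", call. = FALSE)
  }
  state$eta <- state$eta / exp(1 / sqrt(state$cluster_count + state$iter))
  state$iter <- state$iter + 1L
  state
}

#' Single FES center update
#'
#' Moves a center a fraction `eta` of the way toward a presented point:
#' `center + eta * (point - center)`.
#'
#' @param center,point Numeric vectors of equal length.
#' @param eta Step size in `[0, 1]`.
#' @return The displaced center.
#' @examples
#' fes_update_center(c(0, 0), c(2, 4), 0.5)
#' @export
fes_update_center <- function(center, point, eta) {
  if (length(center) != length(point)) {
    stop("`center` and `point` must have the same dimension", call. = FALSE)
  }
  if (!is.numeric(eta) || length(eta) != 1L || eta < 0 || eta > 1) {
    stop("`eta` must lie in [0, 1]", call. = FALSE)
  }
  center + eta * (point - center)
}

# One MacQueen step: the winning center, having previously won `wins`
# records (the initializing record included), absorbs `point` and moves to
# the running mean of all its wins.
macqueen_update <- function(center, point, wins) {
  wins <- wins + 1
  list(center = center + (point - center) / wins, wins = wins)
}

# Move each dead center to the point farthest from its nearest live center.
reseed_dead_centers <- function(X, C, labels, dead) {
  for (j in dead) {
    dist_to_own <- rowSums((X - C[labels, , drop = FALSE])^2)
    far <- which.max(dist_to_own)
    C[j, ] <- X[far, ]
  }
  C
}

new_result <- function(method, assignments, C, k, n_iter, mse_trace,
                       eta_trace, converged, reason, config,
                       n_dist_evals = NA_real_, init_idx = NULL) {
  structure(list(
    method = method, assignments = assignments, centers = C, k = k,
    n_iter = n_iter, mse_trace = mse_trace, eta_trace = eta_trace,
    converged = converged, reason = reason,
    dead_centers = setdiff(seq_len(k), sort(unique(assignments))),
    n_dist_evals = n_dist_evals, config = config, init_idx = init_idx
  ), class = "feskm_result")
}

#' @export
print.feskm_result <- function(x, ...) {
  cat(sprintf("<%s k-means> k=%d, %d epochs (%s), final MSE %.6g\n",
              x$method, x$k, x$n_iter, x$reason,
              x$mse_trace[length(x$mse_trace)]))
  if (length(x$dead_centers)) {
    cat("  dead centers:", paste(x$dead_centers, collapse = ", "), "\n")
  }
  invisible(x)
}

check_config <- function(points, config) {
  stopifnot(inherits(points, "pointset"), inherits(config, "run_config"))
  if (config$k > points$n) {
    stop("`k` cannot exceed the number of records", call. = FALSE)
  }
}

#' Batch (Lloyd) k-means
#'
#' The standard alternating scheme: assign every record to its nearest
#' center, then move every non-empty center to the centroid of its members.
#' The recorded MSE trace (within-class variance divided by N, evaluated
#' after each centroid update) is non-increasing.  Terminates when cluster
#' membership stops changing, when the largest center displacement falls
#' below `epsilon`, or after `max_iter` epochs.
#'
#' @param points A [point_set()].
#' @param config A [run_config()].
#' @return A `feskm_result`; see [fes_kmeans()] for the fields.
#' @export
lloyd_kmeans <- function(points, config) {
  check_config(points, config)
  with_seed(config$seed, {
    X <- points$coords
    k <- config$k
    cs <- init_centers(points, k)
    C <- cs$centers
    prev_lab <- NULL
    mse_trace <- numeric(0)
    reason <- "max_iter"
    converged <- FALSE
    lab <- integer(points$n)
    for (it in seq_len(config$max_iter)) {
      lab <- argmin_rows(dist2_matrix(X, C))
      Cold <- C
      for (j in seq_len(k)) {
        sel <- lab == j
        if (any(sel)) C[j, ] <- colMeans(X[sel, , drop = FALSE])
      }
      if (config$reseed_dead) {
        dead <- setdiff(seq_len(k), unique(lab))
        if (length(dead)) C <- reseed_dead_centers(X, C, lab, dead)
      }
      mse_trace <- c(mse_trace, sum(rowSums((X - C[lab, , drop = FALSE])^2)) /
                       points$n)
      if (!is.null(prev_lab) && all(lab == prev_lab)) {
        reason <- "membership_stable"; converged <- TRUE; break
      }
      shift <- sqrt(max(rowSums((C - Cold)^2)))
      if (shift < config$epsilon) {
        reason <- "center_change"; converged <- TRUE; break
      }
      prev_lab <- lab
    }
    lab <- argmin_rows(dist2_matrix(X, C))
    new_result("lloyd", lab, C, k, length(mse_trace), mse_trace, NULL,
               converged, reason, config, init_idx = cs$init_idx)
  })
}

#' Online (MacQueen) k-means
#'
#' Records are presented one at a time; the winning center moves by
#' `1/n_i` of its difference to the presented point, where `n_i` is the
#' center's cumulative win count including the record that initialized it.
#' After each full pass, membership is recomputed and the same convergence
#' tests as [lloyd_kmeans()] are applied.
#'
#' @inheritParams lloyd_kmeans
#' @return A `feskm_result`.
#' @export
macqueen_kmeans <- function(points, config) {
  check_config(points, config)
  with_seed(config$seed, {
    X <- points$coords
    k <- config$k
    cs <- init_centers(points, k)
    C <- cs$centers
    wins <- rep(1, k)          # the initializing record counts as a win
    prev_lab <- NULL
    mse_trace <- numeric(0)
    reason <- "max_iter"
    converged <- FALSE
    lab <- integer(points$n)
    for (it in seq_len(config$max_iter)) {
      ord <- if (config$shuffle) sample.int(points$n) else seq_len(points$n)
      Cold <- C
      for (nn in ord) {
        x <- X[nn, ]
        j <- which.min(dist2_to_rows(x, C))
        up <- macqueen_update(C[j, ], x, wins[j])
        wins[j] <- up$wins
        C[j, ] <- up$center
      }
      lab <- argmin_rows(dist2_matrix(X, C))
      if (config$reseed_dead) {
        dead <- setdiff(seq_len(k), unique(lab))
        if (length(dead)) {
          C <- reseed_dead_centers(X, C, lab, dead)
          lab <- argmin_rows(dist2_matrix(X, C))
        }
      }
      mse_trace <- c(mse_trace, sum(rowSums((X - C[lab, , drop = FALSE])^2)) /
                       points$n)
      if (!is.null(prev_lab) && all(lab == prev_lab)) {
        reason <- "membership_stable"; converged <- TRUE; break
      }
      shift <- sqrt(max(rowSums((C - Cold)^2)))
      if (shift < config$epsilon) {
        reason <- "center_change"; converged <- TRUE; break
      }
      prev_lab <- lab
    }
    new_result("macqueen", lab, C, k, length(mse_trace), mse_trace, NULL,
               converged, reason, config, init_idx = cs$init_idx)
  })
}

#' FES-k-means: k-d-tree-filtered k-means with Mashor's adaptation rate
#'
#' Builds the k-d tree once, initializes centers at `k` random records, and
#' then iterates epochs: every record is assigned to its nearest center
#' (tree filtering against the centers as of the start of the epoch —
#' identical, label for label, to a brute-force nearest-center scan), the
#' records are presented in order and each moves its assigned center by
#' [fes_update_center()] with the epoch's adaptation rate, and the rate then
#' decays by [mashor_eta_update()].  Convergence is declared when membership
#' stops changing, the largest center displacement in an epoch falls below
#' `epsilon`, the MSE stabilizes (relative change below `1e-8`), or
#' `max_iter` epochs have run.
#'
#' @inheritParams lloyd_kmeans
#' @return An object of class `feskm_result` with fields `assignments`
#'   (labels in `1..k`, computed against the final centers), `centers`,
#'   `n_iter`, `mse_trace` (per-epoch MSE = within-class variance / N),
#'   `eta_trace` (per-epoch adaptation rate actually used), `converged`,
#'   `reason`, `dead_centers`, and `n_dist_evals` — the instrumented count of
#'   point-to-center distance evaluations (tree-filter leaf work plus the
#'   per-epoch MSE pass), comparable against the brute-force cost
#'   `N * k * epochs`.
#' @examples
#' g <- generate_blobs(synth_spec(n_clusters = 3, points_per_cluster = 50,
#'                                seed = 7))
#' res <- fes_kmeans(g$points, run_config(k = 3, seed = 1))
#' res$k - length(res$dead_centers)   # non-empty clusters
#' @export
fes_kmeans <- function(points, config) {
  check_config(points, config)
  with_seed(config$seed, {
    X <- points$coords
    k <- config$k
    tree <- build_kdtree(points, config$leaf_size)
    cs <- init_centers(points, k)
    C <- cs$centers
    eta <- config$eta0
    state <- list(eta = eta, iter = 1L, cluster_count = k)
    prev_lab <- NULL
    prev_mse <- NULL
    mse_trace <- numeric(0)
    eta_trace <- numeric(0)
    evals <- 0
    reason <- "max_iter"
    converged <- FALSE
    for (it in seq_len(config$max_iter)) {
      fa <- filter_assign(tree, C)
      lab <- fa$assignments
      evals <- evals + fa$n_dist_evals
      ord <- if (config$shuffle) sample.int(points$n) else seq_len(points$n)
      Cold <- C
      for (nn in ord) {
        j <- lab[nn]
        C[j, ] <- C[j, ] + eta * (X[nn, ] - C[j, ])
      }
      if (config$reseed_dead) {
        dead <- setdiff(seq_len(k), unique(lab))
        if (length(dead)) C <- reseed_dead_centers(X, C, lab, dead)
      }
      eta_trace <- c(eta_trace, eta)
      state <- mashor_eta_update(state)
      eta <- state$eta
      mse <- sum(rowSums((X - C[lab, , drop = FALSE])^2)) / points$n
      evals <- evals + points$n
      mse_trace <- c(mse_trace, mse)
      if (!is.null(prev_lab) && all(lab == prev_lab)) {
        reason <- "membership_stable"; converged <- TRUE; break
      }
      shift <- sqrt(max(rowSums((C - Cold)^2)))
      if (shift < config$epsilon) {
        reason <- "center_change"; converged <- TRUE; break
      }
      if (!is.null(prev_mse) &&
          abs(mse - prev_mse) < 1e-8 * max(prev_mse, .Machine$double.eps)) {
        reason <- "mse_stable"; converged <- TRUE; break
      }
      prev_lab <- lab
      prev_mse <- mse
    }
    fa <- filter_assign(tree, C)
    evals <- evals + fa$n_dist_evals
    new_result("fes", fa$assignments, C, k, length(mse_trace), mse_trace,
               eta_trace, converged, reason, config,
               n_dist_evals = evals, init_idx = cs$init_idx)
  })
}

#' Dispatch a clustering run from a configuration
#'
#' @inheritParams lloyd_kmeans
#' @return A `feskm_result` from the method named in `config$method`.
#' @export
run_clustering <- function(points, config) {
  switch(config$method,
         fes = fes_kmeans(points, config),
         lloyd = lloyd_kmeans(points, config),
         macqueen = macqueen_kmeans(points, config))
}
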