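# Independent oracles and small generators used across the suite.

rand_pointset <- function(n, d, seed, duplicates = FALSE) {
  set.seed(seed)
  X <- matrix(stats::runif(n * d, -10, 10), n, d)
  if (duplicates && n >= 4) {
    X[2, ] <- X[1, ]                       # exact duplicate pair
    X[n, ] <- X[n - 1, ]
  }
  point_set(X)
}

# Linear-scan nearest neighbor: ties to the lowest index via which.min.
brute_nn <- function(X, q) {
  d2 <- colSums((t(X) - q)^2)
  i <- which.min(d2)
  list(index = i, distance = sqrt(d2[i]))
}

# Brute-force nearest-center labels, ties to the lowest center index.
brute_assign <- function(X, C) {
  n <- nrow(X)
  d2 <- matrix(0, n, nrow(C))
  for (j in seq_len(nrow(C))) {
    d2[, j] <- rowSums((X - rep(C[j, ], each = n))^2)
  }
  max.col(-d2, ties.method = "first")
}

# Standalone brute-force FES variant: no k-d tree, sequential presentation,
# winners taken against the centers frozen at the start of each epoch.
# Mirrors the contract of fes_kmeans() step for step so that the tree path
# must reproduce it bitwise.
fes_brute <- function(points, config) {
  feskmeans:::with_seed(config$seed, {
    X <- points$coords
    n <- nrow(X)
    k <- config$k
    cs <- init_centers(points, k)
    C <- cs$centers
    eta <- config$eta0
    iter <- 1L
    prev_lab <- NULL
    prev_mse <- NULL
    mse_trace <- numeric(0)
    eta_trace <- numeric(0)
    reason <- "max_iter"
    for (it in seq_len(config$max_iter)) {
      lab <- brute_assign(X, C)
      ord <- if (config$shuffle) sample.int(n) else seq_len(n)
      Cold <- C
      for (nn in ord) {
        j <- lab[nn]
        C[j, ] <- C[j, ] + eta * (X[nn, ] - C[j, ])
      }
      eta_trace <- c(eta_trace, eta)
      eta <- eta / exp(1 / sqrt(k + iter))
      iter <- iter + 1L
      mse <- sum(rowSums((X - C[lab, , drop = FALSE])^2)) / n
      mse_trace <- c(mse_trace, mse)
      if (!is.null(prev_lab) && all(lab == prev_lab)) {
        reason <- "membership_stable"; break
      }
      shift <- sqrt(max(rowSums((C - Cold)^2)))
      if (shift < config$epsilon) {
        reason <- "center_change"; break
      }
      if (!is.null(prev_mse) &&
          abs(mse - prev_mse) < 1e-8 * max(prev_mse, .Machine$double.eps)) {
        reason <- "mse_stable"; break
      }
      prev_lab <- lab
      prev_mse <- mse
    }
    list(assignments = brute_assign(X, C), centers = C,
         eta_trace = eta_trace, mse_trace = mse_trace, reason = reason)
  })
}

# Davies-Bouldin computed a second way: explicit loops, no dist()/outer().
dbi_reference <- function(X, lab, C) {
  live <- sort(unique(lab))
  m <- length(live)
  e <- numeric(m)
  for (a in seq_len(m)) {
    mem <- X[lab == live[a], , drop = FALSE]
    s <- 0
    for (r in seq_len(nrow(mem))) {
      s <- s + sqrt(sum((mem[r, ] - C[live[a], ])^2))
    }
    e[a] <- s / nrow(mem)
  }
  total <- 0
  for (a in seq_len(m)) {
    worst <- -Inf
    for (b in seq_len(m)) {
      if (a == b) next
      D <- sqrt(sum((C[live[a], ] - C[live[b], ])^2))
      worst <- max(worst, (e[a] + e[b]) / D)
    }
    total <- total + worst
  }
  total / m
}

# Tukey quartiles by explicit order-statistic interpolation (type 7).
quartile_reference <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Permutation-corrected label agreement for small k (exhaustive matching).
perm_agreement <- function(lab, truth) {
  k <- max(truth, lab)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- 0
  for (p in perms(seq_len(k))) {
    best <- max(best, mean(p[lab] == truth))
  }
  best
}

# All leaf nodes of a kd-tree, left to right.
collect_leaves <- function(node) {
  if (node$leaf) return(list(node))
  c(collect_leaves(node$left), collect_leaves(node$right))
}

separated_blobs <- function(n_clusters, per_cluster, seed, spread = 1,
                            box = c(0, 100)) {
  generate_blobs(synth_spec(n_clusters = n_clusters,
                            points_per_cluster = per_cluster, dim = 2,
                            center_box = box, base_spread = spread,
                            seed = seed))
}
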