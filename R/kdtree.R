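#' Build a k-d tree over a point set
#'
#' Recursive axis-aligned subdivision of the data: at every internal node the
#' cell (the tight bounding box of the node's points) is split at the midpoint
#' of its longest side; ties between equally long sides go to the lowest
#' dimension index, and points lying exactly on the splitting value go to the
#' left child.  Should a midpoint ever fail to separate the points, the split
#' slides to the median coordinate so that each splitting hyperplane leaves a
#' data point on both sides.  Recursion stops when a node holds at most
#' `leaf_size` points, or when all its points coincide (such a leaf may exceed
#' `leaf_size`).  Every node carries its point count and coordinate sum, so
#' whole subtrees can later be assigned to a cluster center in one step.
#'
#' @param points A [point_set()].
#' @param leaf_size Maximum number of points per leaf (default 10).
#' @return An object of class `kdtree` with elements `root`, `leaf_size` and
#'   `points`.  Nodes are nested lists with fields `lo`, `hi` (cell bounds),
#'   `count`, `vsum`, `idx` (row indices into the point set), `leaf`, and for
#'   internal nodes `split_dim`, `split_val`, `left`, `right`.
#' @examples
#' ps <- point_set(matrix(runif(60), 30, 2))
#' tr <- build_kdtree(ps, leaf_size = 4)
#' tr$root$count
#' @export
build_kdtree <- function(points, leaf_size = 10) {
  stopifnot(inherits(points, "pointset"))
  leaf_size <- stop_if_not_count(leaf_size, "leaf_size")
  root <- kd_build(points$coords, seq_len(points$n), leaf_size)
  structure(list(root = root, leaf_size = leaf_size, points = points),
            class = "kdtree")
}

kd_build <- function(X, idx, leaf_size) {
  pts <- X[idx, , drop = FALSE]
  lo <- apply(pts, 2, min)
  hi <- apply(pts, 2, max)
  ext <- hi - lo
  n <- length(idx)
  if (n <= leaf_size || all(ext == 0)) {
    return(list(lo = lo, hi = hi, count = n, vsum = colSums(pts),
                idx = idx, leaf = TRUE))
  }
  dim <- unname(which.max(ext))    # first maximum = lowest dimension index
  val <- unname((lo[dim] + hi[dim]) / 2)
  left_mask <- pts[, dim] <= val
  if (!any(left_mask) || all(left_mask)) {
    # Sliding midpoint: with tight cells the midpoint always separates the
    # min from the max along the longest side, so this is defensive only.
    val <- unname(stats::median(pts[, dim]))
    left_mask <- pts[, dim] <= val
    if (!any(left_mask) || all(left_mask)) {
      return(list(lo = lo, hi = hi, count = n, vsum = colSums(pts),
                  idx = idx, leaf = TRUE))
    }
  }
  left <- kd_build(X, idx[left_mask], leaf_size)
  right <- kd_build(X, idx[!left_mask], leaf_size)
  list(lo = lo, hi = hi, count = n, vsum = left$vsum + right$vsum,
       idx = idx, leaf = FALSE,
       split_dim = dim, split_val = val, left = left, right = right)
}

#' @export
print.kdtree <- function(x, ...) {
  cat(sprintf("<kdtree> %d points, %d dims, leaf_size %d\n",
              x$root$count, length(x$root$lo), x$leaf_size))
  invisible(x)
}

# Smallest squared distance from query q to the closed box [lo, hi].
box_mindist2 <- function(lo, hi, q) {
  d <- pmax(lo - q, q - hi, 0)
  sum(d * d)
}

#' Exact nearest neighbor query
#'
#' Returns the index of the stored point closest (Euclidean) to `query`,
#' descending the tree toward the query's cell first and pruning any subtree
#' whose cell cannot beat the best distance found so far.  Exact ties are
#' broken to the lowest point index.
#'
#' @param tree A [build_kdtree()] result.
#' @param query Numeric vector of the tree's dimensionality.
#' @return A list with `index` (row index into the point set) and `distance`
#'   (Euclidean).
#' @examples
#' ps <- point_set(rbind(c(0, 0), c(10, 10)))
#' nearest_neighbor(build_kdtree(ps), c(1, 1))
#' @export
nearest_neighbor <- function(tree, query) {
  stopifnot(inherits(tree, "kdtree"))
  query <- as.numeric(query)
  if (length(query) != tree$points$d) {
    stop("query dimension does not match the tree", call. = FALSE)
  }
  st <- new.env(parent = emptyenv())
  st$best_d2 <- Inf
  st$best_idx <- NA_integer_
  kd_nn(tree$root, tree$points$coords, query, st)
  list(index = st$best_idx, distance = sqrt(st$best_d2))
}

kd_nn <- function(node, X, q, st) {
  if (box_mindist2(node$lo, node$hi, q) > st$best_d2) return(invisible())
  if (node$leaf) {
    pts <- X[node$idx, , drop = FALSE]
    d2 <- colSums((t(pts) - q)^2)
    m <- min(d2)
    i <- min(node$idx[d2 == m])
    if (m < st$best_d2 || (m == st$best_d2 && i < st$best_idx)) {
      st$best_d2 <- m
      st$best_idx <- i
    }
    return(invisible())
  }
  if (q[node$split_dim] <= node$split_val) {
    kd_nn(node$left, X, q, st)
    kd_nn(node$right, X, q, st)
  } else {
    kd_nn(node$right, X, q, st)
    kd_nn(node$left, X, q, st)
  }
  invisible()
}

#' Candidate-center pruning test
#'
#' Decides whether `candidate` can be discarded for an entire cell: it returns
#' `TRUE` exactly when no point of the closed box `[bbox_lo, bbox_hi]` is
#' strictly closer to `candidate` than to `winner`.  Because the difference of
#' the two squared distances is linear in the box point, it suffices to test
#' the box corner extremal in the direction `candidate - winner`; the test is
#' therefore exact (lossless).
#'
#' @param bbox_lo,bbox_hi Numeric vectors, the closed cell bounds
#'   (`bbox_lo <= bbox_hi` componentwise).
#' @param candidate,winner Numeric center coordinates, `candidate != winner`.
#' @return `TRUE` if the candidate is provably never the strict winner inside
#'   the box.
#' @examples
#' prune_candidate(c(0, 0), c(1, 1), candidate = c(10, 10), winner = c(.5, .5))
#' @export
prune_candidate <- function(bbox_lo, bbox_hi, candidate, winner) {
  if (any(bbox_lo > bbox_hi)) stop("invalid box: bbox_lo > bbox_hi",
                                   call. = FALSE)
  v <- candidate - winner
  p <- ifelse(v > 0, bbox_hi, bbox_lo)
  sum((p - candidate)^2) >= sum((p - winner)^2)
}

# Directional pruning used inside filter_assign: identical corner test, but
# on an exact tie the point goes to the lower center index, so a candidate
# with a lower index than the current winner survives a tie.
prune_candidate_idx <- function(lo, hi, C, j, w) {
  v <- C[j, ] - C[w, ]
  p <- ifelse(v > 0, hi, lo)
  dc <- sum((p - C[j, ])^2)
  dw <- sum((p - C[w, ])^2)
  if (j < w) dc > dw else dc >= dw
}

#' Assign every point to its nearest center by tree filtering
#'
#' Traverses the tree with the full center list as candidates at the root.
#' At each node the candidate closest to the cell midpoint is kept as the
#' local winner and every other candidate is pruned when no point of the cell
#' can be strictly closer to it (ties to the lowest center index).  When a
#' single candidate survives, the whole subtree is assigned in bulk from the
#' node's stored point count and coordinate sum without touching individual
#' points.  The labels are contractually identical to a brute-force
#' nearest-center scan; only the amount of distance arithmetic differs.
#'
#' Centers that coincide exactly are collapsed to the lowest index before
#' traversal, matching the brute-force tie-break.
#'
#' @param tree A [build_kdtree()] result.
#' @param centers A `centerset` (see [init_centers()]) or a k x d numeric
#'   matrix.
#' @return A list with `assignments` (length-N integer labels in `1..k`),
#'   `counts` (points per center), `vector_sum` (k x d coordinate sums) and
#'   `n_dist_evals` (number of point-to-center distance evaluations actually
#'   performed).
#' @export
filter_assign <- function(tree, centers) {
  stopifnot(inherits(tree, "kdtree"))
  C <- center_matrix(centers)
  if (ncol(C) != tree$points$d) {
    stop("center dimension does not match the tree", call. = FALSE)
  }
  k <- nrow(C)
  # collapse exactly coincident centers onto the lowest index
  key <- apply(C, 1, paste, collapse = "\r")
  first <- match(key, key)
  active <- sort(unique(first))

  st <- new.env(parent = emptyenv())
  st$labels <- integer(tree$points$n)
  st$counts <- integer(k)
  st$vsum <- matrix(0, k, ncol(C))
  st$evals <- 0
  kd_filter(tree$root, tree$points$coords, C, active, st)
  list(assignments = st$labels, counts = st$counts, vector_sum = st$vsum,
       n_dist_evals = st$evals)
}

kd_filter <- function(node, X, C, cand, st) {
  if (length(cand) > 1L) {
    mid <- (node$lo + node$hi) / 2
    d2mid <- dist2_to_rows(mid, C[cand, , drop = FALSE])
    w <- cand[which.min(d2mid)]
    keep <- vapply(cand, function(j) {
      j == w || !prune_candidate_idx(node$lo, node$hi, C, j, w)
    }, logical(1))
    cand <- cand[keep]
  }
  if (length(cand) == 1L) {
    j <- cand
    st$labels[node$idx] <- j
    st$counts[j] <- st$counts[j] + node$count
    st$vsum[j, ] <- st$vsum[j, ] + node$vsum
    return(invisible())
  }
  if (node$leaf) {
    pts <- X[node$idx, , drop = FALSE]
    d2 <- dist2_matrix(pts, C[cand, , drop = FALSE])
    st$evals <- st$evals + length(d2)
    lab <- cand[argmin_rows(d2)]
    st$labels[node$idx] <- lab
    for (j in unique(lab)) {
      sel <- lab == j
      st$counts[j] <- st$counts[j] + sum(sel)
      st$vsum[j, ] <- st$vsum[j, ] + colSums(pts[sel, , drop = FALSE])
    }
    return(invisible())
  }
  kd_filter(node$left, X, C, cand, st)
  kd_filter(node$right, X, C, cand, st)
  invisible()
}
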