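#' Within-class variance (SSE)
#'
#' Sum over all records of the squared Euclidean distance to the assigned
#' cluster center — the quantity the k-means variants minimize.
#'
#' @param points A [point_set()].
#' @param assignments Integer labels in `1..k`, one per record.
#' @param centers A `centerset` or k x d matrix.
#' @return Non-negative scalar.
#' @export
sse <- function(points, assignments, centers) {
  stopifnot(inherits(points, "pointset"))
  C <- center_matrix(centers)
  check_labels(assignments, points$n, nrow(C))
  sum(rowSums((points$coords - C[assignments, , drop = FALSE])^2))
}

check_labels <- function(assignments, n, k) {
  if (length(assignments) != n) {
    stop("one label per record required", call. = FALSE)
  }
  if (any(assignments < 1L) || any(assignments > k)) {
    stop(sprintf("labels must lie in 1..%d", k), call. = FALSE)
  }
  invisible(TRUE)
}

#' Mean square error in decibels
#'
#' `10 * log10(SSE / N)`: the mean squared point-to-center distance on a
#' decibel scale, the convention used to compare cluster quality across
#' methods and data fractions.  A perfect fit (SSE = 0) has no finite dB
#' value; `-Inf` is returned with a warning.
#'
#' @inheritParams sse
#' @return Scalar dB value (`-Inf` for a degenerate, zero-error fit).
#' @export
mse_db <- function(points, assignments, centers) {
  s <- sse(points, assignments, centers)
  if (s == 0) {
    warning("SSE is zero: MSE has no finite dB value", call. = FALSE)
    return(-Inf)
  }
  10 * log10(s / points$n)
}

#' Average dispersion of one cluster
#'
#' Mean Euclidean (not squared) distance of the member records to the
#' cluster center — the per-cluster dispersion entering the Davies-Bouldin
#' index.
#'
#' @param member_coords Matrix of member coordinates (one row per member).
#' @param center Numeric center vector.
#' @return Non-negative scalar.
#' @export
cluster_dispersion <- function(member_coords, center) {
  member_coords <- as.matrix(member_coords)
  if (nrow(member_coords) < 1L) stop("empty cluster", call. = FALSE)
  if (ncol(member_coords) != length(center)) {
    stop("dimension mismatch", call. = FALSE)
  }
  mean(sqrt(rowSums((member_coords - rep(center,
                                         each = nrow(member_coords)))^2)))
}

#' Davies-Bouldin validity index
#'
#' For every pair of clusters the ratio `(e_i + e_j) / D_ij` of summed
#' average dispersions to the Euclidean distance between the centers is
#' formed; each cluster contributes its worst (largest) ratio and the index
#' is the mean of these maxima.  Lower is better.  Empty (dead) clusters are
#' excluded, with a warning, and `k` is reduced accordingly; coincident
#' centers of two live clusters are an error (the ratio is undefined).
#'
#' @inheritParams sse
#' @return An object of class `dbi_report`: list with `index`, `dispersions`
#'   (named by cluster), `center_distances`, `pairwise_ratios` (live-cluster
#'   matrices), `live` (cluster indices included) and `dead`.
#' @export
davies_bouldin <- function(points, assignments, centers) {
  stopifnot(inherits(points, "pointset"))
  C <- center_matrix(centers)
  k <- nrow(C)
  check_labels(assignments, points$n, k)
  live <- sort(unique(assignments))
  dead <- setdiff(seq_len(k), live)
  if (length(dead)) {
    warning(sprintf("excluding %d dead cluster(s) from the DBI: %s",
                    length(dead), paste(dead, collapse = ", ")),
            call. = FALSE)
  }
  m <- length(live)
  if (m < 2L) stop("the DBI needs at least two non-empty clusters",
                   call. = FALSE)
  e <- vapply(live, function(j) {
    cluster_dispersion(points$coords[assignments == j, , drop = FALSE],
                       C[j, ])
  }, numeric(1))
  D <- as.matrix(stats::dist(C[live, , drop = FALSE]))
  if (any(D[upper.tri(D)] == 0)) {
    stop("coincident centers of two non-empty clusters: DBI undefined",
         call. = FALSE)
  }
  R <- (outer(e, e, `+`)) / D
  diag(R) <- -Inf
  idx <- mean(apply(R, 1, max))
  diag(R) <- NA_real_
  dimnames(D) <- dimnames(R) <- list(live, live)
  names(e) <- live
  structure(list(index = idx, dispersions = e, center_distances = D,
                 pairwise_ratios = R, live = live, dead = dead),
            class = "dbi_report")
}

#' @export
print.dbi_report <- function(x, ...) {
  cat(sprintf("<Davies-Bouldin> index %.4f over %d clusters",
              x$index, length(x$live)))
  if (length(x$dead)) cat(sprintf(" (%d dead excluded)", length(x$dead)))
  cat("\n")
  invisible(x)
}
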