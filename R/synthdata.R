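#' Specification for a synthetic geospatial point dataset
#'
#' Describes a Gaussian-blob dataset mimicking clustered point data from
#' spatial epidemiology: well-separated or edge-connected clusters of planar
#' records, an optional density gradient (clusters farther from the origin
#' are more diffuse), and optional appended 0/1 indicator dimensions of the
#' kind produced by exposure flags (within 1 km of a risk source, etc.).
#'
#' @param n_clusters Number of clusters (default 10).
#' @param points_per_cluster Records per cluster (default 3600, i.e. a
#'   36,000-point dataset at the defaults).
#' @param dim Number of Gaussian coordinate dimensions (default 2).
#' @param center_box Length-2 numeric, the (common) coordinate range in which
#'   cluster centers are placed (default `c(0, 100)`).
#' @param base_spread Within-cluster standard deviation, coordinate units
#'   (default 2).
#' @param density_gradient If `TRUE`, the per-cluster spread grows linearly
#'   with the center's distance from the origin.
#' @param binary_dims Number of Bernoulli(0.25) indicator columns appended.
#' @param separable If `TRUE` (default) centers are drawn with pairwise
#'   separation of at least `6 * base_spread`; if `FALSE` ("hard" mode)
#'   placement is unconstrained and clusters may run into each other.
#' @param seed Integer seed; generation is fully reproducible.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_clusters = 10, points_per_cluster = 3600, dim = 2,
                       center_box = c(0, 100), base_spread = 2,
                       density_gradient = FALSE, binary_dims = 0,
                       separable = TRUE, seed = 1L) {
  n_clusters <- stop_if_not_count(n_clusters, "n_clusters")
  points_per_cluster <- stop_if_not_count(points_per_cluster,
                                          "points_per_cluster")
  dim <- stop_if_not_count(dim, "dim")
  binary_dims <- stop_if_not_count(binary_dims, "binary_dims", min = 0L)
  if (!is.numeric(center_box) || length(center_box) != 2L ||
      center_box[2] <= center_box[1]) {
    stop("`center_box` must be an increasing length-2 range", call. = FALSE)
  }
  if (!is.numeric(base_spread) || base_spread <= 0) {
    stop("`base_spread` must be positive", call. = FALSE)
  }
  structure(list(n_clusters = n_clusters,
                 points_per_cluster = points_per_cluster, dim = dim,
                 center_box = center_box, base_spread = base_spread,
                 density_gradient = isTRUE(density_gradient),
                 binary_dims = binary_dims, separable = isTRUE(separable),
                 seed = seed),
            class = "synth_spec")
}

#' Generate a synthetic clustered point dataset
#'
#' Draws cluster centers uniformly in the center box — rejecting draws closer
#' than `6 * base_spread` to an existing center in separable mode — then
#' scatters `points_per_cluster` Gaussian records around each.  With
#' `density_gradient`, the spread of cluster `i` is
#' `base_spread * (0.5 + |c_i| / max_j |c_j|)`, so clusters near the origin
#' are concentrated and distant ones diffuse.  Indicator columns, if any,
#' are i.i.d. Bernoulli(0.25).
#'
#' @param spec A [synth_spec()].
#' @return List with `points` (a [point_set()]; Gaussian dimensions named
#'   `x1, x2, ...`, indicators `b1, b2, ...`), `labels` (ground-truth cluster
#'   of each record, `1..n_clusters`) and `centers` (true cluster centers).
#' @examples
#' g <- generate_blobs(synth_spec(n_clusters = 3, points_per_cluster = 20,
#'                                seed = 42))
#' table(g$labels)
#' @export
generate_blobs <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    k <- spec$n_clusters
    d <- spec$dim
    min_sep2 <- if (spec$separable) (6 * spec$base_spread)^2 else 0
    centers <- matrix(NA_real_, k, d)
    tries <- 0L
    max_tries <- 1000L * k
    placed <- 0L
    while (placed < k) {
      cand <- stats::runif(d, spec$center_box[1], spec$center_box[2])
      ok <- placed == 0L || min_sep2 == 0 ||
        min(rowSums((centers[seq_len(placed), , drop = FALSE] -
                       rep(cand, each = placed))^2)) >= min_sep2
      if (ok) {
        placed <- placed + 1L
        centers[placed, ] <- cand
      }
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("could not place separated centers in `center_box`; ",
             "enlarge the box or reduce `base_spread`/`n_clusters`",
             call. = FALSE)
      }
    }
    norms <- sqrt(rowSums(centers^2))
    spreads <- if (spec$density_gradient) {
      spec$base_spread * (0.5 + norms / max(norms))
    } else {
      rep(spec$base_spread, k)
    }
    ppc <- spec$points_per_cluster
    coords <- matrix(NA_real_, k * ppc, d)
    for (j in seq_len(k)) {
      rows <- (j - 1L) * ppc + seq_len(ppc)
      coords[rows, ] <- rep(centers[j, ], each = ppc) +
        matrix(stats::rnorm(ppc * d, sd = spreads[j]), ppc, d)
    }
    labels <- rep(seq_len(k), each = ppc)
    dim_names <- paste0("x", seq_len(d))
    if (spec$binary_dims > 0L) {
      B <- matrix(stats::rbinom(nrow(coords) * spec$binary_dims, 1, 0.25),
                  nrow(coords), spec$binary_dims)
      coords <- cbind(coords, B)
      dim_names <- c(dim_names, paste0("b", seq_len(spec$binary_dims)))
    }
    list(points = point_set(coords, dim_names = dim_names),
         labels = labels, centers = centers)
  })
}
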