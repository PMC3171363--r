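#' Point sets
#'
#' A `pointset` holds the N x d numeric records to be clustered: planar or
#' projected coordinates, optionally mixed with further numeric attributes
#' (distances, prevalence rates, 0/1 exposure indicators and the like, as is
#' typical for georeferenced epidemiological records).
#'
#' @param coords Numeric matrix (or object coercible to one) with one row per
#'   record and one column per dimension.  All entries must be finite.
#' @param ids Vector of unique record identifiers, one per row.  Defaults to
#'   `1:N`.
#' @param dim_names Optional character vector of dimension labels; defaults to
#'   the column names of `coords` or `"V1"..."Vd"`.
#'
#' @return An object of class `pointset`: a list with elements `coords`
#'   (numeric matrix), `ids`, `dim_names`, `n` and `d`.
#' @examples
#' ps <- point_set(matrix(rnorm(20), 10, 2))
#' ps$n
#' @export
point_set <- function(coords, ids = NULL, dim_names = NULL) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords)) stop("`coords` must be numeric", call. = FALSE)
  storage.mode(coords) <- "double"
  if (nrow(coords) < 1L) stop("a pointset needs at least one record",
                              call. = FALSE)
  if (ncol(coords) < 1L) stop("a pointset needs at least one dimension",
                              call. = FALSE)
  if (!all(is.finite(coords))) {
    bad <- which(!is.finite(coords), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite coordinate at row %d, dimension %d",
                 bad[1L], bad[2L]), call. = FALSE)
  }
  if (is.null(ids)) ids <- seq_len(nrow(coords))
  if (length(ids) != nrow(coords)) {
    stop("`ids` must have one entry per row of `coords`", call. = FALSE)
  }
  if (anyDuplicated(ids)) stop("record ids must be unique", call. = FALSE)
  if (is.null(dim_names)) {
    dim_names <- colnames(coords)
    if (is.null(dim_names)) dim_names <- paste0("V", seq_len(ncol(coords)))
  }
  if (length(dim_names) != ncol(coords)) {
    stop("`dim_names` must have one entry per dimension", call. = FALSE)
  }
  colnames(coords) <- dim_names
  structure(
    list(coords = coords, ids = ids, dim_names = dim_names,
         n = nrow(coords), d = ncol(coords)),
    class = "pointset"
  )
}

#' @export
print.pointset <- function(x, ...) {
  cat(sprintf("<pointset> %d records x %d dimensions (%s)\n",
              x$n, x$d, paste(x$dim_names, collapse = ", ")))
  invisible(x)
}

#' Standardize a point set
#'
#' Z-scores every dimension (mean 0, sd 1).  Constant dimensions are centered
#' but left unscaled.  Useful when coordinate dimensions are mixed with
#' attributes on very different scales; clustering itself never rescales.
#'
#' @param points A [point_set()].
#' @return A new `pointset` with standardized coordinates.
#' @export
zscore_points <- function(points) {
  stopifnot(inherits(points, "pointset"))
  X <- scale(points$coords)
  sds <- attr(X, "scaled:scale")
  if (any(sds == 0)) {
    X[, sds == 0] <- sweep(points$coords[, sds == 0, drop = FALSE], 2,
                           colMeans(points$coords[, sds == 0, drop = FALSE]))
  }
  point_set(`attributes<-`(X, list(dim = dim(X))),
            ids = points$ids, dim_names = points$dim_names)
}
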