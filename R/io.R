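#' Read a point set from CSV
#'
#' Expects a comma-separated file with a header row, dot decimals, UTF-8.
#' By default the column named `id` (if present) supplies record identifiers
#' and every other numeric column becomes a feature dimension; both choices
#' can be overridden.  Non-finite or missing values in a selected feature
#' column are rejected with the offending row numbers.
#'
#' @param path Path to the CSV file.
#' @param id_column Optional name of the identifier column.
#' @param feature_columns Optional character vector of feature column names.
#' @return A [point_set()] with `dim_names` taken from the header.
#' @export
read_points_csv <- function(path, id_column = NULL, feature_columns = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) < 1L) stop("no data rows in file", call. = FALSE)
  if (is.null(id_column) && "id" %in% names(df)) id_column <- "id"
  if (!is.null(id_column)) {
    if (!id_column %in% names(df)) {
      stop(sprintf("id column '%s' not found", id_column), call. = FALSE)
    }
    ids <- df[[id_column]]
    if (anyDuplicated(ids)) {
      dup <- which(duplicated(ids))[1L]
      stop(sprintf("duplicate id at row %d", dup), call. = FALSE)
    }
  } else {
    ids <- seq_len(nrow(df))
  }
  if (is.null(feature_columns)) {
    feature_columns <- setdiff(names(df)[vapply(df, is.numeric, logical(1))],
                               id_column)
    if (length(feature_columns) == 0L) {
      stop("no numeric feature columns found", call. = FALSE)
    }
  } else {
    missing_cols <- setdiff(feature_columns, names(df))
    if (length(missing_cols)) {
      stop(sprintf("feature column(s) not found: %s",
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
    }
  }
  feat <- df[feature_columns]
  for (cn in feature_columns) {
    v <- suppressWarnings(as.numeric(feat[[cn]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop(sprintf("non-numeric or missing value in column '%s' at row %s",
                   cn, paste(utils::head(bad, 5), collapse = ", ")),
           call. = FALSE)
    }
    feat[[cn]] <- v
  }
  point_set(as.matrix(feat), ids = ids, dim_names = feature_columns)
}

#' Write a point set to CSV
#'
#' Inverse of [read_points_csv()]: columns `id`, then one per dimension, and
#' optionally a ground-truth `label` column (as written by the `simulate`
#' command).
#'
#' @param points A [point_set()].
#' @param path Output path.
#' @param labels Optional integer labels appended as a `label` column.
#' @return The path, invisibly.
#' @export
write_points_csv <- function(points, path, labels = NULL) {
  stopifnot(inherits(points, "pointset"))
  df <- data.frame(id = points$ids)
  df <- cbind(df, as.data.frame(points$coords))
  if (!is.null(labels)) df$label <- labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Assemble a serializable run report
#'
#' @param result A `feskm_result`.
#' @param points The clustered [point_set()].
#' @param input_path Optional provenance string (file the points came from).
#' @param dbi Optional [davies_bouldin()] report to include.
#' @return A plain list (class `run_report`) that round-trips through JSON.
#' @export
build_run_report <- function(result, points, input_path = NULL, dbi = NULL) {
  s <- sse(points, result$assignments, result$centers)
  structure(list(
    method = result$method,
    k = result$k,
    config = list(eta0 = result$config$eta0, epsilon = result$config$epsilon,
                  max_iter = result$config$max_iter,
                  seed = result$config$seed, shuffle = result$config$shuffle),
    input = list(n = points$n, d = points$d,
                 path = if (is.null(input_path)) NA else input_path),
    n_iter = result$n_iter,
    converged = result$converged,
    reason = result$reason,
    sse = s,
    mse_db = if (s > 0) 10 * log10(s / points$n) else NA,
    dbi = if (is.null(dbi)) NA else dbi$index,
    dead_centers = as.list(result$dead_centers),
    version = as.character(utils::packageVersion("feskmeans"))
  ), class = "run_report")
}

#' Write the standard output files of a clustering run
#'
#' Emits into `out_dir`: `assignments.csv` (`id`, `cluster`, `distance`,
#' `is_outlier`), `centers.csv` (one row per center), `report.json`, and —
#' when the corresponding objects are supplied — `benchmark.csv`.
#'
#' @param result A `feskm_result`.
#' @param points The clustered [point_set()].
#' @param out_dir Output directory (created if needed).
#' @param outliers Optional [distance_outliers()] report; without it the
#'   `is_outlier` column is all `FALSE`.
#' @param dbi Optional [davies_bouldin()] report for `report.json`.
#' @param benchmark Optional [run_benchmark()] data frame.
#' @param input_path Optional provenance string recorded in the report.
#' @return Named character vector of the files written, invisibly.
#' @export
write_outputs <- function(result, points, out_dir, outliers = NULL,
                          dbi = NULL, benchmark = NULL, input_path = NULL) {
  stopifnot(inherits(points, "pointset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory",
                                 call. = FALSE)
  files <- character(0)

  if (is.null(outliers)) {
    C <- center_matrix(result$centers)
    distance <- sqrt(rowSums((points$coords -
                                C[result$assignments, , drop = FALSE])^2))
    rec <- data.frame(id = points$ids, cluster = result$assignments,
                      distance = distance, is_outlier = FALSE)
  } else {
    rec <- outliers$records
  }
  f <- file.path(out_dir, "assignments.csv")
  utils::write.csv(rec, f, row.names = FALSE)
  files["assignments"] <- f

  C <- center_matrix(result$centers)
  cdf <- data.frame(cluster = seq_len(nrow(C)))
  cdf <- cbind(cdf, as.data.frame(C))
  names(cdf)[-1] <- points$dim_names
  f <- file.path(out_dir, "centers.csv")
  utils::write.csv(cdf, f, row.names = FALSE)
  files["centers"] <- f

  rep <- build_run_report(result, points, input_path = input_path, dbi = dbi)
  f <- file.path(out_dir, "report.json")
  jsonlite::write_json(unclass(rep), f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  files["report"] <- f

  if (!is.null(benchmark)) {
    f <- file.path(out_dir, "benchmark.csv")
    utils::write.csv(benchmark, f, row.names = FALSE)
    files["benchmark"] <- f
  }
  invisible(files)
}

#' Export clustered points as GeoJSON
#'
#' Writes a `FeatureCollection` of `Point` features, one per record, with
#' properties `id`, `cluster`, `distance` and `is_outlier`.  Two dimensions
#' of the point set must be designated as planar x and y; coordinates are
#' emitted exactly as stored (no reprojection).
#'
#' @param points A [point_set()].
#' @param result A `feskm_result`.
#' @param x_dim,y_dim Dimension names or indices for the geographic x and y
#'   coordinates; must differ.
#' @param path Output path.
#' @param outliers Optional [distance_outliers()] report supplying the
#'   `is_outlier` property.
#' @return The path, invisibly.
#' @export
export_geojson <- function(points, result, x_dim, y_dim, path,
                           outliers = NULL) {
  stopifnot(inherits(points, "pointset"))
  resolve_dim <- function(d) {
    if (is.character(d)) d <- match(d, points$dim_names)
    d <- as.integer(d)
    if (is.na(d) || d < 1L || d > points$d) {
      stop("unknown coordinate dimension", call. = FALSE)
    }
    d
  }
  xi <- resolve_dim(x_dim)
  yi <- resolve_dim(y_dim)
  if (xi == yi) stop("`x_dim` and `y_dim` must differ", call. = FALSE)
  C <- center_matrix(result$centers)
  lab <- result$assignments
  distance <- sqrt(rowSums((points$coords - C[lab, , drop = FALSE])^2))
  flag <- if (is.null(outliers)) rep(FALSE, points$n) else
    outliers$records$is_outlier
  features <- lapply(seq_len(points$n), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(points$coords[i, xi],
                                         points$coords[i, yi])),
         properties = list(id = points$ids[i], cluster = lab[i],
                           distance = distance[i], is_outlier = flag[i]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
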