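# Readers and writers.  CSV with header rows is the interchange format;
# polygons travel as GeoJSON (RFC 7946 geometry structure, but planar km
# coordinates -- documented as non-geodetic).

villages_required_cols <- function() {
  c("village_id", "state_id", "district_id", "x_km", "y_km", "population")
}

clusters_required_cols <- function() {
  c("cluster_id", "district_id", "state_id", "x_km", "y_km", "n_children",
    paste0("fail_", indicator_names()), "rural", "population")
}

# read.csv with character classes applied only to columns present
read_csv_typed <- function(path, classes) {
  hdr <- names(utils::read.csv(path, nrows = 1L))
  classes <- classes[names(classes) %in% hdr]
  if (length(classes) == 0L) classes <- NA
  utils::read.csv(path, stringsAsFactors = FALSE, colClasses = classes)
}

check_schema <- function(df, required, what) {
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing columns: %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Write / read the village table
#'
#' Validates the schema and row-level invariants (positive population,
#' true prevalences inside (0, 1)) and reports offending row indices.
#'
#' @param villages Village data frame.
#' @param path CSV file path.
#' @return `read_villages()` returns the validated data frame;
#'   `write_villages()` returns `path` invisibly.
#' @export
write_villages <- function(villages, path) {
  check_schema(villages, villages_required_cols(), "villages")
  utils::write.csv(villages, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_villages
#' @param path CSV file path.
#' @export
read_villages <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read_csv_typed(path, c(village_id = "character",
                               state_id = "character",
                               district_id = "character"))
  check_schema(df, villages_required_cols(), "villages")
  bad <- which(!is.finite(df$population) | df$population < 1)
  if (length(bad)) {
    stop("villages: invalid population at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  for (ind in indicator_names()) {
    col <- paste0("true_", ind)
    if (col %in% names(df)) {
      bad <- which(!(df[[col]] > 0 & df[[col]] < 1))
      if (length(bad)) {
        stop(sprintf("villages: %s outside (0,1) at row(s) %s", col,
                     paste(utils::head(bad, 5L), collapse = ", ")),
             call. = FALSE)
      }
    }
  }
  df
}

#' Write / read the cluster survey table
#'
#' @param clusters Survey data frame.
#' @param path CSV file path.
#' @return As [write_villages()] / [read_villages()].
#' @export
write_clusters <- function(clusters, path) {
  check_schema(clusters, clusters_required_cols(), "clusters")
  utils::write.csv(clusters, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clusters
#' @export
read_clusters <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read_csv_typed(path, c(cluster_id = "character",
                               district_id = "character",
                               state_id = "character",
                               source_village_id = "character"))
  check_schema(df, clusters_required_cols(), "clusters")
  bad <- which(!is.finite(df$population) | df$population < 1)
  if (length(bad)) {
    stop("clusters: invalid population at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  for (ind in indicator_names()) {
    col <- paste0("fail_", ind)
    bad <- which(df[[col]] < 0 | df[[col]] > df$n_children)
    if (length(bad)) {
      stop(sprintf("clusters: %s outside [0, n_children] at row(s) %s",
                   col, paste(utils::head(bad, 5L), collapse = ", ")),
           call. = FALSE)
    }
  }
  df
}

#' Write / read candidate pairs
#'
#' @param pairs Data frame `cluster_id`, `village_id` (+ optional
#'   predicate flags).
#' @param path CSV file path.
#' @return As [write_villages()] / [read_villages()].
#' @export
write_pairs <- function(pairs, path) {
  check_schema(pairs, c("cluster_id", "village_id"), "pairs")
  utils::write.csv(pairs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read_csv_typed(path, c(cluster_id = "character",
                               village_id = "character"))
  check_schema(df, c("cluster_id", "village_id"), "pairs")
  df
}

#' Write / read polygons as GeoJSON
#'
#' A FeatureCollection of Polygon features with an `id` property.
#' Coordinates are planar kilometers, not longitude/latitude; the
#' non-geodetic convention is recorded in a top-level `crs_note` member.
#'
#' @param polygons Named list of open-ring polygon matrices.
#' @param path Output `.geojson` path.
#' @return `read_polygons_geojson()` returns a named list of polygon
#'   matrices; the writer returns `path` invisibly.
#' @export
write_polygons_geojson <- function(polygons, path) {
  features <- lapply(names(polygons), function(id) {
    p <- polygons[[id]]
    ring <- rbind(p, p[1L, , drop = FALSE])  # GeoJSON rings are closed
    list(
      type = "Feature",
      properties = list(id = id),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)), function(i) {
          c(ring[i, 1L], ring[i, 2L])
        }))
      )
    )
  })
  obj <- list(type = "FeatureCollection",
              crs_note = "planar kilometers (synthetic, non-geodetic)",
              features = features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_polygons_geojson
#' @export
read_polygons_geojson <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path)
  if (!identical(obj$type, "FeatureCollection")) {
    stop("not a GeoJSON FeatureCollection", call. = FALSE)
  }
  out <- lapply(obj$features, function(f) {
    ring <- f$geometry$coordinates[[1L]]
    m <- do.call(rbind, lapply(ring, function(xy) {
      c(as.numeric(xy[[1L]]), as.numeric(xy[[2L]]))
    }))
    colnames(m) <- c("x", "y")
    # drop the closing vertex back to the open-ring convention
    if (nrow(m) > 1L && all(m[1L, ] == m[nrow(m), ])) {
      m <- m[-nrow(m), , drop = FALSE]
    }
    m
  })
  names(out) <- vapply(obj$features, function(f) f$properties$id,
                       character(1L))
  out
}

#' Read a pipeline configuration file
#'
#' YAML file whose keys override the defaults of [synthetic_config()]
#' (under `synthetic:`) and the pipeline stage parameters (under
#' `pipeline:`; see [pipeline_config()]).
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  syn <- do.call(synthetic_config, raw$synthetic %||% list())
  do.call(pipeline_config, c(list(synthetic = syn), raw$pipeline %||% list()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
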