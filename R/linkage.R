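# Fuzzy spatial linkage of displaced survey clusters to census villages.
#
# Five steps: represent villages by Thiessen (Voronoi) polygons clipped
# to their district, buffer each cluster's reported point by the maximum
# displacement radius, overlay buffers with village polygons to get
# candidate pairs, filter on district identity / rural status /
# population ordering, deduplicate, and finally extract the reliable
# label set of unambiguous one-to-one matches (averaging when several
# single-candidate clusters hit the same village).

#' Thiessen polygons for point villages within a district
#'
#' Thin wrapper over [voronoi_cells()] matching the linkage vocabulary:
#' Voronoi cells of the village points clipped to the (convex) district
#' polygon.  Duplicate points are perturbed by an epsilon with a
#' warning.
#'
#' @param points Two-column matrix of village points.
#' @param district_polygon Convex district polygon.
#' @return List of polygons in input order.
#' @export
thiessen_polygons <- function(points, district_polygon) {
  pts <- as.matrix(points)
  inside <- apply(pts, 1L, point_in_convex_polygon, poly = district_polygon)
  if (!all(inside)) {
    stop("all points must lie inside the district polygon", call. = FALSE)
  }
  voronoi_cells(pts, district_polygon)
}

#' Circular buffers around cluster points
#'
#' @param clusters Data frame with `cluster_id`, `x_km`, `y_km`.
#' @param radius_km Buffer radius in km (default 5, the maximum ordinary
#'   GPS displacement).
#' @param n_segments Polygonal approximation of the disc (default 64).
#' @return Named list of buffer polygons keyed by `cluster_id`.
#' @export
buffer_clusters <- function(clusters, radius_km = 5, n_segments = 64L) {
  if (!is.numeric(radius_km) || radius_km <= 0) {
    stop("radius_km must be positive", call. = FALSE)
  }
  out <- lapply(seq_len(nrow(clusters)), function(i) {
    disc_polygon(c(clusters$x_km[i], clusters$y_km[i]), radius_km,
                 n_segments)
  })
  names(out) <- clusters$cluster_id
  out
}

#' Spatial overlay of cluster buffers with village polygons
#'
#' One candidate pair per (cluster, village) whose geometries intersect;
#' boundary touching counts.  Duplicate village entries are dissolved so
#' each (cluster, village) pair appears once.  Clusters whose buffer
#' intersects no village are flagged unmatched via the `"unmatched"`
#' attribute.
#'
#' @param buffers Named list of buffer polygons (from
#'   [buffer_clusters()]).
#' @param village_polygons Named list of village polygons.
#' @return Data frame `cluster_id`, `village_id`; attribute
#'   `"unmatched"` holds the ids of unmatched clusters.
#' @export
overlay_candidates <- function(buffers, village_polygons) {
  dup <- duplicated(names(village_polygons))
  if (any(dup)) village_polygons <- village_polygons[!dup]
  vids <- names(village_polygons)
  # bounding boxes for cheap rejection
  bb <- t(vapply(village_polygons, function(p) {
    c(min(p[, 1L]), max(p[, 1L]), min(p[, 2L]), max(p[, 2L]))
  }, numeric(4L)))
  res <- vector("list", length(buffers))
  unmatched <- character(0)
  for (i in seq_along(buffers)) {
    buf <- buffers[[i]]
    bx <- range(buf[, 1L]); by <- range(buf[, 2L])
    cand <- which(bb[, 1L] <= bx[2L] & bb[, 2L] >= bx[1L] &
                    bb[, 3L] <= by[2L] & bb[, 4L] >= by[1L])
    hit <- cand[vapply(cand, function(j) {
      convex_polygons_intersect(village_polygons[[j]], buf)
    }, logical(1L))]
    if (length(hit) == 0L) {
      unmatched <- c(unmatched, names(buffers)[i])
      res[[i]] <- NULL
    } else {
      res[[i]] <- data.frame(cluster_id = names(buffers)[i],
                             village_id = vids[hit],
                             stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(cluster_id = character(0), village_id = character(0),
                      stringsAsFactors = FALSE)
  }
  out <- out[!duplicated(out[, c("cluster_id", "village_id")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmatched") <- unmatched
  out
}

#' Filter candidate pairs on district, rural status and population
#'
#' Keeps pairs where cluster and village share the district identifier,
#' both are rural, and the village population strictly exceeds the
#' cluster population.  Pairs with missing population are dropped with
#' a warning.
#'
#' @param pairs Data frame `cluster_id`, `village_id` (from
#'   [overlay_candidates()]).
#' @param clusters Survey data frame (`cluster_id`, `district_id`,
#'   `rural`, `population`).
#' @param villages Village data frame (`village_id`, `district_id`,
#'   `population`); a `rural` column defaults to `TRUE` if absent.
#' @return Filtered pairs data frame with the predicate columns
#'   `same_district`, `both_rural`, `population_ok` retained for
#'   inspection.
#' @export
filter_pairs <- function(pairs, clusters, villages) {
  ci <- match(pairs$cluster_id, clusters$cluster_id)
  vi <- match(pairs$village_id, villages$village_id)
  if (anyNA(ci) || anyNA(vi)) {
    stop("pairs reference unknown cluster or village ids", call. = FALSE)
  }
  v_rural <- if ("rural" %in% names(villages)) villages$rural[vi] else TRUE
  c_rural <- if ("rural" %in% names(clusters)) clusters$rural[ci] else TRUE
  vpop <- villages$population[vi]
  cpop <- clusters$population[ci]
  pop_na <- is.na(vpop) | is.na(cpop)
  if (any(pop_na)) {
    warning(sum(pop_na), " pair(s) dropped for missing population",
            call. = FALSE)
  }
  same_district <- clusters$district_id[ci] == villages$district_id[vi]
  both_rural <- as.logical(v_rural) & as.logical(c_rural)
  population_ok <- !pop_na & vpop > cpop
  keep <- same_district & both_rural & population_ok
  keep[is.na(keep)] <- FALSE
  out <- pairs[keep, , drop = FALSE]
  out$same_district <- same_district[keep]
  out$both_rural <- both_rural[keep]
  out$population_ok <- population_ok[keep]
  rownames(out) <- NULL
  out
}

#' Extract the reliable label set
#'
#' Clusters with exactly one candidate village are unambiguous; a
#' village matched by several such clusters receives the unweighted mean
#' of their estimates.  The remaining clusters (two or more candidates)
#' form the fuzzy set C with candidate lists V_c.
#'
#' @param pairs Filtered pairs data frame.
#' @param cluster_estimates Data frame with `cluster_id` and one column
#'   per indicator (e.g. from [estimate_clusters()]).
#' @param indicators Indicator column names (default
#'   [indicator_names()]).
#' @return Object of class `reliable_label_set`: `labels` (data frame
#'   `village_id` + one column per indicator for L0), `fuzzy` (data
#'   frame of fuzzy clusters with their indicator values), `candidates`
#'   (named list of candidate village-id vectors per fuzzy cluster).
#' @export
reliable_label_set <- function(pairs, cluster_estimates,
                               indicators = indicator_names()) {
  have <- intersect(indicators, names(cluster_estimates))
  if (!length(have)) stop("no indicator columns found", call. = FALSE)
  counts <- table(pairs$cluster_id)
  singles <- names(counts)[counts == 1L]
  fuzzies <- names(counts)[counts >= 2L]

  est <- cluster_estimates[match(pairs$cluster_id,
                                 cluster_estimates$cluster_id), have,
                           drop = FALSE]
  single_rows <- pairs$cluster_id %in% singles
  if (!any(single_rows)) {
    warning("no one-to-one matches: reliable label set is empty",
            call. = FALSE)
    labels <- data.frame(village_id = character(0),
                         stringsAsFactors = FALSE)
    for (ind in have) labels[[ind]] <- numeric(0)
  } else {
    sv <- pairs$village_id[single_rows]
    se <- est[single_rows, , drop = FALSE]
    agg <- stats::aggregate(se, by = list(village_id = sv), FUN = mean)
    labels <- agg[order(agg$village_id), , drop = FALSE]
    rownames(labels) <- NULL
  }
  cand <- split(pairs$village_id, pairs$cluster_id)[fuzzies]
  cand <- lapply(cand, sort)
  fuzzy <- cluster_estimates[match(fuzzies, cluster_estimates$cluster_id),
                             c("cluster_id", have), drop = FALSE]
  rownames(fuzzy) <- NULL
  singles_df <- data.frame(
    cluster_id = singles,
    village_id = pairs$village_id[match(singles, pairs$cluster_id)],
    stringsAsFactors = FALSE)
  singles_df <- cbind(singles_df,
                      cluster_estimates[match(singles,
                                              cluster_estimates$cluster_id),
                                        have, drop = FALSE])
  rownames(singles_df) <- NULL
  structure(list(labels = labels, fuzzy = fuzzy, candidates = cand,
                 singles = singles_df),
            class = "reliable_label_set")
}

#' @export
print.reliable_label_set <- function(x, ...) {
  cat(sprintf(
    "reliable_label_set: %d reliable village(s) (L0), %d fuzzy cluster(s)\n",
    nrow(x$labels), nrow(x$fuzzy)))
  invisible(x)
}

#' Run the full five-step linkage
#'
#' Buffers the clusters, overlays buffers with the village polygons,
#' applies the district/rural/population filters and extracts the
#' reliable label set.
#'
#' @param population A `synthetic_population` (or any list with
#'   `villages` and `village_polygons`).
#' @param clusters Survey data frame.
#' @param cluster_estimates Output of [estimate_clusters()].
#' @param radius_km Buffer radius (default 5).
#' @return List: `pairs` (filtered candidate pairs), `label_set` (a
#'   `reliable_label_set`), `unmatched` (cluster ids with no overlay
#'   hit or removed by filtering).
#' @export
link_clusters <- function(population, clusters, cluster_estimates,
                          radius_km = 5) {
  buffers <- buffer_clusters(clusters, radius_km = radius_km)
  raw <- overlay_candidates(buffers, population$village_polygons)
  pairs <- filter_pairs(raw, clusters, population$villages)
  label_set <- reliable_label_set(pairs, cluster_estimates)
  dropped <- setdiff(clusters$cluster_id, unique(pairs$cluster_id))
  list(pairs = pairs, label_set = label_set,
       unmatched = union(attr(raw, "unmatched"), dropped))
}
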