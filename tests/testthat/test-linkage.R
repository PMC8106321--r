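test_that("thiessen polygons partition the district and reject outside points", {
  bnd <- rect_polygon(0, 0, 20, 10)
  withr::with_seed(61, {
    pts <- cbind(runif(12, 0, 20), runif(12, 0, 10))
    cells <- thiessen_polygons(pts, bnd)
    expect_equal(sum(vapply(cells, polygon_area, numeric(1))), 200,
                 tolerance = 1e-9)
  })
  expect_error(thiessen_polygons(rbind(c(25, 5)), bnd), "inside")
})

test_that("buffers have the right extent and reject non-positive radii", {
  cl <- data.frame(cluster_id = "C1", x_km = 10, y_km = 10)
  buf <- buffer_clusters(cl, radius_km = 5)[[1]]
  expect_equal(polygon_area(buf), pi * 25, tolerance = 0.005)
  expect_true(point_in_convex_polygon(c(10 + 4.9, 10), buf))
  expect_false(point_in_convex_polygon(c(10 + 5.1, 10), buf))
  expect_error(buffer_clusters(cl, radius_km = 0), "positive")
})

test_that("overlay finds exactly the intersecting villages and dissolves duplicates", {
  # three villages inside the buffer, one far away
  vp <- list(
    V1 = rect_polygon(9, 9, 11, 11),
    V2 = rect_polygon(13, 9, 15, 11),
    V3 = rect_polygon(9, 13, 11, 15),
    V4 = rect_polygon(40, 40, 42, 42)
  )
  cl <- data.frame(cluster_id = "C1", x_km = 10, y_km = 10)
  buf <- buffer_clusters(cl, radius_km = 5)
  pairs <- overlay_candidates(buf, vp)
  expect_setequal(pairs$village_id, c("V1", "V2", "V3"))
  # duplicated polygon ids are dissolved to one pair
  pairs2 <- overlay_candidates(buf, vp[c(1, 1, 2)])
  expect_equal(nrow(pairs2), 2L)
  # a cluster with no hits is flagged unmatched
  cl2 <- data.frame(cluster_id = "C2", x_km = 100, y_km = 100)
  p3 <- overlay_candidates(buffer_clusters(cl2, 5), vp)
  expect_equal(attr(p3, "unmatched"), "C2")
})

test_that("overlay agrees with a distance-based oracle on a random layout", {
  withr::with_seed(62, {
    bnd <- rect_polygon(0, 0, 50, 50)
    pts <- cbind(runif(40, 0, 50), runif(40, 0, 50))
    vp <- voronoi_cells(pts, bnd)
    names(vp) <- sprintf("V%02d", 1:40)
    cl <- data.frame(cluster_id = sprintf("C%02d", 1:8),
                     x_km = runif(8, 5, 45), y_km = runif(8, 5, 45))
    r <- 5
    pairs <- overlay_candidates(buffer_clusters(cl, r), vp)
    # oracle: a convex polygon meets the disc iff the minimum distance
    # from the center to the polygon is at most the radius
    seg_dist <- function(p, a, b) {
      ab <- b - a
      t <- max(0, min(1, sum((p - a) * ab) / sum(ab * ab)))
      sqrt(sum((p - (a + t * ab))^2))
    }
    poly_dist <- function(p, poly) {
      if (point_in_convex_polygon(p, poly)) return(0)
      n <- nrow(poly)
      min(vapply(seq_len(n), function(i) {
        seg_dist(p, poly[i, ], poly[if (i == n) 1L else i + 1L, ])
      }, numeric(1)))
    }
    got <- paste(pairs$cluster_id, pairs$village_id)
    apothem_band <- c(r * cos(pi / 64), r)  # 64-gon boundary band
    for (i in 1:8) {
      for (j in 1:40) {
        d <- poly_dist(c(cl$x_km[i], cl$y_km[i]), vp[[j]])
        key <- paste(cl$cluster_id[i], names(vp)[j])
        if (d < apothem_band[1] - 1e-9) expect_true(key %in% got)
        if (d > apothem_band[2] + 1e-9) expect_false(key %in% got)
      }
    }
  })
})

test_that("pair filtering matches brute-force application of the three predicates", {
  clusters <- data.frame(
    cluster_id = paste0("C", 1:4),
    district_id = c("D1", "D1", "D2", "D2"),
    rural = c(TRUE, TRUE, FALSE, TRUE),
    population = c(100, 600, 100, 100))
  villages <- data.frame(
    village_id = paste0("V", 1:5),
    district_id = c("D1", "D1", "D2", "D2", "D3"),
    rural = TRUE,
    population = c(500, 500, 500, 50, 500))
  pairs <- expand.grid(cluster_id = clusters$cluster_id,
                       village_id = villages$village_id,
                       stringsAsFactors = FALSE)
  got <- filter_pairs(pairs, clusters, villages)
  # brute-force oracle over all 20 pairs
  oracle <- pairs[apply(pairs, 1, function(r) {
    cc <- clusters[clusters$cluster_id == r[1], ]
    vv <- villages[villages$village_id == r[2], ]
    cc$district_id == vv$district_id && cc$rural && vv$rural &&
      vv$population > cc$population
  }), ]
  expect_setequal(paste(got$cluster_id, got$village_id),
                  paste(oracle$cluster_id, oracle$village_id))
  # spot checks: population rule and district rule
  expect_false(any(got$cluster_id == "C2"))  # village pop 500 < cluster 600
  expect_false(any(got$cluster_id == "C3"))  # urban cluster
  expect_false(any(got$village_id == "V5"))  # no cluster in D3
})

test_that("missing populations drop pairs with a warning", {
  clusters <- data.frame(cluster_id = "C1", district_id = "D1",
                         rural = TRUE, population = NA_real_)
  villages <- data.frame(village_id = "V1", district_id = "D1",
                         rural = TRUE, population = 100)
  pairs <- data.frame(cluster_id = "C1", village_id = "V1")
  expect_warning(out <- filter_pairs(pairs, clusters, villages), "population")
  expect_equal(nrow(out), 0L)
})

test_that("reliable label set averages one-to-one matches and isolates fuzzy clusters", {
  pairs <- data.frame(
    cluster_id = c("C1", "C2", "C3", "C3", "C4", "C4", "C4"),
    village_id = c("V1", "V1", "V2", "V3", "V4", "V5", "V6"))
  est <- data.frame(cluster_id = paste0("C", 1:4),
                    stunting = c(0.30, 0.50, 0.40, 0.20),
                    underweight = c(0.1, 0.2, 0.3, 0.4),
                    wasting = c(0.05, 0.15, 0.25, 0.35))
  ls <- reliable_label_set(pairs, est)
  # V1 is matched by two single-candidate clusters: label is their mean
  expect_equal(ls$labels$stunting[ls$labels$village_id == "V1"], 0.40)
  expect_equal(ls$labels$underweight[ls$labels$village_id == "V1"], 0.15)
  # C3 and C4 are fuzzy
  expect_setequal(ls$fuzzy$cluster_id, c("C3", "C4"))
  expect_equal(ls$candidates[["C3"]], c("V2", "V3"))
  expect_equal(ls$candidates[["C4"]], c("V4", "V5", "V6"))
  # singles table records the forced assignments
  expect_setequal(ls$singles$cluster_id, c("C1", "C2"))
  # no one-to-one matches at all: empty L0 with a warning
  expect_warning(
    empty <- reliable_label_set(pairs[3:7, ], est), "empty")
  expect_equal(nrow(empty$labels), 0L)
})

test_that("reliable label set equals brute-force enumeration on a random table", {
  withr::with_seed(63, {
    pairs <- unique(data.frame(
      cluster_id = sprintf("C%02d", sample(1:12, 60, replace = TRUE)),
      village_id = sprintf("V%02d", sample(1:25, 60, replace = TRUE))))
    est <- data.frame(cluster_id = sprintf("C%02d", 1:12),
                      stunting = runif(12), underweight = runif(12),
                      wasting = runif(12))
    ls <- suppressWarnings(reliable_label_set(pairs, est))
    counts <- table(pairs$cluster_id)
    singles <- names(counts)[counts == 1]
    # oracle: per village, mean over single-candidate clusters hitting it
    sv <- pairs$village_id[pairs$cluster_id %in% singles]
    for (v in unique(sv)) {
      cls <- pairs$cluster_id[pairs$village_id == v &
                                pairs$cluster_id %in% singles]
      expect_equal(ls$labels$stunting[ls$labels$village_id == v],
                   mean(est$stunting[match(cls, est$cluster_id)]))
    }
    expect_setequal(ls$fuzzy$cluster_id, names(counts)[counts >= 2])
    for (cc in ls$fuzzy$cluster_id) {
      expect_setequal(ls$candidates[[cc]],
                      pairs$village_id[pairs$cluster_id == cc])
    }
  })
})

test_that("linkage recovers the true source village for nearly all nearby clusters", {
  hits <- 0L; total <- 0L
  for (s in 101:102) {
    cfg <- synthetic_config(seed = s)
    pop <- generate_population(cfg)
    cl <- sample_survey(pop)
    buf <- buffer_clusters(cl, radius_km = 5)
    pairs <- filter_pairs(overlay_candidates(buf, pop$village_polygons),
                          cl, pop$villages)
    d <- sqrt((cl$x_km - cl$true_x_km)^2 + (cl$y_km - cl$true_y_km)^2)
    near <- which(d <= 5)
    key <- paste(cl$cluster_id, cl$source_village_id)
    hits <- hits + sum(key[near] %in%
                         paste(pairs$cluster_id, pairs$village_id))
    total <- total + length(near)
  }
  expect_gte(hits / total, 0.99)
})

test_that("filters are monotone: filtering never adds pairs", {
  pipe <- small_pipeline()
  raw <- overlay_candidates(
    buffer_clusters(pipe$clusters, 5), pipe$population$village_polygons)
  filtered <- pipe$linkage$pairs
  expect_true(all(paste(filtered$cluster_id, filtered$village_id) %in%
                    paste(raw$cluster_id, raw$village_id)))
})
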