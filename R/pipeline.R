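# End-to-end pipeline: simulate -> estimate clusters -> link -> predict
# (bias-corrected) -> summarize -> sensitivity, with a provenance record.

#' Pipeline configuration
#'
#' Stage parameters with defaults matching the production settings of
#' the method: 5 km linkage radius, T = 5 correction rounds, MCMC
#' burn-in 500 with 5,000 monitored iterations, k = 10 neighbors with
#' median-distance bandwidth.
#'
#' @param synthetic A [synthetic_config()] for the data generator.
#' @param radius_km Linkage buffer radius (default 5).
#' @param iterations Bias-correction rounds T (default 5).
#' @param k Neighbors in the proximity graph (default 10).
#' @param bandwidth Gaussian bandwidth or `NULL` for the median edge
#'   distance.
#' @param lambda Ridge on the unlabeled Laplacian diagonal (default 0).
#' @param mcmc An [mcmc_settings()].
#' @param n_repeats Random-assignment repeats in the sensitivity stage.
#' @param seed Pipeline-level seed (also seeds stages that have no seed
#'   of their own).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            radius_km = 5,
                            iterations = 5L,
                            k = 10L,
                            bandwidth = NULL,
                            lambda = 0,
                            mcmc = mcmc_settings(),
                            n_repeats = 5L,
                            seed = synthetic$seed) {
  if (is.list(mcmc) && !inherits(mcmc, "mcmc_settings")) {
    mcmc <- do.call(mcmc_settings, mcmc)
  }
  structure(list(synthetic = synthetic, radius_km = radius_km,
                 iterations = as.integer(iterations), k = as.integer(k),
                 bandwidth = bandwidth, lambda = lambda, mcmc = mcmc,
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pipeline on a synthetic country
#'
#' Executes simulate, cluster estimation, linkage, bias-corrected
#' semisupervised prediction (per indicator), summaries and (optionally)
#' the sensitivity analyses.  When `out_dir` is given, writes
#' `villages.csv`, `clusters.csv`, `villages.geojson`,
#' `districts.geojson`, `cluster_estimates.csv`, `pairs.csv`,
#' `labels_reliable.csv`, `predictions.csv`, `summaries_district.csv`,
#' `summaries_state.csv`, `village_rankings.csv`, sensitivity tables and
#' `provenance.json`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory (created if missing).
#' @param sensitivity Run the sensitivity stage (default `TRUE`).
#' @param quiet Suppress stage messages.
#' @return List of class `pipeline_result` with all stage outputs.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         sensitivity = TRUE, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  say("stage simulate")
  population <- stage("simulate", generate_population(config$synthetic))
  clusters <- stage("simulate", sample_survey(population))

  say("stage estimate-clusters")
  cluster_estimates <- stage("estimate-clusters",
                             estimate_clusters(clusters, config$mcmc))

  say("stage link")
  linkage <- stage("link", link_clusters(population, clusters,
                                         cluster_estimates,
                                         radius_km = config$radius_km))

  say("stage predict")
  vil <- population$villages
  feat_cols <- grep("^f[0-9]+$", names(vil), value = TRUE)
  X <- as.matrix(vil[, feat_cols, drop = FALSE])
  graph <- stage("predict", build_graph(X, k = config$k,
                                        bandwidth = config$bandwidth))
  preds <- vil[, c("village_id", "state_id", "district_id")]
  fits <- list()
  for (ind in indicator_names()) {
    ls <- linkage$label_set
    ridx <- match(ls$labels$village_id, vil$village_id)
    if (length(ridx) == 0L) {
      stop("pipeline stage 'predict' failed: empty reliable label set",
           call. = FALSE)
    }
    y0 <- numeric(nrow(vil))
    y0[ridx] <- ls$labels[[ind]]
    cand_idx <- lapply(ls$candidates, function(v) match(v, vil$village_id))
    fit <- stage("predict", run_bias_corrected(
      y0 = y0, graph = graph, cluster_values = ls$fuzzy[[ind]],
      candidates = cand_idx, reliable_idx = ridx,
      iterations = config$iterations, lambda = config$lambda))
    preds[[ind]] <- fit$y
    fits[[ind]] <- fit
  }

  say("stage summarize")
  summaries <- stage("summarize", area_summaries(preds))
  msd <- stage("summarize", mean_sd_correlation(summaries$district))
  agg_cor <- stage("summarize", district_aggregation_correlation(
    preds, cluster_estimates, clusters))

  sens <- NULL
  if (sensitivity) {
    say("stage sensitivity")
    sens <- stage("sensitivity", list(
      robustness = random_label_robustness(
        graph, vil$village_id, linkage$label_set,
        indicator = "stunting", n_repeats = config$n_repeats,
        iterations = config$iterations, seed = config$seed),
      range = range_vs_cluster_size(
        stats::setNames(preds$stunting, preds$village_id),
        linkage$label_set$candidates)
    ))
  }

  result <- structure(list(
    population = population, clusters = clusters,
    cluster_estimates = cluster_estimates, linkage = linkage,
    graph = graph, predictions = preds, fits = fits,
    summaries = summaries, mean_sd_correlation = msd,
    district_aggregation_correlation = agg_cor,
    sensitivity = sens, config = config
  ), class = "pipeline_result")

  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "pipeline_result: %d villages, %d clusters, %d reliable labels\n",
    nrow(x$predictions), nrow(x$clusters),
    nrow(x$linkage$label_set$labels)))
  cat("district aggregation correlation:\n")
  print(round(x$district_aggregation_correlation, 3))
  invisible(x)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_villages(result$population$villages, p("villages.csv"))
  write_clusters(result$clusters, p("clusters.csv"))
  write_polygons_geojson(result$population$village_polygons,
                         p("villages.geojson"))
  write_polygons_geojson(result$population$district_polygons,
                         p("districts.geojson"))
  utils::write.csv(result$cluster_estimates, p("cluster_estimates.csv"),
                   row.names = FALSE)
  write_pairs(result$linkage$pairs, p("pairs.csv"))
  utils::write.csv(result$linkage$label_set$labels,
                   p("labels_reliable.csv"), row.names = FALSE)
  utils::write.csv(result$predictions, p("predictions.csv"),
                   row.names = FALSE)
  utils::write.csv(result$summaries$district, p("summaries_district.csv"),
                   row.names = FALSE)
  utils::write.csv(result$summaries$state, p("summaries_state.csv"),
                   row.names = FALSE)
  utils::write.csv(result$summaries$villages, p("village_rankings.csv"),
                   row.names = FALSE)
  if (!is.null(result$sensitivity)) {
    utils::write.csv(result$sensitivity$robustness,
                     p("sensitivity_robustness.csv"), row.names = FALSE)
    utils::write.csv(result$sensitivity$range$table,
                     p("sensitivity_range.csv"), row.names = FALSE)
  }
  cfg <- result$config
  prov <- list(
    package = "villagessl",
    version = as.character(utils::packageVersion("villagessl")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seeds = list(pipeline = cfg$seed, synthetic = cfg$synthetic$seed,
                 mcmc = cfg$mcmc$seed),
    parameters = list(
      radius_km = cfg$radius_km, iterations = cfg$iterations,
      k = cfg$k, bandwidth = cfg$bandwidth, lambda = cfg$lambda,
      mcmc_burn_in = cfg$mcmc$burn_in, mcmc_n_iter = cfg$mcmc$n_iter,
      n_states = cfg$synthetic$n_states,
      districts_per_state = cfg$synthetic$districts_per_state,
      villages_per_district = cfg$synthetic$villages_per_district,
      feature_dim = cfg$synthetic$feature_dim,
      cluster_fraction = cfg$synthetic$cluster_fraction
    ),
    record_counts = list(
      villages = nrow(result$population$villages),
      clusters = nrow(result$clusters),
      pairs = nrow(result$linkage$pairs),
      reliable_labels = nrow(result$linkage$label_set$labels),
      fuzzy_clusters = nrow(result$linkage$label_set$fuzzy),
      unmatched_clusters = length(result$linkage$unmatched)
    )
  )
  jsonlite::write_json(prov, p("provenance.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(out_dir)
}
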