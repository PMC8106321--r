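# Descriptive summaries, rankings and the three sensitivity analyses.

# Median-unbiased quantiles (type 8), the package-wide convention.
q8 <- function(x, p) as.numeric(stats::quantile(x, p, type = 8, names = FALSE))

# equal-count bins 1..n_bins, ties broken by id (deterministic)
equal_count_bins <- function(values, ids, n_bins = 10L) {
  n <- length(values)
  ord <- order(values, ids)
  bins <- integer(n)
  bins[ord] <- ceiling(seq_len(n) * n_bins / n)
  bins
}

# dense ranking, highest value = rank 1, ties share a rank
dense_rank_desc <- function(x) {
  ux <- sort(unique(x), decreasing = TRUE)
  match(x, ux)
}

#' Per-district and per-state summaries and village rankings
#'
#' Means, SDs and interquartile ranges per district and state; national
#' equal-count decile bins (decile 10 = highest burden); and dense
#' within-district, within-state and national ranks (rank 1 = highest
#' burden), per indicator.
#'
#' @param predictions Data frame with `village_id`, `district_id`,
#'   `state_id` and one column per indicator.
#' @param indicators Indicator columns to summarize (default
#'   [indicator_names()]).
#' @return List: `district` and `state` summary data frames (long, one
#'   row per area x indicator), and `villages` -- one row per village
#'   with decile and rank columns per indicator.
#' @export
area_summaries <- function(predictions, indicators = indicator_names()) {
  indicators <- intersect(indicators, names(predictions))
  if (!length(indicators)) stop("no indicator columns found", call. = FALSE)

  summarize_by <- function(group) {
    rows <- list()
    for (ind in indicators) {
      sp <- split(predictions[[ind]], predictions[[group]])
      sp <- sp[lengths(sp) > 0L]
      rows[[ind]] <- data.frame(
        area_id = names(sp),
        indicator = ind,
        n_villages = lengths(sp),
        mean = vapply(sp, mean, numeric(1L)),
        sd = vapply(sp, stats::sd, numeric(1L)),
        p25 = vapply(sp, q8, numeric(1L), p = 0.25),
        p75 = vapply(sp, q8, numeric(1L), p = 0.75),
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  }

  villages <- predictions[, c("village_id", "district_id", "state_id",
                              indicators), drop = FALSE]
  for (ind in indicators) {
    v <- predictions[[ind]]
    villages[[paste0("decile_", ind)]] <-
      equal_count_bins(v, predictions$village_id)
    villages[[paste0("rank_national_", ind)]] <- dense_rank_desc(v)
    villages[[paste0("rank_state_", ind)]] <-
      stats::ave(v, predictions$state_id,
                 FUN = function(z) dense_rank_desc(z))
    villages[[paste0("rank_district_", ind)]] <-
      stats::ave(v, predictions$district_id,
                 FUN = function(z) dense_rank_desc(z))
  }
  list(district = summarize_by("district_id"),
       state = summarize_by("state_id"),
       villages = villages)
}

#' Correlation between district means and district SDs
#'
#' Pearson correlation, per indicator, of the district-wide mean against
#' the district-wide SD of village predictions.  Degenerate inputs (no
#' spread in either vector) yield `NA` with a warning.
#'
#' @param district_summary The `district` element of [area_summaries()].
#' @return Named numeric vector, one correlation per indicator.
#' @export
mean_sd_correlation <- function(district_summary) {
  inds <- unique(district_summary$indicator)
  out <- stats::setNames(rep(NA_real_, length(inds)), inds)
  for (ind in inds) {
    d <- district_summary[district_summary$indicator == ind, ]
    if (nrow(d) < 3L) {
      warning("fewer than 3 districts for ", ind, call. = FALSE)
      next
    }
    if (stats::sd(d$mean) == 0 || stats::sd(d$sd) == 0 ||
        anyNA(d$sd)) {
      warning("degenerate mean/SD spread for ", ind,
              "; correlation undefined", call. = FALSE)
      next
    }
    out[ind] <- stats::cor(d$mean, d$sd)
  }
  out
}

#' Robustness of predictions to random initial label assignment
#'
#' Instead of seeding the semisupervised regression with the reliable
#' one-to-one label set, each repeat assigns every labeled cluster's
#' indicator value to one village drawn uniformly from its candidate
#' list (single-candidate clusters have a forced assignment), then runs
#' the full bias-corrected iteration.  Reported are the 25th, 50th and
#' 75th percentiles of the final predictions per repeat; stable
#' quartiles across repeats mean the method does not hinge on the
#' initial assignment.
#'
#' @param graph A [build_graph()] result (or feature matrix).
#' @param village_ids Village ids in graph node order.
#' @param label_set A `reliable_label_set` (its fuzzy clusters and
#'   candidate lists are used).
#' @param indicator Indicator name to analyze.
#' @param n_repeats Number of random assignments (default 5).
#' @param iterations Correction rounds T (default 5).
#' @param seed Base seed; repeat r uses `seed + r`.
#' @return Data frame: `repeat_id`, `q25`, `q50`, `q75`.
#' @export
random_label_robustness <- function(graph, village_ids, label_set,
                                    indicator = "stunting",
                                    n_repeats = 5L, iterations = 5L,
                                    seed = 1L) {
  if (n_repeats < 2L) stop("need at least 2 repeats", call. = FALSE)
  if (!inherits(graph, "proximity_graph")) graph <- build_graph(graph)
  n <- graph$n
  fuzzy_vals <- label_set$fuzzy[[indicator]]
  cand_idx <- lapply(label_set$candidates,
                     function(v) match(v, village_ids))
  single_idx <- match(label_set$singles$village_id, village_ids)
  single_vals <- label_set$singles[[indicator]]
  rows <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    drawn <- withr::with_seed(seed + r, vapply(cand_idx, function(v) {
      v[sample.int(length(v), 1L)]
    }, integer(1L)))
    # one village per labeled cluster: random draw for fuzzy clusters,
    # the forced assignment for single-candidate clusters; collisions
    # keep the first cluster's value
    assigned <- c(single_idx, drawn)
    vals <- c(single_vals, fuzzy_vals)
    keep <- !duplicated(assigned)
    y0 <- numeric(n)
    y0[assigned[keep]] <- vals[keep]
    fit <- run_bias_corrected(
      y0 = y0, graph = graph, cluster_values = fuzzy_vals,
      candidates = cand_idx, reliable_idx = assigned[keep],
      iterations = iterations)
    rows[[r]] <- data.frame(repeat_id = r,
                            q25 = q8(fit$y, 0.25),
                            q50 = q8(fit$y, 0.50),
                            q75 = q8(fit$y, 0.75))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Prediction range across each cluster's candidate villages
#'
#' For every fuzzy cluster, the spread (max minus min) of the final
#' predictions over its candidate villages, together with the Spearman
#' rank correlation between candidate-set size and range.  A growing
#' range with candidate count mirrors the intuition that heavily
#' ambiguous clusters carry more prediction uncertainty.
#'
#' @param predictions Named numeric vector of village predictions (names
#'   are village ids) or a plain vector with `village_ids` supplied.
#' @param candidates Named list of candidate village-id vectors per
#'   cluster.
#' @param village_ids Optional village ids aligned with `predictions`.
#' @return List: `table` (data frame `cluster_id`, `n_candidates`,
#'   `range`) and `spearman` (rank correlation).
#' @export
range_vs_cluster_size <- function(predictions, candidates,
                                  village_ids = names(predictions)) {
  p <- as.numeric(predictions)
  names(p) <- village_ids
  tab <- data.frame(
    cluster_id = names(candidates),
    n_candidates = lengths(candidates),
    range = vapply(candidates, function(v) {
      vals <- p[v]
      if (!length(vals)) return(NA_real_)
      max(vals) - min(vals)
    }, numeric(1L)),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  sp <- if (nrow(tab) >= 3L && stats::sd(tab$n_candidates) > 0 &&
            stats::sd(tab$range, na.rm = TRUE) > 0) {
    stats::cor(tab$n_candidates, tab$range, method = "spearman",
               use = "complete.obs")
  } else NA_real_
  list(table = tab, spearman = sp)
}

#' District-level agreement between predictions and labeled clusters
#'
#' Pearson correlation, per indicator, between district means of the
#' final village predictions and district means of the labeled cluster
#' estimates -- the aggregation consistency check.
#'
#' @param predictions Data frame `village_id`, `district_id` + indicator
#'   columns.
#' @param cluster_estimates Data frame `cluster_id` + indicator columns.
#' @param clusters Survey data frame giving each cluster's
#'   `district_id`.
#' @param indicators Indicator columns (default [indicator_names()]).
#' @return Named numeric vector of correlations.
#' @export
district_aggregation_correlation <- function(predictions, cluster_estimates,
                                             clusters,
                                             indicators = indicator_names()) {
  indicators <- intersect(indicators, names(predictions))
  cd <- clusters$district_id[match(cluster_estimates$cluster_id,
                                   clusters$cluster_id)]
  out <- stats::setNames(rep(NA_real_, length(indicators)), indicators)
  for (ind in indicators) {
    vm <- tapply(predictions[[ind]], predictions$district_id, mean)
    cm <- tapply(cluster_estimates[[ind]], cd, mean)
    common <- intersect(names(vm), names(cm))
    if (length(common) < 3L) {
      warning("fewer than 3 districts with labeled clusters for ", ind,
              call. = FALSE)
      next
    }
    a <- as.numeric(vm[common]); b <- as.numeric(cm[common])
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("degenerate district means for ", ind, call. = FALSE)
      next
    }
    out[ind] <- stats::cor(a, b)
  }
  out
}
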