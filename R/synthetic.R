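# Synthetic country generator.
#
# Emulates the data situation the estimation pipeline is built for: a
# census frame of rural villages nested in districts and states, each
# village carrying a feature vector of amenity flags and demographic
# proportions, and a survey that observes binomial child anthropometric
# outcomes in a subsample of villages whose GPS locations are then
# randomly displaced for confidentiality.

#' Configuration of the synthetic country and survey
#'
#' True village prevalences follow a logistic model
#' `logit(p) = beta + w'(x - x_bar) + f_state + v_district + u_village`
#' with centered normal random effects at the three geographic levels,
#' so the generated data carry both the nested variance structure the
#' multilevel shrinkage model assumes and the feature signal (`w'x`)
#' that the semisupervised cluster assumption requires.  The feature
#' effect is centered at the national mean `x_bar` so that
#' `baseline_logit` controls national prevalence regardless of `w`; the
#' defaults give national means near 38/35/22% for stunting /
#' underweight / wasting.
#'
#' @param n_states Number of states.
#' @param districts_per_state Districts per state.
#' @param villages_per_district Villages per district.
#' @param feature_dim Number of census features d (amenity flags and
#'   proportions), default 40.
#' @param baseline_logit Baseline log-odds per indicator; a scalar is
#'   recycled to the three indicators (stunting, underweight, wasting).
#' @param effect_vector Feature effects w, length `feature_dim`; default
#'   is sparse with `n_active_features` nonzero entries of size
#'   `effect_size` and alternating sign.
#' @param n_active_features,effect_size Used only to build the default
#'   `effect_vector`.
#' @param sigma2_state,sigma2_district,sigma2_village Variances of the
#'   state, district and village random effects on the logit scale.
#' @param cluster_fraction Fraction of villages surveyed as clusters,
#'   in (0, 1).
#' @param children_per_cluster Integer range (length 2) of sampled
#'   children per cluster.
#' @param district_km Side length of the square district, in km.
#' @param displacement_max_km Maximum GPS displacement for ordinary
#'   clusters (5 km).
#' @param displacement_far_km Maximum displacement for the far-displaced
#'   subset (10 km).
#' @param displacement_far_frac Fraction of clusters displaced on the far
#'   regime (0.01).
#' @param population_meanlog,population_sdlog Log-normal village
#'   population parameters.
#' @param seed Integer seed controlling all generator randomness.
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_states = 4L,
                             districts_per_state = 3L,
                             villages_per_district = 60L,
                             feature_dim = 40L,
                             baseline_logit = c(stunting = -0.62,
                                                underweight = -0.79,
                                                wasting = -1.61),
                             effect_vector = NULL,
                             n_active_features = 5L,
                             effect_size = 0.8,
                             sigma2_state = 0.3,
                             sigma2_district = 0.1,
                             sigma2_village = 0.6,
                             cluster_fraction = 0.25,
                             children_per_cluster = c(10L, 40L),
                             district_km = 25,
                             displacement_max_km = 5,
                             displacement_far_km = 10,
                             displacement_far_frac = 0.01,
                             population_meanlog = log(800),
                             population_sdlog = 0.9,
                             seed = 1L) {
  cfg <- list(
    n_states = as.integer(n_states),
    districts_per_state = as.integer(districts_per_state),
    villages_per_district = as.integer(villages_per_district),
    feature_dim = as.integer(feature_dim),
    baseline_logit = baseline_logit,
    effect_vector = effect_vector,
    n_active_features = as.integer(n_active_features),
    effect_size = effect_size,
    sigma2_state = sigma2_state,
    sigma2_district = sigma2_district,
    sigma2_village = sigma2_village,
    cluster_fraction = cluster_fraction,
    children_per_cluster = as.integer(children_per_cluster),
    district_km = district_km,
    displacement_max_km = displacement_max_km,
    displacement_far_km = displacement_far_km,
    displacement_far_frac = displacement_far_frac,
    population_meanlog = population_meanlog,
    population_sdlog = population_sdlog,
    seed = as.integer(seed)
  )
  if (cfg$n_states < 1L || cfg$districts_per_state < 1L ||
      cfg$villages_per_district < 1L) {
    stop("hierarchy dimensions must be positive integers", call. = FALSE)
  }
  if (cfg$feature_dim < 1L) stop("feature_dim must be >= 1", call. = FALSE)
  if (length(cfg$baseline_logit) == 1L) {
    cfg$baseline_logit <- stats::setNames(rep(cfg$baseline_logit, 3L),
                                          indicator_names())
  }
  if (length(cfg$baseline_logit) != 3L) {
    stop("baseline_logit must have length 1 or 3", call. = FALSE)
  }
  names(cfg$baseline_logit) <- indicator_names()
  if (is.null(cfg$effect_vector)) {
    w <- numeric(cfg$feature_dim)
    k <- min(cfg$n_active_features, cfg$feature_dim)
    if (k > 0L) w[seq_len(k)] <- cfg$effect_size * (-1)^(seq_len(k) + 1L)
    cfg$effect_vector <- w
  }
  if (length(cfg$effect_vector) != cfg$feature_dim) {
    stop("effect_vector must have length feature_dim", call. = FALSE)
  }
  for (v in c("sigma2_state", "sigma2_district", "sigma2_village")) {
    stopifnot_scalar(cfg[[v]], v)
    if (cfg[[v]] < 0) stop(sprintf("'%s' must be >= 0", v), call. = FALSE)
  }
  if (!(cfg$cluster_fraction > 0 && cfg$cluster_fraction < 1)) {
    stop("cluster_fraction must lie strictly in (0, 1)", call. = FALSE)
  }
  if (length(cfg$children_per_cluster) != 2L ||
      any(cfg$children_per_cluster < 1L) ||
      cfg$children_per_cluster[1L] > cfg$children_per_cluster[2L]) {
    stop("children_per_cluster must be an increasing positive integer range",
         call. = FALSE)
  }
  if (cfg$displacement_far_frac < 0 || cfg$displacement_far_frac > 1) {
    stop("displacement_far_frac must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$displacement_far_km < cfg$displacement_max_km) {
    stop("displacement_far_km must be >= displacement_max_km", call. = FALSE)
  }
  class(cfg) <- "synthetic_config"
  cfg
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "synthetic_config: %d states x %d districts x %d villages (d = %d)\n",
    x$n_states, x$districts_per_state, x$villages_per_district,
    x$feature_dim))
  cat(sprintf("  logit variances state/district/village: %.3g / %.3g / %.3g\n",
              x$sigma2_state, x$sigma2_district, x$sigma2_village))
  cat(sprintf("  cluster_fraction %.3g, children %d-%d, seed %d\n",
              x$cluster_fraction, x$children_per_cluster[1L],
              x$children_per_cluster[2L], x$seed))
  invisible(x)
}

# 16-digit hierarchical village code: state(2) district(3) subunit(3)
# village(8), emulating census identifier structure.
village_code <- function(state, district, serial) {
  sprintf("%02d%03d%03d%08d", state, district, 1L, serial)
}

#' Generate the synthetic census village frame
#'
#' Lays states out on a grid of rectangular blocks, tiles each state with
#' rectangular districts, scatters villages uniformly within each
#' district and takes their Voronoi cells (clipped to the district) as
#' village polygons.  Features are a half/half mix of Bernoulli amenity
#' flags and Beta-distributed proportions, both with district-level
#' heterogeneity so that feature similarity carries geographic signal, as
#' it does for real census amenities.  True prevalences for the three
#' indicators follow the logistic model described in
#' [synthetic_config()].
#'
#' @param config A [synthetic_config()].
#' @param polygons Build village Voronoi polygons (default `TRUE`).
#'   Setting `FALSE` skips the geometry (useful for purely statistical
#'   experiments).
#' @return An object of class `synthetic_population`: a list with
#'   `villages` (data frame), `village_polygons` (named list),
#'   `district_polygons` (named list), `effects` (the drawn random
#'   effects, for diagnostics) and `config`.
#' @export
generate_population <- function(config, polygons = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, generate_population_impl(config, polygons))
}

generate_population_impl <- function(cfg, polygons) {
  S <- cfg$n_states; D <- cfg$districts_per_state; V <- cfg$villages_per_district
  d <- cfg$feature_dim
  n_districts <- S * D
  n_villages <- n_districts * V

  # state blocks on a near-square national grid; districts tile each
  # state block on a near-square grid of district_km squares
  d_cols <- ceiling(sqrt(D)); d_rows <- ceiling(D / d_cols)
  state_w <- d_cols * cfg$district_km
  state_h <- d_rows * cfg$district_km
  s_cols <- ceiling(sqrt(S))

  district_polygons <- vector("list", n_districts)
  district_ids <- character(n_districts)
  state_of_district <- character(n_districts)
  idx <- 0L
  for (s in seq_len(S)) {
    sx <- ((s - 1L) %% s_cols) * state_w
    sy <- ((s - 1L) %/% s_cols) * state_h
    for (k in seq_len(D)) {
      idx <- idx + 1L
      dx <- sx + ((k - 1L) %% d_cols) * cfg$district_km
      dy <- sy + ((k - 1L) %/% d_cols) * cfg$district_km
      district_polygons[[idx]] <- rect_polygon(dx, dy, dx + cfg$district_km,
                                               dy + cfg$district_km)
      district_ids[idx] <- sprintf("%02d%03d", s, (s - 1L) * D + k)
      state_of_district[idx] <- sprintf("%02d", s)
    }
  }
  names(district_polygons) <- district_ids

  # feature schema: first half Bernoulli amenity flags, second half Beta
  # proportions; both get district-level heterogeneity
  n_bin <- d %/% 2L
  n_beta <- d - n_bin
  flag_logit <- stats::qlogis(stats::runif(n_bin, 0.2, 0.8))
  beta_mean <- stats::runif(n_beta, 0.2, 0.8)
  beta_conc <- stats::runif(n_beta, 8, 25)
  dist_flag_shift <- matrix(stats::rnorm(n_districts * n_bin, 0, 0.8),
                            n_districts, n_bin)
  dist_beta_shift <- matrix(stats::rnorm(n_districts * n_beta, 0, 0.3),
                            n_districts, n_beta)

  # random effects per indicator (independent draws across indicators)
  ind <- indicator_names()
  f_state <- matrix(stats::rnorm(S * 3L, 0, sqrt(cfg$sigma2_state)), S, 3L,
                    dimnames = list(NULL, ind))
  v_district <- matrix(stats::rnorm(n_districts * 3L, 0,
                                    sqrt(cfg$sigma2_district)),
                       n_districts, 3L, dimnames = list(NULL, ind))
  u_village <- matrix(stats::rnorm(n_villages * 3L, 0,
                                   sqrt(cfg$sigma2_village)),
                      n_villages, 3L, dimnames = list(NULL, ind))

  rows <- vector("list", n_districts)
  village_polygons <- vector("list", n_villages)
  poly_names <- character(n_villages)
  vidx <- 0L
  for (k in seq_len(n_districts)) {
    poly <- district_polygons[[k]]
    xr <- range(poly[, 1L]); yr <- range(poly[, 2L])
    px <- stats::runif(V, xr[1L], xr[2L])
    py <- stats::runif(V, yr[1L], yr[2L])
    pop <- pmax(50L, pmin(20000L, round(stats::rlnorm(
      V, cfg$population_meanlog, cfg$population_sdlog))))
    flags <- matrix(stats::rbinom(V * n_bin, 1L,
                                  stats::plogis(rep(flag_logit + dist_flag_shift[k, ],
                                                    each = V))),
                    V, n_bin)
    mu <- stats::plogis(stats::qlogis(rep(beta_mean, each = V)) +
                          rep(dist_beta_shift[k, ], each = V))
    conc <- rep(beta_conc, each = V)
    props <- matrix(stats::rbeta(V * n_beta, mu * conc, (1 - mu) * conc),
                    V, n_beta)
    X <- cbind(flags, props)
    colnames(X) <- paste0("f", seq_len(d))
    s <- match(state_of_district[k], sprintf("%02d", seq_len(S)))
    sl <- (vidx + 1L):(vidx + V)
    ids <- village_code(s, k, sl)
    rows[[k]] <- data.frame(
      village_id = ids,
      state_id = state_of_district[k],
      district_id = district_ids[k],
      x_km = px, y_km = py,
      population = as.integer(pop),
      X,
      stringsAsFactors = FALSE
    )
    if (polygons) {
      cells <- voronoi_cells(cbind(px, py), poly)
      village_polygons[sl] <- cells
    }
    poly_names[sl] <- ids
    vidx <- vidx + V
  }
  villages <- do.call(rbind, rows)
  rownames(villages) <- NULL
  names(village_polygons) <- poly_names

  # feature effect, centered at the national mean so baseline_logit
  # controls national prevalence
  wx <- as.vector(as.matrix(
    villages[, paste0("f", seq_len(d)), drop = FALSE]) %*% cfg$effect_vector)
  wx_c <- wx - mean(wx)
  s_of_village <- match(villages$state_id, sprintf("%02d", seq_len(S)))
  k_of_village <- match(villages$district_id, district_ids)
  for (i in seq_len(3L)) {
    ind <- indicator_names()[i]
    logit <- cfg$baseline_logit[i] + wx_c +
      f_state[s_of_village, i] + v_district[k_of_village, i] +
      u_village[, i]
    villages[[paste0("true_", ind)]] <- stats::plogis(logit)
  }
  structure(list(
    villages = villages,
    village_polygons = if (polygons) village_polygons else NULL,
    district_polygons = district_polygons,
    effects = list(state = f_state, district = v_district,
                   village = u_village, wx = wx_c,
                   wx_var = stats::var(wx)),
    config = cfg
  ), class = "synthetic_population")
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat(sprintf("synthetic_population: %d villages in %d districts, %d states\n",
              nrow(x$villages), length(x$district_polygons),
              x$config$n_states))
  invisible(x)
}

#' Displace a point within its district, DHS-style
#'
#' Draws a uniform angle and a uniform distance on `[0, R]`, where `R`
#' is the far radius (10 km) with probability `displacement_far_frac`
#' and otherwise the ordinary maximum (5 km).  Candidates outside the
#' district polygon are rejected and redrawn; after `max_attempts`
#' failures the radius is halved per retry, and as a last resort the
#' true location is returned with a warning.
#'
#' @param point True location, length-2 numeric (km).
#' @param district_polygon Convex district polygon.
#' @param config A [synthetic_config()] (for the displacement rules).
#' @param max_attempts Rejection draws before radius shrinking starts.
#' @return List with `point` (displaced location) and `far` (logical,
#'   whether the far regime was drawn).
#' @export
displace_gps <- function(point, district_polygon, config, max_attempts = 100L) {
  if (!point_in_convex_polygon(point, district_polygon)) {
    stop("true point must lie inside the district polygon", call. = FALSE)
  }
  far <- stats::runif(1L) < config$displacement_far_frac
  R <- if (far) config$displacement_far_km else config$displacement_max_km
  for (i in seq_len(max_attempts)) {
    cand <- point + stats::runif(1L, 0, R) *
      c(cos(a <- stats::runif(1L, 0, 2 * pi)), sin(a))
    if (point_in_convex_polygon(cand, district_polygon)) {
      return(list(point = cand, far = far))
    }
  }
  r <- R
  for (i in seq_len(30L)) {
    r <- r / 2
    cand <- point + stats::runif(1L, 0, r) *
      c(cos(a <- stats::runif(1L, 0, 2 * pi)), sin(a))
    if (point_in_convex_polygon(cand, district_polygon)) {
      return(list(point = cand, far = far))
    }
  }
  warning("displacement failed to find an interior point; using true location",
          call. = FALSE)
  list(point = point, far = far)
}

#' Survey a synthetic population
#'
#' Selects `ceiling(cluster_fraction * N)` villages by simple random
#' sampling without replacement, draws the number of measured children
#' uniformly from the configured range, binomial failure counts per
#' indicator at the village's true prevalences, a cluster population
#' uniform on `[1, village population]`, and a displaced GPS location via
#' [displace_gps()].
#'
#' @param population A `synthetic_population`.
#' @param config Optional [synthetic_config()]; defaults to the one the
#'   population was generated with.
#' @return Data frame of clusters (class `synthetic_survey` attribute
#'   kept as a plain data frame): `cluster_id`, `source_village_id`,
#'   `state_id`, `district_id`, `x_km`, `y_km` (displaced), `true_x_km`,
#'   `true_y_km`, `n_children`, `fail_stunting`, `fail_underweight`,
#'   `fail_wasting`, `rural`, `population`, `displaced_far`.
#' @export
sample_survey <- function(population, config = population$config) {
  stopifnot(inherits(population, "synthetic_population"))
  withr::with_seed(config$seed + 1L, sample_survey_impl(population, config))
}

sample_survey_impl <- function(population, cfg) {
  vil <- population$villages
  N <- nrow(vil)
  n_clusters <- ceiling(cfg$cluster_fraction * N)
  if (n_clusters < 1L) stop("cluster_fraction * N < 1", call. = FALSE)
  sel <- sort(sample.int(N, n_clusters))
  src <- vil[sel, , drop = FALSE]
  n_children <- sample(seq(cfg$children_per_cluster[1L],
                           cfg$children_per_cluster[2L]),
                       n_clusters, replace = TRUE)
  fails <- sapply(indicator_names(), function(ind) {
    stats::rbinom(n_clusters, n_children, src[[paste0("true_", ind)]])
  })
  cpop <- vapply(src$population, function(p) sample.int(p, 1L), integer(1L))
  pts <- matrix(NA_real_, n_clusters, 2L)
  far <- logical(n_clusters)
  for (i in seq_len(n_clusters)) {
    dp <- population$district_polygons[[src$district_id[i]]]
    res <- displace_gps(c(src$x_km[i], src$y_km[i]), dp, cfg)
    pts[i, ] <- res$point
    far[i] <- res$far
  }
  data.frame(
    cluster_id = sprintf("C%05d", seq_len(n_clusters)),
    source_village_id = src$village_id,
    state_id = src$state_id,
    district_id = src$district_id,
    x_km = pts[, 1L], y_km = pts[, 2L],
    true_x_km = src$x_km, true_y_km = src$y_km,
    n_children = as.integer(n_children),
    fail_stunting = as.integer(fails[, "stunting"]),
    fail_underweight = as.integer(fails[, "underweight"]),
    fail_wasting = as.integer(fails[, "wasting"]),
    rural = TRUE,
    population = as.integer(cpop),
    displaced_far = far,
    stringsAsFactors = FALSE
  )
}
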