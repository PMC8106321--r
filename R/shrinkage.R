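# Precision-weighted cluster prevalence estimation.
#
# A four-level random-intercept logistic model -- child i in cluster j in
# district k in state l:
#
#   logit(pi_ijkl) = beta + u_jkl + v_kl + f_l,
#   u ~ N(0, s2u), v ~ N(0, s2v), f ~ N(0, s2f),
#
# fitted by MCMC.  Because the linear predictor is constant within a
# cluster, the child-level Bernoulli likelihood collapses exactly to one
# binomial term per cluster, which is what the sampler works with.  The
# sampler is random-walk Metropolis-within-Gibbs for beta and the random
# effects (each block vectorized over its units) with conjugate
# inverse-gamma Gibbs draws for the three variances.  Priors are diffuse:
# N(0, 1e6) on beta and IG(0.001, 0.001) on each variance.  The
# individual-level latent residual variance is the usual logistic
# constant pi^2/3.

#' MCMC settings for the four-level model
#'
#' @param burn_in Burn-in iterations discarded (default 500).
#' @param n_iter Monitored iterations (default 5000).
#' @param seed Integer seed for the chain.
#' @param adapt_interval Step-size adaptation cadence during burn-in.
#' @param keep_draws Keep per-cluster prevalence draws (memory scales
#'   with clusters x iterations; off by default).
#' @param ess_warn Warn when the effective sample size of any variance
#'   chain falls below this (default 100).
#' @return A list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(burn_in = 500L, n_iter = 5000L, seed = 1L,
                          adapt_interval = 50L, keep_draws = FALSE,
                          ess_warn = 100) {
  s <- list(burn_in = as.integer(burn_in), n_iter = as.integer(n_iter),
            seed = as.integer(seed), adapt_interval = as.integer(adapt_interval),
            keep_draws = isTRUE(keep_draws), ess_warn = ess_warn)
  if (s$burn_in < 0L || s$n_iter < 1L) stop("bad chain lengths", call. = FALSE)
  class(s) <- "mcmc_settings"
  s
}

#' Latent-variable level-1 variance of a logistic model
#'
#' The conventional individual-level residual variance on the latent
#' scale, `pi^2 / 3`.
#'
#' @return A numeric scalar, about 3.2899.
#' @export
latent_level1_variance <- function() pi^2 / 3

#' Fit the four-level random-intercept logistic model
#'
#' Accepts child-level binary records.  Each record must carry its
#' cluster, district and state identifier; records are collapsed to
#' per-cluster binomial counts (exact for this model) before sampling.
#' Starting values come from method-of-moments on clamped empirical
#' logits.  A level observed with a single unit has its variance fixed
#' at 0 with a warning.
#'
#' @param child_outcomes Data frame with columns `outcome` (0/1),
#'   `cluster_id`, `district_id`, `state_id`.
#' @param settings An [mcmc_settings()].
#' @return Object of class `four_level_fit`: posterior chains for
#'   `beta`, `sigma2_u`, `sigma2_v`, `sigma2_f`; per-cluster posterior
#'   prevalence means/sds; acceptance rates; effective sample sizes.
#' @seealso [predict_cluster_probabilities()], [fit_multilevel_counts()]
#' @export
fit_multilevel <- function(child_outcomes, settings = mcmc_settings()) {
  req <- c("outcome", "cluster_id", "district_id", "state_id")
  miss <- setdiff(req, names(child_outcomes))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  y <- child_outcomes$outcome
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  key <- child_outcomes$cluster_id
  agg_y <- rowsum(as.numeric(y), key)
  agg_n <- rowsum(rep(1, length(y)), key)
  first <- !duplicated(key)
  map <- child_outcomes[first, c("cluster_id", "district_id", "state_id")]
  ord <- match(rownames(agg_y), map$cluster_id)
  fit_multilevel_counts(
    y = as.vector(agg_y), n = as.vector(agg_n),
    cluster_id = rownames(agg_y),
    district_id = map$district_id[ord],
    state_id = map$state_id[ord],
    settings = settings
  )
}

#' Fit the four-level model from per-cluster binomial counts
#'
#' Same model as [fit_multilevel()], taking the collapsed sufficient
#' statistics directly: failures `y` out of `n` children per cluster.
#'
#' @param y,n Integer vectors of failures and children per cluster.
#' @param cluster_id,district_id,state_id Identifier vectors, one entry
#'   per cluster.
#' @param settings An [mcmc_settings()].
#' @return A `four_level_fit`.
#' @export
fit_multilevel_counts <- function(y, n, cluster_id, district_id, state_id,
                                  settings = mcmc_settings()) {
  stopifnot(length(y) == length(n), length(y) == length(cluster_id),
            length(y) == length(district_id), length(y) == length(state_id))
  if (any(y < 0 | y > n)) stop("need 0 <= y <= n", call. = FALSE)
  withr::with_seed(settings$seed, gibbs_4level(
    as.numeric(y), as.numeric(n), as.character(cluster_id),
    as.character(district_id), as.character(state_id), settings))
}

gibbs_4level <- function(y, n, cluster_id, district_id, state_id, st) {
  J <- length(y)
  dist_f <- factor(district_id)
  state_f <- factor(state_id)
  K <- nlevels(dist_f); L <- nlevels(state_f)
  dj <- as.integer(dist_f)
  sj <- as.integer(state_f)
  # state of each district (consistency check on nesting)
  sk <- vapply(seq_len(K), function(k) unique(sj[dj == k]), integer(1L))

  est_u <- J > 1L; est_v <- K > 1L; est_f <- L > 1L
  if (!est_f) warning("single state: state variance fixed at 0", call. = FALSE)
  if (!est_v) warning("single district: district variance fixed at 0", call. = FALSE)
  if (!est_u) warning("single cluster: cluster variance fixed at 0", call. = FALSE)

  # method-of-moments starting values on clamped empirical logits
  lg <- logit_clamped(y / n)
  m_state <- as.vector(tapply(lg, sj, mean))
  m_dist <- as.vector(tapply(lg, dj, mean))
  beta <- mean(lg)
  f <- if (est_f) m_state - beta else rep(0, L)
  v <- if (est_v) m_dist - (beta + f[sk]) else rep(0, K)
  u <- if (est_u) lg - (beta + v[dj] + f[sj]) else rep(0, J)
  s2u <- if (est_u) max(stats::var(u), 0.05) else 0
  s2v <- if (est_v) max(stats::var(v), 0.02) else 0
  s2f <- if (est_f) max(stats::var(f), 0.02) else 0

  a0 <- 0.001; b0 <- 0.001  # IG prior
  beta_prior_var <- 1e6

  step_u <- 0.5; step_v <- 0.3; step_f <- 0.3; step_b <- 0.2
  eta <- beta + u + v[dj] + f[sj]
  ll <- binom_loglik(y, n, eta)

  n_tot <- st$burn_in + st$n_iter
  chains <- matrix(NA_real_, st$n_iter, 4L,
                   dimnames = list(NULL, c("beta", "sigma2_u", "sigma2_v",
                                           "sigma2_f")))
  p_sum <- numeric(J); p_sq <- numeric(J)
  p_draws <- if (st$keep_draws) matrix(NA_real_, st$n_iter, J) else NULL
  acc <- c(u = 0, v = 0, f = 0, beta = 0)
  acc_win <- c(u = 0, v = 0, f = 0, beta = 0); win_n <- 0L

  for (it in seq_len(n_tot)) {
    # clusters: independent univariate RW-MH, vectorized
    if (est_u) {
      u_p <- u + step_u * stats::rnorm(J)
      eta_p <- eta + (u_p - u)
      ll_p <- binom_loglik(y, n, eta_p)
      lr <- ll_p - ll + (u^2 - u_p^2) / (2 * s2u)
      ok <- log(stats::runif(J)) < lr
      u[ok] <- u_p[ok]; eta[ok] <- eta_p[ok]; ll[ok] <- ll_p[ok]
      acc_win["u"] <- acc_win["u"] + mean(ok)
    }
    # districts
    if (est_v) {
      v_p <- v + step_v * stats::rnorm(K)
      eta_p <- eta + (v_p - v)[dj]
      dll <- rowsum(binom_loglik(y, n, eta_p) - ll, dj, reorder = TRUE)
      lr <- as.vector(dll) + (v^2 - v_p^2) / (2 * s2v)
      ok <- log(stats::runif(K)) < lr
      v[ok] <- v_p[ok]
      eta <- beta + u + v[dj] + f[sj]
      ll <- binom_loglik(y, n, eta)
      acc_win["v"] <- acc_win["v"] + mean(ok)
    }
    # states
    if (est_f) {
      f_p <- f + step_f * stats::rnorm(L)
      eta_p <- eta + (f_p - f)[sj]
      dll <- rowsum(binom_loglik(y, n, eta_p) - ll, sj, reorder = TRUE)
      lr <- as.vector(dll) + (f^2 - f_p^2) / (2 * s2f)
      ok <- log(stats::runif(L)) < lr
      f[ok] <- f_p[ok]
      eta <- beta + u + v[dj] + f[sj]
      ll <- binom_loglik(y, n, eta)
      acc_win["f"] <- acc_win["f"] + mean(ok)
    }
    # intercept
    b_p <- beta + step_b * stats::rnorm(1L)
    eta_p <- eta + (b_p - beta)
    ll_p <- binom_loglik(y, n, eta_p)
    lr <- sum(ll_p - ll) + (beta^2 - b_p^2) / (2 * beta_prior_var)
    if (log(stats::runif(1L)) < lr) {
      beta <- b_p; eta <- eta_p; ll <- ll_p
      acc_win["beta"] <- acc_win["beta"] + 1
    }
    # interweaving sweeps: exact Gibbs moves along the confounded
    # directions (shift mass between adjacent levels, leaving the
    # linear predictor unchanged) -- these fix the slow mixing of the
    # intercept against the random-effect means
    if (est_f) {
      prec <- L / s2f + 1 / beta_prior_var
      delta <- stats::rnorm(1L, (sum(f) / s2f - beta / beta_prior_var) / prec,
                            1 / sqrt(prec))
      beta <- beta + delta; f <- f - delta
    } else if (est_v) {
      prec <- K / s2v + 1 / beta_prior_var
      delta <- stats::rnorm(1L, (sum(v) / s2v - beta / beta_prior_var) / prec,
                            1 / sqrt(prec))
      beta <- beta + delta; v <- v - delta
    }
    if (est_f && est_v) {
      Kl <- tabulate(sk, L)                      # districts per state
      sv <- as.vector(rowsum(v, sk, reorder = TRUE))
      prec <- 1 / s2f + Kl / s2v
      delta <- stats::rnorm(L, (sv / s2v - f / s2f) / prec, 1 / sqrt(prec))
      f <- f + delta; v <- v - delta[sk]
    }
    if (est_v && est_u) {
      Jk <- tabulate(dj, K)                      # clusters per district
      su <- as.vector(rowsum(u, dj, reorder = TRUE))
      prec <- 1 / s2v + Jk / s2u
      delta <- stats::rnorm(K, (su / s2u - v / s2v) / prec, 1 / sqrt(prec))
      v <- v + delta; u <- u - delta[dj]
    }
    # variances: conjugate inverse-gamma
    if (est_u) s2u <- 1 / stats::rgamma(1L, a0 + J / 2, b0 + sum(u^2) / 2)
    if (est_v) s2v <- 1 / stats::rgamma(1L, a0 + K / 2, b0 + sum(v^2) / 2)
    if (est_f) s2f <- 1 / stats::rgamma(1L, a0 + L / 2, b0 + sum(f^2) / 2)

    win_n <- win_n + 1L
    if (it <= st$burn_in && win_n == st$adapt_interval) {
      rate <- acc_win / win_n
      adj <- function(step, r) min(5, max(1e-3, step * exp(r - 0.44)))
      step_u <- adj(step_u, rate["u"]); step_v <- adj(step_v, rate["v"])
      step_f <- adj(step_f, rate["f"]); step_b <- adj(step_b, rate["beta"])
      acc_win[] <- 0; win_n <- 0L
    }
    if (it > st$burn_in) {
      i <- it - st$burn_in
      chains[i, ] <- c(beta, s2u, s2v, s2f)
      p <- stats::plogis(eta)
      p_sum <- p_sum + p
      p_sq <- p_sq + p^2
      if (st$keep_draws) p_draws[i, ] <- p
      acc <- acc + acc_win; acc_win[] <- 0; win_n <- 0L
    }
  }

  prev <- p_sum / st$n_iter
  prev_sd <- sqrt(pmax(p_sq / st$n_iter - prev^2, 0))
  ess_var <- c(sigma2_u = if (est_u) ess(chains[, "sigma2_u"]) else NA_real_,
               sigma2_v = if (est_v) ess(chains[, "sigma2_v"]) else NA_real_,
               sigma2_f = if (est_f) ess(chains[, "sigma2_f"]) else NA_real_)
  low <- ess_var[!is.na(ess_var) & ess_var < st$ess_warn]
  if (length(low)) {
    warning("low effective sample size for ",
            paste(names(low), collapse = ", "), call. = FALSE)
  }
  structure(list(
    clusters = data.frame(cluster_id = cluster_id,
                          district_id = district_id, state_id = state_id,
                          y = y, n = n,
                          prevalence = prev, prevalence_sd = prev_sd,
                          stringsAsFactors = FALSE),
    chains = chains,
    p_draws = p_draws,
    estimated = c(u = est_u, v = est_v, f = est_f),
    acceptance = acc / st$n_iter,
    ess = ess_var,
    latent_level1_variance = latent_level1_variance(),
    settings = st
  ), class = "four_level_fit")
}

#' @export
print.four_level_fit <- function(x, ...) {
  pm <- colMeans(x$chains)
  cat(sprintf("four_level_fit: %d clusters; posterior means beta = %.3f, ",
              nrow(x$clusters), pm["beta"]))
  cat(sprintf("s2u = %.3f, s2v = %.3f, s2f = %.3f\n",
              pm["sigma2_u"], pm["sigma2_v"], pm["sigma2_f"]))
  invisible(x)
}

#' Posterior cluster prevalences
#'
#' Converts the per-draw linear predictors to probabilities and averages
#' over the monitored draws: `mean over draws of
#' inv_logit(beta + u + v + f)` per cluster.
#'
#' @param model A `four_level_fit`.
#' @return Data frame: `cluster_id`, `prevalence`, `prevalence_sd`.
#' @export
predict_cluster_probabilities <- function(model) {
  stopifnot(inherits(model, "four_level_fit"))
  model$clusters[, c("cluster_id", "prevalence", "prevalence_sd")]
}

#' Precision-weighted estimates for all three indicators
#'
#' Fits the four-level model to each indicator's per-cluster counts in a
#' survey table (as produced by [sample_survey()] or read with
#' [read_clusters()]) and returns the shrunken prevalence estimates.
#'
#' @param clusters Survey data frame with `cluster_id`, `district_id`,
#'   `state_id`, `n_children` and `fail_<indicator>` columns.
#' @param settings An [mcmc_settings()]; each indicator's chain uses
#'   `seed`, `seed + 1`, `seed + 2`.
#' @return Data frame with one row per cluster: `cluster_id`, the three
#'   prevalence columns, and `sd_<indicator>` columns.  The fitted models
#'   are attached as attribute `"fits"`.
#' @export
estimate_clusters <- function(clusters, settings = mcmc_settings()) {
  out <- data.frame(cluster_id = clusters$cluster_id,
                    stringsAsFactors = FALSE)
  fits <- list()
  for (i in seq_along(indicator_names())) {
    ind <- indicator_names()[i]
    st <- settings
    st$seed <- settings$seed + i - 1L
    fit <- fit_multilevel_counts(
      y = clusters[[paste0("fail_", ind)]], n = clusters$n_children,
      cluster_id = clusters$cluster_id,
      district_id = clusters$district_id, state_id = clusters$state_id,
      settings = st)
    pred <- predict_cluster_probabilities(fit)
    ord <- match(out$cluster_id, pred$cluster_id)
    out[[ind]] <- pred$prevalence[ord]
    out[[paste0("sd_", ind)]] <- pred$prevalence_sd[ord]
    fits[[ind]] <- fit
  }
  attr(out, "fits") <- fits
  out
}

#' Variance partitioning coefficients
#'
#' Shares of total geographic variance attributable to the state,
#' district and village levels:
#' `vpc_z = sigma_z^2 / (sigma_state^2 + sigma_district^2 +
#' sigma_village^2) * 100`, reported to 0.1.  The denominator is the
#' three-level geographic total; the individual-level latent constant
#' `pi^2/3` is deliberately not part of it.
#'
#' @param variances Numeric length-3 vector of variances in the order
#'   state, district, village (names optional).
#' @return List with `vpc` (named, rounded to 0.1), `vpc_raw`
#'   (unrounded) and `total` (sum of the three variances).
#' @export
compute_vpc <- function(variances) {
  v <- as.numeric(variances)
  if (length(v) != 3L || any(!is.finite(v)) || any(v < 0)) {
    stop("'variances' must be three finite non-negative values", call. = FALSE)
  }
  total <- sum(v)
  if (total == 0) stop("all variances are zero; VPC undefined", call. = FALSE)
  raw <- v / total * 100
  names(raw) <- c("state", "district", "village")
  list(vpc = round(raw, 1L), vpc_raw = raw, total = total)
}

#' Three-level decomposition of village-level values
#'
#' Partitions the variance of a village-level quantity (on the
#' percentage scale) into state, district and village components with a
#' random-intercept linear model
#' `value = mu + f_state + v_district + e_village`, fitted by REML
#' (glmmTMB).  The village component is the residual variance.  Standard
#' errors of the variance components come from the fitted model's
#' sdreport by the delta method.
#'
#' @param values Numeric vector of village values (percent, 0-100).
#' @param district_ids,state_ids Grouping vectors aligned with `values`.
#' @return Object of class `variance_components`: data frame with
#'   `level`, `variance`, `se`, `vpc`, plus attributes `total` and the
#'   fitted model.
#' @export
fit_variance_decomposition <- function(values, district_ids, state_ids) {
  stopifnot(length(values) == length(district_ids),
            length(values) == length(state_ids))
  if (stats::sd(values) == 0) {
    stop("constant input: variance components are all zero, VPC undefined",
         call. = FALSE)
  }
  df <- data.frame(value = as.numeric(values),
                   district = factor(district_ids),
                   state = factor(state_ids))
  fit <- glmmTMB::glmmTMB(value ~ 1 + (1 | state) + (1 | district),
                          data = df, REML = TRUE)
  vc <- glmmTMB::VarCorr(fit)$cond
  v_state <- as.numeric(vc$state)
  v_district <- as.numeric(vc$district)
  v_village <- attr(vc, "sc")^2

  se <- tryCatch({
    sdr <- summary(fit$sdr, select = "fixed")
    th <- sdr[rownames(sdr) %in% c("theta"), , drop = FALSE]
    bd <- sdr[rownames(sdr) %in% c("betad", "betadisp"), , drop = FALSE]
    # theta rows are log-sd of the random effects in formula order
    # (state, district); betad is the log residual sd -- delta method
    # gives se(sigma^2) = 2 sigma^2 se(log sigma)
    re_se <- 2 * exp(2 * th[, 1L]) * th[, 2L]
    c(state = re_se[1L], district = re_se[2L],
      village = 2 * exp(2 * bd[1L, 1L]) * bd[1L, 2L])
  }, error = function(e) c(state = NA_real_, district = NA_real_,
                           village = NA_real_))

  vpc <- compute_vpc(c(v_state, v_district, v_village))
  out <- data.frame(
    level = c("state", "district", "village"),
    variance = c(v_state, v_district, v_village),
    se = as.numeric(se),
    vpc = as.numeric(vpc$vpc),
    stringsAsFactors = FALSE
  )
  structure(out, total = vpc$total, vpc_raw = vpc$vpc_raw, fit = fit,
            class = c("variance_components", "data.frame"))
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Three-level variance decomposition (percent-scale values)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat(sprintf("total geographic variance: %.4g\n", attr(x, "total")))
  invisible(x)
}
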