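test_that("no-heterogeneity data give flat estimates and near-zero variances", {
  d <- sim_counts(seed = 21, S = 5L, D = 2L, Jc = 10L, nch = 200L,
                  beta = 0, s2u = 0, s2v = 0, s2f = 0)
  fit <- suppressWarnings(fit_multilevel_counts(
    d$y, d$n, d$cluster_id, d$district_id, d$state_id, quick_mcmc(31)))
  pred <- predict_cluster_probabilities(fit)
  expect_true(all(abs(pred$prevalence - 0.5) < 0.05))
  pm <- colMeans(fit$chains)
  expect_lt(pm["sigma2_u"], 0.05)
  expect_lt(pm["sigma2_v"], 0.1)
  expect_lt(pm["sigma2_f"], 0.1)
})

test_that("a huge cluster escapes shrinkage toward the grand mean", {
  d <- sim_counts(seed = 22, S = 4L, D = 2L, Jc = 8L, nch = 40L,
                  beta = 0, s2u = 0.3, s2v = 0, s2f = 0)
  # append one cluster with overwhelming data at 30% prevalence
  y <- c(d$y, 3000); n <- c(d$n, 10000)
  cl <- c(d$cluster_id, "cBIG")
  di <- c(d$district_id, d$district_id[1])
  st <- c(d$state_id, d$state_id[1])
  fit <- suppressWarnings(fit_multilevel_counts(y, n, cl, di, st,
                                                quick_mcmc(32)))
  pred <- predict_cluster_probabilities(fit)
  expect_equal(pred$prevalence[pred$cluster_id == "cBIG"], 0.30,
               tolerance = 0.01 / 0.30)
})

test_that("posterior prevalences equal the recomputed draw-wise mean", {
  d <- sim_counts(seed = 23, S = 3L, D = 2L, Jc = 4L, nch = 20L)
  st <- quick_mcmc(33)
  st$keep_draws <- TRUE
  fit <- suppressWarnings(fit_multilevel_counts(
    d$y, d$n, d$cluster_id, d$district_id, d$state_id, st))
  # independent recomputation from the stored per-draw probabilities
  expect_equal(fit$clusters$prevalence, unname(colMeans(fit$p_draws)),
               tolerance = 1e-12)
  sd_oracle <- apply(fit$p_draws, 2, function(p) {
    sqrt(mean(p^2) - mean(p)^2)
  })
  expect_equal(fit$clusters$prevalence_sd, unname(sd_oracle),
               tolerance = 1e-8)
})

test_that("estimates are shrunken between raw proportion and grand mean, more for small n", {
  d <- sim_counts(seed = 24, S = 4L, D = 3L, Jc = 10L, nch = 30L,
                  beta = 0, s2u = 0.4, s2v = 0.05, s2f = 0.05)
  # two extra clusters with identical raw prevalence 0.8, different size
  y <- c(d$y, 8, 80); n <- c(d$n, 10, 100)
  cl <- c(d$cluster_id, "cSMALL", "cLARGE")
  di <- c(d$district_id, d$district_id[1], d$district_id[1])
  st <- c(d$state_id, d$state_id[1], d$state_id[1])
  fit <- suppressWarnings(fit_multilevel_counts(y, n, cl, di, st,
                                                mcmc_settings(300, 1500, 34)))
  pred <- predict_cluster_probabilities(fit)
  grand <- mean(colMeans(fit$chains)["beta"])
  small_lg <- qlogis(pred$prevalence[pred$cluster_id == "cSMALL"])
  large_lg <- qlogis(pred$prevalence[pred$cluster_id == "cLARGE"])
  raw_lg <- qlogis(0.8)
  # both pulled below the raw value, toward the grand mean
  expect_lt(small_lg, raw_lg)
  expect_lt(large_lg, raw_lg)
  expect_gt(small_lg, grand)
  expect_gt(large_lg, grand)
  # the small cluster sits strictly closer to the grand mean
  expect_lt(abs(small_lg - grand), abs(large_lg - grand))
})

test_that("chains are reproducible under a fixed seed and sized per settings", {
  d <- sim_counts(seed = 25, S = 3L, D = 2L, Jc = 5L)
  f1 <- suppressWarnings(fit_multilevel_counts(
    d$y, d$n, d$cluster_id, d$district_id, d$state_id, quick_mcmc(35)))
  f2 <- suppressWarnings(fit_multilevel_counts(
    d$y, d$n, d$cluster_id, d$district_id, d$state_id, quick_mcmc(35)))
  expect_identical(f1$chains, f2$chains)
  expect_identical(f1$clusters$prevalence, f2$clusters$prevalence)
  expect_equal(nrow(f1$chains), 800L)
  expect_equal(f1$latent_level1_variance, pi^2 / 3, tolerance = 1e-12)
})

test_that("child-level records collapse to the same fit as counts", {
  d <- sim_counts(seed = 26, S = 3L, D = 2L, Jc = 4L, nch = 12L)
  children <- do.call(rbind, lapply(seq_along(d$y), function(j) {
    data.frame(outcome = c(rep(1L, d$y[j]), rep(0L, d$n[j] - d$y[j])),
               cluster_id = d$cluster_id[j],
               district_id = d$district_id[j],
               state_id = d$state_id[j])
  }))
  f_child <- suppressWarnings(fit_multilevel(children, quick_mcmc(36)))
  f_count <- suppressWarnings(fit_multilevel_counts(
    d$y, d$n, d$cluster_id, d$district_id, d$state_id, quick_mcmc(36)))
  expect_identical(f_child$chains, f_count$chains)
  expect_error(fit_multilevel(transform(children, outcome = outcome + 0.5)),
               "binary")
  expect_error(fit_multilevel(children[, -1]), "missing columns")
})

test_that("a single-unit level has its variance fixed at zero with a warning", {
  d <- sim_counts(seed = 27, S = 1L, D = 3L, Jc = 5L, s2f = 0)
  expect_warning(
    fit <- fit_multilevel_counts(d$y, d$n, d$cluster_id, d$district_id,
                                 d$state_id, quick_mcmc(37)),
    "single state")
  expect_true(all(fit$chains[, "sigma2_f"] == 0))
})

test_that("VPC formula is exact on symmetric and degenerate inputs", {
  v <- compute_vpc(c(1, 1, 1))
  expect_equal(unname(v$vpc), c(33.3, 33.3, 33.3))
  expect_equal(v$total, 3)
  expect_error(compute_vpc(c(0, 0, 0)), "zero")
  expect_error(compute_vpc(c(-1, 1, 1)), "non-negative")
  expect_error(compute_vpc(c(1, 2)), "three")
})

test_that("variance decomposition recovers a generated three-level structure", {
  set.seed(41)
  S <- 60L; D <- 5L; V <- 12L
  st <- rep(seq_len(S), each = D * V)
  di <- rep(seq_len(S * D), each = V)
  val <- 40 + rnorm(S, 0, sqrt(27.6))[st] + rnorm(S * D, 0, sqrt(8.2))[di] +
    rnorm(S * D * V, 0, sqrt(79.3))
  vc <- fit_variance_decomposition(val, sprintf("d%03d", di),
                                   sprintf("s%02d", st))
  expect_equal(vc$level, c("state", "district", "village"))
  expect_true(all(vc$variance > 0))
  expect_true(all(is.finite(vc$se)))
  # village (residual) variance is tightly estimated
  expect_lt(abs(vc$variance[3] - 79.3) / 79.3, 0.1)
  expect_equal(sum(vc$vpc), 100, tolerance = 0.002)
  expect_equal(attr(vc, "total"), sum(vc$variance), tolerance = 1e-8)
})

test_that("shifting one district moves only the upper-level components", {
  set.seed(42)
  S <- 10L; D <- 6L; V <- 30L
  st <- rep(seq_len(S), each = D * V)
  di <- rep(seq_len(S * D), each = V)
  val <- 30 + rnorm(S, 0, 2)[st] + rnorm(S * D, 0, 1)[di] +
    rnorm(S * D * V, 0, 5)
  vc0 <- fit_variance_decomposition(val, di, st)
  val2 <- val + ifelse(di == 1L, 8, 0)
  vc1 <- fit_variance_decomposition(val2, di, st)
  expect_equal(vc1$variance[3], vc0$variance[3], tolerance = 1e-4)
  expect_gt(vc1$variance[2], vc0$variance[2])
})

test_that("grouping-free data pushes state and district shares to zero", {
  set.seed(43)
  S <- 30L; D <- 5L; V <- 40L
  st <- rep(seq_len(S), each = D * V)
  di <- rep(seq_len(S * D), each = V)
  val <- rnorm(S * D * V, 50, 10)
  vc <- fit_variance_decomposition(val, di, st)
  expect_lt(vc$vpc[1] + vc$vpc[2], 5)
  expect_error(fit_variance_decomposition(rep(3, 100),
                                          rep(1:10, 10), rep(1:2, 50)),
               "constant")
})
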