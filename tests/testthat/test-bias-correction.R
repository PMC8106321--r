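test_that("correction assigns each cluster to its closest-prediction candidate", {
  y <- c(0.30, 0.42, 0.55, 0.10)
  out <- correction_assign(y, cluster_values = 0.40,
                           candidates = list(1:3),
                           reliable_idx = 4L, reliable_values = 0.10)
  expect_equal(out$selected, 2L)  # |0.42 - 0.40| = 0.02 is smallest
  expect_equal(out$y[2], 0.40)
  expect_equal(out$y[4], 0.10)   # reliable label reverted
  expect_setequal(out$labeled_idx, c(2L, 4L))
})

test_that("gap ties go to the smallest village index", {
  # 0.25 and 0.75 are exactly representable: both gaps equal 0.25
  y <- c(0.25, 0.75, 0.99)
  out <- correction_assign(y, 0.50, list(c(2L, 1L)), 3L, 0.99)
  expect_equal(out$selected, 1L)
})

test_that("village collisions resolve by smaller gap then smaller cluster", {
  y <- c(0.50, 0.90)
  # both clusters want village 1; cluster 2 has the smaller gap
  out <- correction_assign(y, cluster_values = c(0.60, 0.55),
                           candidates = list(1L, 1L),
                           reliable_idx = 2L, reliable_values = 0.90)
  expect_equal(out$y[1], 0.55)
  # equal gaps: first cluster wins
  out2 <- correction_assign(y, cluster_values = c(0.45, 0.55),
                            candidates = list(1L, 1L),
                            reliable_idx = 2L, reliable_values = 0.90)
  expect_equal(out2$y[1], 0.45)
})

test_that("correction matches exhaustive enumeration on random instances", {
  withr::with_seed(71, {
    for (rep in 1:5) {
      n <- 30L
      y <- runif(n)
      nc <- 6L
      cand <- lapply(1:nc, function(i) sort(sample.int(n, sample(1:4, 1))))
      cv <- runif(nc)
      rel <- sort(sample.int(n, 3))
      out <- suppressWarnings(correction_assign(y, cv, cand, rel, y[rel]))
      # oracle: brute-force argmin per cluster
      sel_oracle <- vapply(1:nc, function(c_) {
        vc <- cand[[c_]]
        g <- abs(y[vc] - cv[c_])
        vc[order(g, vc)][1]
      }, integer(1))
      expect_equal(out$selected, sel_oracle)
      expect_true(all(out$labeled_idx %in% c(rel, sel_oracle)))
      expect_equal(out$y[rel], y[rel])
    }
  })
})

test_that("clusters without candidates are skipped with a warning", {
  y <- c(0.2, 0.8)
  expect_warning(
    out <- correction_assign(y, c(0.5, 0.3), list(integer(0), 1L),
                             2L, 0.8),
    "no candidate")
  expect_true(is.na(out$selected[1]))
  expect_equal(out$selected[2], 1L)
})

test_that("initialization is a plain harmonic solve from the reliable set", {
  withr::with_seed(72, {
    X <- matrix(rnorm(30 * 4), 30, 4)
    g <- build_graph(X, k = 4)
    rel <- c(3L, 11L, 25L)
    y0 <- numeric(30)
    y0[rel] <- c(0.2, 0.5, 0.4)
    y1 <- ssl_initialize(y0, g, rel)
    direct <- harmonic_solve(g, y0[rel], rel)
    expect_equal(y1, direct)
    # fully labeled problem returns the labels untouched
    full_labels <- runif(30)
    yfull <- ssl_initialize(full_labels, g, 1:30)
    expect_equal(yfull, full_labels)
    one <- ssl_initialize(c(0.3, numeric(29)), g, 1L)
    expect_equal(one, rep(0.3, 30))
  })
})

test_that("one iteration equals initialize, correct, solve", {
  withr::with_seed(73, {
    X <- matrix(rnorm(40 * 4), 40, 4)
    g <- build_graph(X, k = 5)
    rel <- sort(sample.int(40, 4))
    relv <- runif(4, 0.3, 0.5)
    y0 <- numeric(40)
    y0[rel] <- relv
    cand <- lapply(1:5, function(i) sort(sample.int(40, 3)))
    cv <- runif(5, 0.2, 0.6)
    fit <- run_bias_corrected(y0, g, cv, cand, rel, iterations = 1L)
    # manual unrolling
    y1 <- harmonic_solve(g, relv, rel)
    corr <- correction_assign(y1, cv, cand, rel, relv)
    y_manual <- harmonic_solve(g, corr$labeled_values, corr$labeled_idx)
    expect_equal(fit$y, y_manual)
    expect_equal(fit$y_init, y1)
  })
})

test_that("single-candidate clusters already labeled give a fixed point", {
  withr::with_seed(74, {
    X <- matrix(rnorm(20 * 3), 20, 3)
    g <- build_graph(X, k = 3)
    rel <- c(2L, 9L, 15L)
    relv <- c(0.25, 0.40, 0.30)
    y0 <- numeric(20)
    y0[rel] <- relv
    # every cluster maps to exactly one candidate, already in L0
    fit1 <- run_bias_corrected(y0, g, relv, as.list(rel), rel,
                               iterations = 1L)
    fit5 <- run_bias_corrected(y0, g, relv, as.list(rel), rel,
                               iterations = 5L)
    expect_equal(fit1$y, fit5$y, tolerance = 1e-10)
    expect_equal(fit1$y, fit1$y_init, tolerance = 1e-10)
  })
})

test_that("reliable labels are reverted exactly at every iteration", {
  withr::with_seed(75, {
    X <- matrix(rnorm(50 * 5), 50, 5)
    g <- build_graph(X, k = 5)
    rel <- sort(sample.int(50, 5))
    relv <- runif(5, 0.2, 0.6)
    y0 <- numeric(50)
    y0[rel] <- relv
    cand <- lapply(1:8, function(i) sort(sample.int(50, sample(2:5, 1))))
    cv <- runif(8, 0.1, 0.7)
    for (T in 1:4) {
      fit <- run_bias_corrected(y0, g, cv, cand, rel, iterations = T)
      expect_identical(fit$y[rel], relv)
      expect_lte(length(fit$labeled_idx), length(rel) + length(cand))
      # maximum principle: predictions within the span of all labels
      lo <- min(c(relv, cv)); hi <- max(c(relv, cv))
      expect_true(all(fit$y >= lo - 1e-12 & fit$y <= hi + 1e-12))
    }
  })
})

test_that("the iteration is deterministic", {
  withr::with_seed(76, {
    X <- matrix(rnorm(30 * 4), 30, 4)
    g <- build_graph(X, k = 4)
    rel <- c(1L, 10L)
    y0 <- numeric(30); y0[rel] <- c(0.3, 0.5)
    cand <- list(c(5L, 6L), c(20L, 21L, 22L))
    f1 <- run_bias_corrected(y0, g, c(0.35, 0.55), cand, rel, iterations = 3L)
    f2 <- run_bias_corrected(y0, g, c(0.35, 0.55), cand, rel, iterations = 3L)
    expect_identical(f1$y, f2$y)
    expect_identical(f1$history, f2$history)
  })
})
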