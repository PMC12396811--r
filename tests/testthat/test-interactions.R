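test_that("trend classification labels the canonical cases", {
  up <- trend_classification(c(1, 2, 3, 4, 5))
  expect_equal(up$label, "increasing")
  expect_equal(up$rho, 1)
  down <- trend_classification(c(5, 4, 3, 2, 1))
  expect_equal(down$label, "decreasing")
  expect_equal(down$rho, -1)
  expect_equal(trend_classification(c(1, 1, 1, 1))$label, "constant")
  # flat but noisy series (sub-10% relative range)
  expect_equal(trend_classification(c(10, 10.2, 9.9, 10.1, 10, 10.05))$label,
               "constant")
  expect_error(trend_classification(c(1, 2, 3)),
               class = "branchdyn_invalid_parameter")
})

test_that("trend classification is invariant to positive affine transforms", {
  withr::with_seed(13, {
    for (rep in 1:10) {
      s <- cumsum(rnorm(8))
      a <- runif(1, 0.5, 3); b <- rnorm(1)
      t1 <- trend_classification(s)
      t2 <- trend_classification(a * s + b)
      expect_equal(t1$rho, t2$rho)
      expect_equal(t1$p_value, t2$p_value)
    }
  })
})

test_that("1-Wasserstein distance: identity, translation, closed form", {
  u <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(wasserstein_1d(u, sample(u)), 0)
  expect_equal(wasserstein_1d(u, u + 2.5), 2.5)
  expect_equal(wasserstein_1d(u, u - 0.7), 0.7)

  # W1(U(0,1), U(0,2)) = 1/2
  withr::with_seed(17, {
    a <- runif(5000); b <- runif(5000, 0, 2)
  })
  expect_lt(abs(wasserstein_1d(a, b) - 0.5), 0.02)

  # unequal sample lengths are handled exactly
  expect_equal(wasserstein_1d(c(0, 1), c(0.5)), 0.5)
})

test_that("Wasserstein metric axioms hold on random sample triples", {
  withr::with_seed(23, {
    for (rep in 1:100) {
      x <- rpois(40, runif(1, 2, 50))
      y <- rpois(35, runif(1, 2, 50))
      z <- rpois(50, runif(1, 2, 50))
      dxy <- wasserstein_1d(x, y)
      dyz <- wasserstein_1d(y, z)
      dxz <- wasserstein_1d(x, z)
      expect_gte(dxy, 0)
      expect_equal(dxy, wasserstein_1d(y, x))
      expect_lte(dxz, dxy + dyz + 1e-12)
      expect_equal(wasserstein_1d(x, x), 0)
    }
  })
})

test_that("Wasserstein matrix is symmetric with matching laws close", {
  # gene A on stage 5+ has the same law as gene B there, very different
  # elsewhere
  n <- 420
  set.seed(29)
  sim <- small_world(seed = 9, cells_per_stage = 60, n_genes = 2)
  counts <- sim$counts
  st5 <- sim$annotation$stage == 5
  counts[st5, 1] <- rpois(sum(st5), 30)
  counts[st5, 2] <- rpois(sum(st5), 30)
  counts[!st5, 2] <- rpois(sum(!st5), 200)
  W <- wasserstein_matrix(counts, sim$annotation, colnames(counts),
                          group_by = "stage")
  expect_true(all(diag(unclass(W)) == 0))
  expect_identical(unclass(W), t(unclass(W)))
  same_law <- W["g01@5", "g02@5"]
  expect_lt(same_law, 0.1 * median(W[upper.tri(W)]))
})

test_that("joint density normalizes and localizes correctly", {
  withr::with_seed(37, {
    a <- rnorm(5000); b <- rnorm(5000)
  })
  jd <- joint_density(a, b, n_grid = 128)
  cell <- diff(jd$x[1:2]) * diff(jd$y[1:2])
  expect_lt(abs(sum(jd$z) * cell - 1), 1e-3)
  peak <- which(jd$z == max(jd$z), arr.ind = TRUE)
  expect_lt(abs(jd$x[peak[1]]), 0.1)
  expect_lt(abs(jd$y[peak[2]]), 0.1)

  # perfectly correlated pair: negligible mass off the diagonal band
  jd2 <- joint_density(a, a)
  bw <- 3 * sd(a) * 5000^(-1 / 6)
  off <- abs(outer(jd2$x, jd2$y, "-")) > 3 * bw
  cell2 <- diff(jd2$x[1:2]) * diff(jd2$y[1:2])
  expect_lt(sum(jd2$z[off]) * cell2, 0.01)

  # zero-variance axis falls back to 1D x point mass
  expect_message(jd3 <- joint_density(a, rep(2, 5000)), regexp = "zero-variance")
  cell3 <- diff(jd3$x[1:2]) * diff(jd3$y[1:2])
  expect_lt(abs(sum(jd3$z) * cell3 - 1), 1e-3)
})

test_that("single candidate regulator takes importance one", {
  sim <- small_world(seed = 15, cells_per_stage = 40, n_genes = 2)
  rs <- suppressMessages(regulation_strength_series(
    sim$counts, sim$annotation, "g01", "g02",
    windows_per_segment = 2, n_trees = 20, seed = 1))
  expect_true(all(rs$importance == 1 | rs$importance == 0))
  expect_true(any(rs$importance == 1))
})

test_that("independent genes share importance diffusely (null calibration)", {
  sim <- small_world(seed = 16, cells_per_stage = 50, n_genes = 12)
  rs <- suppressMessages(regulation_strength_series(
    sim$counts, sim$annotation, "g01", "g02",
    windows_per_segment = 2, n_trees = 50, seed = 2))
  p <- ncol(sim$counts) - 1
  expect_lte(mean(rs$importance), 2 / p)
})

test_that("a ramped regulator-target coupling is labeled increasing", {
  # scaled-down: 6 replicates (the acceptance suite covers burst trends; this
  # checks the regulation analogue qualitatively)
  hits <- vapply(1:6, function(s) {
    withr::with_seed(s, {
      n <- 600
      ann <- line_annotation(n)
      # bursty regulator (high variance) with a coupling ramp to the target
      reg <- rpois(n, 40 * rbeta(n, 0.5, 0.5))
      coupling <- seq(0, 1.5, length.out = n)
      tgt <- rpois(n, 5 + coupling * reg)
      noise <- sapply(1:6, function(g) rpois(n, 15))
      counts <- cbind(reg = reg, tgt = tgt, noise)
      dimnames(counts) <- list(ann$cell_id,
                               c("reg", "tgt", sprintf("n%d", 1:6)))
      storage.mode(counts) <- "integer"
    })
    rs <- suppressMessages(regulation_strength_series(
      counts, ann, "reg", "tgt", windows_per_segment = 8,
      overlap_fraction = 0.5, n_trees = 60, seed = s))
    tr <- regulation_trends(rs)
    tr$label[tr$branch == "all"] == "increasing"
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
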