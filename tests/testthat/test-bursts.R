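test_that("Gauss-Jacobi rule matches a dense-eigendecomposition oracle", {
  # independent Golub-Welsch via base eigen() on the full Jacobi matrix
  gj_dense <- function(n, a, b) {
    k <- seq_len(n) - 1
    ab <- a + b
    alpha <- (b^2 - a^2) / ((2 * k + ab) * (2 * k + ab + 2))
    alpha[1] <- (b - a) / (ab + 2)
    k2 <- seq_len(n - 1)
    beta2 <- ifelse(k2 == 1, 4 * (a + 1) * (b + 1) / ((ab + 2)^2 * (ab + 3)),
                    4 * k2 * (k2 + a) * (k2 + b) * (k2 + ab) /
                      ((2 * k2 + ab)^2 * (2 * k2 + ab + 1) * (2 * k2 + ab - 1)))
    J <- diag(alpha, n, n)
    off <- sqrt(beta2)
    J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
    J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
    e <- eigen(J, symmetric = TRUE)
    ord <- order(e$values)
    list(nodes = e$values[ord], z2 = e$vectors[1, ord]^2)
  }
  withr::with_seed(41, {
    for (rep in 1:10) {
      a <- runif(1, -0.99, 40); b <- runif(1, -0.99, 40)
      n <- sample(8:64, 1)
      rule <- branchdyn:::gauss_jacobi(n, a, b)
      oracle <- gj_dense(n, a, b)
      expect_lt(max(abs(rule$nodes - oracle$nodes)), 1e-8)
      expect_lt(max(abs(rule$z2 / sum(rule$z2) -
                          oracle$z2 / sum(oracle$z2))), 1e-8)
    }
  })
})

test_that("Beta-Poisson pmf: limits, oracle agreement, mean identity", {
  # vanishing synthesis: all mass at zero
  expect_gt(beta_poisson_pmf(0, 1, 1, 1e-6), 1 - 1e-5)

  # quadrature vs brute-force trapezoid oracle, entrywise 1e-6
  k <- 0:200
  pm <- beta_poisson_pmf(k, 0.5, 10, 100)
  po <- bp_pmf_oracle(k, 0.5, 10, 100)
  expect_lt(max(abs(pm - po)), 1e-6)

  # normalization to a high cutoff
  expect_lt(abs(sum(beta_poisson_pmf(0:500, 0.5, 10, 100)) - 1), 1e-8)

  # law of total expectation: mean = s * k_syn * k_on / (k_on + k_off)
  pmf <- beta_poisson_pmf(0:500, 0.5, 10, 100, s = 1.3)
  expect_lt(abs(sum((0:500) * pmf) - 1.3 * 100 * 0.5 / 10.5), 1e-6)
})

test_that("cell size factors are median-normalized totals", {
  m <- matrix(c(50, 50, 100, 100, 200, 200), 3, 2, byrow = TRUE,
              dimnames = list(paste0("c", 1:3), c("g1", "g2")))
  expect_equal(unname(estimate_cell_sizes(m)), c(0.5, 1, 2))

  m2 <- matrix(10L, 4, 3, dimnames = list(paste0("c", 1:4), paste0("g", 1:3)))
  expect_true(all(estimate_cell_sizes(m2) == 1))

  m3 <- m; m3[2, ] <- 0L
  expect_error(estimate_cell_sizes(m3), regexp = "c2",
               class = "branchdyn_degenerate_data")
})

test_that("estimated sizes track the simulator's true sizes", {
  # ~500 cells x 80 genes: enough genes that per-gene burst noise averages
  # out of the totals
  sched <- default_stage_schedule(cells_per_stage = 72)
  prog <- gene_program(sched, sprintf("g%02d", 1:80), k_on = 1, k_off = 3,
                       k_syn = 60)
  sim <- simulate_branching_dataset(
    simulation_config(sched, prog, size_sdlog = 0.4, seed = 21))
  s_hat <- estimate_cell_sizes(sim$counts)
  expect_gt(cor(s_hat, sim$sizes, method = "spearman"), 0.95)
})

test_that("burst MLE: constitutive mean, scale equivariance, degeneracy", {
  # near-constitutive data: fitted mean is preserved
  x <- withr::with_seed(31, rpois(5000, 20))
  f <- fit_burst_params(x, seed = 1)
  mean_hat <- f$k_syn * f$k_on / (f$k_on + f$k_off)
  expect_lt(abs(mean_hat - 20) / 20, 0.05)

  # doubling all sizes halves k_syn exactly and leaves k_on, k_off unchanged
  y <- simulate_two_state_counts(two_state_params(0.5, 10, 100), 2000, seed = 3)
  f1 <- fit_burst_params(y, rep(1, 2000), seed = 1)
  f2 <- fit_burst_params(y, rep(2, 2000), seed = 1)
  expect_equal(f1$k_syn / f2$k_syn, 2, tolerance = 1e-6)
  expect_equal(f1$k_on, f2$k_on, tolerance = 1e-8)
  expect_equal(f1$k_off, f2$k_off, tolerance = 1e-8)

  expect_error(fit_burst_params(rep(0L, 100)),
               class = "branchdyn_degenerate_data")
})

test_that("burst size and frequency are recovered (scaled-down study)", {
  # 3 seeds here; the 10-seed median study runs in the acceptance suite
  est <- vapply(1:3, function(s) {
    x <- simulate_two_state_counts(two_state_params(0.5, 10, 100), 5000,
                                   seed = s)
    f <- fit_burst_params(x, seed = s)
    c(f$BS, f$BF)
  }, numeric(2))
  expect_lt(abs(median(est[1, ]) - 10) / 10, 0.2)
  expect_lt(abs(median(est[2, ]) - 0.5) / 0.5, 0.2)
})

test_that("likelihood at the truth beats strongly perturbed parameters", {
  ll <- function(x, kon, koff, ksyn) {
    sum(log(pmax(beta_poisson_pmf(sort(unique(x)), kon, koff, ksyn,
                                  order = 60)[match(x, sort(unique(x)))],
                 1e-300)))
  }
  hits <- vapply(1:5, function(s) {
    x <- simulate_two_state_counts(two_state_params(0.5, 10, 100), 4000,
                                   seed = 100 + s)
    l0 <- ll(x, 0.5, 10, 100)
    all(l0 >= c(ll(x, 0.75, 10, 100), ll(x, 0.5, 15, 100),
                ll(x, 0.5, 10, 150), ll(x, 0.25, 5, 50)))
  }, logical(1))
  expect_gte(mean(hits), 0.95 - 1e-9)
})

test_that("burst trajectory emits one estimate per window with trend labels", {
  sim <- trend_world(seed = 5, cells_per_stage = 40)
  bt <- suppressMessages(
    burst_trajectory(sim$counts, sim$annotation, "g1",
                     windows_per_segment = 4, sizes = sim$sizes, seed = 1))
  expect_equal(nrow(bt), 16) # 4 segments x 4 windows
  expect_true(all(c("BS", "BF", "t_mid") %in% names(bt)))
  tr <- burst_trends(bt)
  expect_setequal(unique(tr$metric), c("BS", "BF"))
  expect_true(all(tr$label %in% c("increasing", "decreasing", "constant",
                                  "non-monotone")))
})
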