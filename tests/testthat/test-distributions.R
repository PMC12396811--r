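test_that("mixture density: closed forms, modes and normalization", {
  # exponential at the origin
  expect_equal(mixture_pdf(0, gamma_components(1, 1, 1)), 1)

  # shifted branch-point component: argmax on a fine grid is loc + (a-1)/rate
  comp <- gamma_components(1, 2.898, 1.5106, loc = 15.481)
  grid <- seq(15.481, 40, by = 0.001)
  expect_lt(abs(grid[which.max(mixture_pdf(grid, comp))] -
                  (15.481 + (2.898 - 1) / 1.5106)), 0.002)

  # symmetric two-component mixture has its mean at the centre
  c0 <- 20
  comp2 <- gamma_components(c(0.5, 0.5), c(100, 100), c(10, 10),
                            loc = c(c0 - 10, c0 + 10 - 2 * 10))
  xs <- seq(0, 60, length.out = 20001)
  dens <- mixture_pdf(xs, comp2)
  expect_lt(abs(sum(xs * dens) * diff(xs[1:2]) - c0), 1e-3)
})

test_that("every mixture pdf integrates to one (quadrature property)", {
  set.seed(7)
  for (rep in 1:10) {
    m <- sample(1:3, 1)
    w <- rgamma(m, 1) + 0.1
    comp <- gamma_components(w / sum(w), shape = runif(m, 0.5, 50),
                             rate = runif(m, 0.1, 5),
                             loc = runif(m, 0, 10))
    hi <- max(comp$loc + qgamma(1 - 1e-8, comp$shape, rate = comp$rate))
    xs <- seq(min(comp$loc), hi, length.out = 40001)
    total <- sum(mixture_pdf(xs, comp)) * diff(xs[1:2])
    expect_lt(abs(total - 1), 1e-6)
  }
})

test_that("KL divergence: hand value, nonnegativity, zero at identity", {
  # model whose discretized support probabilities are {0.75, 0.25}:
  # solve the exponential rate giving mass ratio 3 between cells [0,.5) and
  # [.5,1.5) after renormalization (independent root-finding oracle)
  ratio3 <- function(r) {
    m0 <- pgamma(0.5, 1, rate = r)
    m1 <- pgamma(1.5, 1, rate = r) - m0
    m0 / m1 - 3
  }
  r <- uniroot(ratio3, c(0.1, 10), tol = 1e-12)$root
  d <- manual_empirical(c(0, 1), c(0.5, 0.5))
  kl <- suppressMessages(kl_divergence(d, gamma_components(1, 1, r)))
  expect_equal(kl, 0.5 * log(0.5 / 0.75) + 0.5 * log(0.5 / 0.25),
               tolerance = 1e-6)

  # zero iff data equals the discretized model on the support
  comp <- gamma_components(1, 40, 2)
  vals <- 0:60
  q <- pgamma(vals + 0.5, 40, rate = 2) - pgamma(pmax(vals - 0.5, 0), 40, rate = 2)
  d_eq <- manual_empirical(vals, q / sum(q))
  expect_lt(suppressMessages(kl_divergence(d_eq, comp)), 1e-9)

  # Gibbs inequality on random data/model pairs
  set.seed(11)
  for (rep in 1:10) {
    x <- rpois(300, runif(1, 3, 60))
    comp <- gamma_components(1, runif(1, 1, 60), runif(1, 0.2, 4))
    expect_gte(suppressMessages(kl_divergence(x, comp)), 0)
  }
})

test_that("single-Gamma KL fit recovers parameters within 5% at n = 5000", {
  x <- sample_gamma_mixture(gamma_components(1, 5, 0.5), 5000, seed = 1)
  f <- fit_mixture(x, 1, seed = 1)
  expect_lt(abs(f$components$shape - 5) / 5, 0.05)
  expect_lt(abs(f$components$rate - 0.5) / 0.5, 0.05)
})

test_that("two-component fit recovers weights and means of separated mixtures", {
  truth <- gamma_components(c(0.5, 0.5), c(100, 900), c(10, 30))
  x <- sample_gamma_mixture(truth, 5000, seed = 2)
  f <- fit_mixture(x, 2, seed = 1)
  expect_lt(max(abs(f$components$weight - c(0.5, 0.5))), 0.05)
  means <- f$components$shape / f$components$rate
  expect_lt(max(abs(means - c(10, 30)) / c(10, 30)), 0.03)
})

test_that("richer mixtures achieve no worse KL (nesting)", {
  x <- sample_gamma_mixture(gamma_components(1, 5, 0.5), 3000, seed = 3)
  f1 <- fit_mixture(x, 1, seed = 1)
  f2 <- fit_mixture(x, 2, seed = 1)
  expect_lte(f2$kl, f1$kl + 1e-8)
})

test_that("all-constant samples raise a degenerate-data error", {
  expect_error(fit_mixture(rep(7, 100), 1),
               class = "branchdyn_degenerate_data")
})

test_that("modality selection is correct on clear cases (scaled-down study)", {
  # 5 seeds per class here; the 50-replicate confusion study runs in the
  # acceptance suite
  m1 <- vapply(1:5, function(s) select_modality(
    sample_gamma_mixture(gamma_components(1, 5, 0.5), 2000, seed = s),
    seed = s)$m, integer(1))
  expect_gte(mean(m1 == 1L), 0.8)
  m2 <- vapply(1:5, function(s) select_modality(
    sample_gamma_mixture(gamma_components(c(.5, .5), c(100, 900), c(10, 30)),
                         5000, seed = s), seed = s)$m, integer(1))
  expect_gte(mean(m2 == 2L), 0.8)
  m3 <- vapply(1:5, function(s) select_modality(
    sample_gamma_mixture(gamma_components(rep(1 / 3, 3), c(100, 400, 900),
                                          c(10, 20, 30)), 5000, seed = s),
    seed = s)$m, integer(1))
  expect_gte(mean(m3 == 3L), 0.8)
})

test_that("component statistics match shifted-Gamma closed forms", {
  st <- mixture_stats(gamma_components(1, 4, 2, loc = 3))
  expect_equal(st$components$mean, 3 + 4 / 2)
  expect_equal(st$components$variance, 4 / 4)
  expect_equal(st$components$skewness, 1)
  expect_equal(st$components$ex_kurtosis, 1.5)
  expect_equal(st$components$peak, 3 + (4 - 1) / 2)

  # shape <= 1: the peak sits at the boundary
  st1 <- mixture_stats(gamma_components(1, 0.8, 1, loc = 2))
  expect_equal(st1$components$peak, 2)
})

test_that("closed-form component moments agree with numerical quadrature", {
  set.seed(5)
  for (rep in 1:5) {
    shape <- runif(1, 2, 100); rate <- runif(1, 0.5, 10); loc <- runif(1, 0, 5)
    comp <- gamma_components(1, shape, rate, loc = loc)
    hi <- loc + qgamma(1 - 1e-10, shape, rate = rate)
    xs <- seq(loc, hi, length.out = 200001)
    dx <- diff(xs[1:2])
    dens <- mixture_pdf(xs, comp)
    mu_num <- sum(xs * dens) * dx
    v_num <- sum((xs - mu_num)^2 * dens) * dx
    st <- mixture_stats(comp)$components
    expect_lt(abs(mu_num - st$mean) / st$mean, 1e-4)
    expect_lt(abs(v_num - st$variance) / st$variance, 1e-4)
  }
})

test_that("mixture peak finder locates the modes of a separated mixture", {
  comp <- gamma_components(c(0.5, 0.5), c(100, 900), c(10, 30))
  pk <- mixture_stats(comp)$peaks
  expect_equal(length(pk), 2)
  expect_lt(abs(pk[1] - 99 / 10), 0.1)
  expect_lt(abs(pk[2] - 899 / 30), 0.1)
})

test_that("tidy and glance expose the fit in broom form", {
  x <- sample_gamma_mixture(gamma_components(1, 5, 0.5), 1000, seed = 9)
  f <- fit_mixture(x, 1, seed = 1)
  td <- tidy(f)
  expect_true(all(c("weight", "shape", "rate", "mean", "peak") %in% names(td)))
  gl <- glance(f)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("m", "kl", "bic", "n") %in% names(gl)))
  mc <- select_modality(x, seed = 1)
  expect_equal(sum(tidy(mc)$selected), 1)
})
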