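#' Gamma-mixture density
#'
#' Density of `sum_i w_i * Gamma(shape_i, rate_i)` shifted by `loc_i`, the
#' mechanistic stationary law of bursty transcription: a single component is
#' the Gamma limit of the two-state model (shape = on-rate per degradation
#' time, rate = off-rate / synthesis rate), mixtures of two or three
#' components model bi-/trimodal windows.
#'
#' @param x evaluation points.
#' @param fit a `gamma_mixture_fit` (from [fit_mixture()]) or a components
#'   table from [gamma_components()].
#' @return Density values (0 below every component's `loc`).
#' @examples
#' mixture_pdf(0, gamma_components(1, 1, 1)) # exponential at the origin: 1
#' @export
mixture_pdf <- function(x, fit) {
  comp <- fit_components(fit)
  out <- numeric(length(x))
  for (i in seq_len(nrow(comp))) {
    out <- out + comp$weight[i] *
      dgamma(x - comp$loc[i], shape = comp$shape[i], rate = comp$rate[i])
  }
  out
}

fit_components <- function(fit) {
  if (inherits(fit, "gamma_mixture_fit")) return(fit$components)
  validate_components(tibble::as_tibble(fit))
}

# probability mass the mixture assigns to the integer cell [m-1/2, m+1/2);
# vectorized over values x components in one pgamma call (hot path)
cell_mass_raw <- function(values, weight, shape, rate, loc) {
  nv <- length(values); m <- length(weight)
  up <- rep(values + 0.5, times = m) - rep(loc, each = nv)
  lo <- up - 1
  sh <- rep(shape, each = nv); ra <- rep(rate, each = nv)
  mass <- pgamma(up, sh, rate = ra) - pgamma(lo, sh, rate = ra)
  as.vector(matrix(mass, nv, m) %*% weight)
}

mixture_cell_mass <- function(values, comp) {
  cell_mass_raw(values, comp$weight, comp$shape, comp$rate, comp$loc)
}

#' Kullback-Leibler divergence between windowed data and a fitted mixture
#'
#' `sum_m p_data(m) log(p_data(m) / q(m))` over the data support, where the
#' model probability at integer `m` integrates the mixture density over
#' `[m - 1/2, m + 1/2)` (continuity correction) and is renormalized over the
#' support.  Model probabilities are floored at 1e-12 (with a message) so an
#' observed value far outside the model yields a large, finite penalty.
#'
#' @param data an [empirical_distribution()] or a nonnegative integer vector.
#' @param fit a `gamma_mixture_fit` or components table.
#' @return Nonnegative scalar; 0 iff the two distributions agree on the
#'   support.
#' @examples
#' d <- empirical_distribution(rpois(500, 20))
#' kl_divergence(d, gamma_components(1, shape = 40, rate = 2))
#' @export
kl_divergence <- function(data, fit) {
  data <- as_empirical(data)
  comp <- fit_components(fit)
  q <- mixture_cell_mass(data$value, comp)
  tot <- sum(q)
  if (!is.finite(tot) || tot <= 0) {
    # model carries no numerically representable mass on the support
    rlang::inform("model probability floored at 1e-12 on the whole support.",
                  class = "branchdyn_floor_note")
    q <- rep(1e-12, length(q))
  } else {
    q <- q / tot
    if (any(q < 1e-12)) {
      rlang::inform("model probability floored at 1e-12 on part of the support.",
                    class = "branchdyn_floor_note")
      q <- pmax(q, 1e-12)
    }
  }
  # zero-probability support points contribute 0 (p log p -> 0)
  pos <- data$prob > 0
  sum(data$prob[pos] * log(data$prob[pos] / q[pos]))
}

# objective on the transformed parameter vector
# theta = (log shape_1..m, log rate_1..m, [loc_1..m,] logit-weights_1..m-1)
theta_to_components <- function(theta, m, use_loc, loc_max) {
  shape <- exp(theta[seq_len(m)])
  rate <- exp(theta[m + seq_len(m)])
  k <- 2 * m
  loc <- rep(0, m)
  if (use_loc) {
    loc <- pmin(theta[k + seq_len(m)], loc_max)
    k <- k + m
  }
  w <- if (m == 1L) 1 else {
    z <- c(theta[k + seq_len(m - 1L)], 0)
    z <- exp(z - max(z))
    z / sum(z)
  }
  tibble::tibble(weight = w, shape = shape, rate = rate, loc = loc)
}

kl_objective <- function(theta, m, values, probs, use_loc, loc_max) {
  shape <- exp(theta[seq_len(m)])
  rate <- exp(theta[m + seq_len(m)])
  k <- 2L * m
  loc <- rep(0, m)
  if (use_loc) {
    loc <- pmin(theta[k + seq_len(m)], loc_max)
    k <- k + m
  }
  w <- if (m == 1L) 1 else {
    z <- c(theta[k + seq_len(m - 1L)], 0)
    z <- exp(z - max(z))
    z / sum(z)
  }
  if (any(!is.finite(shape)) || any(!is.finite(rate))) return(1e10)
  q <- cell_mass_raw(values, w, shape, rate, loc)
  tot <- sum(q)
  if (!is.finite(tot) || tot <= 0) return(1e10)
  q <- pmax(q / tot, 1e-12)
  sum(probs * log(probs / q))
}

# moment-matched starting components from a seeded k-means split of samples
mixture_start <- function(samples, m, seed) {
  if (m == 1L) {
    mu <- mean(samples); v <- max(var(samples), 0.25)
    return(tibble::tibble(weight = 1, shape = max(mu^2 / v, 0.05),
                          rate = max(mu / v, 1e-4), loc = 0))
  }
  cluster <- tryCatch({
    km <- withr::with_seed(seed, kmeans(samples, centers = m, nstart = 3))
    match(km$cluster, order(km$centers))
  }, error = function(e) {
    # fewer distinct values than centers: fall back to a quantile split
    as.integer(cut(rank(samples, ties.method = "first"),
                   breaks = m, labels = FALSE))
  })
  comp <- purrr::map_dfr(seq_len(m), function(cl) {
    x <- samples[cluster == cl]
    mu <- mean(x); v <- max(var(x), 0.25)
    if (!is.finite(v)) v <- 0.25
    tibble::tibble(weight = length(x) / length(samples),
                   shape = max(mu^2 / v, 0.05), rate = max(mu / v, 1e-4),
                   loc = 0)
  })
  comp$weight <- comp$weight / sum(comp$weight)
  comp
}

components_to_theta <- function(comp, use_loc) {
  th <- c(log(comp$shape), log(comp$rate))
  if (use_loc) th <- c(th, comp$loc)
  m <- nrow(comp)
  if (m > 1L) {
    w <- pmax(comp$weight, 1e-6)
    th <- c(th, log(w[-m]) - log(w[m]))
  }
  th
}

#' Fit a Gamma mixture to count data by KL minimization
#'
#' Minimizes the Kullback-Leibler divergence between the empirical count
#' distribution and the continuity-corrected (integer-discretized) mixture,
#' by multi-start quasi-Newton optimization on log-shape, log-rate and
#' logit-simplex weights.  Starts are drawn from a seeded k-means split of the
#' samples with method-of-moments per group, plus log-normal perturbations.
#'
#' @param samples nonnegative numeric sample (real values are rounded to the
#'   integer grid before fitting).
#' @param m number of mixture components (1, 2 or 3).
#' @param n_starts number of optimizer starts (default 10).
#' @param seed integer seed controlling starts (default 0).
#' @param use_loc fit a location shift per component (default FALSE; shifted
#'   fits are ill-conditioned and off unless requested).  Shifts are bounded
#'   above by `min(samples)`.
#' @param maxit maximum BFGS iterations per start.
#' @return Object of class `gamma_mixture_fit`: components tibble (ordered by
#'   component mean), achieved `kl`, discretized log-likelihood `loglik`,
#'   `bic`, sample size `n`, the empirical distribution fitted, and optimizer
#'   metadata.
#' @examples
#' x <- sample_gamma_mixture(gamma_components(1, 5, 0.5), 2000, seed = 1)
#' fit_mixture(x, m = 1)
#' @export
fit_mixture <- function(samples, m, n_starts = 10, seed = 0, use_loc = FALSE,
                        maxit = 150) {
  if (!m %in% 1:3) stop_invalid("`m` must be 1, 2 or 3.")
  if (length(samples) == 0L || any(!is.finite(samples)) || any(samples < 0)) {
    stop_invalid("`samples` must be nonnegative and finite.")
  }
  samples <- round(samples)
  if (length(unique(samples)) == 1L) {
    stop_invalid(
      "all samples are identical; a Gamma mixture is degenerate here - treat the window as an m = 1 point mass instead.",
      class = "branchdyn_degenerate_data")
  }
  emp <- empirical_distribution(samples)
  values <- emp$value; probs <- emp$prob
  loc_max <- min(samples)
  base <- mixture_start(samples, m, seed)
  starts <- vector("list", n_starts)
  starts[[1L]] <- base
  rng <- withr::with_seed(seed + 1L, {
    lapply(seq_len(max(0L, n_starts - 1L)), function(i) {
      comp <- base
      comp$shape <- comp$shape * rlnorm(m, 0, 0.35)
      comp$rate <- comp$rate * rlnorm(m, 0, 0.35)
      if (m > 1L) {
        w <- comp$weight * rlnorm(m, 0, 0.3)
        comp$weight <- w / sum(w)
      }
      comp
    })
  })
  for (i in seq_along(rng)) starts[[i + 1L]] <- rng[[i]]
  if (m > 1L) {
    # collapsed start: m near-identical copies of the single-component moment
    # fit, so the search space nests the m = 1 solution
    single <- mixture_start(samples, 1L, seed)
    starts[[length(starts) + 1L]] <- tibble::tibble(
      weight = rep(1 / m, m),
      shape = single$shape * exp(seq(-0.02, 0.02, length.out = m)),
      rate = rep(single$rate, m), loc = 0)
  }

  best <- NULL
  converged <- FALSE
  since_improved <- 0L
  for (si in seq_along(starts)) {
    th0 <- components_to_theta(starts[[si]], use_loc)
    opt <- tryCatch(
      optim(th0, kl_objective, m = m, values = values, probs = probs,
            use_loc = use_loc, loc_max = loc_max, method = "BFGS",
            control = list(maxit = maxit, reltol = 1e-8)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value - 1e-7) {
      since_improved <- 0L
    } else {
      since_improved <- since_improved + 1L
    }
    if (is.null(best) || opt$value < best$value) {
      best <- opt
      converged <- opt$convergence == 0L
    }
    # flat multi-start surface: stop once further starts stop paying
    if (si >= 5L && since_improved >= 3L) break
  }
  if (is.null(best)) {
    stop_invalid("all optimizer starts failed.", class = "branchdyn_fit_error")
  }
  comp <- theta_to_components(best$par, m, use_loc, loc_max)
  comp <- comp[order(comp$loc + comp$shape / comp$rate), , drop = FALSE]
  # proper (un-renormalized) discretized pmf for the log-likelihood
  q_full <- pmax(mixture_cell_mass(values, comp), 1e-300)
  n <- attr(emp, "n")
  loglik <- n * sum(probs * log(q_full))
  n_par <- (3L + as.integer(use_loc)) * m - 1L
  structure(list(components = comp, m = m, kl = max(best$value, 0),
                 loglik = loglik, bic = n_par * log(n) - 2 * loglik,
                 n = n, data = emp, converged = converged,
                 n_starts = n_starts, seed = seed, use_loc = use_loc),
            class = "gamma_mixture_fit")
}

#' @export
print.gamma_mixture_fit <- function(x, ...) {
  cat(sprintf("<gamma_mixture_fit> m = %d, n = %d, KL = %.5g, BIC = %.5g\n",
              x$m, x$n, x$kl, x$bic))
  print(x$components)
  invisible(x)
}

#' Select the modality (1-3 Gamma components) of a count distribution
#'
#' Fits mixtures with one, two and three components and selects the simplest
#' adequate model by BIC computed from the discretized log-likelihood; since
#' the achieved KL always improves with more components, BIC supplies the
#' parsimony pressure.  Near-ties (difference below `delta_bic`) are resolved
#' toward fewer components.
#'
#' @inheritParams fit_mixture
#' @param max_m largest number of components considered (default 3).
#' @param delta_bic BIC margin under which the simpler model wins (default 2).
#' @return Object of class `modality_call`: selected `m`, per-candidate `fits`
#'   list, `bic` and `kl` vectors.
#' @examples
#' x <- sample_gamma_mixture(gamma_components(1, 5, 0.5), 1000, seed = 1)
#' select_modality(x)$m
#' @export
select_modality <- function(samples, max_m = 3, delta_bic = 2, n_starts = 10,
                            seed = 0, use_loc = FALSE) {
  fits <- lapply(seq_len(max_m), function(m)
    fit_mixture(samples, m, n_starts = n_starts, seed = seed, use_loc = use_loc))
  bic <- vapply(fits, function(f) f$bic, numeric(1))
  kl <- vapply(fits, function(f) f$kl, numeric(1))
  m_sel <- 1L
  for (m in seq_len(max_m)[-1L]) {
    if (bic[m] < bic[m_sel] - delta_bic) m_sel <- m
  }
  structure(list(m = m_sel, fits = fits, bic = bic, kl = kl,
                 delta_bic = delta_bic),
            class = "modality_call")
}

#' @export
print.modality_call <- function(x, ...) {
  cat(sprintf("<modality_call> selected m = %d (BIC: %s)\n", x$m,
              paste(sprintf("%.1f", x$bic), collapse = ", ")))
  invisible(x)
}

#' Closed-form and numeric summary statistics of a fitted mixture
#'
#' Per-component moments use the shifted-Gamma closed forms (mean
#' `loc + shape/rate`, variance `shape/rate^2`, skewness `2/sqrt(shape)`,
#' excess kurtosis `6/shape`, peak `loc + (shape-1)/rate` for shape > 1, else
#' `loc`); mixture-level peak positions are the local maxima of the mixture
#' density, located on a fine grid and refined by golden-section search.
#'
#' @param fit a `gamma_mixture_fit` or components table.
#' @return A list of class `distribution_stats` with `components` (tibble of
#'   per-component statistics) and `peaks` (mixture-density local maxima).
#' @examples
#' mixture_stats(gamma_components(1, 408.27, 19.49))
#' @export
mixture_stats <- function(fit) {
  comp <- fit_components(fit)
  stats_tbl <- dplyr::mutate(
    comp,
    mean = .data$loc + .data$shape / .data$rate,
    variance = .data$shape / .data$rate^2,
    skewness = 2 / sqrt(.data$shape),
    ex_kurtosis = 6 / .data$shape,
    peak = ifelse(.data$shape > 1,
                  .data$loc + (.data$shape - 1) / .data$rate, .data$loc),
    component = dplyr::row_number()) |>
    dplyr::relocate("component")
  structure(list(components = stats_tbl, peaks = mixture_peaks(comp)),
            class = "distribution_stats")
}

# local maxima of the mixture density: coarse grid + optimize() refinement
mixture_peaks <- function(comp, n_grid = 2000L) {
  lo <- min(comp$loc)
  hi <- max(comp$loc + qgamma(1 - 1e-6, comp$shape, rate = comp$rate))
  grid <- seq(lo, hi, length.out = n_grid)
  dens <- mixture_pdf(grid, comp)
  is_peak <- which(diff(sign(diff(dens))) == -2) + 1L
  if (length(is_peak) == 0L) {
    return(grid[which.max(dens)])
  }
  vapply(is_peak, function(i) {
    optimize(function(x) -mixture_pdf(x, comp),
             lower = grid[max(1L, i - 2L)],
             upper = grid[min(n_grid, i + 2L)])$minimum
  }, numeric(1))
}

#' @export
print.distribution_stats <- function(x, ...) {
  cat("<distribution_stats> mixture peaks:",
      paste(sprintf("%.3f", x$peaks), collapse = ", "), "\n")
  print(x$components)
  invisible(x)
}
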