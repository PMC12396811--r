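# Gauss-Jacobi nodes/weights on [-1, 1] for weight (1-x)^a (1+x)^b:
# Golub-Welsch on the analytic Jacobi recurrence, tridiagonal QL in C++
gauss_jacobi <- function(n, a, b) {
  .jacobi_rule_cpp(as.integer(n), a, b)
}

# quadrature of the Beta(k_on, k_off) density on (0, 1): nodes p_q and
# weights summing to 1, with the Beta kernel absorbed into the weights.
# All scalar factors (mu0, 2^-(a+b+1), 1/B) cancel under normalization, so
# the raw squared first eigenvector components are used directly - immune to
# the mu0 overflow at extreme k_off.
beta_quadrature <- function(k_on, k_off, order) {
  gj <- gauss_jacobi(order, a = k_off - 1, b = k_on - 1)
  z2 <- gj$z2
  list(p = (gj$nodes + 1) / 2, w = z2 / sum(z2))
}

#' Beta-Poisson probability mass function
#'
#' Stationary count law of the two-state model:
#' `P(X = k) = integral_0^1 Poisson(k; s * k_syn * p) Beta(p; k_on, k_off) dp`,
#' evaluated by Gauss-Jacobi quadrature (which absorbs the Beta kernel, so
#' endpoint singularities for `k_on < 1` or `k_off < 1` are handled exactly).
#' With `order = NULL` the quadrature order escalates (64, 128, ..., 1024)
#' until two successive orders agree within 1e-9; exhaustion raises a
#' numerical error.
#'
#' @param k nonnegative integer count(s).
#' @param k_on,k_off Beta parameters (> 0): burst frequency and inverse burst
#'   duration per mRNA lifetime.
#' @param k_syn synthesis rate (> 0).
#' @param s cell size factor (scalar, > 0).
#' @param order fixed quadrature order, or `NULL` for auto-escalation.
#' @return Probabilities `P(X = k)`.
#' @examples
#' beta_poisson_pmf(0:5, k_on = 0.5, k_off = 10, k_syn = 100)
#' @export
beta_poisson_pmf <- function(k, k_on, k_off, k_syn, s = 1, order = NULL) {
  check_positive(k_on, "k_on"); check_positive(k_off, "k_off")
  check_positive(k_syn, "k_syn"); check_positive(s, "s")
  if (any(k < 0) || any(k != round(k))) stop_invalid("`k` must be nonnegative integers.")
  lam <- s * k_syn
  pmf_at <- function(ord) {
    q <- beta_quadrature(k_on, k_off, ord)
    vapply(k, function(ki) sum(q$w * dpois(ki, lam * q$p)), numeric(1))
  }
  if (!is.null(order)) return(pmf_at(order))
  ord <- 64L
  prev <- pmf_at(ord)
  repeat {
    ord <- ord * 2L
    cur <- pmf_at(ord)
    if (max(abs(cur - prev)) < 1e-9) return(cur)
    if (ord >= 1024L) {
      stop_invalid("Beta-Poisson quadrature did not converge (order escalation exhausted).",
                   class = "branchdyn_numerical_error")
    }
    prev <- cur
  }
}

#' Estimate per-cell size factors from total counts
#'
#' `s_j` = cell total / median cell total, so `median(s) = 1`.  A crude but
#' robust proxy for sequencing depth x cell volume, entering the Beta-Poisson
#' likelihood as a Poisson rate multiplier.
#'
#' @param counts cells x genes count matrix.
#' @return Named numeric vector of size factors (one per cell).
#' @examples
#' m <- matrix(c(50, 50, 100, 100, 200, 200), 3, 2, byrow = TRUE,
#'             dimnames = list(paste0("c", 1:3), c("g1", "g2")))
#' estimate_cell_sizes(m)
#' @export
estimate_cell_sizes <- function(counts) {
  counts <- check_count_matrix(counts)
  totals <- rowSums(counts)
  zero <- rownames(counts)[totals == 0]
  if (length(zero) > 0L) {
    stop_invalid(paste0("cells with all-zero counts: ",
                        paste(head(zero, 10), collapse = ", ")),
                 class = "branchdyn_degenerate_data")
  }
  s <- totals / median(totals)
  names(s) <- rownames(counts)
  s
}

# negative log-likelihood of aggregated (count, size) groups; `memo` caches
# the (k_on, k_off) quadrature so k_syn-only moves reuse the nodes
bp_negloglik <- function(theta, kk, ss, nn, order,
                         memo = new.env(parent = emptyenv()),
                         lb = NULL, ub = NULL) {
  pen <- 0
  if (!is.null(lb)) {
    excess <- pmax(lb - theta, 0) + pmax(theta - ub, 0)
    if (any(excess > 0)) {
      pen <- 1e4 * sum(excess)
      theta <- pmin(pmax(theta, lb), ub)
    }
  }
  k_on <- exp(theta[1]); k_off <- exp(theta[2]); k_syn <- exp(theta[3])
  key <- c(k_on, k_off)
  q <- if (!is.null(memo) && identical(memo$key, key)) memo$q else {
    qq <- tryCatch(beta_quadrature(k_on, k_off, order), error = function(e) NULL)
    if (!is.null(memo) && !is.null(qq)) {
      memo$key <- key
      memo$q <- qq
    }
    qq
  }
  if (is.null(q)) return(1e10)
  lam <- outer(q$p, ss * k_syn)           # order x groups
  if (is.null(memo$kmat)) {
    memo$kmat <- matrix(kk, nrow = length(q$p), ncol = length(kk), byrow = TRUE)
  }
  P <- colSums(q$w * dpois(memo$kmat, lam))
  if (any(!is.finite(P))) return(1e10)
  -sum(nn * log(pmax(P, 1e-300))) + pen
}

#' Maximum-likelihood Beta-Poisson burst parameters
#'
#' Fits `(k_on, k_off, k_syn)` by maximizing the Beta-Poisson likelihood of
#' the observed counts (cell sizes as Poisson rate multipliers) by Nelder-Mead
#' search on the log scale, with box bounds `k_on, k_off` in `[1e-3, 1e3]`
#' and `k_syn` in `[1e-2, 1e5]` enforced by a soft penalty, from 8
#' moment-matched multi-starts.  All fitted rates are
#' per effective mRNA decay time.  Burst size `BS = k_syn / k_off`, burst
#' frequency `BF = k_on`.
#'
#' @param counts nonnegative integer vector.
#' @param sizes per-cell size factors aligned to `counts` (default all 1).
#' @param n_starts optimizer starts (default 8).
#' @param seed integer seed for the jittered starts.
#' @param order Gauss-Jacobi quadrature order used inside the likelihood
#'   (default 40; fixed-order Gauss-Jacobi is the standard choice for this
#'   likelihood and is accurate to ~1e-12 for per-lifetime rates up to ~150).
#' @return Object of class `burst_fit` with `k_on`, `k_off`, `k_syn`, `BS`,
#'   `BF`, `loglik`, `n`, `converged`.
#' @examples
#' x <- simulate_two_state_counts(two_state_params(0.5, 10, 100), 300, seed = 1)
#' fit_burst_params(x)
#' @export
fit_burst_params <- function(counts, sizes = NULL, n_starts = 8, seed = 0,
                             order = 40L) {
  counts <- check_counts_vector(counts)
  n <- length(counts)
  if (is.null(sizes)) sizes <- rep(1, n)
  check_positive(sizes, "sizes")
  if (length(sizes) != n) stop_invalid("`sizes` must align with `counts`.")
  if (all(counts == 0L)) {
    stop_invalid("all counts are zero; burst parameters are unidentifiable.",
                 class = "branchdyn_degenerate_data")
  }
  # aggregate identical (count, size) pairs; exact and much faster when sizes
  # are constant or few-valued
  key <- paste(counts, signif(sizes, 12))
  agg <- !duplicated(key)
  nn <- as.numeric(table(key)[key[agg]])
  kk <- counts[agg]; ss <- sizes[agg]

  mu <- mean(counts / sizes)
  lb <- log(c(1e-3, 1e-3, 1e-2)); ub <- log(c(1e3, 1e3, 1e5))
  grid <- expand.grid(k_on = c(0.3, 1), k_off = c(3, 30))
  starts <- lapply(seq_len(nrow(grid)), function(i) {
    c(grid$k_on[i], grid$k_off[i],
      mu * (grid$k_on[i] + grid$k_off[i]) / grid$k_on[i])
  })
  extra <- max(0L, n_starts - length(starts))
  jit <- withr::with_seed(seed, {
    lapply(seq_len(extra), function(i) {
      base <- starts[[1 + (i - 1) %% length(starts)]]
      base * rlnorm(3, 0, 0.5)
    })
  })
  starts <- c(starts, jit)[seq_len(min(n_starts, length(starts) + extra))]

  best <- NULL
  memo <- new.env(parent = emptyenv())
  since_improved <- 0L
  for (si in seq_along(starts)) {
    th0 <- pmin(pmax(log(starts[[si]]), lb + 1e-6), ub - 1e-6)
    # optimize the offset from th0 so the search path is exactly invariant
    # under log-scale translations (size rescaling shifts only th0)
    opt <- tryCatch(
      optim(c(0, 0, 0),
            function(d) bp_negloglik(th0 + d, kk = kk, ss = ss, nn = nn,
                                     order = order, memo = memo,
                                     lb = lb, ub = ub),
            method = "Nelder-Mead",
            control = list(maxit = 500, reltol = 1e-7)),
      error = function(e) NULL)
    if (is.null(opt)) next
    opt$par <- th0 + opt$par
    if (is.null(best) || opt$value < best$value - 1e-4) {
      since_improved <- 0L
    } else {
      since_improved <- since_improved + 1L
    }
    if (is.null(best) || opt$value < best$value) best <- opt
    if (si >= 4L && since_improved >= 2L) break
  }
  if (is.null(best)) stop_invalid("all burst-fit starts failed.",
                                  class = "branchdyn_fit_error")
  par <- pmin(pmax(best$par, lb), ub)
  k_on <- exp(par[1]); k_off <- exp(par[2]); k_syn <- exp(par[3])
  structure(list(k_on = k_on, k_off = k_off, k_syn = k_syn,
                 BS = k_syn / k_off, BF = k_on,
                 loglik = -best$value, n = n,
                 converged = best$convergence == 0L, order = order),
            class = "burst_fit")
}

#' @export
print.burst_fit <- function(x, ...) {
  cat(sprintf(
    "<burst_fit> k_on=%.4g k_off=%.4g k_syn=%.4g | BS=%.4g BF=%.4g (n=%d, loglik=%.2f)\n",
    x$k_on, x$k_off, x$k_syn, x$BS, x$BF, x$n, x$loglik))
  invisible(x)
}

#' Burst-kinetics trajectory of one gene along the branching tree
#'
#' Fits Beta-Poisson burst parameters in every pseudo-time window of every
#' branch segment and classifies the per-segment monotone trend of burst size
#' and burst frequency (Spearman rank correlation against window order).
#'
#' @param counts cells x genes count matrix.
#' @param annotation trajectory annotation.
#' @param gene gene id.
#' @param windows optional window table from [assign_windows()]; by default
#'   windows are built with `overlap_fraction = 0.5` for a smooth trend
#'   series.
#' @param windows_per_segment,min_cells,overlap_fraction passed to
#'   [assign_windows()] when `windows` is NULL.
#' @param sizes optional size factors; estimated from `counts` by default.
#' @param rho_threshold,alpha trend-classification parameters, see
#'   [trend_classification()].
#' @param ... passed to [fit_burst_params()].
#' @return Tibble of class `burst_trajectory`: one row per window with
#'   `branch`, `window_index`, `t_mid`, `n_cells`, `k_on`, `k_off`, `k_syn`,
#'   `BS`, `BF`, `loglik`; per-segment trend labels in `attr(, "trends")`.
#' @export
burst_trajectory <- function(counts, annotation, gene, windows = NULL,
                             windows_per_segment = 8, min_cells = 10,
                             overlap_fraction = 0.5, sizes = NULL,
                             rho_threshold = 0.6, alpha = 0.05, ...) {
  counts <- check_count_matrix(counts)
  check_annotation(annotation)
  if (!gene %in% colnames(counts)) stop_invalid(sprintf("gene '%s' not found.", gene))
  if (is.null(windows)) {
    windows <- assign_windows(annotation, windows_per_segment, min_cells,
                              overlap_fraction)
  }
  if (is.null(sizes)) {
    sizes <- estimate_cell_sizes(counts)
  } else {
    if (is.null(names(sizes))) {
      if (length(sizes) != nrow(counts)) {
        stop_invalid("`sizes` must align with the rows of `counts`.")
      }
      names(sizes) <- rownames(counts)
    }
  }
  rows <- purrr::map(seq_len(nrow(windows)), function(i) {
    cells <- windows$cells[[i]]
    if (length(cells) < min_cells) {
      rlang::inform(sprintf("window %d skipped (%d cells < min_cells).",
                            windows$window_index[i], length(cells)))
      return(NULL)
    }
    fit <- fit_burst_params(counts[cells, gene], sizes[cells], ...)
    tibble::tibble(branch = windows$branch[i],
                   window_index = windows$window_index[i],
                   t_mid = (windows$t_lo[i] + windows$t_hi[i]) / 2,
                   n_cells = length(cells),
                   k_on = fit$k_on, k_off = fit$k_off, k_syn = fit$k_syn,
                   BS = fit$BS, BF = fit$BF, loglik = fit$loglik)
  })
  out <- dplyr::bind_rows(rows)
  trends <- dplyr::bind_rows(
    dplyr::mutate(segment_trend_table(out, "BS", rho_threshold, alpha),
                  metric = "BS", .after = "branch"),
    dplyr::mutate(segment_trend_table(out, "BF", rho_threshold, alpha),
                  metric = "BF", .after = "branch"))
  attr(out, "trends") <- trends
  attr(out, "gene") <- gene
  class(out) <- c("burst_trajectory", class(out))
  out
}

#' Per-segment trend summary of a burst trajectory
#'
#' @param x a [burst_trajectory()] result.
#' @return Tibble with one row per segment x metric (`BS`, `BF`): trend
#'   `label`, Spearman `rho`, `p_value`.
#' @export
burst_trends <- function(x) {
  stopifnot(inherits(x, "burst_trajectory"))
  attr(x, "trends")
}
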