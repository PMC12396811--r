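#' Tidy a fitted Gamma mixture into its component table
#'
#' @param x a `gamma_mixture_fit`.
#' @param ... unused.
#' @return Tibble: one row per component with `weight`, `shape`, `rate`,
#'   `loc` and the closed-form `mean`, `variance`, `skewness`,
#'   `ex_kurtosis`, `peak`.
#' @export
tidy.gamma_mixture_fit <- function(x, ...) {
  mixture_stats(x)$components
}

#' One-row model summary of a fitted Gamma mixture
#' @param x a `gamma_mixture_fit`.
#' @param ... unused.
#' @return Tibble: `m`, `kl`, `loglik`, `bic`, `n`, `converged`.
#' @export
glance.gamma_mixture_fit <- function(x, ...) {
  tibble::tibble(m = x$m, kl = x$kl, loglik = x$loglik, bic = x$bic,
                 n = x$n, converged = x$converged)
}

#' Tidy a modality call into its per-candidate score table
#' @param x a `modality_call`.
#' @param ... unused.
#' @return Tibble: `m`, `kl`, `bic`, `selected`.
#' @export
tidy.modality_call <- function(x, ...) {
  tibble::tibble(m = seq_along(x$bic), kl = x$kl, bic = x$bic,
                 selected = seq_along(x$bic) == x$m)
}

#' Tidy a Beta-Poisson burst fit
#' @param x a `burst_fit`.
#' @param ... unused.
#' @return One-row tibble: `k_on`, `k_off`, `k_syn`, `BS`, `BF`.
#' @export
tidy.burst_fit <- function(x, ...) {
  tibble::tibble(k_on = x$k_on, k_off = x$k_off, k_syn = x$k_syn,
                 BS = x$BS, BF = x$BF)
}

#' One-row summary of a Beta-Poisson burst fit
#' @param x a `burst_fit`.
#' @param ... unused.
#' @return Tibble: `loglik`, `n`, `converged`.
#' @export
glance.burst_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, n = x$n, converged = x$converged)
}

#' Tidy a Wasserstein matrix into long pair form
#' @param x a `wasserstein_matrix`.
#' @param ... unused.
#' @return Tibble: `item_a`, `item_b`, `distance` (upper triangle).
#' @export
tidy.wasserstein_matrix <- function(x, ...) {
  m <- unclass(x)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(item_a = rownames(m)[idx[, 1]],
                 item_b = colnames(m)[idx[, 2]],
                 distance = m[idx])
}
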