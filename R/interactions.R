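# per-branch trend table for a window-indexed series (branches with < 4
# windows are skipped)
segment_trend_table <- function(df, col, rho_threshold, alpha) {
  out <- purrr::map_dfr(split(df, df$branch), function(g) {
    if (nrow(g) < 4L) return(NULL)
    dplyr::mutate(
      trend_classification(g[[col]][order(g$t_mid)], rho_threshold, alpha),
      branch = g$branch[1], .before = 1)
  })
  if (nrow(out) == 0L) {
    out <- tibble::tibble(branch = character(), label = character(),
                          rho = double(), p_value = double(), n = integer())
  }
  out
}

#' Classify the monotone trend of an ordered series
#'
#' Spearman rank correlation of the series against its index: `increasing`
#' if `rho >= rho_threshold` with `p < alpha`, `decreasing` if
#' `rho <= -rho_threshold` with `p < alpha`, `constant` if `|rho|` is below
#' threshold and the relative range of the series is under 10%, otherwise
#' `non-monotone`.  Invariant under positive affine transforms of the series
#' (rank-based), except that the constant label also inspects the relative
#' range.
#'
#' @param series ordered numeric vector, length >= 4.
#' @param rho_threshold Spearman threshold in (0, 1), default 0.6.
#' @param alpha significance level, default 0.05.
#' @return One-row tibble: `label`, `rho`, `p_value`, `n`.
#' @examples
#' trend_classification(c(1, 2, 3, 4, 5))
#' @export
trend_classification <- function(series, rho_threshold = 0.6, alpha = 0.05) {
  if (length(series) < 4L) stop_invalid("`series` must have length >= 4.")
  if (rho_threshold <= 0 || rho_threshold >= 1) {
    stop_invalid("`rho_threshold` must lie in (0, 1).")
  }
  lab_tbl <- function(label, rho, p) {
    tibble::tibble(label = label, rho = rho, p_value = p, n = length(series))
  }
  if (length(unique(series)) == 1L) return(lab_tbl("constant", NA_real_, NA_real_))
  ct <- suppressWarnings(
    cor.test(series, seq_along(series), method = "spearman", exact = NULL))
  rho <- unname(ct$estimate); p <- ct$p.value
  rel_range <- diff(range(series)) / max(abs(mean(series)), .Machine$double.eps)
  label <- if (rho >= rho_threshold && p < alpha) "increasing"
  else if (rho <= -rho_threshold && p < alpha) "decreasing"
  else if (abs(rho) < rho_threshold && rel_range < 0.10) "constant"
  else "non-monotone"
  lab_tbl(label, rho, p)
}

#' Exact 1-Wasserstein distance between two samples
#'
#' Integral over \[0, 1\] of the absolute difference of the two empirical
#' quantile functions, computed exactly from the merged quantile breakpoints
#' (no binning).  Satisfies the metric axioms and the translation property
#' `W1(u, u + c) = |c|` exactly.
#'
#' @param u,v nonempty numeric samples (any lengths).
#' @return Nonnegative scalar.
#' @examples
#' wasserstein_1d(c(1, 2, 3), c(4, 5, 6)) # a pure shift: 3
#' @export
wasserstein_1d <- function(u, v) {
  if (length(u) == 0L || length(v) == 0L) stop_invalid("samples must be nonempty.")
  u <- sort(u); v <- sort(v)
  n <- length(u); m <- length(v)
  t <- sort(unique(c(seq_len(n) / n, seq_len(m) / m)))
  lo <- c(0, t[-length(t)])
  mid <- (lo + t) / 2
  sum((t - lo) * abs(u[ceiling(mid * n)] - v[ceiling(mid * m)]))
}

#' Pairwise Wasserstein distances between gene x group expression laws
#'
#' Distances between the count distributions of each selected gene within
#' each stage (or branch) group — small distances flag gene pairs whose
#' expression laws track each other along the trajectory.
#'
#' @param counts cells x genes count matrix.
#' @param annotation trajectory annotation.
#' @param genes gene ids to compare.
#' @param group_by `"stage"` or `"branch"`.
#' @param min_cells groups smaller than this are excluded (with a message).
#' @return Symmetric matrix of class `wasserstein_matrix` with
#'   `"gene@group"` dimnames; zero diagonal.
#' @export
wasserstein_matrix <- function(counts, annotation, genes,
                               group_by = c("stage", "branch"),
                               min_cells = 10) {
  counts <- check_count_matrix(counts)
  check_annotation(annotation)
  group_by <- match.arg(group_by)
  missing <- setdiff(genes, colnames(counts))
  if (length(missing) > 0L) {
    stop_invalid(paste0("gene(s) not in matrix: ", paste(missing, collapse = ", ")))
  }
  grp <- as.character(annotation[[group_by]])
  keep <- names(which(table(grp) >= min_cells))
  dropped <- setdiff(unique(grp), keep)
  if (length(dropped) > 0L) {
    rlang::inform(paste0("excluded undersized group(s): ",
                         paste(dropped, collapse = ", ")))
  }
  items <- tidyr::crossing(gene = genes, group = keep)
  pull <- function(i) {
    cells <- annotation$cell_id[grp == items$group[i]]
    as.numeric(counts[cells, items$gene[i]])
  }
  samples <- lapply(seq_len(nrow(items)), pull)
  lab <- paste0(items$gene, "@", items$group)
  k <- length(samples)
  D <- matrix(0, k, k, dimnames = list(lab, lab))
  for (i in seq_len(k)) for (j in seq_len(k)) if (j > i) {
    D[i, j] <- D[j, i] <- wasserstein_1d(samples[[i]], samples[[j]])
  }
  structure(D, class = c("wasserstein_matrix", class(D)))
}

#' Gaussian-kernel joint density of two genes
#'
#' 2D kernel density estimate on a regular grid (Scott's-rule bandwidth per
#' axis); the total mass times the grid cell area is 1 within 1e-3.  If one
#' axis has zero variance the estimate degenerates to a 1D density times a
#' point mass on that axis (with a message).
#'
#' @param a,b equal-length numeric samples (e.g. two genes' counts across one
#'   window's cells).
#' @param n_grid grid resolution per axis (default 64).
#' @param lims optional `c(xlo, xhi, ylo, yhi)` limits.
#' @return List of class `joint_density`: `x`, `y` (grid axes), `z` (density
#'   matrix).
#' @export
joint_density <- function(a, b, n_grid = 64, lims = NULL) {
  if (length(a) != length(b) || length(a) < 2L) {
    stop_invalid("`a` and `b` must be equal-length samples (n >= 2).")
  }
  n <- length(a)
  scott <- function(x) sd(x) * n^(-1 / 6)
  if (sd(a) == 0 || sd(b) == 0) {
    rlang::inform("zero-variance axis: falling back to 1D density x point mass.")
    flip <- sd(a) == 0
    live <- if (flip) b else a
    const <- if (flip) a[1] else b[1]
    d <- density(live, bw = scott(live), n = n_grid)
    yg <- seq(const - 0.5, const + 0.5, length.out = n_grid)
    dy <- diff(yg[1:2])
    z <- matrix(0, n_grid, n_grid)
    j0 <- which.min(abs(yg - const))
    z[, j0] <- d$y / dy
    out <- if (flip) list(x = yg, y = d$x, z = t(z)) else list(x = d$x, y = yg, z = z)
    return(structure(out, class = "joint_density"))
  }
  h <- c(4 * scott(a), 4 * scott(b))  # kde2d uses h/4 as the kernel sd
  if (is.null(lims)) {
    lims <- c(range(a) + c(-1, 1) * h[1], range(b) + c(-1, 1) * h[2])
  }
  kd <- MASS::kde2d(a, b, h = h, n = n_grid, lims = lims)
  structure(list(x = kd$x, y = kd$y, z = kd$z), class = "joint_density")
}

# --- miniature tree-ensemble importance (GENIE3-style) ----------------------

# best variance-reducing split of y by numeric x; returns improvement and
# threshold (NULL if no valid split)
best_split <- function(x, y, min_leaf) {
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  n <- length(ys)
  cs <- cumsum(ys); css <- cumsum(ys^2)
  tot_sse <- css[n] - cs[n]^2 / n
  i <- seq_len(n - 1)
  valid <- xs[i] != xs[i + 1] & i >= min_leaf & (n - i) >= min_leaf
  if (!any(valid)) return(NULL)
  i <- i[valid]
  sse_l <- css[i] - cs[i]^2 / i
  sse_r <- (css[n] - css[i]) - (cs[n] - cs[i])^2 / (n - i)
  red <- tot_sse - (sse_l + sse_r)
  bi <- which.max(red)
  if (red[bi] <= 0) return(NULL)
  list(threshold = (xs[i[bi]] + xs[i[bi] + 1]) / 2, improvement = red[bi])
}

# one regression tree grown on (X, y); accumulates per-feature variance
# reduction into `imp` (an environment-backed vector) and returns it
grow_tree <- function(X, y, mtry, min_node, imp) {
  recurse <- function(rows) {
    if (length(rows) < min_node || var(y[rows]) == 0) return(invisible())
    feats <- sample.int(ncol(X), mtry)
    best <- NULL; best_f <- NA_integer_
    for (f in feats) {
      sp <- best_split(X[rows, f], y[rows], min_leaf = 2L)
      if (!is.null(sp) && (is.null(best) || sp$improvement > best$improvement)) {
        best <- sp; best_f <- f
      }
    }
    if (is.null(best)) return(invisible())
    imp[best_f] <<- imp[best_f] + best$improvement
    left <- rows[X[rows, best_f] <= best$threshold]
    right <- setdiff(rows, left)
    recurse(left); recurse(right)
  }
  recurse(seq_len(nrow(X)))
  imp
}

# normalized per-feature importance from a forest of `n_trees` trees
rf_importance <- function(X, y, n_trees = 100, mtry = NULL, min_node = 5,
                          seed = 0) {
  p <- ncol(X)
  mtry <- mtry %||% max(1L, ceiling(sqrt(p)))
  imp <- numeric(p)
  withr::with_seed(seed, {
    for (t in seq_len(n_trees)) {
      boot <- sample.int(nrow(X), replace = TRUE)
      imp <- grow_tree(X[boot, , drop = FALSE], y[boot], mtry, min_node, imp)
    }
  })
  names(imp) <- colnames(X)
  tot <- sum(imp)
  if (tot == 0) imp else imp / tot
}

#' Regulation-strength series of one gene pair along the trajectory
#'
#' Per pseudo-time window, a small random-forest regression (default 100
#' trees, square-root feature subsampling, seeded) predicts the target gene's
#' log-normalized expression from all other genes in that window's cells; the
#' regulator's share of the total variance reduction is its regulation
#' strength.  The ordered series is trend-classified overall and per branch
#' segment.
#'
#' @param counts cells x genes count matrix (>= 2 genes).
#' @param annotation trajectory annotation.
#' @param regulator,target gene ids.
#' @param windows optional [assign_windows()] table (default: overlapping
#'   windows, `overlap_fraction = 0.5`).
#' @param windows_per_segment,min_cells,overlap_fraction used when `windows`
#'   is NULL.
#' @param n_trees trees per window (default 100).
#' @param seed integer seed; window `i` uses `seed + i`.
#' @param rho_threshold,alpha trend-classification parameters.
#' @return Tibble of class `regulation_trend`: `window_index`, `branch`,
#'   `t_mid`, `importance`; overall and per-segment trends in
#'   `attr(, "trends")`, regulator/target in attributes.
#' @export
regulation_strength_series <- function(counts, annotation, regulator, target,
                                       windows = NULL, windows_per_segment = 8,
                                       min_cells = 10, overlap_fraction = 0.5,
                                       n_trees = 100, seed = 0,
                                       rho_threshold = 0.6, alpha = 0.05) {
  counts <- check_count_matrix(counts)
  check_annotation(annotation)
  if (ncol(counts) < 2L) stop_invalid("need >= 2 genes.")
  for (g in c(regulator, target)) {
    if (!g %in% colnames(counts)) stop_invalid(sprintf("gene '%s' not found.", g))
  }
  if (regulator == target) stop_invalid("regulator and target must differ.")
  if (is.null(windows)) {
    windows <- assign_windows(annotation, windows_per_segment, min_cells,
                              overlap_fraction)
  }
  sizes <- rowSums(counts)
  sizes <- sizes / median(sizes[sizes > 0])
  sizes[sizes == 0] <- 1
  expr <- log1p(counts / sizes)
  predictors <- setdiff(colnames(counts), target)
  rows <- purrr::map(seq_len(nrow(windows)), function(i) {
    cells <- windows$cells[[i]]
    y <- expr[cells, target]
    if (var(y) == 0) {
      rlang::inform(sprintf("window %d: constant target; importance 0.",
                            windows$window_index[i]))
      importance <- 0
    } else {
      imp <- rf_importance(expr[cells, predictors, drop = FALSE], y,
                           n_trees = n_trees, seed = seed + i)
      importance <- unname(imp[regulator])
    }
    tibble::tibble(window_index = windows$window_index[i],
                   branch = windows$branch[i],
                   t_mid = (windows$t_lo[i] + windows$t_hi[i]) / 2,
                   importance = importance)
  })
  out <- dplyr::bind_rows(rows)
  seg_trends <- segment_trend_table(out, "importance", rho_threshold, alpha)
  overall <- if (nrow(out) >= 4) {
    dplyr::mutate(trend_classification(out$importance, rho_threshold, alpha),
                  branch = "all") |> dplyr::relocate("branch")
  } else NULL
  attr(out, "trends") <- dplyr::bind_rows(overall, seg_trends)
  attr(out, "regulator") <- regulator
  attr(out, "target") <- target
  class(out) <- c("regulation_trend", class(out))
  out
}

#' Trend summary of a regulation-strength series
#'
#' @param x a [regulation_strength_series()] result.
#' @return Tibble of trend labels (overall row `branch = "all"` plus one per
#'   segment with >= 4 windows).
#' @export
regulation_trends <- function(x) {
  stopifnot(inherits(x, "regulation_trend"))
  attr(x, "trends")
}
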