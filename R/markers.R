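#' Rank genes by standardized dispersion (HVG ranking)
#'
#' Counts are log-normalized (per-cell total scaling to the median total,
#' then log1p); per-gene dispersion (variance / mean) is z-scored within 20
#' equal-frequency bins of mean expression, and genes are ranked by the
#' z-score, descending.  The top `threshold` genes pass the
#' highly-variable-gene criterion; ties break by gene id so the ranking is
#' deterministic.
#'
#' @param counts cells x genes count matrix (>= 2 cells).
#' @param threshold HVG rank cutoff (default 30).
#' @param n_bins mean-expression bins for the dispersion z-score (default 20;
#'   automatically reduced so each bin keeps at least ~10 genes).
#' @return Tibble: `gene`, `mean`, `dispersion`, `dispersion_z`, `hvg_rank`,
#'   `hvg_pass`.
#' @export
rank_hvg <- function(counts, threshold = 30, n_bins = 20) {
  counts <- check_count_matrix(counts)
  if (nrow(counts) < 2L) stop_invalid("need >= 2 cells.")
  threshold <- check_count_scalar(threshold, "threshold")
  totals <- rowSums(counts)
  sf <- totals / median(totals[totals > 0])
  sf[sf == 0] <- 1
  X <- log1p(counts / sf)
  mu <- colMeans(X)
  v <- apply(X, 2, var)
  disp <- ifelse(mu > 0, v / mu, 0)
  # keep >= ~10 genes per bin so within-bin z-scores stay meaningful
  n_bins_eff <- max(1L, min(n_bins, floor(ncol(counts) / 10)))
  bin <- if (n_bins_eff == 1L) rep(1L, length(mu)) else {
    as.integer(cut(rank(mu, ties.method = "first"),
                   breaks = n_bins_eff, labels = FALSE))
  }
  z <- numeric(length(disp))
  for (b in unique(bin)) {
    i <- bin == b
    s <- sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  ord <- order(-z, colnames(counts))
  rank_out <- integer(length(z)); rank_out[ord] <- seq_along(ord)
  if (ncol(counts) <= threshold) {
    rlang::warn("fewer genes than the HVG threshold; all genes pass.")
  }
  tibble::tibble(gene = colnames(counts), mean = mu, dispersion = disp,
                 dispersion_z = z, hvg_rank = rank_out,
                 hvg_pass = rank_out <= threshold)
}

#' Two-sample distribution-shift test between pre- and post-branch counts
#'
#' Two-sample Kolmogorov-Smirnov test on the count distributions — sensitive
#' to any change of distribution shape (not just location), matching the
#' modality-change framing of a branch event.
#'
#' @param pre,post nonnegative integer count vectors.
#' @param min_n minimum group size (default 10).
#' @return One-row tibble: `statistic`, `p_value`.
#' @examples
#' branch_shift_test(rpois(100, 5), rpois(100, 50))
#' @export
branch_shift_test <- function(pre, post, min_n = 10) {
  if (length(pre) < min_n || length(post) < min_n) {
    stop_invalid(sprintf("both groups need >= %d observations.", min_n),
                 class = "branchdyn_undersized_group")
  }
  kt <- suppressWarnings(ks.test(pre, post))
  tibble::tibble(statistic = unname(kt$statistic), p_value = kt$p.value)
}

#' Screen marker genes: HVG ranking x pre/post-branch distribution shift
#'
#' A marker gene must (1) rank inside the top `hvg_threshold` highly variable
#' genes and (2) show a significant pre- vs post-branch distribution change —
#' a Kolmogorov-Smirnov test of the pooled pre-branch cells against each
#' post-branch segment, Benjamini-Hochberg corrected across all gene x branch
#' tests, significant on at least one branch at FDR `fdr`.  The marker set is
#' the intersection of the two criteria.
#'
#' @param counts cells x genes count matrix.
#' @param annotation trajectory annotation with a `pre` segment and at least
#'   one of `branch1` / `branch2`.
#' @param hvg_threshold HVG rank cutoff (default 30).
#' @param fdr Benjamini-Hochberg false-discovery level (default 0.05).
#' @param min_cells minimum cells per compared group.
#' @param modality also call modality (1-3) per gene on the pre/branch1/
#'   branch2 pooled distributions (default FALSE; a full mixture fit per gene
#'   x segment is expensive).
#' @param seed seed for the modality fits.
#' @return Tibble (`MarkerReport`): per gene `hvg_rank`, `hvg_pass`,
#'   per-branch `ks_stat_*`, `p_*`, `q_*`, best-branch `ks_stat`, `p`, `q`,
#'   `shift_pass`, modality columns (NA unless `modality = TRUE`), and
#'   `is_marker`.
#' @export
select_markers <- function(counts, annotation, hvg_threshold = 30, fdr = 0.05,
                           min_cells = 10, modality = FALSE, seed = 0) {
  counts <- check_count_matrix(counts)
  check_annotation(annotation)
  if (!"pre" %in% annotation$branch) {
    stop_invalid("annotation has no pre-branch segment.",
                 class = "branchdyn_annotation_error")
  }
  branches <- intersect(c("branch1", "branch2"), unique(annotation$branch))
  if (length(branches) == 0L) {
    stop_invalid("annotation has no post-branch segment.",
                 class = "branchdyn_annotation_error")
  }
  hvg <- rank_hvg(counts, threshold = hvg_threshold)
  pre_cells <- annotation$cell_id[annotation$branch == "pre"]
  tests <- tidyr::crossing(gene = colnames(counts), branch = branches)
  res <- purrr::map_dfr(seq_len(nrow(tests)), function(i) {
    g <- tests$gene[i]; b <- tests$branch[i]
    post_cells <- annotation$cell_id[annotation$branch == b]
    st <- branch_shift_test(counts[pre_cells, g], counts[post_cells, g],
                            min_n = min_cells)
    tibble::tibble(gene = g, branch = b, ks_stat = st$statistic,
                   p = st$p_value)
  })
  res$q <- p.adjust(res$p, method = "BH")
  wide <- res |>
    tidyr::pivot_wider(names_from = "branch",
                       values_from = c("ks_stat", "p", "q"))
  best <- res |>
    dplyr::group_by(.data$gene) |>
    dplyr::slice_min(.data$q, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("gene", "ks_stat", "p", "q")
  shift <- res |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(shift_pass = any(.data$q < fdr))
  report <- hvg |>
    dplyr::left_join(best, by = "gene") |>
    dplyr::left_join(wide, by = "gene") |>
    dplyr::left_join(shift, by = "gene") |>
    dplyr::mutate(is_marker = .data$hvg_pass & .data$shift_pass)
  report$modality_pre <- NA_integer_
  report$modality_branch1 <- NA_integer_
  report$modality_branch2 <- NA_integer_
  if (isTRUE(modality)) {
    for (seg in c("pre", branches)) {
      col <- paste0("modality_", seg)
      report[[col]] <- vapply(report$gene, function(g) {
        x <- segment_counts(counts, annotation, g, seg)
        tryCatch(select_modality(x, seed = seed)$m,
                 error = function(e) NA_integer_)
      }, integer(1))
    }
  }
  dplyr::arrange(report, .data$hvg_rank)
}
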