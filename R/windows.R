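#' Partition cells into pseudo-time windows per branch segment
#'
#' Every "pseudo-time point" of the analysis is really a pseudo-time window: a
#' contiguous block of cells along one branch segment.  Cells are rank-ordered
#' by pseudotime within each segment (branch label) and split into
#' `windows_per_segment` equal-frequency windows; with
#' `overlap_fraction = f > 0` consecutive windows share a fraction `f` of
#' their members (trend series use overlapping windows for smoothness,
#' distribution fits use disjoint ones).
#'
#' @param annotation trajectory annotation tibble (`cell_id`, `pseudotime`,
#'   `stage`, `branch`).
#' @param windows_per_segment windows per branch segment (default 8, sized so
#'   a 400-cell dataset gives ~30-50 cells per window).
#' @param min_cells minimum cells per window / per segment (default 10).
#' @param overlap_fraction fraction of members shared by consecutive windows,
#'   in \[0, 1).
#' @param segments branch labels to window (default all present).
#' @return Tibble with one row per window: `window_index`, `branch`, `t_lo`,
#'   `t_hi`, `n_cells`, `cells` (list column of cell ids), ordered pre,
#'   branch_point, branch1, branch2 and by pseudotime within segment.
#' @examples
#' sim <- simulate_branching_dataset(simulation_config(
#'   default_stage_schedule(25), gene_program(default_stage_schedule(25), "g1"),
#'   seed = 1))
#' assign_windows(sim$annotation, windows_per_segment = 2)
#' @export
assign_windows <- function(annotation, windows_per_segment = 8, min_cells = 10,
                           overlap_fraction = 0, segments = NULL) {
  check_annotation(annotation)
  windows_per_segment <- check_count_scalar(windows_per_segment, "windows_per_segment")
  min_cells <- check_count_scalar(min_cells, "min_cells")
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop_invalid("`overlap_fraction` must lie in [0, 1).")
  }
  segments <- segments %||% intersect(BRANCH_LEVELS, unique(annotation$branch))
  out <- list()
  for (b in segments) {
    ann_b <- branch_cells(annotation, b)
    n <- nrow(ann_b)
    if (n < min_cells) {
      stop_invalid(sprintf("segment '%s' has %d cells, fewer than min_cells = %d.",
                           b, n, min_cells),
                   class = "branchdyn_windowing_error")
    }
    k <- windows_per_segment
    idx <- window_rank_slices(n, k, overlap_fraction)
    occ <- vapply(idx, length, integer(1))
    if (any(occ < min_cells)) {
      stop_invalid(sprintf(
        "segment '%s': %d windows over %d cells leaves windows below min_cells = %d.",
        b, k, n, min_cells),
        class = "branchdyn_windowing_error")
    }
    out[[b]] <- tibble::tibble(
      branch = b,
      t_lo = vapply(idx, function(i) min(ann_b$pseudotime[i]), numeric(1)),
      t_hi = vapply(idx, function(i) max(ann_b$pseudotime[i]), numeric(1)),
      n_cells = occ,
      cells = lapply(idx, function(i) ann_b$cell_id[i]))
  }
  win <- dplyr::bind_rows(out)
  win$window_index <- seq_len(nrow(win))
  dplyr::relocate(win, "window_index")
}

# rank slices for k windows over n ordered cells with member-overlap f
window_rank_slices <- function(n, k, f) {
  if (k == 1L) return(list(seq_len(n)))
  if (f == 0) {
    b <- round(seq(0, n, length.out = k + 1))
    return(lapply(seq_len(k), function(i) seq.int(b[i] + 1L, b[i + 1L])))
  }
  len <- n / ((k - 1) * (1 - f) + 1)
  step <- (n - len) / (k - 1)
  lapply(seq_len(k), function(i) {
    lo <- round(1 + (i - 1) * step)
    hi <- if (i == k) n else round((i - 1) * step + len)
    seq.int(lo, max(lo, hi))
  })
}

#' Empirical distribution of an integer count sample
#'
#' Relative frequencies over the distinct observed values — the windowed data
#' distribution that the mechanistic Gamma-mixture models are fitted against.
#'
#' @param counts nonnegative integer vector (length >= 1).
#' @return Tibble with columns `value` (sorted distinct counts) and `prob`
#'   (relative frequencies, summing to 1), class `empirical_distribution`,
#'   with attribute `n` (sample size).
#' @examples
#' empirical_distribution(c(3, 3, 5))
#' @export
empirical_distribution <- function(counts) {
  counts <- check_counts_vector(counts)
  tab <- table(counts)
  out <- tibble::tibble(value = as.integer(names(tab)),
                        prob = as.numeric(tab) / length(counts))
  attr(out, "n") <- length(counts)
  class(out) <- c("empirical_distribution", class(out))
  out
}

as_empirical <- function(x) {
  if (inherits(x, "empirical_distribution")) return(x)
  empirical_distribution(x)
}

#' Pool the cells of a branch segment and return their counts for one gene
#'
#' The "before branch" / "at branching point" / "after branch" distributions
#' are computed by pooling all cells of the corresponding stage clusters.
#'
#' @param counts cells x genes count matrix.
#' @param annotation trajectory annotation.
#' @param gene gene id.
#' @param segment branch label.
#' @return Integer vector of counts.
#' @export
segment_counts <- function(counts, annotation, gene, segment) {
  counts <- check_count_matrix(counts)
  check_annotation(annotation)
  if (!gene %in% colnames(counts)) {
    stop_invalid(sprintf("gene '%s' not in count matrix.", gene))
  }
  cells <- annotation$cell_id[annotation$branch == segment]
  if (length(cells) == 0L) {
    stop_invalid(sprintf("no cells with branch label '%s'.", segment),
                 class = "branchdyn_annotation_error")
  }
  as.integer(counts[cells, gene])
}
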