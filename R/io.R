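#' Read a cells x genes count matrix
#'
#' Supports Matrix Market triplets (`matrix.mtx` plus `genes.tsv` /
#' `cells.tsv` one-id-per-line label files) and dense CSV/TSV (header row of
#' gene names, first column of cell ids).  MTX orientation is normalized to
#' cells x genes using the label files; non-integer entries are rounded with
#' a warning; negative entries are a format error.
#'
#' @param path path to the `.mtx`, `.csv` or `.tsv` file.
#' @param format `"auto"` (by extension) or explicit.
#' @param genes_file,cells_file label files for MTX input; default
#'   `genes.tsv` / `cells.tsv` next to the matrix.
#' @return Integer matrix, cells x genes, with cell/gene ids as dimnames.
#' @export
read_counts <- function(path, format = c("auto", "mtx", "csv", "tsv"),
                        genes_file = NULL, cells_file = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", csv = "csv", tsv = "tsv",
                     stop_invalid(sprintf("cannot infer format of '%s'.", path),
                                  class = "branchdyn_format_error"))
  }
  if (!file.exists(path)) {
    stop_invalid(sprintf("file not found: %s", path),
                 class = "branchdyn_format_error")
  }
  if (format == "mtx") {
    dir <- dirname(path)
    genes_file <- genes_file %||% file.path(dir, "genes.tsv")
    cells_file <- cells_file %||% file.path(dir, "cells.tsv")
    for (f in c(genes_file, cells_file)) {
      if (!file.exists(f)) {
        stop_invalid(sprintf("label file not found: %s", f),
                     class = "branchdyn_format_error")
      }
    }
    m <- as.matrix(Matrix::readMM(path))
    genes <- readr::read_tsv(genes_file, col_names = FALSE,
                             show_col_types = FALSE)[[1]]
    cells <- readr::read_tsv(cells_file, col_names = FALSE,
                             show_col_types = FALSE)[[1]]
    if (nrow(m) == length(cells) && ncol(m) == length(genes)) {
      # cells x genes already
    } else if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
      m <- t(m)
    } else {
      stop_invalid(sprintf(
        "matrix is %d x %d but labels give %d cells / %d genes (%s, %s).",
        nrow(m), ncol(m), length(cells), length(genes),
        basename(cells_file), basename(genes_file)),
        class = "branchdyn_format_error")
    }
    dimnames(m) <- list(cells, genes)
  } else {
    reader <- if (format == "csv") readr::read_csv else readr::read_tsv
    df <- reader(path, show_col_types = FALSE)
    cells <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- cells
  }
  if (any(m < 0)) {
    stop_invalid(sprintf("negative entries in %s.", basename(path)),
                 class = "branchdyn_format_error")
  }
  if (any(m != round(m))) {
    rlang::warn("non-integer counts rounded to integers.")
    m <- round(m)
  }
  storage.mode(m) <- "integer"
  check_count_matrix(m)
}

#' Write a count matrix as Matrix Market triplet or dense CSV
#'
#' @param counts cells x genes integer matrix with dimnames.
#' @param path output `.mtx` or `.csv` path; MTX gains sibling `genes.tsv`
#'   and `cells.tsv` label files.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  counts <- check_count_matrix(counts)
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    dir <- dirname(path)
    writeLines(colnames(counts), file.path(dir, "genes.tsv"))
    writeLines(rownames(counts), file.path(dir, "cells.tsv"))
  } else {
    df <- tibble::as_tibble(counts, rownames = "cell_id")
    readr::write_csv(df, path)
  }
  invisible(path)
}

#' Read a trajectory annotation CSV
#'
#' Expects the header `cell_id,pseudotime,stage,branch`; pseudotime must be
#' finite, branch labels must come from `pre`, `branch_point`, `branch1`,
#' `branch2` (the topology is fixed at one bifurcation), and — when a count
#' matrix is supplied — every annotated cell must exist in it.
#'
#' @param path CSV path.
#' @param counts optional count matrix to validate cell ids against.
#' @return Tibble annotation.
#' @export
read_annotation <- function(path, counts = NULL) {
  if (!file.exists(path)) {
    stop_invalid(sprintf("file not found: %s", path),
                 class = "branchdyn_format_error")
  }
  ann <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           cell_id = readr::col_character(),
                           pseudotime = readr::col_double(),
                           stage = readr::col_integer(),
                           branch = readr::col_character()))
  check_annotation(ann)
  if (!is.null(counts)) {
    counts <- check_count_matrix(counts)
    missing <- setdiff(ann$cell_id, rownames(counts))
    if (length(missing) > 0L) {
      stop_invalid(paste0("annotated cells absent from the count matrix: ",
                          paste(head(missing, 10), collapse = ", ")),
                   class = "branchdyn_annotation_error")
    }
  }
  ann
}

#' Write a trajectory annotation CSV
#' @param annotation annotation tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  check_annotation(annotation)
  readr::write_csv(annotation, path)
  invisible(path)
}

#' Write a deterministic report bundle with a checksum manifest
#'
#' Serializes whichever results are present — mixture-fit reports (JSON),
#' burst table (CSV), marker report (TSV), regulation-trend series (CSV),
#' Wasserstein matrix (CSV) — plus a run-config snapshot and a log, then a
#' `manifest.csv` listing every file with its md5 checksum.  Re-running the
#' same seed and config reproduces identical checksums.
#'
#' @param results named list; recognized elements: `fits` (named list of
#'   `gamma_mixture_fit`), `bursts` (`burst_trajectory` or tibble), `markers`
#'   (tibble), `trends` (`regulation_trend` or tibble), `wasserstein`
#'   (`wasserstein_matrix`), `config` (any JSON-serializable list).
#' @param out_dir output directory (created if needed).
#' @param force overwrite existing files (default FALSE: collision is an
#'   error).
#' @return Tibble manifest (`file`, `md5`), invisibly written to
#'   `manifest.csv`.
#' @export
write_reports <- function(results, out_dir, force = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- character(0)
  emit <- function(fname, writer) {
    fp <- file.path(out_dir, fname)
    if (file.exists(fp) && !force) {
      stop_invalid(sprintf("'%s' exists; use force = TRUE to overwrite.", fp),
                   class = "branchdyn_collision_error")
    }
    writer(fp)
    files <<- c(files, fp)
  }
  if (!is.null(results$fits)) {
    emit("fits.json", function(fp) {
      payload <- lapply(results$fits, function(f) {
        st <- mixture_stats(f)
        list(m = f$m, kl = f$kl, bic = f$bic, n = f$n,
             components = as.data.frame(f$components),
             stats = list(peaks = st$peaks,
                          means = st$components$mean,
                          variances = st$components$variance,
                          skewness = st$components$skewness,
                          ex_kurtosis = st$components$ex_kurtosis))
      })
      jsonlite::write_json(payload, fp, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    })
  }
  if (!is.null(results$bursts)) {
    emit("bursts.csv", function(fp)
      readr::write_csv(tibble::as_tibble(results$bursts), fp))
  }
  if (!is.null(results$markers)) {
    emit("markers.tsv", function(fp)
      readr::write_tsv(tibble::as_tibble(results$markers), fp))
  }
  if (!is.null(results$trends)) {
    emit("trends.csv", function(fp)
      readr::write_csv(tibble::as_tibble(results$trends), fp))
  }
  if (!is.null(results$wasserstein)) {
    emit("wasserstein.csv", function(fp) {
      df <- tibble::as_tibble(unclass(results$wasserstein), rownames = "item")
      readr::write_csv(df, fp)
    })
  }
  emit("config.json", function(fp) {
    jsonlite::write_json(results$config %||% list(), fp, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  })
  emit("run.log", function(fp) {
    writeLines(c(sprintf("outputs: %d", length(files)),
                 sprintf("written: %s", basename(files))), fp)
  })
  manifest <- tibble::tibble(file = basename(files),
                             md5 = unname(tools::md5sum(files)))
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  invisible(manifest)
}

#' Run the full branch-resolved analysis pipeline
#'
#' Chains windowing, modality selection per segment, burst trajectories,
#' marker screening, regulation-strength series and the Wasserstein matrix on
#' one dataset; every stochastic step is seeded from `seed`, so identical
#' inputs give identical results.
#'
#' @param counts cells x genes count matrix.
#' @param annotation trajectory annotation.
#' @param genes genes for the per-gene analyses (modality, bursts, pairwise);
#'   default: the two top-ranked markers (or top HVGs if fewer than two
#'   markers pass).
#' @param seed integer master seed.
#' @param windows_per_segment,min_cells window scheme (overlap 0 for fits,
#'   0.5 for trend series).
#' @param n_trees trees per window in the regulation forests.
#' @param hvg_threshold,fdr marker-screening parameters.
#' @return Named list of class `branchdyn_results`: `markers`, `modality`
#'   (tibble gene x segment), `fits`, `bursts` (list of burst trajectories),
#'   `regulation` (list of series), `wasserstein`, `windows`, `config`.
#' @export
run_pipeline <- function(counts, annotation, genes = NULL, seed = 0,
                         windows_per_segment = 4, min_cells = 10,
                         n_trees = 50, hvg_threshold = 30, fdr = 0.05) {
  counts <- check_count_matrix(counts)
  check_annotation(annotation)
  markers <- select_markers(counts, annotation, hvg_threshold = hvg_threshold,
                            fdr = fdr, min_cells = min_cells)
  if (is.null(genes)) {
    ranked <- markers[order(markers$hvg_rank), ]
    genes <- head(ranked$gene[ranked$is_marker], 2)
    if (length(genes) < 2) genes <- head(ranked$gene, 2)
  }
  trend_windows <- assign_windows(annotation, windows_per_segment, min_cells,
                                  overlap_fraction = 0.5)
  segments <- intersect(BRANCH_LEVELS, unique(annotation$branch))
  modality <- tidyr::crossing(gene = genes, segment = segments)
  fits <- list()
  calls <- integer(nrow(modality))
  for (i in seq_len(nrow(modality))) {
    x <- segment_counts(counts, annotation, modality$gene[i], modality$segment[i])
    call <- select_modality(x, seed = seed)
    calls[i] <- call$m
    fits[[paste0(modality$gene[i], "@", modality$segment[i])]] <-
      call$fits[[call$m]]
  }
  modality$m <- calls
  bursts <- setNames(lapply(genes, function(g)
    burst_trajectory(counts, annotation, g, windows = trend_windows,
                     min_cells = min_cells, seed = seed)), genes)
  regulation <- list()
  if (length(genes) >= 2) {
    pair <- genes[1:2]
    regulation <- list(
      forward = regulation_strength_series(counts, annotation, pair[1], pair[2],
                                           windows = trend_windows,
                                           n_trees = n_trees, seed = seed),
      reverse = regulation_strength_series(counts, annotation, pair[2], pair[1],
                                           windows = trend_windows,
                                           n_trees = n_trees, seed = seed))
  }
  wass <- wasserstein_matrix(counts, annotation, genes, group_by = "stage",
                             min_cells = min_cells)
  structure(list(markers = markers, modality = modality, fits = fits,
                 bursts = bursts, regulation = regulation, wasserstein = wass,
                 windows = trend_windows,
                 config = list(seed = seed, genes = genes,
                               windows_per_segment = windows_per_segment,
                               min_cells = min_cells, n_trees = n_trees,
                               hvg_threshold = hvg_threshold, fdr = fdr)),
            class = "branchdyn_results")
}

#' @export
print.branchdyn_results <- function(x, ...) {
  cat(sprintf("<branchdyn_results> genes: %s | markers: %d | windows: %d\n",
              paste(x$config$genes, collapse = ", "),
              sum(x$markers$is_marker), nrow(x$windows)))
  invisible(x)
}
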