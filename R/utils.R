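# internal validation helpers

stop_invalid <- function(msg, class = "branchdyn_invalid_parameter") {
  rlang::abort(msg, class = class)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x)) || any(x <= 0)) {
    stop_invalid(sprintf("`%s` must be strictly positive and finite.", name))
  }
  invisible(x)
}

check_count_scalar <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != as.integer(x)) {
    stop_invalid(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

check_counts_vector <- function(x, name = "counts") {
  if (length(x) == 0L) stop_invalid(sprintf("`%s` must be non-empty.", name))
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) ||
      any(x != round(x))) {
    stop_invalid(sprintf("`%s` must contain nonnegative integers.", name))
  }
  invisible(as.integer(round(x)))
}

# branch labels of the fixed binary topology
BRANCH_LEVELS <- c("pre", "branch_point", "branch1", "branch2")

check_annotation <- function(annotation) {
  req <- c("cell_id", "pseudotime", "stage", "branch")
  missing <- setdiff(req, names(annotation))
  if (length(missing) > 0L) {
    stop_invalid(paste0("annotation is missing column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "branchdyn_annotation_error")
  }
  if (anyDuplicated(annotation$cell_id)) {
    stop_invalid("annotation cell ids must be unique.",
                 class = "branchdyn_annotation_error")
  }
  if (!is.numeric(annotation$pseudotime) || any(!is.finite(annotation$pseudotime))) {
    stop_invalid("annotation pseudotime must be finite numeric.",
                 class = "branchdyn_annotation_error")
  }
  bad <- setdiff(unique(as.character(annotation$branch)), BRANCH_LEVELS)
  if (length(bad) > 0L) {
    stop_invalid(paste0("unknown branch label(s): ", paste(bad, collapse = ", "),
                        "; allowed: ", paste(BRANCH_LEVELS, collapse = ", ")),
                 class = "branchdyn_annotation_error")
  }
  invisible(annotation)
}

check_count_matrix <- function(counts) {
  if (inherits(counts, "Matrix")) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop_invalid("`counts` must be a numeric cells x genes matrix.")
  }
  if (any(counts < 0)) stop_invalid("`counts` contains negative entries.",
                                    class = "branchdyn_format_error")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_invalid("`counts` must carry cell ids (rownames) and gene ids (colnames).")
  }
  counts
}

# cells of `annotation` restricted to one branch label, ordered by pseudotime
branch_cells <- function(annotation, branch) {
  ann <- annotation[annotation$branch == branch, , drop = FALSE]
  ann[order(ann$pseudotime), , drop = FALSE]
}
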