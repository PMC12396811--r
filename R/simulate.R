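#' Two-state (telegraph) transcription parameters
#'
#' The telegraph model switches a promoter OFF -> ON at rate `k_on`, ON -> OFF
#' at rate `k_off`, transcribes at rate `k_syn` while ON, and degrades mRNA at
#' rate `delta`.  Rates are expressed per mRNA-degradation time, so
#' `delta = 1` by convention.  At stationarity the count law is Beta-Poisson:
#' `X ~ Poisson(k_syn/delta * p)` with `p ~ Beta(k_on, k_off)`.
#'
#' @param k_on OFF -> ON switching rate (> 0).
#' @param k_off ON -> OFF switching rate (> 0).
#' @param k_syn transcription rate while ON (> 0).
#' @param delta mRNA degradation rate; fixed to 1 unless overridden.
#' @return An object of class `two_state_params`.
#' @examples
#' two_state_params(k_on = 0.5, k_off = 10, k_syn = 100)
#' @export
two_state_params <- function(k_on, k_off, k_syn, delta = 1) {
  check_positive(k_on, "k_on")
  check_positive(k_off, "k_off")
  check_positive(k_syn, "k_syn")
  check_positive(delta, "delta")
  structure(list(k_on = k_on, k_off = k_off, k_syn = k_syn, delta = delta),
            class = "two_state_params")
}

#' @export
print.two_state_params <- function(x, ...) {
  cat(sprintf(
    "<two_state_params> k_on=%g k_off=%g k_syn=%g delta=%g (BS=%g, BF=%g)\n",
    x$k_on, x$k_off, x$k_syn, x$delta, x$k_syn / x$k_off, x$k_on))
  invisible(x)
}

#' Sample stationary telegraph-model mRNA counts
#'
#' Draws from the stationary distribution of the two-state model by the exact
#' Beta-Poisson compound representation: a per-cell active fraction
#' `p ~ Beta(k_on, k_off)` followed by `Poisson(s * k_syn/delta * p)`, where
#' `s` is an optional per-cell size factor.
#'
#' @param params a [two_state_params()] object.
#' @param n_cells number of cells to draw.
#' @param seed integer seed; the draw is a pure function of
#'   `(params, n_cells, seed, sizes)`.
#' @param sizes optional per-cell size factors (length `n_cells`, > 0);
#'   default all 1.
#' @return Integer vector of length `n_cells`.
#' @examples
#' x <- simulate_two_state_counts(two_state_params(1, 1, 50), 1000, seed = 1)
#' mean(x) # ~ 50 * 1 / (1 + 1) = 25
#' @export
simulate_two_state_counts <- function(params, n_cells, seed, sizes = NULL) {
  stopifnot(inherits(params, "two_state_params"))
  n_cells <- check_count_scalar(n_cells, "n_cells")
  if (is.null(sizes)) sizes <- rep(1, n_cells)
  check_positive(sizes, "sizes")
  if (length(sizes) != n_cells) stop_invalid("`sizes` must have length `n_cells`.")
  withr::with_seed(seed, {
    p <- rbeta(n_cells, params$k_on, params$k_off)
    rpois(n_cells, sizes * params$k_syn / params$delta * p)
  })
}

#' Specify Gamma-mixture components
#'
#' A mixture of (optionally location-shifted) Gamma densities in the
#' shape/rate convention:
#' `f(x) = sum_i w_i * dgamma(x - loc_i, shape_i, rate_i)`.
#'
#' @param weight component weights; nonnegative, summing to 1 within 1e-9.
#' @param shape Gamma shape parameters (> 0).
#' @param rate Gamma rate parameters (> 0); the mean of a component is
#'   `loc + shape/rate`.
#' @param loc location shifts (default 0).
#' @return A tibble with columns `weight`, `shape`, `rate`, `loc`.
#' @examples
#' gamma_components(c(0.5, 0.5), shape = c(100, 900), rate = c(10, 30))
#' @export
gamma_components <- function(weight, shape, rate, loc = 0) {
  comp <- tibble::tibble(weight = weight, shape = shape, rate = rate, loc = loc)
  validate_components(comp)
  comp
}

validate_components <- function(comp) {
  if (!all(c("weight", "shape", "rate") %in% names(comp))) {
    stop_invalid("mixture components need columns weight, shape, rate.")
  }
  if (is.null(comp$loc)) comp$loc <- 0
  if (any(comp$weight < 0) || abs(sum(comp$weight) - 1) > 1e-9) {
    stop_invalid("component weights must be nonnegative and sum to 1 (within 1e-9).")
  }
  check_positive(comp$shape, "shape")
  check_positive(comp$rate, "rate")
  invisible(comp)
}

#' Sample from a Gamma mixture
#'
#' @param components a components table from [gamma_components()] (or any data
#'   frame with columns `weight`, `shape`, `rate` and optionally `loc`).
#' @param n number of draws.
#' @param seed integer seed.
#' @return Numeric vector of length `n`; every draw exceeds its component's
#'   `loc`.
#' @examples
#' sample_gamma_mixture(gamma_components(1, 2.898, 1.5106, loc = 15.481), 5, seed = 1)
#' @export
sample_gamma_mixture <- function(components, n, seed) {
  comp <- validate_components(tibble::as_tibble(components))
  if (is.null(comp$loc)) comp$loc <- 0
  n <- check_count_scalar(n, "n")
  withr::with_seed(seed, {
    idx <- sample.int(nrow(comp), n, replace = TRUE, prob = comp$weight)
    comp$loc[idx] + rgamma(n, shape = comp$shape[idx], rate = comp$rate[idx])
  })
}

#' Stage schedule for the branching topology
#'
#' Encodes the fixed binary topology `pre -> branch_point -> {branch1,
#' branch2}` as an ordered stage table.  Each branch label may span several
#' consecutive stages (e.g. four pre-branch stage clusters).
#'
#' @param stage integer stage ids (unique).
#' @param branch branch label per stage, each one of
#'   `"pre"`, `"branch_point"`, `"branch1"`, `"branch2"`.
#' @param n_cells cells per stage (>= 1).
#' @return A tibble with class `stage_schedule`.
#' @examples
#' default_stage_schedule()
#' @export
stage_schedule <- function(stage, branch, n_cells) {
  sched <- tibble::tibble(stage = as.integer(stage),
                          branch = as.character(branch),
                          n_cells = as.integer(n_cells))
  if (anyDuplicated(sched$stage)) stop_invalid("stage ids must be unique.",
                                               class = "branchdyn_config_error")
  bad <- setdiff(sched$branch, BRANCH_LEVELS)
  if (length(bad) > 0L) {
    stop_invalid(paste0("unknown branch label(s): ", paste(bad, collapse = ", ")),
                 class = "branchdyn_config_error")
  }
  if (any(sched$n_cells < 1L)) stop_invalid("each stage needs >= 1 cell.",
                                            class = "branchdyn_config_error")
  need <- c("pre", "branch_point", "branch1", "branch2")
  if (!all(need %in% sched$branch)) {
    stop_invalid("schedule must contain pre, branch_point, branch1 and branch2 stages.",
                 class = "branchdyn_config_error")
  }
  class(sched) <- c("stage_schedule", class(sched))
  sched
}

#' Default 7-stage schedule
#'
#' Four pre-branch stage clusters, one branch-point cluster, and one cluster
#' on each post-branch segment — the stage structure of a small mouse-embryo
#' style dataset.
#'
#' @param cells_per_stage cells in every stage (default 60, for 420 cells).
#' @param pre_stages,branch_stages number of pre-branch stages and of stages
#'   per post-branch segment.
#' @return A `stage_schedule` tibble.
#' @export
default_stage_schedule <- function(cells_per_stage = 60, pre_stages = 4,
                                   branch_stages = 1) {
  branch <- c(rep("pre", pre_stages), "branch_point",
              rep("branch1", branch_stages), rep("branch2", branch_stages))
  stage_schedule(stage = seq_along(branch), branch = branch,
                 n_cells = rep(cells_per_stage, length(branch)))
}

#' Per-gene, per-stage expression program
#'
#' Builds the long table of expression mechanisms consumed by
#' [simulate_branching_dataset()]: one row per gene x stage, each row either a
#' two-state parameter set (`kind = "two_state"`) or a Gamma-mixture
#' specification (`kind = "mixture"`, see [set_stage_mixture()]).  Scalar
#' kinetic arguments are recycled over stages; vectors of length
#' `nrow(schedule)` give stage-dependent schedules (e.g. a burst size ramp).
#'
#' @param schedule a [stage_schedule()].
#' @param genes character vector of gene ids.
#' @param k_on,k_off,k_syn kinetic rates; scalar or per-stage vectors.
#' @return Tibble with columns `gene`, `stage`, `kind`, `k_on`, `k_off`,
#'   `k_syn`, `mixture` (list column, `NULL` unless `kind == "mixture"`).
#' @examples
#' sched <- default_stage_schedule(20)
#' gene_program(sched, c("g1", "g2"), k_on = 1, k_off = 3, k_syn = 60)
#' @export
gene_program <- function(schedule, genes, k_on = 1, k_off = 3, k_syn = 60) {
  stopifnot(inherits(schedule, "stage_schedule"))
  ns <- nrow(schedule)
  rec <- function(x, name) {
    if (length(x) == 1L) x <- rep(x, ns)
    if (length(x) != ns) {
      stop_invalid(sprintf("`%s` must be scalar or one value per stage.", name),
                   class = "branchdyn_config_error")
    }
    check_positive(x, name)
    x
  }
  k_on <- rec(k_on, "k_on"); k_off <- rec(k_off, "k_off")
  k_syn <- rec(k_syn, "k_syn")
  tidyr::crossing(gene = genes, stage = schedule$stage) |>
    dplyr::arrange(match(.data$gene, genes), .data$stage) |>
    dplyr::mutate(kind = "two_state",
                  k_on = k_on[match(.data$stage, schedule$stage)],
                  k_off = k_off[match(.data$stage, schedule$stage)],
                  k_syn = k_syn[match(.data$stage, schedule$stage)],
                  mixture = list(NULL))
}

#' Override stages of a gene program with a Gamma-mixture law
#'
#' A single two-state gene cannot produce a trimodal count law, so trimodal
#' stages are specified directly as Gamma mixtures; counts are emitted as the
#' size-scaled mixture draw rounded to the nearest integer.
#'
#' @param program a [gene_program()] table.
#' @param gene gene id to modify.
#' @param stages stage ids to override.
#' @param components a [gamma_components()] table.
#' @return The modified program.
#' @export
set_stage_mixture <- function(program, gene, stages, components) {
  comp <- validate_components(tibble::as_tibble(components))
  i <- program$gene == gene & program$stage %in% stages
  if (!any(i)) stop_invalid("no matching gene/stage rows in program.",
                            class = "branchdyn_config_error")
  program$kind[i] <- "mixture"
  program$mixture[i] <- list(comp)
  program
}

#' Simulation configuration
#'
#' @param schedule a [stage_schedule()].
#' @param program a [gene_program()] covering every schedule stage for every
#'   gene.
#' @param size_sdlog sdlog of the log-normal cell-size distribution (sizes are
#'   median-normalized to 1); default 0.2, a mild depth variation typical of
#'   plate-based data.
#' @param seed integer seed fixing all randomness; identical configs give
#'   identical datasets.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(schedule, program, size_sdlog = 0.2, seed = 0) {
  stopifnot(inherits(schedule, "stage_schedule"))
  missing <- dplyr::anti_join(
    tidyr::crossing(gene = unique(program$gene), stage = schedule$stage),
    program, by = c("gene", "stage"))
  if (nrow(missing) > 0L) {
    stop_invalid("program does not cover every gene x stage combination.",
                 class = "branchdyn_config_error")
  }
  if (size_sdlog < 0) stop_invalid("`size_sdlog` must be >= 0.",
                                   class = "branchdyn_config_error")
  structure(list(schedule = schedule, program = program,
                 size_sdlog = size_sdlog, seed = seed),
            class = "simulation_config")
}

# pseudotime interval per stage: trunk stages (pre + branch_point) partition
# [0, t_b]; each branch's stages partition (t_b, 1]
stage_intervals <- function(schedule) {
  trunk <- schedule[schedule$branch %in% c("pre", "branch_point"), , drop = FALSE]
  n_trunk <- nrow(trunk)
  n_b1 <- sum(schedule$branch == "branch1")
  n_b2 <- sum(schedule$branch == "branch2")
  depth <- n_trunk + max(n_b1, n_b2)
  t_b <- n_trunk / depth
  out <- schedule
  out$t_lo <- NA_real_; out$t_hi <- NA_real_
  tr <- which(schedule$branch %in% c("pre", "branch_point"))
  out$t_lo[tr] <- (seq_len(n_trunk) - 1) / n_trunk * t_b
  out$t_hi[tr] <- seq_len(n_trunk) / n_trunk * t_b
  for (b in c("branch1", "branch2")) {
    ib <- which(schedule$branch == b)
    nb <- length(ib)
    out$t_lo[ib] <- t_b + (seq_len(nb) - 1) / nb * (1 - t_b)
    out$t_hi[ib] <- t_b + seq_len(nb) / nb * (1 - t_b)
  }
  out
}

#' Simulate a branching single-cell dataset
#'
#' Generates a cells x genes count matrix and its trajectory annotation from a
#' [simulation_config()].  Each cell draws a log-normal size factor
#' (median-normalized to 1) and a uniform pseudotime inside its stage's
#' sub-interval of \[0, 1\]; each gene draws per-stage counts from its
#' programmed mechanism — stationary Beta-Poisson for two-state stages
#' (`Poisson(s_j * k_syn * p)`, `p ~ Beta(k_on, k_off)`), or a rounded
#' size-scaled Gamma-mixture draw for mixture stages.
#'
#' @param config a [simulation_config()].
#' @return A list with elements `counts` (integer matrix, cells x genes, with
#'   cell/gene ids as dimnames), `annotation` (tibble `cell_id`, `pseudotime`,
#'   `stage`, `branch`) and `sizes` (true per-cell size factors).
#' @examples
#' sched <- default_stage_schedule(cells_per_stage = 20)
#' prog <- gene_program(sched, paste0("g", 1:3))
#' sim <- simulate_branching_dataset(simulation_config(sched, prog, seed = 1))
#' dim(sim$counts)
#' @export
simulate_branching_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  sched <- stage_intervals(config$schedule)
  genes <- unique(config$program$gene)
  n_cells <- sum(sched$n_cells)
  withr::with_seed(config$seed, {
    sizes <- rlnorm(n_cells, 0, config$size_sdlog)
    sizes <- sizes / median(sizes)
    cell_stage <- rep(sched$stage, sched$n_cells)
    pt <- runif(n_cells,
                rep(sched$t_lo, sched$n_cells),
                rep(sched$t_hi, sched$n_cells))
    cell_id <- sprintf("cell_%04d", seq_len(n_cells))
    annotation <- tibble::tibble(
      cell_id = cell_id, pseudotime = pt, stage = cell_stage,
      branch = rep(sched$branch, sched$n_cells))
    counts <- matrix(0L, n_cells, length(genes),
                     dimnames = list(cell_id, genes))
    for (g in genes) {
      prog_g <- config$program[config$program$gene == g, , drop = FALSE]
      for (k in seq_len(nrow(sched))) {
        rows <- which(cell_stage == sched$stage[k])
        pk <- prog_g[prog_g$stage == sched$stage[k], , drop = FALSE]
        s <- sizes[rows]
        if (pk$kind == "two_state") {
          p <- rbeta(length(rows), pk$k_on, pk$k_off)
          counts[rows, g] <- rpois(length(rows), s * pk$k_syn * p)
        } else {
          comp <- pk$mixture[[1L]]
          idx <- sample.int(nrow(comp), length(rows), replace = TRUE,
                            prob = comp$weight)
          x <- comp$loc[idx] + rgamma(length(rows), comp$shape[idx],
                                      rate = comp$rate[idx])
          counts[rows, g] <- as.integer(pmax(0, round(s * x)))
        }
      }
    }
  })
  names(sizes) <- rownames(counts)
  list(counts = counts, annotation = annotation, sizes = sizes)
}
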