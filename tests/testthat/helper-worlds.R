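# shared fixture builders (all programmatic; no stored data)

# small default branching world: 7 stages, n genes, all flat kinetics
small_world <- function(seed, cells_per_stage = 25, n_genes = 4,
                        k_on = 1, k_off = 3, k_syn = 60) {
  sched <- default_stage_schedule(cells_per_stage)
  prog <- gene_program(sched, sprintf("g%02d", seq_len(n_genes)),
                       k_on = k_on, k_off = k_off, k_syn = k_syn)
  simulate_branching_dataset(simulation_config(sched, prog, seed = seed))
}

# marker-screen world: `n_flat` flat genes plus `n_marker` genes whose
# synthesis rate switches on both branches after the branch point
marker_world <- function(seed, n_flat = 45, n_marker = 5,
                         cells_per_stage = 60) {
  sched <- default_stage_schedule(cells_per_stage)
  flat <- gene_program(sched, sprintf("flat%02d", seq_len(n_flat)))
  shifted <- gene_program(sched, sprintf("mk%02d", seq_len(n_marker)),
                          k_syn = c(60, 60, 60, 60, 60, 150, 20))
  sim <- simulate_branching_dataset(
    simulation_config(sched, dplyr::bind_rows(flat, shifted), seed = seed))
  sim$programmed <- sprintf("mk%02d", seq_len(n_marker))
  sim
}

# burst-trend world: burst size ramps down 12 -> 6 before the branch, up on
# branch1, down on branch2 (k_on and k_off held fixed, k_syn carries the ramp)
trend_world_schedule <- function(cells_per_stage = 150) {
  branch <- c(rep("pre", 4), "branch_point", rep("branch1", 4), rep("branch2", 4))
  stage_schedule(seq_along(branch), branch, rep(cells_per_stage, length(branch)))
}

trend_world <- function(seed, cells_per_stage = 150, size_sdlog = 0) {
  sched <- trend_world_schedule(cells_per_stage)
  bs <- c(seq(12, 6, length.out = 4), 6,
          seq(7, 14, length.out = 4), seq(6, 3, length.out = 4))
  # branch2 raises burst frequency (k_on 2) while its burst size decays, so
  # mean counts stay in the identifiable range on both branches; sizes are
  # held at 1 here (size handling has its own tests) - constant sizes let
  # the likelihood aggregate identical counts, an ~6x speedup
  k_on <- c(rep(0.5, 9), rep(2, 4))
  prog <- gene_program(sched, "g1", k_on = k_on, k_off = 10, k_syn = 10 * bs)
  simulate_branching_dataset(
    simulation_config(sched, prog, size_sdlog = size_sdlog, seed = seed))
}

# single-segment annotation with evenly spread pseudotime (windowing tests)
line_annotation <- function(n, branch = "pre") {
  tibble::tibble(cell_id = sprintf("c%03d", seq_len(n)),
                 pseudotime = seq(0, 1, length.out = n),
                 stage = 1L, branch = branch)
}

# independent Beta-Poisson pmf oracle: trapezoid integration on a sqrt grid
# (substitution p = u^2 keeps the k_on < 1 endpoint finite)
bp_pmf_oracle <- function(k, k_on, k_off, k_syn, n_grid = 1e5) {
  u <- seq(0, 1, length.out = n_grid)
  p <- u^2
  vapply(k, function(ki) {
    f <- 2 * u^(2 * k_on - 1) * (1 - p)^(k_off - 1) * dpois(ki, k_syn * p)
    if (!is.finite(f[1])) f[1] <- if (2 * k_on - 1 == 0) 2 * (ki == 0) else 0
    sum((f[-1] + f[-n_grid]) / 2 * diff(u)) / beta(k_on, k_off)
  }, numeric(1))
}

# build an empirical_distribution from explicit (value, prob) pairs
manual_empirical <- function(values, probs, n = 1000L) {
  out <- tibble::tibble(value = as.integer(values), prob = probs)
  attr(out, "n") <- n
  class(out) <- c("empirical_distribution", class(out))
  out
}
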