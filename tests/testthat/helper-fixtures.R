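# Small in-code fixtures shared across test files.

# a tiny multi-cohort study built by hand (deterministic counts)
toy_study <- function(n_species = 6, cohorts = c("A", "B"),
                      n_control = 4, n_case = 4, seed = 1) {
  set.seed(seed)
  counts <- matrix(rpois(n_species * length(cohorts) * (n_control + n_case),
                         lambda = 50),
                   nrow = n_species)
  rownames(counts) <- sprintf("sp%02d", seq_len(n_species))
  colnames(counts) <- sprintf("s%03d", seq_len(ncol(counts)))
  samples <- data.frame(
    sample_id = colnames(counts),
    cohort = rep(cohorts, each = n_control + n_case),
    group = rep(rep(c("control", "case"), c(n_control, n_case)),
                length(cohorts)),
    stringsAsFactors = FALSE)
  join_metadata(counts, samples)
}

# small simulated study for pipeline-level tests
small_sim_study <- function(n_species = 80, n_effects = 8, fold_change = 3,
                            n_control = 25, n_case = 25, depth = 5e4,
                            cohorts = c("A", "B"), theta = 1e-3, seed = 42) {
  dm <- dm_params(n_species = n_species, theta = theta,
                  n_effects = n_effects, fold_change = fold_change)
  designs <- lapply(cohorts, function(co)
    cohort_design(co, n_control, n_case, depth))
  names(designs) <- cohorts
  simulate_study(dm, designs, seed = seed)
}

# build a study from explicit per-cohort case/control abundance vectors for
# one species of interest plus filler species
directional_study <- function(case_vals, control_vals, cohorts) {
  stopifnot(length(case_vals) == length(cohorts))
  n_ca <- length(case_vals[[1]]); n_co <- length(control_vals[[1]])
  cols <- list(); meta <- list()
  for (k in seq_along(cohorts)) {
    block <- rbind(sp_target = c(control_vals[[k]], case_vals[[k]]),
                   sp_fill1 = 40, sp_fill2 = 60)
    cols[[k]] <- block
    meta[[k]] <- data.frame(
      sample_id = sprintf("%s_%02d", cohorts[k], seq_len(n_co + n_ca)),
      cohort = cohorts[k],
      group = rep(c("control", "case"), c(n_co, n_ca)),
      stringsAsFactors = FALSE)
  }
  counts <- do.call(cbind, cols)
  samples <- do.call(rbind, meta)
  colnames(counts) <- samples$sample_id
  join_metadata(counts, samples)
}
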