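#' Sample a heavy-tailed base composition
#'
#' Draws species base proportions from a log-normal rank-abundance profile:
#' proportions are `exp(N(0, sigma^2))` renormalised to the simplex. With
#' `sigma = 0` the composition is uniform.
#'
#' @param n_species Number of species (>= 2).
#' @param sigma Log-scale standard deviation of the rank-abundance profile.
#' @param seed Optional integer seed.
#' @return A proportion vector summing to one.
#' @export
sample_base_composition <- function(n_species, sigma = 2, seed = NULL) {
  if (n_species < 2) stop("n_species must be at least 2")
  .seed_in(seed)
  x <- exp(rnorm(n_species, 0, sigma))
  x / sum(x)
}

#' Dirichlet-multinomial generator parameters
#'
#' Bundles everything the multi-cohort generator needs: the base composition
#' pi (drawn afresh per simulation when `base_proportions` is `NULL`), the
#' overdispersion `theta` mapping to a Dirichlet concentration
#' `alpha = pi * (1 - theta) / theta`, the identity of the differentially
#' abundant ("effect") species, and the multiplicative case fold change.
#'
#' Effect species default to a uniform draw from the upper half of the base
#' abundance distribution (`effect_pool = "abundant"`), emulating an analysis
#' set from which rare, undetectable species have already been filtered;
#' `effect_pool = "all"` spikes uniformly at random.
#'
#' @param n_species Number of species.
#' @param base_proportions Optional fixed simplex vector; when `NULL` a new
#'   composition is drawn per simulation from [sample_base_composition()].
#' @param sigma Log-normal spread used when drawing base proportions.
#' @param theta Overdispersion in (0, 1); smaller is closer to multinomial.
#' @param n_effects Number of effect species (ignored when `effect_species`
#'   is given).
#' @param effect_species Optional fixed indices of effect species.
#' @param fold_change Multiplicative factor applied to effect-species
#'   proportions in cases (1.1/1.2/1.4 correspond to 10/20/40% changes);
#'   values below 1 simulate depletions.
#' @param effect_pool `"abundant"` (upper half of base abundance) or `"all"`.
#' @return An object of class `dm_params`.
#' @export
dm_params <- function(n_species = 994, base_proportions = NULL, sigma = 2,
                      theta = 1e-4, n_effects = 50, effect_species = NULL,
                      fold_change = 1.2, effect_pool = c("abundant", "all")) {
  effect_pool <- match.arg(effect_pool)
  if (!is.null(base_proportions)) {
    if (any(base_proportions <= 0)) stop("base proportions must be positive")
    if (abs(sum(base_proportions) - 1) > 1e-8)
      stop("base proportions must sum to 1")
    n_species <- length(base_proportions)
  }
  if (theta <= 0 || theta >= 1) stop("theta must lie in (0, 1)")
  if (any(fold_change <= 0)) stop("fold_change must be positive")
  structure(list(n_species = n_species, base_proportions = base_proportions,
                 sigma = sigma, theta = theta, n_effects = n_effects,
                 effect_species = effect_species, fold_change = fold_change,
                 effect_pool = effect_pool),
            class = "dm_params")
}

#' @export
print.dm_params <- function(x, ...) {
  cat(sprintf(paste0("Dirichlet-multinomial parameters: %d species, theta=%g,",
                     " %d effect species at fold change %g (%s pool)\n"),
              x$n_species, x$theta,
              if (is.null(x$effect_species)) x$n_effects
              else length(x$effect_species),
              x$fold_change[1], x$effect_pool))
  invisible(x)
}

# realise base proportions and effect set for one simulation
.dm_realise <- function(dm) {
  pi0 <- dm$base_proportions
  if (is.null(pi0)) pi0 <- sample_base_composition(dm$n_species, dm$sigma)
  eff <- dm$effect_species
  if (is.null(eff)) {
    pool <- switch(dm$effect_pool,
                   abundant = order(pi0, decreasing = TRUE)[
                     seq_len(dm$n_species %/% 2)],
                   all = seq_len(dm$n_species))
    eff <- sample(pool, dm$n_effects)
  }
  list(pi0 = pi0, effect = sort(eff))
}

# case composition: multiply effect species and renormalise (closure)
.case_composition <- function(pi0, effect, fold_change) {
  pi1 <- pi0
  pi1[effect] <- pi1[effect] * fold_change
  pi1 / sum(pi1)
}

#' Cohort design
#'
#' @param cohort Cohort label.
#' @param n_control,n_case Per-arm sample sizes (>= 1).
#' @param depth Sequencing depth (reads per sample).
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(cohort, n_control, n_case, depth) {
  if (n_control < 1 || n_case < 1) stop("each arm needs at least one sample")
  if (depth <= 0) stop("depth must be positive")
  structure(list(cohort = cohort, n_control = as.integer(n_control),
                 n_case = as.integer(n_case), depth = as.integer(depth)),
            class = "cohort_design")
}

#' Default four-cohort design
#'
#' The four CRC case-control cohorts used throughout: US (52 control / 48
#' case), AT (63/46), HK (92/73) and FD (64/88), at each cohort's rarefied
#' per-sample read depth (2,419,973; 1,596,424; 1,222,507; 856,204).
#'
#' @return A named list of [cohort_design()] objects.
#' @export
default_cohort_designs <- function() {
  list(US = cohort_design("US", 52, 48, 2419973),
       AT = cohort_design("AT", 63, 46, 1596424),
       HK = cohort_design("HK", 92, 73, 1222507),
       FD = cohort_design("FD", 64, 88, 856204))
}

# draw one cohort's counts given control/case compositions
.sim_cohort_counts <- function(pi0, pi1, theta, design) {
  a0 <- (1 - theta) / theta
  n <- design$n_control + design$n_case
  p <- cbind(.rdirichlet(design$n_control, pi0 * a0),
             .rdirichlet(design$n_case, pi1 * a0))
  counts <- matrix(0L, length(pi0), n)
  for (j in seq_len(n)) counts[, j] <- rmultinom(1, design$depth, p[, j])
  counts
}

#' Simulate one cohort from the Dirichlet-multinomial model
#'
#' Each sample's composition is drawn from a Dirichlet distribution with
#' concentration `pi * (1 - theta) / theta` (case samples use the
#' effect-modified, renormalised composition) and read counts from a
#' multinomial at the design depth.
#'
#' @param dm [dm_params()] object.
#' @param design [cohort_design()] object.
#' @param seed Optional integer seed.
#' @return An `mm_study` with one cohort; attribute `truth` records the
#'   realised base proportions and effect species.
#' @export
simulate_cohort <- function(dm, design, seed = NULL) {
  .seed_in(seed)
  real <- .dm_realise(dm)
  pi1 <- .case_composition(real$pi0, real$effect, dm$fold_change[1])
  counts <- .sim_cohort_counts(real$pi0, pi1, dm$theta, design)
  rownames(counts) <- sprintf("sp%04d", seq_len(nrow(counts)))
  colnames(counts) <- sprintf("%s_s%03d", design$cohort,
                              seq_len(ncol(counts)))
  samples <- data.frame(
    sample_id = colnames(counts), cohort = design$cohort,
    group = rep(c("control", "case"), c(design$n_control, design$n_case)),
    stringsAsFactors = FALSE)
  study <- join_metadata(counts, samples)
  attr(study, "truth") <- list(base_proportions = real$pi0,
                               effect_species = real$effect,
                               fold_change = dm$fold_change[1],
                               theta = dm$theta)
  study
}

#' Simulate a multi-cohort study
#'
#' Draws one base composition and effect set, then simulates every cohort in
#' `designs` from it with [simulate_cohort()]'s model (cohorts share the
#' composition and effects but differ in size and depth).
#'
#' @param dm [dm_params()] object.
#' @param designs List of [cohort_design()] objects; defaults to the
#'   four-cohort design of [default_cohort_designs()].
#' @param seed Optional integer seed.
#' @return An `mm_study`; attribute `truth` records the realised generator
#'   state (base proportions, effect indices, fold change, theta, designs).
#' @export
simulate_study <- function(dm = dm_params(), designs = default_cohort_designs(),
                           seed = NULL) {
  .seed_in(seed)
  real <- .dm_realise(dm)
  pi1 <- .case_composition(real$pi0, real$effect, dm$fold_change[1])
  cms <- lapply(designs, function(d) {
    counts <- .sim_cohort_counts(real$pi0, pi1, dm$theta, d)
    colnames(counts) <- sprintf("%s_s%03d", d$cohort, seq_len(ncol(counts)))
    counts
  })
  counts <- do.call(cbind, cms)
  rownames(counts) <- sprintf("sp%04d", seq_len(nrow(counts)))
  samples <- do.call(rbind, lapply(designs, function(d) data.frame(
    sample_id = sprintf("%s_s%03d", d$cohort,
                        seq_len(d$n_control + d$n_case)),
    cohort = d$cohort,
    group = rep(c("control", "case"), c(d$n_control, d$n_case)),
    stringsAsFactors = FALSE)))
  study <- join_metadata(counts, samples)
  attr(study, "truth") <- list(base_proportions = real$pi0,
                               effect_species = real$effect,
                               fold_change = dm$fold_change[1],
                               theta = dm$theta, designs = designs)
  study
}

#' Attach an age-like confounder and re-draw abundances under it
#'
#' Adds a continuous covariate (cases shifted by `case_shift` to emulate a
#' confounded design) and re-draws every sample's counts with the
#' composition of the affected species multiplied by `exp(X_i * beta1)`,
#' renormalised. With `beta1 = 0` and the same seed the counts equal a plain
#' [simulate_study()] draw.
#'
#' @param study An `mm_study` produced by [simulate_study()] (its `truth`
#'   attribute supplies the generator state).
#' @param beta1 Per-unit log-abundance slope of the covariate.
#' @param species Indices of covariate-affected species; defaults to the
#'   effect species recorded in `truth`.
#' @param covariate Name under which the covariate is stored (default "age").
#' @param mean0,sd0 Control-arm covariate mean and SD.
#' @param case_shift Added to the covariate mean in cases.
#' @param seed Optional integer seed.
#' @return The study with the covariate column added and counts re-drawn;
#'   `truth$beta1` and `truth$confounder` record the generation values.
#' @export
attach_confounder <- function(study, beta1, species = NULL,
                              covariate = "age", mean0 = 60, sd0 = 10,
                              case_shift = 8, seed = NULL) {
  if (!is.finite(beta1)) stop("beta1 must be finite")
  truth <- attr(study, "truth")
  if (is.null(truth)) stop("study carries no generator state ('truth')")
  .seed_in(seed)
  if (is.null(species)) species <- truth$effect_species
  n <- ncol(study$counts)
  x <- rnorm(n, mean0 + ifelse(study$samples$group == "case", case_shift, 0),
             sd0)
  pi0 <- truth$base_proportions
  pi1 <- .case_composition(pi0, truth$effect_species, truth$fold_change)
  a0 <- (1 - truth$theta) / truth$theta
  depth <- colSums(study$counts)
  counts <- study$counts
  for (j in seq_len(n)) {
    base <- if (study$samples$group[j] == "case") pi1 else pi0
    comp <- base
    comp[species] <- comp[species] * exp(x[j] * beta1)
    comp <- comp / sum(comp)
    p <- .rdirichlet(1, comp * a0)[, 1]
    counts[, j] <- rmultinom(1, depth[j], p)
  }
  study$counts <- counts
  study$samples[[covariate]] <- x
  truth$beta1 <- beta1
  truth$confounder <- x
  truth$confounded_species <- species
  attr(study, "truth") <- truth
  study
}

#' Log-ratio variance matrix
#'
#' `T[i, j] = var(log(x_i / x_j))` across samples, the quantity the SparCC
#' estimator inverts. For latent log-normal abundances with basis variances
#' `omega^2` and correlations `rho` it equals
#' `omega_i^2 + omega_j^2 - 2 rho_ij omega_i omega_j` exactly.
#'
#' @param frac Species x samples matrix of strictly positive fractions (or
#'   any positive abundances; ratios remove the scale).
#' @return Symmetric matrix of log-ratio variances (zero diagonal).
#' @export
logratio_variance <- function(frac) {
  if (any(frac <= 0)) stop("fractions must be strictly positive")
  v <- log(frac)
  cv <- stats::cov(t(v))
  d <- diag(cv)
  tmat <- outer(d, d, "+") - 2 * cv
  diag(tmat) <- 0
  tmat
}

#' Simulate compositions with a latent correlation structure
#'
#' Latent per-sample log-abundances are multivariate normal with covariance
#' `diag(omega) %*% rho %*% diag(omega)`; they are exponentiated, closed to
#' the simplex and sampled into counts with a multinomial at `depth` reads.
#'
#' @param rho Target basis correlation matrix (symmetric, unit diagonal,
#'   positive semi-definite).
#' @param omega Per-species latent log-scale standard deviations (recycled).
#' @param n_samples Number of samples.
#' @param depth Reads per sample.
#' @param mu Latent log-abundance means (defaults to 0).
#' @param seed Optional integer seed.
#' @return List with `counts` (species x samples integer matrix) and
#'   `latent` (the latent fraction matrix before sampling).
#' @export
simulate_correlated_composition <- function(rho, omega = 1, n_samples,
                                            depth = 1e5, mu = 0, seed = NULL) {
  m <- nrow(rho)
  if (!isSymmetric(unname(rho))) stop("rho must be symmetric")
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(sprintf("rho is not positive semi-definite (eigenvalue %.3g)",
                 min(ev)))
  .seed_in(seed)
  omega <- rep_len(omega, m)
  mu <- rep_len(mu, m)
  sigma <- diag(omega) %*% rho %*% diag(omega)
  es <- eigen(sigma, symmetric = TRUE)
  rt <- es$vectors %*% diag(sqrt(pmax(es$values, 0)), m) %*% t(es$vectors)
  z <- rt %*% matrix(rnorm(m * n_samples), m)
  lat <- exp(z + mu)
  lat <- sweep(lat, 2, colSums(lat), "/")
  counts <- matrix(0L, m, n_samples)
  for (j in seq_len(n_samples)) counts[, j] <- rmultinom(1, depth, lat[, j])
  rownames(counts) <- rownames(lat) <- sprintf("sp%04d", seq_len(m))
  colnames(counts) <- colnames(lat) <- sprintf("s%04d", seq_len(n_samples))
  list(counts = counts, latent = lat)
}

#' Simulate a functional-category table linked to species abundances
#'
#' Linked categories are monotone (log-normal copula) functions of their
#' species' relative abundance with noise calibrated so the Spearman
#' correlation is approximately `rho`; unlinked categories are independent
#' log-normal noise. The bivariate-normal relation
#' `rho_spearman = (6 / pi) * asin(r / 2)` sets the latent Pearson `r`.
#'
#' @param study An `mm_study` supplying species abundances.
#' @param links Data frame with columns `species` (row name or index),
#'   `category`, and `rho` (target Spearman correlation in (-1, 1)).
#' @param n_categories Total number of categories (>= number of links).
#' @param seed Optional integer seed.
#' @return Categories x samples abundance matrix (arbitrary positive units;
#'   see [normalize_cpm()]).
#' @export
simulate_function_table <- function(study, links, n_categories = 100,
                                    seed = NULL) {
  if (any(abs(links$rho) >= 1)) stop("target Spearman rho must lie in (-1, 1)")
  .seed_in(seed)
  n <- ncol(study$counts)
  ra <- sweep(study$counts, 2, colSums(study$counts), "/")
  ft <- matrix(exp(rnorm(n_categories * n, 10, 1)), n_categories, n)
  cats <- unique(as.character(links$category))
  extra <- n_categories - length(cats)
  rownames(ft) <- c(cats, sprintf("cat%04d", seq_len(max(extra, 0))))[
    seq_len(n_categories)]
  colnames(ft) <- colnames(study$counts)
  for (i in seq_len(nrow(links))) {
    sp <- links$species[i]
    x <- ra[sp, ]
    u <- rank(x, ties.method = "average") / (n + 1)
    z1 <- qnorm(u)
    r <- 2 * sin(pi * links$rho[i] / 6)
    z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
    ft[as.character(links$category[i]), ] <- exp(10 + z2)
  }
  ft
}

#' Simulate classifier scores with a prescribed AUC
#'
#' Binormal scores: controls from N(0, 1), cases from N(delta, 1) with
#' `delta = sqrt(2) * qnorm(target_auc)`, so the expected AUC equals
#' `target_auc` exactly.
#'
#' @param n_control,n_case Per-arm sample counts.
#' @param target_auc Expected AUC in \[0.5, 1\]; 1 gives perfect separation.
#' @param seed Optional integer seed.
#' @return List with numeric `scores` and factor `labels`
#'   (control/case).
#' @export
simulate_classifier_scores <- function(n_control, n_case, target_auc = 0.8,
                                       seed = NULL) {
  if (target_auc < 0.5 || target_auc > 1)
    stop("target_auc must lie in [0.5, 1]")
  .seed_in(seed)
  delta <- sqrt(2) * qnorm(target_auc) # Inf when target_auc = 1

  scores <- c(rnorm(n_control), rnorm(n_case) + delta)
  labels <- factor(rep(c("control", "case"), c(n_control, n_case)),
                   levels = c("control", "case"))
  list(scores = scores, labels = labels)
}
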