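#' Per-cohort abundance change directions and Mann-Whitney p-values
#'
#' For every species and cohort, the abundance change direction is the sign
#' of `median(case relative abundance) - median(control relative abundance)`
#' (0 only when the point estimate is exactly zero), with a two-sided
#' Mann-Whitney test on relative abundance.
#'
#' @param study An `mm_study` (every cohort needs at least one case and one
#'   control).
#' @return A `direction_table`: list with `direction` (species x cohort
#'   matrix in \{-1, 0, 1\}), `p` (Mann-Whitney p-values) and `delta`
#'   (median differences).
#' @export
direction_summary <- function(study) {
  ra <- relative_abundance(study$counts)
  idx <- .cohort_index(study)
  case <- study$samples$group == "case"
  m <- nrow(ra)
  K <- length(idx)
  dir <- dl <- pv <- matrix(NA_real_, m, K,
                            dimnames = list(rownames(ra), names(idx)))
  for (k in seq_along(idx)) {
    i <- idx[[k]]
    ca <- i[case[i]]; co <- i[!case[i]]
    if (!length(ca) || !length(co))
      stop("cohort ", names(idx)[k], " lacks a case or control arm")
    xc <- ra[, ca, drop = FALSE]; xo <- ra[, co, drop = FALSE]
    dl[, k] <- apply(xc, 1, median) - apply(xo, 1, median)
    dir[, k] <- sign(dl[, k])
    for (s in seq_len(m)) {
      v <- c(xc[s, ], xo[s, ])
      pv[s, k] <- if (length(unique(v)) == 1L) 1 else
        suppressWarnings(wilcox.test(xc[s, ], xo[s, ])$p.value)
    }
  }
  structure(list(direction = dir, p = pv, delta = dl),
            class = "direction_table")
}

#' Divergence filter for discordant species
#'
#' Removes species unsuitable for cross-cohort meta-analysis, in order of
#' precedence: below the abundance floor; absent (all-zero) in at least one
#' cohort; balanced direction discrepancy (as many cohorts up as down among
#' the non-zero directions); or a significant discrepancy — at least one
#' cohort changing opposite to the strict majority direction with
#' Mann-Whitney `p < alpha`. Survivors form the analysis set. The outcome
#' does not depend on cohort order.
#'
#' @param dt A [direction_summary()] result.
#' @param study The `mm_study` the directions were computed from (supplies
#'   abundance/prevalence for the floors).
#' @param abundance_floor Minimum overall mean relative abundance.
#' @param prevalence_floor Minimum fraction of samples with non-zero counts.
#' @param alpha Significance level for the discrepancy rule.
#' @return Factor of filter statuses, one per species, with levels `kept`,
#'   `removed-balanced`, `removed-significant-discrepant`, `removed-missing`,
#'   `removed-low-abundance`.
#' @export
divergence_filter <- function(dt, study, abundance_floor = 1e-6,
                              prevalence_floor = 0.05, alpha = 0.05) {
  ra <- relative_abundance(study$counts)
  idx <- .cohort_index(study)
  mean_ab <- rowMeans(ra)
  prev <- rowMeans(study$counts > 0)
  missing_any <- Reduce(`|`, lapply(idx, function(i)
    rowSums(study$counts[, i, drop = FALSE]) == 0))
  m <- nrow(dt$direction)
  status <- rep("kept", m)
  for (s in seq_len(m)) {
    d <- dt$direction[s, ]
    p <- dt$p[s, ]
    n_up <- sum(d > 0); n_dn <- sum(d < 0)
    if (mean_ab[s] < abundance_floor || prev[s] < prevalence_floor) {
      status[s] <- "removed-low-abundance"
    } else if (missing_any[s]) {
      status[s] <- "removed-missing"
    } else if (n_up == n_dn) {
      status[s] <- "removed-balanced"
    } else {
      maj <- if (n_up > n_dn) 1 else -1
      if (any(d == -maj & p < alpha, na.rm = TRUE))
        status[s] <- "removed-significant-discrepant"
    }
  }
  factor(status, levels = c("kept", "removed-balanced",
                            "removed-significant-discrepant",
                            "removed-missing", "removed-low-abundance"))
}

#' Detect covariates associated with case/control status
#'
#' Within each cohort, continuous covariates are tested with a Welch t-test
#' and categorical ones with a chi-square test against group; covariates
#' present in fewer than `min_present` of a cohort's samples, or constant,
#' are skipped.
#'
#' @param study An `mm_study`.
#' @param covariates Covariate column names; defaults to every metadata
#'   column other than `sample_id`, `cohort`, `group`.
#' @param alpha Flagging level.
#' @param min_present Minimum fraction of non-missing values.
#' @return Data frame with cohort, covariate, test type, p-value, and a
#'   `flagged` indicator.
#' @export
detect_confounders <- function(study, covariates = NULL, alpha = 0.05,
                               min_present = 0.8) {
  sf <- study$samples
  if (is.null(covariates))
    covariates <- setdiff(names(sf), c("sample_id", "cohort", "group"))
  out <- list()
  for (co in levels(sf$cohort)) {
    sub <- sf[sf$cohort == co, , drop = FALSE]
    for (v in covariates) {
      x <- sub[[v]]
      if (mean(!is.na(x)) < min_present) next
      ok <- !is.na(x)
      xs <- x[ok]; g <- sub$group[ok]
      if (length(unique(xs)) < 2) {
        message("covariate ", v, " constant in cohort ", co, "; skipped")
        next
      }
      if (is.numeric(xs)) {
        p <- t.test(xs ~ g)$p.value
        type <- "welch-t"
      } else {
        p <- suppressWarnings(chisq.test(table(xs, g))$p.value)
        type <- "chi-square"
      }
      out[[length(out) + 1L]] <- data.frame(
        cohort = co, covariate = v, test = type, p_value = p,
        flagged = p < alpha, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(cohort = character(), covariate = character(),
                      test = character(), p_value = numeric(),
                      flagged = logical()))
  do.call(rbind, out)
}

#' Adjust abundances for a confounding covariate
#'
#' Fits `log(y + pseudocount) = beta0 + X * beta1` per species by least
#' squares (unless `beta1` is supplied) and returns
#' `y' = y * exp(-X * beta1)`, which removes the covariate's multiplicative
#' effect: `y'_i / y'_j = (y_i / y_j) * exp(-(X_i - X_j) * beta1)`.
#'
#' @param y Abundance vector or species x samples matrix (one cohort).
#' @param x Covariate, one value per sample.
#' @param beta1 Optional fixed slope(s); fitted when `NULL`.
#' @param pseudocount Added before the log for the fit.
#' @return Adjusted abundances, same shape as `y`, with attribute `beta`
#'   (data frame of per-species intercepts and slopes).
#' @export
adjust_confounder <- function(y, x, beta1 = NULL, pseudocount = 0.5) {
  vec <- is.null(dim(y))
  ym <- if (vec) matrix(y, nrow = 1) else as.matrix(y)
  if (length(x) != ncol(ym)) stop("covariate length must match sample count")
  if (var(x) == 0 && is.null(beta1)) {
    warning("covariate has zero variance; no adjustment applied")
    return(y)
  }
  if (is.null(beta1)) {
    ly <- t(log(ym + pseudocount))
    fit <- lm(ly ~ x)
    b <- coef(fit)
    if (is.null(dim(b))) b <- matrix(b, ncol = 1)
    beta0 <- b[1, ]; beta1 <- b[2, ]
  } else {
    beta1 <- rep_len(beta1, nrow(ym)); beta0 <- rep(NA_real_, nrow(ym))
  }
  adj <- ym * exp(-outer(beta1, x))
  out <- if (vec) adj[1, ] else adj
  attr(out, "beta") <- data.frame(beta0 = unname(beta0),
                                  beta1 = unname(beta1))
  out
}

#' Adjust a study for confounder-associated species
#'
#' For each cohort in which `covariate` is flagged by [detect_confounders()]
#' (or for `cohorts` when given), species whose log abundance is
#' significantly associated with the covariate are adjusted with
#' [adjust_confounder()]. Other counts are left untouched. The returned
#' study carries continuous (non-integer) abundances.
#'
#' @param study An `mm_study`.
#' @param covariate Metadata column to adjust for.
#' @param cohorts Cohort labels to adjust; default: flagged cohorts.
#' @param alpha Species-level association level.
#' @param pseudocount Pseudocount for the log-linear fit.
#' @return The study with adjusted abundances.
#' @export
adjust_study <- function(study, covariate = "age", cohorts = NULL,
                         alpha = 0.05, pseudocount = 0.5) {
  if (is.null(cohorts)) {
    cf <- detect_confounders(study, covariates = covariate)
    cohorts <- cf$cohort[cf$flagged]
  }
  idx <- .cohort_index(study)
  counts <- study$counts * 1.0
  for (co in intersect(names(idx), cohorts)) {
    i <- idx[[co]]
    x <- study$samples[[covariate]][i]
    ok <- !is.na(x)
    if (sum(ok) < 3) next
    y <- counts[, i[ok], drop = FALSE]
    ly <- t(log(y + pseudocount))
    fit <- lm(ly ~ x[ok])
    sm <- summary(fit)
    pv <- vapply(sm, function(s) s$coefficients[2, 4], numeric(1))
    hit <- which(pv < alpha)
    if (length(hit)) {
      b1 <- coef(fit)[2, hit]
      counts[hit, i[ok]] <- y[hit, , drop = FALSE] *
        exp(-outer(unname(b1), x[ok]))
    }
  }
  study$counts <- counts
  study
}

# ---- pairwise fold-change rank-sum engine -----------------------------------

# case-control pair index sets for one cohort, capped with seeded subsampling
.sample_pairs <- function(ctl, cas, pair_cap) {
  n_all <- length(ctl) * length(cas)
  if (n_all <= pair_cap) {
    grid <- expand.grid(ctl = ctl, cas = cas)
  } else {
    pick <- sample.int(n_all, pair_cap)
    grid <- data.frame(ctl = ctl[(pick - 1L) %% length(ctl) + 1L],
                       cas = cas[(pick - 1L) %/% length(ctl) + 1L])
  }
  grid
}

# rank sums over pairs for one cohort; rank 1 = most enriched (up) or most
# depleted (down); average ranks on ties
.cohort_rank_sums <- function(logab, ctl, cas, pair_cap, both = TRUE) {
  pr <- .sample_pairs(ctl, cas, pair_cap)
  lfc <- logab[, pr$cas, drop = FALSE] - logab[, pr$ctl, drop = FALSE]
  col_ranks <- function(x) {
    r <- apply(x, 2, rank)
    if (!is.matrix(r)) r <- matrix(r, nrow = nrow(x)) # single species
    r
  }
  up <- rowSums(col_ranks(-lfc))
  down <- if (both) rowSums(col_ranks(lfc)) else NULL
  list(up = up, down = down, n_pairs = nrow(pr))
}

# per-cohort up/down rank-sum matrices for a study
.study_rank_sums <- function(counts, idx, case, pair_cap, pseudocount,
                             both = TRUE) {
  logab <- .rel_log_abundance(counts, pseudocount)
  K <- length(idx)
  m <- nrow(counts)
  up <- matrix(0, m, K, dimnames = list(rownames(counts), names(idx)))
  down <- if (both) up else NULL
  n_pairs <- integer(K)
  for (k in seq_len(K)) {
    i <- idx[[k]]
    rs <- .cohort_rank_sums(logab, i[!case[i]], i[case[i]], pair_cap, both)
    up[, k] <- rs$up
    if (both) down[, k] <- rs$down
    n_pairs[k] <- rs$n_pairs
  }
  list(up = up, down = down, n_pairs = n_pairs)
}

#' Rank-sum meta-analysis of differential abundance
#'
#' The meta-analytic statistic: within every cohort, each case-control pair
#' yields a per-species fold change of (pseudocounted) relative abundance;
#' species are ranked within each pair (rank 1 = most enriched), and the
#' statistic is the sum of ranks over all pairs and cohorts. Small up-sums
#' flag consistent enrichment; the depletion statistic uses the reversed
#' ordering. Significance per rank position is the permutation-estimated
#' percentage of false positives (pfp): case/control labels are permuted
#' within cohorts, and for the species at rank `r` with statistic `s`,
#' `pfp = E[#null statistics <= s] / r`, made non-decreasing along the
#' ranked list.
#'
#' When the number of pairs in a cohort exceeds `pair_cap` a seeded random
#' subset of `pair_cap` pairs is used.
#'
#' @param study An `mm_study` (one or more cohorts; a single cohort gives
#'   the within-cohort rank aggregation).
#' @param species Optional analysis set (names or indices), e.g. the `kept`
#'   species of [divergence_filter()].
#' @param pair_cap Maximum case-control pairs per cohort.
#' @param pseudocount Reads added to every cell before normalisation.
#' @param n_perm Label permutations for pfp (0 skips pfp).
#' @param seed Optional integer seed (pairs and permutations).
#' @return An object of class `meta_diff` with per-species statistics
#'   (`statistic_up`, `statistic_down`), per-cohort rank-sum matrices,
#'   `pfp_up`/`pfp_down`, and bookkeeping fields.
#' @export
meta_rank_sum <- function(study, species = NULL, pair_cap = 2000,
                          pseudocount = 0.5, n_perm = 100, seed = NULL) {
  .seed_in(seed)
  counts <- study$counts
  if (!is.null(species)) counts <- counts[species, , drop = FALSE]
  if (nrow(counts) == 0) stop("analysis set is empty")
  idx <- .cohort_index(study)
  case <- study$samples$group == "case"
  obs <- .study_rank_sums(counts, idx, case, pair_cap, pseudocount)
  fit <- structure(list(
    species = rownames(counts),
    statistic_up = rowSums(obs$up), statistic_down = rowSums(obs$down),
    cohort_up = obs$up, cohort_down = obs$down, n_pairs = obs$n_pairs,
    pfp_up = NULL, pfp_down = NULL, n_perm = 0,
    pair_cap = pair_cap, pseudocount = pseudocount, seed = seed,
    counts = counts, cohort_index = idx, case = case,
    call = match.call()), class = "meta_diff")
  if (n_perm > 0) fit <- estimate_pfp(fit, n_perm = n_perm)
  fit
}

#' Permutation pfp for a rank-sum fit
#'
#' Re-estimates the percentage of false positives of a [meta_rank_sum()]
#' fit: case/control labels are permuted within each cohort `n_perm` times,
#' the rank-sum statistics recomputed, and for the species at rank `r`
#' (statistics ascending) with statistic `s`,
#' `pfp(r) = mean #{null statistics <= s} / r`, capped at 1 and monotonised
#' to be non-decreasing in `r`.
#'
#' @param fit A `meta_diff` object.
#' @param n_perm Number of permutations (>= 20).
#' @param seed Optional integer seed.
#' @return The fit with `pfp_up` and `pfp_down` filled in.
#' @export
estimate_pfp <- function(fit, n_perm = 100, seed = NULL) {
  if (n_perm < 20) stop("use at least 20 permutations")
  .seed_in(seed)
  m <- length(fit$species)
  perm_up <- perm_down <- numeric(m * n_perm)
  case <- fit$case
  for (b in seq_len(n_perm)) {
    pcase <- case
    for (i in fit$cohort_index) pcase[i] <- sample(case[i])
    ps <- .study_rank_sums(fit$counts, fit$cohort_index, pcase,
                           fit$pair_cap, fit$pseudocount)
    sl <- ((b - 1) * m + 1):(b * m)
    perm_up[sl] <- rowSums(ps$up)
    perm_down[sl] <- rowSums(ps$down)
  }
  fit$pfp_up <- .pfp_from_null(fit$statistic_up, perm_up, n_perm)
  fit$pfp_down <- .pfp_from_null(fit$statistic_down, perm_down, n_perm)
  fit$n_perm <- n_perm
  fit
}

.pfp_from_null <- function(stat, null, n_perm) {
  ord <- order(stat)
  null <- sort(null)
  cnt <- findInterval(stat[ord], null) / n_perm
  pfp <- pmin(cummax(cnt / seq_along(stat)), 1)
  out <- numeric(length(stat))
  out[ord] <- pfp
  names(out) <- names(stat)
  out
}

#' @export
print.meta_diff <- function(x, ...) {
  cat("Rank-sum meta-analysis\n")
  cat(sprintf("  %d species, %d cohort(s), pairs per cohort: %s\n",
              length(x$species), length(x$n_pairs),
              paste(x$n_pairs, collapse = "/")))
  if (x$n_perm > 0)
    cat(sprintf("  pfp from %d permutations: %d enriched, %d depleted at pfp < 0.01\n",
                x$n_perm, sum(x$pfp_up < 0.01), sum(x$pfp_down < 0.01)))
  invisible(x)
}

#' @export
summary.meta_diff <- function(object, pfp_cut = 0.01, ...) {
  df <- data.frame(species = object$species,
                   statistic_up = object$statistic_up,
                   statistic_down = object$statistic_down,
                   row.names = NULL, stringsAsFactors = FALSE)
  if (object$n_perm > 0) {
    df$pfp_up <- object$pfp_up
    df$pfp_down <- object$pfp_down
    df$significant <- ifelse(df$pfp_up < pfp_cut, "enriched",
                             ifelse(df$pfp_down < pfp_cut, "depleted", "no"))
  }
  df[order(pmin(df$statistic_up, df$statistic_down)), ]
}

#' Stratified (van Elteren) Mann-Whitney test
#'
#' Combines stratum-wise centred rank sums with weights `1 / (n_s + 1)` and
#' a tie-corrected normal approximation. With a single stratum this equals
#' the standard Mann-Whitney normal approximation (no continuity
#' correction). Strata lacking a case or a control are dropped.
#'
#' @param x Numeric observations.
#' @param group Factor/logical: `case` versus `control` (factor level 2 or
#'   `TRUE` is treated as case).
#' @param strata Stratum labels; `NULL` with `covariate` bins the covariate
#'   into `n_strata` quantile groups; `NULL` without covariate uses one
#'   stratum.
#' @param covariate Optional continuous stratification covariate.
#' @param n_strata Number of quantile bins for `covariate`.
#' @return List with `z` (case-enrichment direction is positive),
#'   `p_value` (two-sided), and `n_strata_used`.
#' @export
stratified_mannwhitney <- function(x, group, strata = NULL, covariate = NULL,
                                   n_strata = 4) {
  if (is.null(strata)) {
    strata <- if (is.null(covariate)) rep(1L, length(x)) else
      .quantile_bins(covariate, n_strata)
  }
  if (is.logical(group)) {
    case <- group
  } else {
    g <- factor(group)
    case <- if ("case" %in% levels(g)) g == "case" else g == levels(g)[nlevels(g)]
  }
  tt <- 0; vv <- 0; used <- 0L
  for (s in split(seq_along(x), strata)) {
    n1 <- sum(case[s]); n0 <- sum(!case[s]); n <- n1 + n0
    if (n1 < 1 || n0 < 1) next
    r <- rank(x[s])
    w <- sum(r[case[s]])
    e <- n1 * (n + 1) / 2
    ties <- table(x[s])
    tiec <- sum(ties^3 - ties)
    v <- n1 * n0 / 12 * ((n + 1) - if (n > 1) tiec / (n * (n - 1)) else 0)
    tt <- tt + (w - e) / (n + 1)
    vv <- vv + v / (n + 1)^2
    used <- used + 1L
  }
  if (used == 0L) stop("no stratum contains both a case and a control")
  if (vv == 0) return(list(z = 0, p_value = 1, n_strata_used = used))
  z <- tt / sqrt(vv)
  list(z = z, p_value = 2 * pnorm(-abs(z)), n_strata_used = used)
}

.quantile_bins <- function(x, n_bins = 4) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                        na.rm = TRUE))
  if (length(br) < 2) return(rep(1L, length(x)))
  cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
}

#' Per-pair fold-change estimate with signed-rank confidence interval
#'
#' For each requested species, natural-log fold changes are computed over
#' case-control pairs (pooled across cohorts, capped per cohort) and
#' summarised by the Hodges-Lehmann pseudomedian with a Wilcoxon
#' signed-rank confidence interval.
#'
#' @param study An `mm_study`.
#' @param species Species names or indices to summarise.
#' @param level Confidence level.
#' @param pair_cap Maximum pairs per cohort.
#' @param pseudocount Reads added before normalisation.
#' @param seed Optional integer seed (pair subsampling).
#' @return Data frame with species, pseudomedian log fold change, CI bounds
#'   and the number of pairs.
#' @export
pairwise_foldchange_ci <- function(study, species, level = 0.95,
                                   pair_cap = 2000, pseudocount = 0.5,
                                   seed = NULL) {
  .seed_in(seed)
  logab <- .rel_log_abundance(study$counts, pseudocount)
  idx <- .cohort_index(study)
  case <- study$samples$group == "case"
  prs <- lapply(idx, function(i)
    .sample_pairs(i[!case[i]], i[case[i]], pair_cap))
  sp <- if (is.character(species)) match(species, rownames(logab)) else species
  out <- lapply(sp, function(s) {
    lfc <- unlist(lapply(prs, function(pr)
      logab[s, pr$cas] - logab[s, pr$ctl]), use.names = FALSE)
    if (length(lfc) < 8) stop("need at least 8 case-control pairs")
    if (diff(range(lfc)) < 1e-12) {
      # degenerate: every pair has the same fold change
      est <- lo <- hi <- lfc[1]
    } else {
      wt <- suppressWarnings(
        wilcox.test(lfc, conf.int = TRUE, conf.level = level))
      est <- unname(wt$estimate); lo <- wt$conf.int[1]; hi <- wt$conf.int[2]
    }
    data.frame(species = rownames(logab)[s],
               estimate = est, lower = lo, upper = hi,
               n_pairs = length(lfc), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Species with a monotone control / early / late stage trend
#'
#' Flags species whose pooled group medians are strictly ordered across
#' control, early-stage and late-stage samples and whose two adjacent
#' comparisons (control vs early, early vs late) both reject at `alpha`
#' under the cohort-stratified Mann-Whitney test. Cases without a stage
#' label are dropped with a message.
#'
#' @param study An `mm_study` whose metadata has a `stage` column with
#'   values `early`/`late` for cases.
#' @param alpha Per-comparison significance level.
#' @return Data frame with per-group medians, the trend direction
#'   (`decreasing`, `increasing` or `none`) and a `flagged` indicator.
#' @export
stage_trend <- function(study, alpha = 0.05) {
  sf <- study$samples
  if (is.null(sf$stage)) stop("metadata has no 'stage' column")
  grp <- ifelse(sf$group == "control", "control", as.character(sf$stage))
  drop <- sf$group == "case" & is.na(sf$stage)
  if (any(drop))
    message("dropping ", sum(drop), " case(s) without stage labels")
  keep <- !drop
  ra <- relative_abundance(study$counts)[, keep, drop = FALSE]
  grp <- grp[keep]; coh <- sf$cohort[keep]
  if (!all(c("control", "early", "late") %in% grp))
    stop("need control, early and late samples")
  out <- lapply(seq_len(nrow(ra)), function(s) {
    med <- tapply(ra[s, ], grp, median)[c("control", "early", "late")]
    dirn <- if (med[1] > med[2] && med[2] > med[3]) "decreasing"
            else if (med[1] < med[2] && med[2] < med[3]) "increasing"
            else "none"
    ce <- grp %in% c("control", "early")
    el <- grp %in% c("early", "late")
    p1 <- stratified_mannwhitney(ra[s, ce], grp[ce] != "control",
                                 strata = coh[ce])$p_value
    p2 <- stratified_mannwhitney(ra[s, el], grp[el] == "late",
                                 strata = coh[el])$p_value
    data.frame(species = rownames(ra)[s], median_control = med[1],
               median_early = med[2], median_late = med[3],
               direction = dirn, p_control_early = p1, p_early_late = p2,
               flagged = dirn != "none" && p1 < alpha && p2 < alpha,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
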