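# exact two-sided Mann-Whitney p by enumeration of all group assignments
exact_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_obs <- sum(rank(pooled)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- combn(length(pooled), n1)
  us <- apply(combos, 2, function(idx)
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(y) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

test_that("direction summary gives signed medians and exact MW p-values", {
  # values chosen without cross-group ties so the exact U distribution applies
  ctl <- list(c(10, 20, 30, 40, 50), c(12, 22, 32, 42, 52))
  cas <- list(c(15, 35, 55, 65, 75), c(17, 37, 57, 67, 77))
  st <- directional_study(cas, ctl, c("A", "B"))
  dt <- direction_summary(st)
  expect_true(all(dt$direction["sp_target", ] == 1))

  # p matches exhaustive enumeration of the U distribution (5 vs 5)
  ra <- relative_abundance(st$counts)
  for (co in c("A", "B")) {
    i <- which(st$samples$cohort == co)
    g <- st$samples$group[i]
    p_exact <- exact_mw_p(ra["sp_target", i[g == "case"]],
                          ra["sp_target", i[g == "control"]])
    expect_equal(dt$p["sp_target", co], p_exact, tolerance = 1e-12)
  }
})

test_that("an all-zero species has direction 0 and p = 1", {
  st <- toy_study(n_species = 4)
  st$counts[2, ] <- 0L
  st$counts <- st$counts[, colSums(st$counts) > 0]
  dt <- direction_summary(st)
  expect_true(all(dt$direction[2, ] == 0))
  expect_true(all(dt$p[2, ] == 1))
})

make_direction_table <- function(dirs, ps) {
  structure(list(direction = matrix(dirs, 1,
                                    dimnames = list("sp_target",
                                                    LETTERS[seq_along(dirs)])),
                 p = matrix(ps, 1), delta = matrix(dirs * 0.1, 1)),
            class = "direction_table")
}

test_that("the divergence filter implements the concordance rules exactly", {
  cases4 <- list(c(10, 12, 14, 16), c(9, 11, 13, 15))
  ctls4 <- list(c(5, 6, 7, 8), c(4, 5, 6, 7))
  st <- directional_study(rep(cases4[1], 4), rep(ctls4[1], 4),
                          c("A", "B", "C", "D"))
  dt <- direction_summary(st)

  # (+,+,+,+) kept
  d1 <- dt
  d1$direction[1, ] <- c(1, 1, 1, 1); d1$p[1, ] <- 0.01
  expect_equal(as.character(divergence_filter(d1, st)[1]), "kept")

  # (+,+,-,-) balanced discrepancy
  d2 <- dt
  d2$direction[1, ] <- c(1, 1, -1, -1); d2$p[1, ] <- 0.01
  expect_equal(as.character(divergence_filter(d2, st)[1]),
               "removed-balanced")

  # (+,+,+,-): removed iff the discordant cohort is significant
  d3 <- dt
  d3$direction[1, ] <- c(1, 1, 1, -1)
  d3$p[1, ] <- c(0.01, 0.01, 0.01, 0.01)
  expect_equal(as.character(divergence_filter(d3, st)[1]),
               "removed-significant-discrepant")
  d3$p[1, 4] <- 0.4
  expect_equal(as.character(divergence_filter(d3, st)[1]), "kept")

  # filter status is invariant to cohort order
  perm <- c(3, 1, 4, 2)
  d3p <- d3
  d3p$direction <- d3$direction[, perm, drop = FALSE]
  d3p$p <- d3$p[, perm, drop = FALSE]
  expect_equal(as.character(divergence_filter(d3p, st)[1]),
               as.character(divergence_filter(d3, st)[1]))

  # species absent in one cohort
  st_miss <- st
  idx_a <- st_miss$samples$cohort == "A"
  st_miss$counts["sp_target", idx_a] <- 0L
  dt_m <- direction_summary(st_miss)
  expect_equal(as.character(divergence_filter(dt_m, st_miss)[1]),
               "removed-missing")

  # below the abundance floor
  st_low <- st
  st_low$counts["sp_target", ] <- rep(c(0L, 1L), length.out = ncol(st$counts))
  dt_l <- direction_summary(st_low)
  expect_equal(as.character(divergence_filter(dt_l, st_low,
                                              abundance_floor = 0.05)[1]),
               "removed-low-abundance")
})

test_that("confounder detection flags shifted covariates and not null ones", {
  set.seed(10)
  flagged_shift <- 0; flagged_null <- 0
  for (i in 1:40) {
    st <- toy_study(n_control = 25, n_case = 25, cohorts = "A", seed = i)
    st$samples$age <- rnorm(50, 60, 8) +
      ifelse(st$samples$group == "case", 8, 0)
    st$samples$noise <- rnorm(50)
    cf <- detect_confounders(st)
    flagged_shift <- flagged_shift + cf$flagged[cf$covariate == "age"]
    flagged_null <- flagged_null + cf$flagged[cf$covariate == "noise"]
  }
  expect_gt(flagged_shift / 40, 0.85)  # powered
  expect_lt(flagged_null / 40, 0.20)   # near nominal type I

  st$samples$const <- 1
  expect_message(detect_confounders(st, covariates = "const"), "constant")
})

test_that("confounder adjustment obeys the printed ratio identity", {
  # direct evaluation: y = 10, X = 2, beta1 = 0.3
  expect_equal(as.numeric(adjust_confounder(10, 2, beta1 = 0.3)),
               10 * exp(-0.6), tolerance = 1e-12)

  set.seed(11)
  y <- matrix(rexp(5 * 30, 0.01), 5)
  x <- rnorm(30, 60, 10)
  adj <- adjust_confounder(y, x)
  b1 <- attr(adj, "beta")$beta1
  for (s in 1:5) {
    lhs <- outer(adj[s, ], adj[s, ], "/")
    rhs <- outer(y[s, ], y[s, ], "/") * exp(-outer(x, x, "-") * b1[s])
    expect_lt(max(abs(lhs - rhs)), 1e-12)
  }

  # residualisation: refitting the slope after adjustment gives ~0
  beta_true <- 0.08
  x2 <- rnorm(200, 0, 5)
  y2 <- exp(3 + beta_true * x2 + rnorm(200, 0, 0.2))
  adj2 <- adjust_confounder(y2, x2, pseudocount = 0)
  refit <- coef(lm(log(adj2) ~ x2))[2]
  expect_lt(abs(refit), 1e-10)

  # beta1 = 0 leaves abundances unchanged
  expect_equal(as.numeric(adjust_confounder(y2, x2, beta1 = 0)), y2)
  expect_warning(adjust_confounder(y2, rep(1, 200)), "zero variance")
})

test_that("the stratified Mann-Whitney reduces to the standard test", {
  set.seed(12)
  x <- c(rnorm(12), rnorm(10, 0.8))
  g <- rep(c("control", "case"), c(12, 10))
  ours <- stratified_mannwhitney(x, g)
  ref <- wilcox.test(x[g == "case"], x[g == "control"],
                     exact = FALSE, correct = FALSE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)

  # with ties
  xt <- round(x)
  ours_t <- stratified_mannwhitney(xt, g)
  ref_t <- wilcox.test(xt[g == "case"], xt[g == "control"],
                       exact = FALSE, correct = FALSE)
  expect_equal(ours_t$p_value, ref_t$p.value, tolerance = 1e-12)
})

test_that("the stratified test matches a hand-computed toy statistic", {
  # stratum 1: controls (1, 2, 3), cases (4, 5, 6); stratum 2: controls
  # (10, 20, 30), cases (5, 15, 25)
  x <- c(1, 2, 3, 4, 5, 6, 10, 20, 30, 5, 15, 25)
  g <- rep(rep(c("control", "case"), each = 3), 2)
  s <- rep(1:2, each = 6)
  # hand computation with weights 1/(n_s + 1) and tie-free variance
  w1 <- 4 + 5 + 6; e1 <- 3 * 7 / 2; v1 <- 3 * 3 * 7 / 12
  w2 <- 1 + 3 + 5; e2 <- e1; v2 <- v1
  tt <- (w1 - e1) / 7 + (w2 - e2) / 7
  vv <- v1 / 49 + v2 / 49
  z_hand <- tt / sqrt(vv)
  ours <- stratified_mannwhitney(x, g, strata = s)
  expect_equal(ours$z, z_hand, tolerance = 1e-12)
  expect_equal(ours$p_value, 2 * pnorm(-abs(z_hand)), tolerance = 1e-12)
})

test_that("stratification removes confounding that fools the pooled test", {
  set.seed(13)
  rejected_strat <- 0; rejected_pooled <- 0
  for (i in 1:30) {
    # two strata with opposite location shifts, no group effect within strata
    n <- 40
    stratum <- rep(1:2, each = n)
    # cases concentrated in stratum 2, which has higher abundance overall
    g <- c(rep(c("control", "case"), c(30, 10)),
           rep(c("control", "case"), c(10, 30)))
    x <- rnorm(2 * n) + ifelse(stratum == 2, 3, 0)
    rejected_strat <- rejected_strat +
      (stratified_mannwhitney(x, g, strata = stratum)$p_value < 0.05)
    rejected_pooled <- rejected_pooled +
      (wilcox.test(x[g == "case"], x[g == "control"])$p.value < 0.05)
  }
  expect_lt(rejected_strat / 30, 0.2)
  expect_gt(rejected_pooled / 30, 0.8)
})

test_that("rank-sum statistics behave on constructed toys", {
  # one species: every rank is 1, statistic = number of pairs
  st1 <- directional_study(list(c(5, 6, 7)), list(c(1, 2, 3)), "A")
  one <- st1
  one$counts <- one$counts["sp_target", , drop = FALSE]
  fit1 <- meta_rank_sum(one, n_perm = 0)
  expect_equal(unname(fit1$statistic_up), fit1$n_pairs[1])

  # species A max-enriched in every pair across 2 cohorts: up-statistic is
  # the minimum possible (= total pairs); verified against brute force
  ctl <- list(c(10, 11, 12), c(9, 10, 11))
  cas <- list(c(100, 110, 120), c(90, 100, 110))
  st2 <- directional_study(cas, ctl, c("A", "B"))
  fit2 <- meta_rank_sum(st2, n_perm = 0)
  expect_equal(unname(fit2$statistic_up["sp_target"]), sum(fit2$n_pairs))

  # brute-force enumeration of all pairs for the toy
  logab <- log(sweep(st2$counts + 0.5, 2, colSums(st2$counts + 0.5), "/"))
  brute <- numeric(nrow(logab))
  for (co in c("A", "B")) {
    i <- which(st2$samples$cohort == co)
    for (ca in i[st2$samples$group[i] == "case"])
      for (cc in i[st2$samples$group[i] == "control"])
        brute <- brute + rank(-(logab[, ca] - logab[, cc]))
  }
  expect_equal(unname(fit2$statistic_up), unname(brute))

  # permutation equivariance: permuting species labels permutes statistics
  perm <- c(2, 3, 1)
  st3 <- st2
  st3$counts <- st3$counts[perm, ]
  fit3 <- meta_rank_sum(st3, n_perm = 0, seed = 99)
  fit2b <- meta_rank_sum(st2, n_perm = 0, seed = 99)
  expect_equal(unname(fit3$statistic_up), unname(fit2b$statistic_up[perm]))
})

test_that("single-cohort rank sums equal within-cohort aggregation", {
  st <- small_sim_study(seed = 3)
  co <- levels(st$samples$cohort)[1]
  keep <- st$samples$cohort == co
  sub <- structure(list(counts = st$counts[, keep],
                        samples = droplevels(st$samples[keep, ])),
                   class = "mm_study")
  fit_all <- meta_rank_sum(st, n_perm = 0, seed = 7)
  fit_one <- meta_rank_sum(sub, n_perm = 0, seed = 7)
  expect_equal(dim(fit_one$cohort_up), c(nrow(st$counts), 1L))
  expect_equal(unname(fit_one$statistic_up),
               unname(fit_one$cohort_up[, 1]))
})

test_that("pfp is monotone, detects spikes, and respects the seed", {
  st <- small_sim_study(n_species = 60, n_effects = 6, fold_change = 4,
                        n_control = 20, n_case = 20, seed = 8)
  fit <- meta_rank_sum(st, n_perm = 30, seed = 9)
  # monotone along the ranked list
  ord <- order(fit$statistic_up)
  expect_true(all(diff(fit$pfp_up[ord]) >= -1e-12))
  # strong spikes reach small pfp
  eff <- attr(st, "truth")$effect_species
  expect_gt(mean(fit$pfp_up[eff] < 0.01), 0.8)
  # byte-identical reruns under the same seed
  fit2 <- meta_rank_sum(st, n_perm = 30, seed = 9)
  expect_identical(fit$pfp_up, fit2$pfp_up)
  expect_identical(fit$statistic_up, fit2$statistic_up)
})

test_that("fold-change pseudomedians and CIs match signed-rank theory", {
  # all pair log fold changes equal: zero-width interval at the common value
  # constant within-arm profiles give a constant per-pair log fold change
  ctl <- list(rep(1, 4)); cas <- list(rep(3, 4))
  stc <- directional_study(cas, ctl, "A")
  res <- pairwise_foldchange_ci(stc, "sp_target", pseudocount = 0)
  expect_lt(res$upper - res$lower, 1e-9)

  # 9 pairs (one case, nine controls): estimate and CI match the
  # Hodges-Lehmann / signed-rank enumeration computed from scratch
  ctl9 <- list(c(2L, 3L, 5L, 8L, 13L, 21L, 34L, 55L, 89L))
  cas9 <- list(10L)
  st9 <- directional_study(cas9, ctl9, "A")
  res9 <- pairwise_foldchange_ci(st9, "sp_target", pseudocount = 0.5)
  ra <- sweep(st9$counts + 0.5, 2, colSums(st9$counts + 0.5), "/")
  g <- st9$samples$group
  v <- log(ra["sp_target", g == "case"]) -
    log(ra["sp_target", g == "control"])
  walsh <- sort(c(outer(v, v, "+")[upper.tri(outer(v, v, "+"),
                                             diag = TRUE)] / 2))
  expect_equal(res9$estimate, median(walsh), tolerance = 1e-9)
  # k = smallest integer whose signed-rank CDF reaches alpha/2; the interval
  # [D_(k), D_(M-k+1)] then has coverage 1 - 2 P(W <= k - 1) >= 0.95
  k <- qsignrank(0.025, 9)
  expect_lt(psignrank(k - 1, 9), 0.025)
  expect_equal(c(res9$lower, res9$upper),
               c(walsh[k], walsh[length(walsh) - k + 1]), tolerance = 1e-9)

  # mirrored arm profiles give a symmetric fold-change multiset: estimate 0
  ctl_s <- list(c(5L, 20L, 5L, 20L))
  cas_s <- list(c(5L, 20L, 5L, 20L))
  st_s <- directional_study(cas_s, ctl_s, "A")
  res_s <- pairwise_foldchange_ci(st_s, "sp_target", pseudocount = 0)
  expect_equal(res_s$estimate, 0, tolerance = 1e-12)
})

test_that("stage trends are flagged only for monotone significant species", {
  set.seed(15)
  n <- 30
  mk_block <- function(mu) pmax(round(rnorm(n, mu, 3)), 0)
  counts <- rbind(
    sp_mono = c(mk_block(60), mk_block(40), mk_block(20)),
    sp_flat = c(mk_block(40), mk_block(40), mk_block(40)),
    sp_bump = c(mk_block(30), mk_block(60), mk_block(30)),
    sp_fill = 50L)
  colnames(counts) <- sprintf("s%03d", seq_len(3 * n))
  samples <- data.frame(
    sample_id = colnames(counts),
    cohort = rep(c("A", "B"), length.out = 3 * n),
    group = rep(c("control", "case", "case"), each = n),
    stage = c(rep(NA, n), rep("early", n), rep("late", n)),
    stringsAsFactors = FALSE)
  st <- join_metadata(counts, samples)
  res <- stage_trend(st)
  expect_true(res$flagged[res$species == "sp_mono"])
  expect_equal(res$direction[res$species == "sp_mono"], "decreasing")
  expect_false(res$flagged[res$species == "sp_flat"])
  expect_false(res$flagged[res$species == "sp_bump"])
})
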