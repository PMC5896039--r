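test_that("Fisher r-to-Z combination matches the closed form", {
  # two cohorts: r = 0.5 at n = 50 and r = 0.3 at n = 100
  comb <- meta_correlation(list(0.5, 0.3), n = c(50, 100))
  zbar <- (47 * atanh(0.5) + 97 * atanh(0.3)) / 144
  expect_equal(comb$z, zbar, tolerance = 1e-10)
  expect_equal(comb$r, tanh(zbar), tolerance = 1e-10)
  expect_equal(comb$r, 0.369, tolerance = 5e-3)
  expect_equal(comb$p, 2 * pnorm(-abs(zbar * sqrt(144))), tolerance = 1e-12)

  # identical correlations are a fixed point
  expect_equal(meta_correlation(list(0.4, 0.4, 0.4), n = c(30, 60, 90))$r,
               0.4, tolerance = 1e-12)
  # symmetric opposite correlations at equal n cancel
  expect_equal(meta_correlation(list(0.6, -0.6), n = c(40, 40))$r, 0)
  # single-cohort reduction is exact
  expect_equal(meta_correlation(list(0.37), n = 25)$r, 0.37,
               tolerance = 1e-12)
  expect_error(meta_correlation(list(1, 0.5), n = c(10, 10)), "infinite")
  expect_error(meta_correlation(list(0.2, 0.3), n = c(3, 50)), "n > 3")
})

test_that("matrix-valued meta-correlation combines element-wise", {
  r1 <- diag(3); r1[1, 2] <- r1[2, 1] <- 0.5
  r2 <- diag(3); r2[1, 2] <- r2[2, 1] <- 0.3
  comb <- meta_correlation(list(r1, r2), n = c(50, 100))
  expect_equal(comb$r[1, 2],
               tanh((47 * atanh(0.5) + 97 * atanh(0.3)) / 144),
               tolerance = 1e-12)
  expect_equal(diag(comb$r), rep(1, 3))
  expect_true(all(is.na(diag(comb$p))))
})

test_that("network construction thresholds edges monotonically", {
  set.seed(40)
  m <- 6
  r <- diag(m)
  p <- matrix(1, m, m)
  pairs <- rbind(c(1, 2), c(2, 3), c(4, 5))
  pv <- c(0.001, 0.03, 0.2)
  for (k in 1:3) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    r[i, j] <- r[j, i] <- 0.5
    p[i, j] <- p[j, i] <- pv[k]
  }
  net05 <- build_network(r, p, p_cut = 0.05)
  net01 <- build_network(r, p, p_cut = 0.01)
  expect_equal(as.integer(igraph::ecount(net05$graph)), 2L)
  expect_equal(as.integer(igraph::ecount(net01$graph)), 1L)
  e05 <- apply(igraph::as_edgelist(net05$graph), 1, paste, collapse = "-")
  e01 <- apply(igraph::as_edgelist(net01$graph), 1, paste, collapse = "-")
  expect_true(all(e01 %in% e05))

  all_ns <- build_network(r, matrix(1, m, m))
  expect_equal(as.integer(igraph::ecount(all_ns$graph)), 0L)
})

test_that("network metrics match hand-computed values", {
  # complete graph: E_global = 1
  rK <- matrix(0.5, 4, 4); diag(rK) <- 1
  pK <- matrix(0.001, 4, 4); diag(pK) <- NA
  netK <- build_network(rK, pK)
  mK <- network_metrics(netK)
  expect_equal(mK$global_efficiency, 1, tolerance = 1e-12)

  # 3-node path: E_global = (2/6) (1 + 1 + 1/2) = 5/6
  rP <- diag(3); pP <- matrix(1, 3, 3)
  rP[1, 2] <- rP[2, 1] <- 0.5; pP[1, 2] <- pP[2, 1] <- 0.01
  rP[2, 3] <- rP[3, 2] <- 0.5; pP[2, 3] <- pP[3, 2] <- 0.01
  netP <- build_network(rP, pP)
  mP <- network_metrics(netP)
  expect_equal(mP$global_efficiency, 5 / 6, tolerance = 1e-12)
  # two edges of weight 0.5: connectance = 4 * 0.5 / 9
  expect_equal(mP$connectance, 2 / 9, tolerance = 1e-12)
  # weighted degree centrality sums incident |r|
  expect_equal(unname(mP$centrality), c(0.5, 1.0, 0.5))

  # metrics are invariant under node relabelling
  perm <- c(3, 1, 2)
  rPp <- rP[perm, perm]; pPp <- pP[perm, perm]
  rownames(rPp) <- colnames(rPp) <- paste0("x", 1:3)
  mPp <- network_metrics(build_network(rPp, pPp))
  expect_equal(mPp$global_efficiency, mP$global_efficiency)
  expect_equal(mPp$connectance, mP$connectance)

  expect_error(network_metrics(build_network(diag(1),
                                             matrix(NA, 1, 1))), "2 nodes")
})

test_that("hub removal collapses a star while leaf removal does not", {
  m <- 6
  r <- diag(m); p <- matrix(1, m, m)
  for (j in 2:m) { r[1, j] <- r[j, 1] <- 0.8; p[1, j] <- p[j, 1] <- 0.001 }
  net <- build_network(r, p)
  g <- net$graph
  hubless <- igraph::induced_subgraph(g, setdiff(igraph::V(g)$name, "sp0001"))
  expect_equal(network_metrics(hubless)$global_efficiency, 0)
  leafless <- igraph::induced_subgraph(g, setdiff(igraph::V(g)$name,
                                                  "sp0002"))
  expect_gt(network_metrics(leafless)$global_efficiency, 0)

  rob <- robustness_analysis(net, n_random = 10, seed = 41)
  targeted <- rob[rob$order_type == "targeted", ]
  rand <- rob[rob$order_type == "random", ]
  # baseline at step 0 equals the full-network metrics
  full <- network_metrics(net)
  expect_equal(targeted$efficiency[1], full$global_efficiency)
  expect_equal(rand$efficiency[1], full$global_efficiency)
  expect_equal(rand$connectance[1], full$connectance)
  # targeted removal (hub first) is at or below the random curve
  expect_true(all(targeted$efficiency <=
                    rand$efficiency + 2 * rand$efficiency_se + 1e-9))
  expect_equal(targeted$efficiency[2], 0) # hub removed first
})

test_that("network comparison detects halved strengths, not identity", {
  set.seed(42)
  m <- 20
  r <- diag(m)
  p <- matrix(1, m, m)
  ut <- which(upper.tri(r))
  vals <- runif(length(ut), 0.2, 0.9)
  r[ut] <- vals; r <- pmax(r, t(r))
  sig <- sample(ut, 40)
  p[sig] <- 0.01; p <- pmin(p, t(p))
  netA <- build_network(r, p)
  same <- compare_networks(netA, netA)
  expect_gt(same$proportion_test$p_value, 0.9)
  expect_gt(same$strength_test$p_value, 0.9)

  r2 <- r / 2; diag(r2) <- 1
  netB <- build_network(r2, p)
  halved <- compare_networks(netA, netB)
  expect_lt(halved$strength_test$p_value, 1e-6)
  expect_gt(halved$proportion_test$p_value, 0.9)
})

test_that("two-block latent structure yields two clusters joined negatively", {
  # positive within blocks, negative between: the combined network keeps the
  # qualitative structure
  m <- 12
  rho <- matrix(-0.35, m, m)
  rho[1:6, 1:6] <- 0.55
  rho[7:12, 7:12] <- 0.55
  diag(rho) <- 1
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  rho <- rho + diag(max(0, -min(ev) + 0.01), m)
  rho <- stats::cov2cor(rho)
  sims <- lapply(1:2, function(k)
    simulate_correlated_composition(rho, omega = 1, n_samples = 250,
                                    depth = 1e4, seed = 42 + k))
  fits <- lapply(sims, function(s) sparcc(s$counts, n_iter = 5,
                                          seed = 50))
  # clip boundary estimates before the z transform
  rs <- lapply(fits, function(f) pmin(pmax(f$rho, -0.999), 0.999))
  comb <- meta_correlation(rs, n = c(250, 250))
  within <- c(comb$r[1:6, 1:6][upper.tri(diag(6))],
              comb$r[7:12, 7:12][upper.tri(diag(6))])
  between <- comb$r[1:6, 7:12]
  expect_gt(median(within), 0.2)
  expect_lt(median(between), -0.1)
})
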