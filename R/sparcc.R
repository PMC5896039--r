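#' SparCC basis correlations from compositional counts
#'
#' Estimates latent ("basis") correlations from log-ratio variances.
#' Per outer iteration the sample fractions are resampled from a
#' Dirichlet posterior (counts + `pseudocount`), the log-ratio variance
#' matrix `t_ij = var(log(x_i / x_j))` computed, basis variances solved from
#' the linear approximation under sparsity, and
#' `rho_ij = (w_i^2 + w_j^2 - t_ij) / (2 w_i w_j)`. The most strongly
#' correlated pair above `threshold` is iteratively excluded from the system
#' and the solve repeated (up to `x_iter` rounds); the final estimate is the
#' element-wise median over outer iterations, clipped to \[-1, 1\].
#'
#' @param counts Species x samples count matrix (>= 3 species, >= 10
#'   samples recommended).
#' @param n_iter Outer (resampling) iterations.
#' @param x_iter Exclusion rounds per iteration.
#' @param threshold Exclusion threshold on `|rho|`.
#' @param pseudocount Dirichlet prior pseudocount.
#' @param resample Resample fractions from the Dirichlet posterior
#'   (`TRUE`, the standard procedure) or use observed pseudocounted
#'   fractions directly (`FALSE`, deterministic and exactly invariant to
#'   per-sample scaling).
#' @param seed Optional integer seed.
#' @return Object of class `sparcc_fit`: `rho` (median basis correlation
#'   matrix), `omega2` (median basis variances), and the call parameters.
#' @export
sparcc <- function(counts, n_iter = 20, x_iter = 10, threshold = 0.1,
                   pseudocount = 1, resample = TRUE, seed = NULL) {
  m <- nrow(counts)
  if (m < 3) stop("need at least 3 species")
  .seed_in(seed)
  if (!resample) n_iter <- 1L
  rhos <- array(NA_real_, c(m, m, n_iter))
  om <- matrix(NA_real_, m, n_iter)
  for (it in seq_len(n_iter)) {
    frac <- if (resample) {
      apply(counts + pseudocount, 2, function(a) .rdirichlet(1, a)[, 1])
    } else {
      sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
    }
    tmat <- logratio_variance(frac)
    est <- .sparcc_solve(tmat, x_iter, threshold)
    rhos[, , it] <- est$rho
    om[, it] <- est$omega2
  }
  rho <- apply(rhos, c(1, 2), median)
  rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- 1
  dimnames(rho) <- list(rownames(counts), rownames(counts))
  structure(list(rho = rho, omega2 = rowMeans(om),
                 n_iter = n_iter, x_iter = x_iter, threshold = threshold,
                 n_samples = ncol(counts), resample = resample),
            class = "sparcc_fit")
}

# one exclusion-iterated basis solve from a log-ratio variance matrix
.sparcc_solve <- function(tmat, x_iter, threshold) {
  m <- nrow(tmat)
  excluded <- matrix(FALSE, m, m)
  basic <- NULL
  for (round in 0:x_iter) {
    mm <- matrix(1, m, m)
    mm[excluded] <- 0
    diag(mm) <- (m - 1) - rowSums(excluded)
    trow <- rowSums(tmat * !excluded)
    omega2 <- tryCatch(solve(mm, trow), error = function(e) NULL)
    if (is.null(omega2)) { warning("singular system; using basic estimate")
                           return(basic) }
    omega2 <- pmax(omega2, 1e-12)
    denom <- 2 * sqrt(outer(omega2, omega2))
    rho <- (outer(omega2, omega2, "+") - tmat) / denom
    diag(rho) <- 1
    rho <- pmin(pmax(rho, -1), 1)
    est <- list(rho = rho, omega2 = omega2)
    if (round == 0) basic <- est
    if (round == x_iter) return(est)
    cand <- abs(rho)
    cand[excluded | row(cand) >= col(cand)] <- 0
    top <- which.max(cand)
    if (cand[top] <= threshold) return(est)
    i <- row(cand)[top]; j <- col(cand)[top]
    # falling below 3 retained partners makes the system uninformative
    if (rowSums(excluded)[i] >= m - 4 || rowSums(excluded)[j] >= m - 4) {
      warning("too many excluded pairs; falling back to basic estimate")
      return(basic)
    }
    excluded[i, j] <- excluded[j, i] <- TRUE
  }
  est
}

#' @export
print.sparcc_fit <- function(x, ...) {
  off <- x$rho[upper.tri(x$rho)]
  cat(sprintf("SparCC fit: %d species, %d samples, %d iterations\n",
              nrow(x$rho), x$n_samples, x$n_iter))
  cat(sprintf("  |rho| median %.3f, max %.3f\n", median(abs(off)),
              max(abs(off))))
  invisible(x)
}

#' Permutation significance for SparCC correlations
#'
#' Each species' counts are permuted independently across samples (breaking
#' all between-species association while preserving margins), SparCC is
#' recomputed, and the two-sided p-value per pair is
#' `(1 + #{|rho_perm| >= |rho_obs|}) / (n_perm + 1)`.
#'
#' @param counts Species x samples count matrix.
#' @param fit A [sparcc()] fit of `counts`.
#' @param n_perm Number of permutations (>= 99 for a 0.05 cutoff).
#' @param n_iter Outer iterations used for each permutation fit.
#' @param seed Optional integer seed.
#' @return Symmetric p-value matrix (diagonal `NA`).
#' @export
sparcc_significance <- function(counts, fit, n_perm = 100, n_iter = 5,
                                seed = NULL) {
  .seed_in(seed)
  m <- nrow(counts)
  hits <- matrix(0, m, m)
  for (b in seq_len(n_perm)) {
    pc <- counts
    for (s in seq_len(m)) pc[s, ] <- pc[s, sample.int(ncol(pc))]
    rp <- sparcc(pc, n_iter = n_iter, x_iter = fit$x_iter,
                 threshold = fit$threshold, resample = fit$resample)$rho
    hits <- hits + (abs(rp) >= abs(fit$rho))
  }
  p <- (1 + hits) / (n_perm + 1)
  diag(p) <- NA
  dimnames(p) <- dimnames(fit$rho)
  p
}
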