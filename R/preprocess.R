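#' Exclude low-depth samples
#'
#' Removes samples whose total read count is unusually low, either below an
#' absolute `min_reads` or, by default, below
#' `median - mad_mult * MAD` of log10 depths within each cohort (a robust
#' per-cohort outlier rule).
#'
#' @param study An `mm_study`, or a count matrix when `min_reads` is given.
#' @param min_reads Absolute minimum total read count; overrides the MAD rule.
#' @param mad_mult MAD multiplier of the per-cohort robust rule.
#' @return Same type as the input, with low-depth samples removed.
#' @export
exclude_low_depth_samples <- function(study, min_reads = NULL, mad_mult = 5) {
  is_study <- inherits(study, "mm_study")
  counts <- if (is_study) study$counts else study
  depth <- colSums(counts)
  if (!is.null(min_reads)) {
    drop <- depth < min_reads
  } else {
    if (!is_study) stop("the MAD rule needs cohort labels; supply min_reads")
    drop <- logical(ncol(counts))
    for (idx in .cohort_index(study)) {
      ld <- log10(depth[idx])
      cut <- median(ld) - mad_mult * stats::mad(ld)
      drop[idx] <- ld < cut
    }
  }
  if (all(drop)) stop("all samples fall below the depth threshold")
  if (any(drop))
    message("excluding ", sum(drop), " low-depth sample(s): ",
            paste(sprintf("%s (%d reads)", colnames(counts)[drop],
                          depth[drop]), collapse = ", "))
  if (is_study) {
    study$counts <- counts[, !drop, drop = FALSE]
    study$samples <- study$samples[!drop, , drop = FALSE]
    study
  } else counts[, !drop, drop = FALSE]
}

#' Rarefy counts to a per-cohort depth
#'
#' Subsamples each sample's reads without replacement to the target depth.
#' The default target is the minimum column sum within each cohort, so
#' cohorts retain their different depths. Wraps [vegan::rrarefy()].
#'
#' @param study An `mm_study`, or a count matrix (single cohort).
#' @param target Target depth; `NULL` uses the per-cohort minimum column sum.
#' @param seed Optional integer seed.
#' @return Same type as the input with every sample summing to its cohort's
#'   target.
#' @export
rarefy_counts <- function(study, target = NULL, seed = NULL) {
  .seed_in(seed)
  is_study <- inherits(study, "mm_study")
  counts <- if (is_study) study$counts else study
  groups <- if (is_study) .cohort_index(study)
            else list(seq_len(ncol(counts)))
  for (idx in groups) {
    depths <- colSums(counts[, idx, drop = FALSE])
    tgt <- if (is.null(target)) min(depths) else target
    low <- depths < tgt
    if (any(low))
      stop("rarefaction target ", tgt, " exceeds depth of sample(s): ",
           paste(colnames(counts)[idx][low], collapse = ", "))
    # rrarefy's "observed counts" heuristic misfires on toys whose smallest
    # non-zero count exceeds 1; inputs are already validated as integer
    counts[, idx] <- t(suppressWarnings(
      vegan::rrarefy(t(counts[, idx, drop = FALSE]), tgt)))
  }
  storage.mode(counts) <- "integer"
  if (is_study) { study$counts <- counts; study } else counts
}

#' Relative abundance
#'
#' @param counts Count matrix (species x samples).
#' @return Matrix of per-sample fractions (columns sum to one).
#' @export
relative_abundance <- function(counts) {
  sweep(counts, 2, colSums(counts), "/")
}

#' Shannon diversity (nats)
#'
#' `H = -sum(p * log(p))` over the non-zero entries of each sample column,
#' in natural-log units.
#'
#' @param am Relative-abundance matrix (columns sum to one) or count matrix
#'   (normalised internally).
#' @return Named numeric vector, one value per sample.
#' @export
shannon_diversity <- function(am) {
  am <- relative_abundance(am)
  apply(am, 2, function(p) { p <- p[p > 0]; -sum(p * log(p)) })
}

#' Bray-Curtis dissimilarity and principal coordinates
#'
#' Computes the Bray-Curtis dissimilarity between samples (via
#' [vegan::vegdist()]) and embeds it by classical multidimensional scaling.
#' Axes with negative eigenvalues are dropped with a warning; each retained
#' axis is oriented so its largest-magnitude coordinate is positive.
#'
#' @param am Relative-abundance (or count) matrix, species x samples.
#' @param k Number of coordinate axes requested.
#' @return List with `dissimilarity` (a `dist`), `points`
#'   (samples x k coordinates), `eig` (eigenvalues) and
#'   `variance_explained`.
#' @export
bray_curtis_pcoa <- function(am, k = 2) {
  if (ncol(am) < 3) stop("need at least 3 samples")
  am <- relative_abundance(am)
  d <- vegan::vegdist(t(am), method = "bray")
  mds <- cmdscale(d, k = min(k, ncol(am) - 1), eig = TRUE)
  neg <- sum(mds$eig < -1e-12)
  if (neg > 0)
    warning(neg, " negative eigenvalue(s) dropped from the embedding")
  pts <- mds$points
  for (j in seq_len(ncol(pts)))
    if (pts[which.max(abs(pts[, j])), j] < 0) pts[, j] <- -pts[, j]
  pos <- mds$eig[mds$eig > 0]
  list(dissimilarity = d, points = pts, eig = mds$eig,
       variance_explained = pos[seq_len(ncol(pts))] / sum(pos))
}

#' PERMANOVA on a dissimilarity matrix
#'
#' Permutational multivariate analysis of variance via [vegan::adonis2()];
#' the permutation p-value is `(1 + #{F_perm >= F_obs}) / (n_perm + 1)`.
#'
#' @param dissim A `dist` object (e.g. from [bray_curtis_pcoa()]).
#' @param labels Grouping vector, one label per sample.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Optional integer seed.
#' @return List with `f` (pseudo-F), `p_value`, `r2` and `n_perm`.
#' @export
permanova_test <- function(dissim, labels, n_perm = 999, seed = NULL) {
  if (n_perm < 99) stop("use at least 99 permutations")
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least two groups")
  if (any(table(labels) < 2)) stop("every group needs at least two samples")
  .seed_in(seed)
  df <- data.frame(labels = labels)
  fit <- vegan::adonis2(dissim ~ labels, data = df, permutations = n_perm)
  list(f = fit$F[1], p_value = fit$`Pr(>F)`[1], r2 = fit$R2[1],
       n_perm = n_perm)
}
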