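#' Copies-per-million normalisation
#'
#' Scales every sample column of a functional-category abundance table to a
#' total of one million.
#'
#' @param x Categories x samples non-negative matrix.
#' @return Matrix whose columns each sum to 1e6.
#' @export
normalize_cpm <- function(x) {
  if (any(x < 0)) stop("abundances must be non-negative")
  cs <- colSums(x)
  if (any(cs == 0))
    stop("zero column sum for sample(s): ",
         paste(colnames(x)[cs == 0], collapse = ", "))
  sweep(x, 2, cs / 1e6, "/")
}

#' Differential functional categories across cohorts (MaxP combination)
#'
#' Per category and cohort, a stratified Mann-Whitney test (strata from
#' `covariate` quantile bins when present) gives a one-sided p-value
#' oriented by the consensus change direction (the sign of the summed
#' per-cohort median differences). The combined statistic is the maximum
#' one-sided p over the K cohorts; since the maximum of K independent
#' uniforms has CDF `u^K`, the combined p-value is `(max p)^K` — significant
#' only when every cohort agrees. BH-FDR is applied across categories.
#'
#' @param ft Categories x samples abundance table (e.g. CPM).
#' @param study The `mm_study` providing cohort/group (and covariate)
#'   metadata aligned with `ft` columns.
#' @param covariate Stratification covariate name (default `"age"`; skipped
#'   when absent).
#' @param n_strata Quantile bins for the covariate.
#' @param fdr BH significance level.
#' @return Data frame with category, consensus direction, per-cohort maximum
#'   p, combined p, BH-adjusted q and significance.
#' @export
differential_categories <- function(ft, study, covariate = "age",
                                    n_strata = 4, fdr = 0.05) {
  idx <- .cohort_index(study)
  if (length(idx) < 2) stop("need at least 2 cohorts")
  case <- study$samples$group == "case"
  K <- length(idx)
  covar <- study$samples[[covariate]]
  out <- lapply(seq_len(nrow(ft)), function(ci) {
    x <- ft[ci, ]
    deltas <- vapply(idx, function(i)
      median(x[i][case[i]]) - median(x[i][!case[i]]), 0)
    dirn <- if (sum(sign(deltas)) >= 0) 1 else -1
    p_one <- vapply(idx, function(i) {
      strata <- if (!is.null(covar) && !anyNA(covar[i]))
        .quantile_bins(covar[i], n_strata) else rep(1L, length(i))
      z <- stratified_mannwhitney(x[i], case[i], strata = strata)$z
      pnorm(-z * dirn)
    }, 0)
    data.frame(category = rownames(ft)[ci],
               direction = if (dirn > 0) "enriched" else "depleted",
               max_p = max(p_one), p_combined = max(p_one)^K,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$q <- p.adjust(res$p_combined, method = "BH")
  res$significant <- res$q < fdr
  res
}

#' Spearman association between species and functional categories
#'
#' Spearman correlations (average ranks) between every species and category
#' pair, two-sided p-values from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`, and BH adjustment across all
#' tested pairs. Pairs with a constant vector are skipped.
#'
#' @param species_ab Species x samples abundance matrix.
#' @param ft Categories x samples abundance matrix (same samples).
#' @param fdr BH significance level.
#' @return Data frame of (species, category) pairs with `rho`, `p`, `q`,
#'   `significant` (q < fdr) and `positive`.
#' @export
spearman_association <- function(species_ab, ft, fdr = 0.05) {
  if (ncol(species_ab) != ncol(ft)) stop("sample columns must match")
  if (ncol(ft) < 10) stop("need at least 10 paired samples")
  n <- ncol(ft)
  const_s <- apply(species_ab, 1, function(v) length(unique(v)) == 1)
  const_c <- apply(ft, 1, function(v) length(unique(v)) == 1)
  if (any(const_s) || any(const_c))
    message("skipping ", sum(const_s), " constant species and ",
            sum(const_c), " constant categories")
  rho <- suppressWarnings(
    cor(t(species_ab), t(ft), method = "spearman"))
  rho[const_s, ] <- NA
  rho[, const_c] <- NA
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-300))
  p <- 2 * pt(-abs(tt), df = n - 2)
  df <- data.frame(
    species = rep(rownames(species_ab), times = nrow(ft)),
    category = rep(rownames(ft), each = nrow(species_ab)),
    rho = as.vector(rho), p = as.vector(p), stringsAsFactors = FALSE)
  df <- df[!is.na(df$rho), , drop = FALSE]
  df$q <- p.adjust(df$p, method = "BH")
  df$significant <- df$q < fdr
  df$positive <- df$rho > 0
  rownames(df) <- NULL
  df
}

#' Group associated categories into pathways
#'
#' Maps the significantly (positively, by default) associated categories of
#' a [spearman_association()] result onto pathways and keeps pathways hit by
#' at least `min_hits` distinct categories. Unmapped categories are counted
#' in a message.
#'
#' @param assoc [spearman_association()] result.
#' @param map Data frame with columns `category` and `pathway`.
#' @param min_hits Minimum distinct associated categories per pathway.
#' @param positive_only Restrict to positive associations.
#' @return Data frame with pathway, hit count and member categories.
#' @export
group_by_pathway <- function(assoc, map, min_hits = 2, positive_only = TRUE) {
  sig <- assoc[assoc$significant & (!positive_only | assoc$positive), ,
               drop = FALSE]
  cats <- unique(sig$category)
  unmapped <- setdiff(cats, map$category)
  if (length(unmapped))
    message(length(unmapped), " associated categories without a pathway mapping")
  hits <- map[map$category %in% cats, , drop = FALSE]
  if (!nrow(hits))
    return(data.frame(pathway = character(), n_hits = integer(),
                      categories = character()))
  sp <- split(unique(hits[c("pathway", "category")])$category,
              unique(hits[c("pathway", "category")])$pathway)
  out <- data.frame(pathway = names(sp),
                    n_hits = vapply(sp, length, 0L),
                    categories = vapply(sp, paste, "", collapse = ";"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[out$n_hits >= min_hits, , drop = FALSE]
  out[order(-out$n_hits), ]
}
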