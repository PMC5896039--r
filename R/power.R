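#' Statistical-power experiment for the rank-sum meta-analysis
#'
#' Per replicate and fold change: a fresh multi-cohort study is simulated
#' from the Dirichlet-multinomial generator, the enrichment rank-sum
#' statistic computed, the `top_k` species with the smallest statistics
#' selected, and the recovered fraction of truly spiked species recorded.
#' The meta-analysis design sums ranks across all cohorts; with
#' `include_single = TRUE` each cohort is additionally evaluated alone
#' (within-cohort rank aggregation) from the same simulated data.
#'
#' @param dm [dm_params()] template; base composition and effect set are
#'   re-drawn each replicate unless fixed in the template. Its
#'   `fold_change` is overridden by `fold_changes`.
#' @param designs List of [cohort_design()]s (default four-cohort design).
#' @param fold_changes Multiplicative case fold changes to evaluate.
#' @param n_reps Replicates per fold change.
#' @param top_k Number of species selected (defaults to the effect-set size).
#' @param pair_cap Maximum case-control pairs per cohort.
#' @param pseudocount Reads added before normalisation.
#' @param include_single Also evaluate each cohort alone.
#' @param seed Optional integer seed.
#' @return Object of class `power_result`: a data frame with one row per
#'   (design, fold change, replicate) and the recovered fraction.
#' @export
run_power_experiment <- function(dm = dm_params(),
                                 designs = default_cohort_designs(),
                                 fold_changes = c(1.1, 1.2, 1.4),
                                 n_reps = 50, top_k = NULL, pair_cap = 2000,
                                 pseudocount = 0.5, include_single = TRUE,
                                 seed = NULL) {
  .seed_in(seed)
  if (is.null(top_k))
    top_k <- if (is.null(dm$effect_species)) dm$n_effects
             else length(dm$effect_species)
  rows <- list()
  for (f in fold_changes) {
    for (r in seq_len(n_reps)) {
      real <- .dm_realise(dm)
      pi1 <- .case_composition(real$pi0, real$effect, f)
      ups <- matrix(0, dm$n_species, length(designs),
                    dimnames = list(NULL, names(designs)))
      for (k in seq_along(designs)) {
        d <- designs[[k]]
        counts <- .sim_cohort_counts(real$pi0, pi1, dm$theta, d)
        logab <- .rel_log_abundance(counts, pseudocount)
        ups[, k] <- .cohort_rank_sums(
          logab, seq_len(d$n_control), d$n_control + seq_len(d$n_case),
          pair_cap, both = FALSE)$up
      }
      rec <- function(stat) mean(order(stat)[seq_len(top_k)] %in% real$effect)
      rows[[length(rows) + 1L]] <- data.frame(
        design = "meta", fold_change = f, rep = r,
        size = sum(vapply(designs, function(d) d$n_control * d$n_case, 0)),
        recovered = rec(rowSums(ups)), stringsAsFactors = FALSE)
      if (include_single)
        for (k in seq_along(designs))
          rows[[length(rows) + 1L]] <- data.frame(
            design = names(designs)[k], fold_change = f, rep = r,
            size = designs[[k]]$n_control * designs[[k]]$n_case,
            recovered = rec(ups[, k]), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "top_k") <- top_k
  attr(out, "n_species") <- dm$n_species
  class(out) <- c("power_result", "data.frame")
  out
}

#' Power curve table
#'
#' Aggregates a [run_power_experiment()] result into mean power with
#' Monte-Carlo standard errors per design and fold change.
#'
#' @param results A `power_result`.
#' @return Data frame with design, sample-size product, fold change, power
#'   and SE.
#' @export
power_curve <- function(results) {
  if (!nrow(results)) stop("empty power result")
  agg <- aggregate(recovered ~ design + size + fold_change, data = results,
                   function(v) c(power = mean(v),
                                 se = sd(v) / sqrt(length(v)),
                                 n = length(v)))
  out <- data.frame(agg[, c("design", "size", "fold_change")],
                    power = agg$recovered[, "power"],
                    se = agg$recovered[, "se"],
                    n_reps = agg$recovered[, "n"])
  out[order(out$fold_change, -out$size), ]
}

#' @export
print.power_result <- function(x, ...) {
  cat("Rank-sum power experiment\n")
  print(power_curve(x), row.names = FALSE)
  invisible(x)
}

#' @export
plot.power_result <- function(x, ...) {
  pc <- power_curve(x)
  fcs <- sort(unique(pc$fold_change))
  cols <- seq_along(fcs)
  plot(NA, xlim = range(pc$size), ylim = c(0, 1), log = "x",
       xlab = "control x case sample-size product", ylab = "power", ...)
  for (i in seq_along(fcs)) {
    sub <- pc[pc$fold_change == fcs[i], ]
    sub <- sub[order(sub$size), ]
    lines(sub$size, sub$power, col = cols[i], type = "b",
          pch = ifelse(sub$design == "meta", 19, 1))
  }
  legend("bottomright", legend = sprintf("fold change %.1f", fcs),
         col = cols, lty = 1, bty = "n")
  invisible(x)
}
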