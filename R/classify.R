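#' ROC curve and AUC
#'
#' AUC by the rank (Mann-Whitney) formula, ties counted one half:
#' `AUC = (sum of case ranks - n_case (n_case + 1) / 2) / (n_case n_control)`.
#'
#' @param scores Numeric classifier scores (larger = more case-like).
#' @param labels Factor/character/logical labels; `case` (or `TRUE`) is the
#'   positive class.
#' @return List with `auc` and a data frame `roc` of (fpr, tpr, threshold)
#'   points.
#' @export
roc_auc <- function(scores, labels) {
  case <- .as_case(labels)
  n1 <- as.numeric(sum(case)); n0 <- as.numeric(sum(!case))
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  last <- cumsum(rle(s)$lengths) # tie-block ends
  tpr <- cumsum(case[ord])[last] / n1
  fpr <- cumsum(!case[ord])[last] / n0
  list(auc = auc,
       roc = data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                        threshold = c(Inf, s[last])))
}

.as_case <- function(labels) {
  if (is.logical(labels)) return(labels)
  g <- factor(labels)
  if ("case" %in% levels(g)) g == "case" else g == levels(g)[nlevels(g)]
}

#' Optimal F1 score over all thresholds
#'
#' Evaluates the F1 score (harmonic mean of precision and recall, `case`
#' positive) at every distinct score threshold and returns the maximum with
#' the full path. Thresholds with no predicted positives score 0.
#'
#' @param scores Numeric classifier scores.
#' @param labels Labels (`case` positive).
#' @return List with `f1` (maximum), `threshold`, and `path` (data frame of
#'   threshold, precision, recall, f1; one row per distinct score).
#' @export
optimal_f1 <- function(scores, labels) {
  case <- .as_case(labels)
  if (!any(case) || all(case)) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  last <- cumsum(rle(s)$lengths) # predicted-positive counts per threshold
  tp <- cumsum(case[ord])[last]
  prec <- tp / last
  rec <- tp / sum(case)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  path <- data.frame(threshold = rev(s[last]), precision = rev(prec),
                     recall = rev(rec), f1 = rev(f1))
  best <- which.max(path$f1)
  list(f1 = path$f1[best], threshold = path$threshold[best], path = path)
}

# median-heuristic inverse bandwidth for the radial kernel
.median_gamma <- function(x, max_points = 200) {
  if (nrow(x) > max_points) x <- x[sample.int(nrow(x), max_points), ,
                                   drop = FALSE]
  d <- dist(x)
  h <- median(d[d > 0])
  if (!is.finite(h) || h == 0) return(1 / ncol(x))
  1 / (2 * h^2)
}

# impute NA by training medians and standardise with training statistics
.fold_standardise <- function(x_train, x_test) {
  med <- apply(x_train, 2, median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  for (j in seq_len(ncol(x_train))) {
    x_train[is.na(x_train[, j]), j] <- med[j]
    x_test[is.na(x_test[, j]), j] <- med[j]
  }
  mu <- colMeans(x_train)
  sdv <- apply(x_train, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(train = sweep(sweep(x_train, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(x_test, 2, mu), 2, sdv, "/"))
}

# fit a radial SVM on training data and score test samples (case-positive)
.svm_score <- function(x_train, y_train, x_test, cost = 1, gamma = NULL) {
  if (nlevels(droplevels(y_train)) < 2)
    stop("a class is missing in the training data")
  std <- .fold_standardise(x_train, x_test)
  if (is.null(gamma)) gamma <- .median_gamma(std$train)
  fit <- e1071::svm(std$train, y_train, kernel = "radial", cost = cost,
                    gamma = gamma, scale = FALSE)
  pred <- stats::predict(fit, std$test, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  s <- dv[, 1]
  if (!grepl("^case", colnames(dv)[1])) s <- -s
  s
}

# stratified fold assignment: folds balanced within each class (and cohort)
.stratified_folds <- function(labels, k, cohort = NULL) {
  fold <- integer(length(labels))
  strat <- if (is.null(cohort)) as.character(labels)
           else paste(cohort, labels)
  for (s in split(seq_along(labels), strat))
    fold[s] <- sample(rep_len(seq_len(k), length(s)))
  fold
}

#' Cross-validated radial-kernel SVM evaluation
#'
#' Stratified k-fold cross-validation: the model is fitted on k-1 folds and
#' scores the held-out fold; imputation and standardisation statistics come
#' from the training folds only. The radial-kernel inverse bandwidth uses
#' the median heuristic unless given.
#'
#' @param features Samples x features numeric matrix.
#' @param labels Class labels (`case` positive).
#' @param k Number of folds.
#' @param cohort Optional cohort labels; folds are then stratified by class
#'   within cohort.
#' @param cost,gamma SVM hyperparameters (`gamma = NULL`: median heuristic).
#' @param seed Optional integer seed (fold assignment).
#' @return Object of class `eval_report`: per-sample out-of-fold scores and
#'   fold ids, pooled AUC, per-fold AUCs, ROC points and the optimal-F1
#'   path.
#' @export
evaluate_cv <- function(features, labels, k = 10, cohort = NULL, cost = 1,
                        gamma = NULL, seed = NULL) {
  .seed_in(seed)
  features <- as.matrix(features)
  labels <- factor(.as_case(labels), levels = c(FALSE, TRUE),
                   labels = c("control", "case"))
  if (min(table(labels)) < k)
    stop("need at least k samples in each class for stratified folds")
  fold <- .stratified_folds(labels, k, cohort)
  scores <- numeric(length(labels))
  for (f in seq_len(k)) {
    tr <- fold != f
    scores[!tr] <- .svm_score(features[tr, , drop = FALSE], labels[tr],
                              features[!tr, , drop = FALSE], cost, gamma)
  }
  ra <- roc_auc(scores, labels)
  fold_auc <- vapply(seq_len(k), function(f)
    roc_auc(scores[fold == f], labels[fold == f])$auc, 0)
  f1 <- optimal_f1(scores, labels)
  structure(list(scores = scores, labels = labels, fold = fold,
                 auc = ra$auc, fold_auc = fold_auc,
                 mean_fold_auc = mean(fold_auc), roc = ra$roc,
                 optimal_f1 = f1$f1, f1_path = f1$path, scheme = "cv"),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Classifier evaluation (%s): pooled AUC %.3f", x$scheme, x$auc))
  if (!is.null(x$mean_fold_auc))
    cat(sprintf(", mean per-fold AUC %.3f", x$mean_fold_auc))
  cat(sprintf(", optimal F1 %.3f\n", x$optimal_f1))
  invisible(x)
}

#' @export
plot.eval_report <- function(x, ...) {
  plot(x$roc$fpr, x$roc$tpr, type = "l", xlab = "false positive rate",
       ylab = "true positive rate", ...)
  abline(0, 1, lty = 3)
  invisible(x)
}

#' Leave-one-cohort-out evaluation with marker re-selection
#'
#' For each cohort: the full marker-selection path (divergence filter, then
#' rank-sum meta-analysis with pfp selection) is run on the remaining
#' cohorts only, a radial SVM is trained on those cohorts' log relative
#' abundances of the selected markers, and the held-out cohort is scored.
#' When fewer than `min_markers` species pass the pfp cutoff, the top
#' `min_markers` by rank-sum statistic are used.
#'
#' @param study An `mm_study` with >= 2 cohorts.
#' @param pfp_cut pfp selection threshold.
#' @param n_perm Permutations for pfp inside each training run.
#' @param pair_cap Pair cap for the training rank-sum.
#' @param min_markers Minimum marker-panel size.
#' @param cost,gamma SVM hyperparameters.
#' @param pseudocount Reads added before normalisation.
#' @param seed Optional integer seed.
#' @return List of class `loco_report`: per-cohort `eval_report`s
#'   (scheme "loco"), selected markers, and `mean_auc`.
#' @export
evaluate_loco <- function(study, pfp_cut = 0.01, n_perm = 50,
                          pair_cap = 500, min_markers = 5, cost = 1,
                          gamma = NULL, pseudocount = 0.5, seed = NULL) {
  .seed_in(seed)
  cohorts <- levels(study$samples$cohort)
  if (length(cohorts) < 2) stop("need at least 2 cohorts")
  logab <- .rel_log_abundance(study$counts, pseudocount)
  reports <- list()
  for (co in cohorts) {
    ho <- study$samples$cohort == co
    tr_study <- structure(list(
      counts = study$counts[, !ho, drop = FALSE],
      samples = droplevels(study$samples[!ho, , drop = FALSE])),
      class = "mm_study")
    dt <- direction_summary(tr_study)
    keep <- which(divergence_filter(dt, tr_study) == "kept")
    fit <- meta_rank_sum(tr_study, species = keep, pair_cap = pair_cap,
                         pseudocount = pseudocount, n_perm = n_perm)
    markers <- fit$species[fit$pfp_up < pfp_cut | fit$pfp_down < pfp_cut]
    if (length(markers) < min_markers) {
      ord <- order(pmin(rank(fit$statistic_up), rank(fit$statistic_down)))
      markers <- unique(c(markers, fit$species[ord]))[seq_len(min_markers)]
    }
    x <- t(logab[markers, , drop = FALSE])
    y <- factor(ifelse(study$samples$group == "case", "case", "control"),
                levels = c("control", "case"))
    scores <- .svm_score(x[!ho, , drop = FALSE], y[!ho],
                         x[ho, , drop = FALSE], cost, gamma)
    ra <- roc_auc(scores, y[ho])
    f1 <- optimal_f1(scores, y[ho])
    reports[[co]] <- structure(
      list(scores = scores, labels = y[ho], fold = NULL, auc = ra$auc,
           fold_auc = NULL, mean_fold_auc = NULL, roc = ra$roc,
           optimal_f1 = f1$f1, f1_path = f1$path, scheme = "loco",
           markers = markers), class = "eval_report")
  }
  structure(list(reports = reports,
                 mean_auc = mean(vapply(reports, `[[`, 0, "auc"))),
            class = "loco_report")
}

#' @export
print.loco_report <- function(x, ...) {
  cat("Leave-one-cohort-out evaluation\n")
  for (co in names(x$reports))
    cat(sprintf("  held-out %s: AUC %.3f (%d markers)\n", co,
                x$reports[[co]]$auc, length(x$reports[[co]]$markers)))
  cat(sprintf("  mean AUC %.3f\n", x$mean_auc))
  invisible(x)
}

#' Append clinical covariates to a feature table
#'
#' Adds the requested metadata covariates as feature columns (categorical
#' covariates are coded as 0/1 dummies); covariates that are entirely
#' missing are skipped with a warning. Missing values are left as `NA` so
#' that [evaluate_cv()] imputes them from training folds only.
#'
#' @param features Samples x features matrix.
#' @param samples Metadata data frame aligned with the feature rows.
#' @param covariates Covariate column names.
#' @return The augmented feature matrix, columns in deterministic order.
#' @export
augment_covariates <- function(features, samples,
                               covariates = c("age", "sex", "bmi")) {
  features <- as.matrix(features)
  for (v in covariates) {
    x <- samples[[v]]
    if (is.null(x) || all(is.na(x))) {
      warning("covariate ", v, " absent or entirely missing; skipped")
      next
    }
    if (!is.numeric(x)) x <- as.numeric(factor(x)) - 1
    features <- cbind(features, setNames(data.frame(x), v))
  }
  as.matrix(features)
}

#' Optimal-F1 distributions under class imbalance
#'
#' At a fixed generator AUC, simulates binormal classifier scores for a
#' balanced and an imbalanced design and records the optimal F1 per
#' simulation — the accuracy-paradox demonstration: at the same AUC, the
#' optimal F1 drops as cases become rare.
#'
#' @param n_control Controls per design.
#' @param n_case Vector of case counts (one design each).
#' @param target_auc Generator AUC.
#' @param n_sims Simulations per design.
#' @param seed Optional integer seed.
#' @return Data frame with design label, case count, simulation index and
#'   optimal F1.
#' @export
imbalance_f1_simulation <- function(n_control = 271, n_case = c(255, 30),
                                    target_auc = 0.8, n_sims = 500,
                                    seed = NULL) {
  .seed_in(seed)
  out <- list()
  for (nc in n_case) {
    lab <- sprintf("%d/%d", n_control, nc)
    f1 <- vapply(seq_len(n_sims), function(i) {
      sim <- simulate_classifier_scores(n_control, nc, target_auc)
      optimal_f1(sim$scores, sim$labels)$f1
    }, 0)
    out[[lab]] <- data.frame(design = lab, n_case = nc,
                             sim = seq_len(n_sims), f1 = f1,
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
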