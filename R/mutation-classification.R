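#' Balance a binary classification set by minority oversampling
#'
#' Duplicates minority-class rows until both classes have equal counts:
#' whole copies of the minority set are cycled in deterministically, and
#' the remainder is a seeded draw without replacement. Original rows are
#' never modified, and the provenance index maps every row of the balanced
#' set back to its source row, so leakage of duplicates across
#' cross-validation splits can be audited.
#'
#' @param X Feature matrix or data frame.
#' @param y Binary 0/1 labels (both classes present).
#' @param seed Seed for the remainder draw.
#' @return A `balanced_dataset` list: `X`, `y` (equal class counts),
#'   `provenance` (source row index of every balanced row).
#' @export
oversample_balance <- function(X, y, seed = 1L) {
  if (!all(y %in% c(0, 1))) stop("labels must be binary 0/1")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  minority <- if (n1 <= n0) which(y == 1) else which(y == 0)
  deficit <- abs(n0 - n1)
  dup <- integer(0)
  if (deficit > 0) {
    cycles <- deficit %/% length(minority)
    rem <- deficit %% length(minority)
    dup <- c(rep(minority, cycles),
             if (rem > 0) with_seed(seed, sample(minority, rem)))
  }
  rows <- c(seq_along(y), dup)
  Xb <- if (is.data.frame(X)) X[rows, , drop = FALSE]
        else X[rows, , drop = FALSE]
  structure(list(X = Xb, y = y[rows], provenance = rows),
            class = "balanced_dataset")
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a randomly chosen positive outscores a randomly chosen
#' negative, with ties counting one half; computed from mid-ranks, so it is
#' invariant under strictly monotone transforms of the scores.
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary 0/1 labels (both present).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Average-precision summary of the precision-recall curve: precision at
#' each score threshold weighted by the recall increment, with tied scores
#' handled as one threshold group.
#'
#' @inheritParams roc_auc
#' @return PR-AUC in `(0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  n1 <- sum(labels == 1)
  if (n1 == 0L || sum(labels == 0) == 0L)
    stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp_end <- cumsum(rle(s)$lengths)
  tp <- cumsum(l)[grp_end]
  fp <- cumsum(1 - l)[grp_end]
  precision <- tp / (tp + fp)
  recall <- tp / n1
  sum(diff(c(0, recall)) * precision)
}

fit_lr <- function(X, y) {
  fit <- glmnet::glmnet(X, factor(y, levels = c(0, 1)),
                        family = "binomial", alpha = 0,
                        lambda = 1 / nrow(X), standardize = FALSE,
                        maxit = 2000)
  list(predict = function(Xnew)
         drop(stats::predict(fit, Xnew, type = "response")),
       importance = drop(as.matrix(stats::coef(fit)))[-1])
}

fit_rf <- function(X, y) {
  fit <- randomForest::randomForest(
    X, factor(y, levels = c(0, 1)), ntree = 100,
    mtry = max(1L, floor(sqrt(ncol(X)))))
  gini <- fit$importance[, "MeanDecreaseGini"]
  total <- sum(gini)
  list(predict = function(Xnew)
         stats::predict(fit, Xnew, type = "prob")[, "1"],
       importance = if (total > 0) gini / total else gini)
}

# Numeric design matrix for classification: factors expanded to dummy
# columns against their first level, no intercept column.
classification_matrix <- function(dataset, variant) {
  design <- variant_design(dataset, variant, for_cox = FALSE)
  mm <- stats::model.matrix(~ ., data = design)
  mm[, colnames(mm) != "(Intercept)", drop = FALSE]
}

#' Repeated cross-validated mutation classification
#'
#' Per-gene binary classification from a feature-set variant: in each of
#' `repeats` repetitions a fresh seeded fold assignment (stratified by
#' mutation status) is drawn; within each fold the training split only is
#' balanced by [oversample_balance()], the learner is fitted, and the
#' untouched test split is scored. AUCs are averaged over all
#' repeats x folds, and feature importances (signed coefficients for
#' logistic regression, normalized mean Gini impurity decrease for random
#' forest) are averaged over all fits.
#'
#' Learners: `logistic_regression` is L2-penalized maximum likelihood
#' (ridge, iteration cap 2000); `random_forest` is a 100-tree CART ensemble
#' with Gini splitting and sqrt-feature subsampling.
#'
#' @param dataset Analysis dataset with clinical columns, spatial features
#'   and binary gene columns.
#' @param gene Gene column name (binary response).
#' @param variant One of [mutation_variants()].
#' @param learner `"logistic_regression"` or `"random_forest"`.
#' @param repeats Number of repeated CV rounds (default 100).
#' @param k Number of folds (default 10).
#' @param seed Master seed; folds and oversampling derive sub-seeds from
#'   it.
#' @param metric `"roc"` (default) or `"pr"` (average precision).
#' @return A `classifier_result` list: `gene`, `variant`, `learner`,
#'   `auc` (mean over repeats x folds), `auc_sd`, `fold_auc`, `importance`
#'   (named, averaged), `metric`.
#' @export
run_mutation_cv <- function(dataset, gene, variant,
                            learner = c("logistic_regression",
                                        "random_forest"),
                            repeats = 100L, k = 10L, seed = 1L,
                            metric = c("roc", "pr")) {
  learner <- match.arg(learner)
  metric <- match.arg(metric)
  y <- dataset[[gene]]
  if (is.null(y)) stop("gene column not found: ", gene)
  if (!all(y %in% c(0, 1))) stop("gene column must be binary 0/1")
  if (min(sum(y == 1), sum(y == 0)) < k)
    stop("minority class smaller than fold count; reduce k")
  X <- classification_matrix(dataset, variant)
  fit_fun <- if (learner == "logistic_regression") fit_lr else fit_rf
  metric_fun <- if (metric == "roc") roc_auc else pr_auc
  aucs <- numeric(0)
  imp_sum <- numeric(ncol(X))
  n_fits <- 0L
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(y, k, sub_seed(seed, r))
    for (f in seq_len(k)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2L)
        stop("training fold with a single class")
      bal <- oversample_balance(X[tr, , drop = FALSE], y[tr],
                                seed = sub_seed(seed, r * 1000L + f))
      fit <- fit_fun(bal$X, bal$y)
      aucs <- c(aucs, metric_fun(fit$predict(X[!tr, , drop = FALSE]),
                                 y[!tr]))
      imp_sum <- imp_sum + fit$importance
      n_fits <- n_fits + 1L
    }
  }
  structure(list(gene = gene, variant = variant, learner = learner,
                 auc = mean(aucs), auc_sd = stats::sd(aucs),
                 fold_auc = aucs,
                 importance = stats::setNames(imp_sum / n_fits,
                                              colnames(X)),
                 metric = metric),
            class = "classifier_result")
}

#' @export
print.classifier_result <- function(x, ...) {
  cat(sprintf("%s | %s | %s: mean %s AUC = %.3f (sd %.3f, %d folds)\n",
              x$gene, x$variant, x$learner, toupper(x$metric), x$auc,
              x$auc_sd, length(x$fold_auc)))
  invisible(x)
}

#' Compare feature-set variants and learners across genes
#'
#' Runs [run_mutation_cv()] for every gene x variant x learner
#' combination and tabulates, per cell, the better learner's AUC; the best
#' variant per gene is flagged.
#'
#' @param dataset Analysis dataset.
#' @param genes Gene column names.
#' @param variants Variants to evaluate (default [mutation_variants()]).
#' @param learners Learners to compare.
#' @param repeats,k,seed,metric Passed to [run_mutation_cv()].
#' @return List with `auc` (genes x variants matrix of best-learner AUC),
#'   `winner` (matrix of winning learner names), `best_variant` (named by
#'   gene), `results` (nested list of `classifier_result`s).
#' @export
compare_variants <- function(dataset, genes,
                             variants = mutation_variants(),
                             learners = c("logistic_regression",
                                          "random_forest"),
                             repeats = 10L, k = 10L, seed = 1L,
                             metric = "roc") {
  auc <- matrix(NA_real_, length(genes), length(variants),
                dimnames = list(genes, variants))
  winner <- matrix(NA_character_, length(genes), length(variants),
                   dimnames = list(genes, variants))
  results <- list()
  for (g in genes) {
    results[[g]] <- list()
    for (v in variants) {
      fits <- lapply(learners, function(l)
        run_mutation_cv(dataset, g, v, l, repeats = repeats, k = k,
                        seed = seed, metric = metric))
      names(fits) <- learners
      results[[g]][[v]] <- fits
      scores <- vapply(fits, `[[`, numeric(1), "auc")
      auc[g, v] <- max(scores)
      winner[g, v] <- learners[which.max(scores)]
    }
  }
  best_variant <- variants[apply(auc, 1, which.max)]
  names(best_variant) <- genes
  list(auc = auc, winner = winner, best_variant = best_variant,
       results = results)
}
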