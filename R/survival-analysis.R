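#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper over [survival::survfit()] returning the step function as a
#' tidy table. The estimate is right-continuous and non-increasing and
#' handles right censoring.
#'
#' @param times Positive follow-up times.
#' @param events Binary event indicators (1 = event observed).
#' @return Data frame with `time`, `n_risk`, `n_event`, `n_censor`, `surv`,
#'   one row per distinct observed time.
#' @export
kaplan_meier <- function(times, events) {
  if (length(times) == 0L) stop("empty input")
  if (any(times <= 0)) stop("times must be positive")
  if (!all(events %in% c(0, 1))) stop("events must be binary 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard 1-degree-of-freedom log-rank chi-square via
#' [survival::survdiff()]. The statistic is symmetric in the group labels.
#'
#' @param groups Two-level grouping vector.
#' @param times Positive follow-up times.
#' @param events Binary event indicators.
#' @return List with `statistic` (chi-square) and `p_value`.
#' @export
logrank_test <- function(groups, times, events) {
  g <- factor(groups)
  if (nlevels(g) != 2L) stop("exactly two non-empty groups required")
  if (sum(events) == 0L) stop("no events observed")
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  list(statistic = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

# Standardized log-rank z-statistics for every candidate split x > cut,
# vectorized across candidates: at each distinct event time the observed
# minus expected events in the high group and its hypergeometric variance
# are accumulated with two n_eventtimes x n_candidates matrix products.
logrank_z_scan <- function(x, times, events, cuts) {
  n <- length(x)
  et <- sort(unique(times[events == 1]))
  atrisk <- outer(et, times, `<=`) * 1          # K x n
  dmat <- outer(et, times, `==`) * rep(events, each = length(et))
  nk <- rowSums(atrisk)
  dk <- rowSums(dmat)
  G <- outer(x, cuts, `>`) * 1                  # n x C
  n1 <- atrisk %*% G
  d1 <- dmat %*% G
  oe <- colSums(d1 - dk * n1 / nk)
  vfac <- ifelse(nk > 1, (nk - dk) / (nk - 1), 0)
  v <- colSums(dk * (n1 / nk) * (1 - n1 / nk) * vfac)
  ifelse(v > 0, oe / sqrt(v), 0)
}

max_abs_z <- function(x, times, events, cuts) {
  z <- abs(logrank_z_scan(x, times, events, cuts))
  k <- which.max(z)  # first index on ties: the smaller cutoff
  c(stat = z[k], idx = k)
}

#' Survival cutpoint by maximally selected rank statistics
#'
#' Scans every midpoint between consecutive distinct feature values whose
#' induced split leaves at least `minprop` of the subjects on each side,
#' computes the standardized two-sample log-rank statistic of each split
#' (high group: `feature > cutoff`), and selects the cutoff maximizing its
#' absolute value (ties resolved toward the smaller cutoff). Because the
#' maximum over many candidate splits inflates the naive log-rank p-value,
#' inference is by a seeded permutation test of the feature values.
#'
#' @param feature Numeric feature vector.
#' @param times Positive follow-up times.
#' @param events Binary event indicators.
#' @param minprop Minimum group proportion per side (default 0.1).
#' @param p_method `"permutation"` (default) or `"none"`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Seed for the permutation draw.
#' @return A `cutpoint_result` list: `cutoff`, `statistic` (max |z|),
#'   `p_value` (`NA` when `p_method = "none"`), `n_low`, `n_high`,
#'   `candidates` scanned.
#' @export
maxstat_cutpoint <- function(feature, times, events, minprop = 0.1,
                             p_method = c("permutation", "none"),
                             n_perm = 1000L, seed = 1L) {
  p_method <- match.arg(p_method)
  n <- length(feature)
  stopifnot(length(times) == n, length(events) == n)
  if (anyNA(feature)) stop("feature contains missing values")
  if (sum(events) == 0L) stop("no events observed")
  u <- sort(unique(feature))
  if (length(u) < 2L) stop("constant feature: no cutpoint exists")
  cuts <- (u[-1] + u[-length(u)]) / 2
  n_high <- vapply(cuts, function(cc) sum(feature > cc), integer(1))
  ok <- n_high >= minprop * n - 1e-9 & (n - n_high) >= minprop * n - 1e-9
  if (!any(ok)) stop("all candidate splits violate minprop")
  cuts <- cuts[ok]
  obs <- max_abs_z(feature, times, events, cuts)
  p <- NA_real_
  if (p_method == "permutation") {
    p <- with_seed(seed, {
      hits <- 0L
      for (b in seq_len(n_perm)) {
        zb <- max_abs_z(sample(feature), times, events, cuts)["stat"]
        if (zb >= obs["stat"] - 1e-12) hits <- hits + 1L
      }
      (1 + hits) / (n_perm + 1)
    })
  }
  cutoff <- cuts[obs["idx"]]
  structure(list(cutoff = unname(cutoff), statistic = unname(obs["stat"]),
                 p_value = p, n_low = sum(feature <= cutoff),
                 n_high = sum(feature > cutoff), candidates = cuts),
            class = "cutpoint_result")
}

#' Benjamini-Hochberg step-up procedure
#'
#' Standard false-discovery-rate control at level `q` over `m` tests (which
#' may exceed the number of p-values actually supplied, e.g. when some
#' tests of the family are reported elsewhere): critical values are
#' `c_r = r * q / m` for the ascending-ranked p-values, and all hypotheses
#' up to the largest rank with `p_r <= c_r` are rejected.
#'
#' @param pvals P-values in `[0, 1]`.
#' @param q False discovery rate (default 0.1).
#' @param m Total number of tests in the family (default `length(pvals)`).
#' @return List with `reject` (logical, input order), and `table`
#'   (data.frame `rank`, `p_sorted`, `critical`, `reject` in ascending-p
#'   order).
#' @export
benjamini_hochberg <- function(pvals, q = 0.1, m = length(pvals)) {
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  if (m < length(pvals)) stop("m must be at least length(pvals)")
  ord <- order(pvals)
  ps <- pvals[ord]
  r <- seq_along(ps)
  crit <- r * q / m
  below <- which(ps <= crit)
  kmax <- if (length(below)) max(below) else 0L
  rej_sorted <- r <= kmax
  reject <- logical(length(pvals))
  reject[ord] <- rej_sorted
  list(reject = reject,
       table = data.frame(rank = r, p_sorted = ps, critical = crit,
                          reject = rej_sorted))
}

#' Binarize features at learned cutpoints
#'
#' High/low stratification of each feature: indicator 1 when the value
#' strictly exceeds its cutoff (values equal to the cutoff fall in the low
#' group); missing values stay missing.
#'
#' @param features Data frame of numeric feature columns.
#' @param cutpoints Named numeric vector of cutoffs, or a named list of
#'   `cutpoint_result` objects.
#' @return Data frame of 0/1 indicator columns named `<feature>_high`.
#' @export
binarize_features <- function(features, cutpoints) {
  if (is.list(cutpoints) && !is.null(names(cutpoints)) &&
      all(vapply(cutpoints, inherits, logical(1), "cutpoint_result")))
    cutpoints <- vapply(cutpoints, `[[`, numeric(1), "cutoff")
  missing <- setdiff(names(cutpoints), names(features))
  if (length(missing)) stop("features lack columns: ",
                            paste(missing, collapse = ", "))
  out <- lapply(names(cutpoints), function(f)
    as.integer(features[[f]] > cutpoints[[f]]))
  names(out) <- paste0(names(cutpoints), "_high")
  as.data.frame(out)
}

#' Multivariate Cox proportional hazards fit
#'
#' Wrapper over [survival::coxph()] with Efron tie handling. Categorical
#' covariates (factors) are expanded against their first (basal) level,
#' whose hazard ratio is reported as exactly 1. Zero-variance covariates
#' are dropped with a warning before fitting.
#'
#' @param design Data frame of covariates (numeric or factor).
#' @param times Positive follow-up times.
#' @param events Binary event indicators (at least one event).
#' @param ties Tie-handling method (default `"efron"`).
#' @return A `cox_model_fit` list: `coefficients` (data frame with `term`,
#'   `coef`, `hr`, `se`, `z`, `p_value`), `basal` (variable/level pairs
#'   with `hr = 1`), `cindex`, `n`, `n_events`, `dropped`, `separation`
#'   (flag for monotone-likelihood / infinite-coefficient fits), `notes`
#'   (captured convergence warnings), and the underlying `fit`.
#' @export
cox_fit <- function(design, times, events, ties = "efron") {
  if (sum(events) < 1L) stop("at least one event required")
  keep <- vapply(design, function(col) {
    if (is.factor(col) || is.character(col)) length(unique(col)) > 1L
    else stats::var(as.numeric(col)) > 0
  }, logical(1))
  if (any(!keep))
    warning("dropping zero-variance covariates: ",
            paste(names(design)[!keep], collapse = ", "))
  design <- design[, keep, drop = FALSE]
  if (ncol(design) == 0L) stop("no usable covariates")
  df <- cbind(data.frame(.time = times, .event = events), design)
  notes <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.time, .event) ~ ., data = df,
                    ties = ties),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(s), coef = s[, "coef"],
                      hr = s[, "exp(coef)"], se = s[, "se(coef)"],
                      z = s[, "z"], p_value = s[, "Pr(>|z|)"],
                      row.names = NULL)
  basal <- do.call(rbind, lapply(names(design), function(v) {
    if (is.factor(design[[v]]))
      data.frame(variable = v, level = levels(design[[v]])[1], hr = 1)
  }))
  if (is.null(basal))
    basal <- data.frame(variable = character(0), level = character(0),
                        hr = numeric(0))
  structure(list(coefficients = coefs, basal = basal,
                 cindex = unname(fit$concordance["concordance"]),
                 n = fit$n, n_events = fit$nevent,
                 dropped = names(keep)[!keep],
                 separation = any(grepl("infinite", notes)) ||
                   any(abs(coefs$coef) > 15, na.rm = TRUE),
                 notes = notes, fit = fit),
            class = "cox_model_fit")
}

#' @export
print.cox_model_fit <- function(x, ...) {
  cat("Cox proportional hazards fit (Efron ties)\n")
  cat(sprintf("n = %d, events = %d, c-index = %.3f\n",
              x$n, x$n_events, x$cindex))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Harrell's concordance index
#'
#' Fraction of comparable patient pairs (usable under right censoring)
#' whose risk ordering agrees with their survival ordering; tied risk
#' scores count one half. Computed with [survival::concordance()] in
#' reverse orientation (higher score = higher risk = earlier failure).
#'
#' @param risk_scores Numeric risk scores (e.g. Cox linear predictors).
#' @param times Positive follow-up times.
#' @param events Binary event indicators.
#' @return Concordance in `[0, 1]`.
#' @export
concordance_index <- function(risk_scores, times, events) {
  n <- length(risk_scores)
  stopifnot(length(times) == n, length(events) == n)
  cf <- survival::concordance(
    survival::Surv(times, events) ~ risk_scores, reverse = TRUE)
  counts <- cf$count
  if (sum(counts[c("concordant", "discordant", "tied.x")]) == 0)
    stop("no comparable pairs under censoring")
  unname(cf$concordance)
}

# Stratified fold assignment: indices 1..n split into k folds with the
# strata (e.g. event status or class label) balanced across folds.
stratified_folds <- function(strata, k, seed) {
  with_seed(seed, {
    fold <- integer(length(strata))
    for (s in unique(strata)) {
      idx <- sample(which(strata == s))
      fold[idx] <- rep_len(sample(k), length(idx))
    }
    fold
  })
}

#' Cross-validated c-index of a Cox feature-set variant
#'
#' Fits the variant's Cox model on each training split of a k-fold
#' cross-validation (folds stratified by event status), scores the held-out
#' subjects by their linear predictor, and reports the median test-fold
#' c-index.
#'
#' @param dataset Analysis dataset (one row per patient) with clinical
#'   columns, spatial features, `time` and `event`.
#' @param variant One of [survival_variants()].
#' @param mutations Optional mutation indicator columns to add (e.g.
#'   `c("EGFR", "STK11", "TP53")`).
#' @param k Number of folds (default 10).
#' @param seed Fold-assignment seed.
#' @return List with `median_cindex`, `fold_cindex` (length `k`), `variant`.
#' @export
cv_cindex <- function(dataset, variant, mutations = NULL, k = 10L,
                      seed = 1L) {
  design <- variant_design(dataset, variant, mutations, for_cox = TRUE)
  fold <- stratified_folds(dataset$event, k, seed)
  scores <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    if (sum(dataset$event[!tr]) == 0L || sum(dataset$event[tr]) == 0L)
      stop("fold without events; reduce k or increase cohort size")
    fit <- cox_fit(design[tr, , drop = FALSE],
                   dataset$time[tr], dataset$event[tr])
    nd <- cbind(data.frame(.time = 1, .event = 0L),
                design[!tr, , drop = FALSE])
    lp <- drop(stats::predict(fit$fit, newdata = nd, type = "lp"))
    concordance_index(lp, dataset$time[!tr], dataset$event[!tr])
  }, numeric(1))
  list(median_cindex = stats::median(scores), fold_cindex = scores,
       variant = variant)
}

#' Cutpoint-stratified survival screen over spatial features
#'
#' The full single-feature screening pipeline: for every feature column a
#' maximally selected rank-statistic cutpoint is learned on the whole
#' cohort, patients are stratified high/low, the two strata are compared by
#' the log-rank test, and the family of p-values is assessed with the
#' Benjamini-Hochberg procedure. (The cutpoint is learned on the same data
#' the test is run on; the permutation p-value of [maxstat_cutpoint()] is
#' the honest selection-adjusted significance.)
#'
#' @param dataset Analysis dataset with `time` and `event`.
#' @param features Feature columns to screen (default: all 15 TIP and TMEC
#'   composition features).
#' @param q False discovery rate for BH (default 0.1).
#' @param minprop,n_perm,seed Passed to [maxstat_cutpoint()].
#' @return Data frame with one row per feature: `feature`, `cutoff`,
#'   `statistic`, `logrank_p`, `perm_p`, `bh_critical`, `significant`.
#' @export
survival_feature_screen <- function(dataset,
                                    features = NULL,
                                    q = 0.1, minprop = 0.1, n_perm = 1000L,
                                    seed = 1L) {
  if (is.null(features)) {
    features <- grep("^[tm]_", spatial_feature_names(), value = TRUE)
    features <- setdiff(features, "t_tumor")  # 15 TME composition features
  }
  rows <- lapply(seq_along(features), function(i) {
    f <- features[i]
    cp <- maxstat_cutpoint(dataset[[f]], dataset$time, dataset$event,
                           minprop = minprop, p_method = "permutation",
                           n_perm = n_perm, seed = sub_seed(seed, i))
    lr <- logrank_test(dataset[[f]] > cp$cutoff, dataset$time,
                       dataset$event)
    data.frame(feature = f, cutoff = cp$cutoff, statistic = cp$statistic,
               logrank_p = lr$p_value, perm_p = cp$p_value)
  })
  out <- do.call(rbind, rows)
  bh <- benjamini_hochberg(out$logrank_p, q = q, m = nrow(out))
  out$bh_critical <- bh$table$critical[match(rank(out$logrank_p,
                                                  ties.method = "first"),
                                             bh$table$rank)]
  out$significant <- bh$reject
  out
}
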