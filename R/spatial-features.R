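#' Tissue prevalence (TIP) of a label grid
#'
#' The distribution of the eight tissue classes over the whole tissue area
#' of a slide: `t_i = n_i / N`, where `N` counts all unmasked,
#' non-background patches. BACKGROUND and masked (filtered-out) patches are
#' excluded from numerator and denominator alike.
#'
#' @param grid Label grid matrix (codes 0-8, optional `mask` attribute).
#' @return Named numeric vector `t_tumor` ... `t_lung` summing to 1, with
#'   attribute `N` (total tissue patch count).
#' @export
tissue_prevalence <- function(grid) {
  validate_grid(grid)
  mask <- grid_mask(grid)
  lab <- grid[!mask]
  lab <- lab[lab != background_code()]
  if (length(lab) == 0L) stop("grid contains no tissue patches")
  counts <- tabulate(lab + 1L, nbins = 8L)
  tip <- counts / length(lab)
  names(tip) <- paste0("t_", tolower(tissue_class_names()))
  attr(tip, "N") <- length(lab)
  tip
}

# Offsets of the 8-connected (Chebyshev distance 1) neighborhood.
.neighbor_offsets <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                           dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

# Per-class counts of tumor-neighboring patches. With multiplicity (the
# default) a patch adjacent to k tumor patches contributes k; with
# unique = TRUE it contributes 1.
tumor_neighbor_counts <- function(grid, unique = FALSE) {
  validate_grid(grid)
  mask <- grid_mask(grid)
  nr <- nrow(grid); nc <- ncol(grid)
  tumor <- which(grid == tissue_classes()[["TUMOR"]] & !mask, arr.ind = TRUE)
  counts <- numeric(8L)
  if (nrow(tumor) == 0L) return(list(b = counts, n_tumor = 0L))
  hit <- if (unique) matrix(FALSE, nr, nc) else NULL
  for (k in seq_len(nrow(.neighbor_offsets))) {
    r <- tumor[, 1] + .neighbor_offsets[k, 1]
    c <- tumor[, 2] + .neighbor_offsets[k, 2]
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    idx <- cbind(r[ok], c[ok])
    lab <- grid[idx]
    keep <- lab != tissue_classes()[["TUMOR"]] &
      lab != background_code() & !mask[idx]
    if (unique) {
      idx <- idx[keep, , drop = FALSE]
      new <- !hit[idx]
      hit[idx[new, , drop = FALSE]] <- TRUE
      lab <- grid[idx[new, , drop = FALSE]]
      counts <- counts + tabulate(lab + 1L, nbins = 8L)
    } else {
      counts <- counts + tabulate(lab[keep] + 1L, nbins = 8L)
    }
  }
  list(b = counts, n_tumor = nrow(tumor))
}

#' Tumor microenvironment composition (TMEC)
#'
#' Distribution of non-tumor, non-background tissue classes among the
#' 8-connected neighbors of tumor patches: `m_j = b_j / B`. Each tumor
#' patch is considered separately, so by default a neighbor adjacent to
#' several tumor patches is counted once per adjacency (multiplicity);
#' `unique_neighbors = TRUE` switches to counting distinct patches.
#'
#' If the grid has no tumor patches, or tumor patches have no qualifying
#' neighbors, the composition is undefined: all entries are `NA` and
#' `B = 0`.
#'
#' @param grid Label grid matrix.
#' @param unique_neighbors Count each neighboring patch at most once.
#' @return Named numeric vector `m_stroma` ... `m_lung` summing to 1 (or
#'   all-`NA` sentinel), with attributes `B` (total neighbor count) and `b`
#'   (per-class counts).
#' @export
tmec <- function(grid, unique_neighbors = FALSE) {
  nb <- tumor_neighbor_counts(grid, unique = unique_neighbors)
  b <- nb$b[-1L]  # tumor itself is excluded from the composition
  B <- sum(b)
  m <- if (nb$n_tumor == 0L || B == 0) rep(NA_real_, 7L) else b / B
  names(m) <- paste0("m_", tolower(setdiff(tissue_class_names(), "TUMOR")))
  attr(m, "B") <- B
  attr(m, "b") <- stats::setNames(b, names(m))
  m
}

#' Intra-tumor lymphocyte ratio (ITLR), patch-wise
#'
#' `b_IMMUNE / n_TUMOR`: the number of immune patches neighboring the tumor
#' (counted exactly as in [tmec()], i.e. with multiplicity by default)
#' divided by the slide's total tumor patch count. Undefined (`NA`) when
#' the grid has no tumor patches.
#'
#' @inheritParams tmec
#' @return Nonnegative scalar, or `NA` sentinel without tumor patches.
#' @export
itlr <- function(grid, unique_neighbors = FALSE) {
  nb <- tumor_neighbor_counts(grid, unique = unique_neighbors)
  if (nb$n_tumor == 0L) return(NA_real_)
  nb$b[[tissue_classes()[["IMMUNE"]] + 1L]] / nb$n_tumor
}

#' Shannon diversity of a tissue-prevalence vector
#'
#' `-sum(t_i * log(t_i))` in nats with `0 log 0 := 0`; ranges from 0
#' (single class) to `log(8)` (uniform prevalence).
#'
#' @param tip Prevalence vector from [tissue_prevalence()] (any nonnegative
#'   vector summing to 1).
#' @return Shannon index in nats.
#' @export
shannon_index <- function(tip) {
  t <- as.numeric(tip)
  if (any(t < 0)) stop("prevalences must be nonnegative")
  nz <- t > 0
  -sum(t[nz] * log(t[nz]))
}

#' Simpson index of a tissue-prevalence vector
#'
#' `sum(t_i^2)`; ranges from `1/8` (uniform) to 1 (single class).
#'
#' @inheritParams shannon_index
#' @return Simpson index.
#' @export
simpson_index <- function(tip) {
  t <- as.numeric(tip)
  if (any(t < 0)) stop("prevalences must be nonnegative")
  sum(t^2)
}

#' All spatial features of one slide
#'
#' @param grid Label grid matrix.
#' @param unique_neighbors Passed to [tmec()] and [itlr()].
#' @return Named numeric vector with the 18 [spatial_feature_names()]
#'   entries (TMEC/ITLR are `NA` when undefined).
#' @export
slide_features <- function(grid, unique_neighbors = FALSE) {
  tip <- tissue_prevalence(grid)
  m <- tmec(grid, unique_neighbors)
  c(tip, m[seq_along(m)],
    itlr = itlr(grid, unique_neighbors),
    shannon = shannon_index(tip), simpson = simpson_index(tip))
}

#' Per-patient spatial feature table
#'
#' Computes [slide_features()] for every grid, then averages per patient
#' with an unweighted mean across that patient's slides. Slides on which
#' TMEC/ITLR are undefined (no tumor) are excluded from the patient's
#' average for those columns only; a patient with no valid slide for a
#' column gets a missing value there.
#'
#' @param grids List of label grids.
#' @param patient_ids Character/factor vector, one id per grid.
#' @param slide_ids Optional slide identifiers (defaults to `slide_1` ...).
#' @param unique_neighbors Passed to [slide_features()].
#' @return Data frame with `patient_id` and the 18 feature columns, one row
#'   per patient, sorted by id. The per-slide table (with `slide_id`) is
#'   attached as attribute `per_slide`.
#' @export
feature_table <- function(grids, patient_ids, slide_ids = NULL,
                          unique_neighbors = FALSE) {
  stopifnot(length(grids) == length(patient_ids))
  if (is.null(slide_ids)) slide_ids <- paste0("slide_", seq_along(grids))
  rows <- t(vapply(grids, slide_features, numeric(18L),
                   unique_neighbors = unique_neighbors))
  per_slide <- data.frame(patient_id = as.character(patient_ids),
                          slide_id = as.character(slide_ids), rows)
  ids <- sort(unique(per_slide$patient_id))
  agg <- t(vapply(ids, function(id) {
    sub <- rows[per_slide$patient_id == id, , drop = FALSE]
    colMeans(sub, na.rm = TRUE)
  }, numeric(18L)))
  agg[is.nan(agg)] <- NA_real_
  out <- data.frame(patient_id = ids, agg, row.names = NULL)
  attr(out, "per_slide") <- per_slide
  out
}

#' Column medians of a spatial feature table
#'
#' Cohort-level summary of per-slide (or per-patient) feature tables:
#' the median of every feature column, ignoring missing values.
#'
#' @param features Data frame containing some or all
#'   [spatial_feature_names()] columns.
#' @return Named numeric vector of medians.
#' @export
feature_medians <- function(features) {
  cols <- intersect(spatial_feature_names(), names(features))
  if (length(cols) == 0L) stop("no spatial feature columns present")
  vapply(features[cols], stats::median, numeric(1), na.rm = TRUE)
}
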