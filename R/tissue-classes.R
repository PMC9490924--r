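#' Tissue classes of the lung H&E patch taxonomy
#'
#' The nine patch-level tissue classes used throughout the package, with
#' their fixed integer codes. `BACKGROUND` (code 8) is the unique non-tissue
#' class: it is excluded from all spatial features. The remaining eight are
#' the tissue classes proper.
#'
#' @return Named integer vector of length 9 mapping class name to code 0-8.
#' @examples
#' tissue_classes()
#' @export
tissue_classes <- function() {
  c(TUMOR = 0L, STROMA = 1L, MIXED = 2L, IMMUNE = 3L, VESSEL = 4L,
    BRONCHI = 5L, NECROSIS = 6L, LUNG = 7L, BACKGROUND = 8L)
}

#' @rdname tissue_classes
#' @export
n_tissue_classes <- function() 9L

#' Code of the background (non-tissue) class
#' @return Integer code 8.
#' @export
background_code <- function() 8L

#' Names of the eight non-background tissue classes, in code order
#' @return Character vector of length 8.
#' @export
tissue_class_names <- function() {
  cls <- tissue_classes()
  names(cls)[cls != background_code()]
}

# Fixed display palette for label grids, one color per code 0-8.
# Chosen for contrast; BACKGROUND renders white.
tissue_palette <- function() {
  c(TUMOR = "#D62728", STROMA = "#BCBD22", MIXED = "#9467BD",
    IMMUNE = "#1F77B4", VESSEL = "#8C564B", BRONCHI = "#E377C2",
    NECROSIS = "#17BECF", LUNG = "#2CA02C", BACKGROUND = "#FFFFFF")
}

#' Column names of the slide-level spatial feature set
#'
#' Tissue prevalence (`t_*`, 8 columns), tumor-microenvironment composition
#' (`m_*`, 7 columns, tumor excluded by definition), and the three scalar
#' spatial metrics.
#'
#' @return Character vector of the 18 feature column names.
#' @export
spatial_feature_names <- function() {
  c(paste0("t_", tolower(tissue_class_names())),
    paste0("m_", tolower(setdiff(tissue_class_names(), "TUMOR"))),
    "itlr", "shannon", "simpson")
}

validate_grid <- function(grid) {
  if (!is.matrix(grid) || !is.numeric(grid))
    stop("label grid must be an integer matrix")
  codes <- unique(as.vector(grid))
  if (any(is.na(codes)) || any(codes < 0L | codes > 8L) ||
      any(codes != as.integer(codes)))
    stop("label grid codes must be integers in 0-8")
  invisible(grid)
}

grid_mask <- function(grid) {
  m <- attr(grid, "mask")
  if (is.null(m)) m <- matrix(FALSE, nrow(grid), ncol(grid))
  m
}
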