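#' Probability-table column names
#'
#' Per-patch class-probability tables carry one probability column per
#' tissue class, in fixed code order `p_tumor` ... `p_background`.
#'
#' @return Character vector of the 9 probability column names.
#' @export
probability_columns <- function() {
  paste0("p_", tolower(names(tissue_classes())))
}

prob_matrix <- function(probs, tol = 1e-6) {
  cols <- probability_columns()
  if (is.data.frame(probs)) {
    missing <- setdiff(cols, names(probs))
    if (length(missing)) stop("probability table lacks columns: ",
                              paste(missing, collapse = ", "))
    p <- as.matrix(probs[cols])
  } else {
    p <- as.matrix(probs)
    if (ncol(p) != n_tissue_classes()) stop("expected 9 probability columns")
  }
  if (any(p < 0)) stop("probabilities must be nonnegative")
  rs <- rowSums(p)
  if (any(abs(rs - 1) > tol)) stop("probability rows must sum to 1 (+/- ", tol, ")")
  p
}

#' Argmax labeling of per-patch class probabilities
#'
#' Each patch receives the class with the highest probability; exact ties
#' are broken deterministically in favor of the lowest class code.
#'
#' @param probs Data frame with the [probability_columns()] (and optionally
#'   `slide_id`, `row`, `col`), or a numeric matrix with 9 columns.
#' @param tol Row-sum tolerance (default 1e-6).
#' @return Integer vector of class codes 0-8, one per row.
#' @export
assign_labels <- function(probs, tol = 1e-6) {
  p <- prob_matrix(probs, tol)
  max.col(p, ties.method = "first") - 1L
}

#' Assemble per-patch labels into a slide-shaped label grid
#'
#' Positions absent from `labels` (e.g. patches removed by the relevance
#' filter) are set to BACKGROUND and recorded in the grid's logical mask
#' attribute, so downstream features can exclude them.
#'
#' @param labels Data frame with 0-based `row`, `col` and integer `label`
#'   columns (codes 0-8).
#' @param shape Integer vector `c(rows, cols)` of the grid.
#' @param slide_id Optional slide identifier stored on the grid.
#' @return Integer matrix with attributes `mask` (logical matrix, `TRUE`
#'   where no label was supplied) and `slide_id`.
#' @export
assemble_grid <- function(labels, shape, slide_id = NULL) {
  stopifnot(length(shape) == 2L, all(shape >= 1))
  if (!all(c("row", "col", "label") %in% names(labels)))
    stop("labels must have columns row, col, label")
  if (nrow(labels) > 0) {
    if (any(labels$row < 0 | labels$row >= shape[1] |
            labels$col < 0 | labels$col >= shape[2]))
      stop("coordinate outside grid shape")
    key <- labels$row * shape[2] + labels$col
    if (anyDuplicated(key)) stop("duplicate (row, col) coordinate")
    if (any(labels$label < 0 | labels$label > 8))
      stop("label codes must be in 0-8")
  }
  grid <- matrix(background_code(), shape[1], shape[2])
  mask <- matrix(TRUE, shape[1], shape[2])
  if (nrow(labels) > 0) {
    idx <- cbind(labels$row + 1L, labels$col + 1L)
    grid[idx] <- as.integer(labels$label)
    mask[idx] <- FALSE
  }
  attr(grid, "mask") <- mask
  attr(grid, "slide_id") <- slide_id
  grid
}

#' Flatten a label grid back to a (row, col, label) table
#'
#' Masked positions are omitted, making this the inverse of
#' [assemble_grid()].
#'
#' @param grid Label grid matrix (with optional `mask` attribute).
#' @return Data frame with 0-based `row`, `col`, `label`.
#' @export
flatten_grid <- function(grid) {
  validate_grid(grid)
  mask <- grid_mask(grid)
  keep <- which(!mask, arr.ind = TRUE)
  data.frame(row = keep[, 1] - 1L, col = keep[, 2] - 1L,
             label = as.integer(grid[keep]))
}

#' Predictive entropy of a class-probability vector
#'
#' Shannon entropy `-sum(p * log(p))` in nats with `0 * log(0) := 0`;
#' bounded by `log(k)` for a k-class vector (log 9 here).
#'
#' @param p Nonnegative probability vector summing to 1 (tolerance 1e-6).
#' @return Entropy in nats.
#' @examples
#' predictive_entropy(rep(1 / 9, 9))  # log(9)
#' @export
predictive_entropy <- function(p) {
  if (any(p < 0)) stop("probabilities must be nonnegative")
  if (abs(sum(p) - 1) > 1e-6) stop("probabilities must sum to 1")
  nz <- p > 0
  -sum(p[nz] * log(p[nz]))
}

row_entropy <- function(p) {
  q <- ifelse(p > 0, p * log(p), 0)
  -rowSums(q)
}

# Lower-median convention: for an even count the lower of the two middle
# order statistics is returned, keeping golden values stable.
lower_median <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sort(x)[ceiling(n / 2)]
}

#' Per-class uncertainty summary of a probability table
#'
#' Labels every patch by [assign_labels()], computes its predictive entropy,
#' and summarizes the median entropy per assigned class. Classes whose
#' median meets or exceeds `threshold` are flagged as needing more training
#' data; classes with no assigned patches report a missing median.
#'
#' @param probs Probability table (see [assign_labels()]).
#' @param threshold Flagging threshold in nats (default 1.5, against the
#'   maximum of log 9 ~ 2.197).
#' @return Data frame with `class`, `code`, `n`, `median_entropy`,
#'   `flagged`, one row per tissue class in code order.
#' @export
classwise_uncertainty <- function(probs, threshold = 1.5) {
  p <- prob_matrix(probs)
  labels <- max.col(p, ties.method = "first") - 1L
  ent <- row_entropy(p)
  cls <- tissue_classes()
  med <- vapply(cls, function(code) lower_median(ent[labels == code]),
                numeric(1))
  n <- vapply(cls, function(code) sum(labels == code), integer(1))
  data.frame(class = names(cls), code = unname(cls), n = unname(n),
             median_entropy = unname(med),
             flagged = unname(ifelse(is.na(med), NA, med >= threshold)))
}

## ---- plain-text / PNG interchange ----------------------------------------

#' Read and write label grids and probability tables
#'
#' Grids interchange as header-less CSV of integer codes (one grid row per
#' line) and as PNG colored with the package's fixed 9-color palette;
#' probability tables as CSV with `slide_id`, `row`, `col` and the
#' [probability_columns()].
#'
#' @param grid Label grid matrix.
#' @param path File path.
#' @name grid_io
#' @export
write_grid_csv <- function(grid, path) {
  validate_grid(grid)
  utils::write.table(grid, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname grid_io
#' @export
read_grid_csv <- function(path) {
  grid <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(grid) <- NULL
  storage.mode(grid) <- "integer"
  validate_grid(grid)
  grid
}

#' @rdname grid_io
#' @export
write_grid_png <- function(grid, path) {
  validate_grid(grid)
  pal <- t(grDevices::col2rgb(tissue_palette())) / 255
  img <- array(0, c(nrow(grid), ncol(grid), 3L))
  for (ch in 1:3)
    img[, , ch] <- matrix(pal[as.vector(grid) + 1L, ch], nrow(grid))
  png::writePNG(img, path)
  invisible(path)
}

#' @rdname grid_io
#' @param probs Probability table data frame.
#' @export
write_probability_csv <- function(probs, path) {
  utils::write.csv(probs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname grid_io
#' @export
read_probability_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
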