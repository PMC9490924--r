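#' Tiling specification for slide rasters
#'
#' Converts a physical patch size in microns to a pixel side length given
#' the raster resolution. The package default reproduces the common
#' 87 um / 172 px patch geometry used for lung H&E tissue maps
#' (mpp = 87/172 ~ 0.5058 um per pixel).
#'
#' @param patch_um Physical patch side in microns (default 87).
#' @param mpp Microns per pixel of the raster (default `87/172`).
#' @return A `tile_spec` list with `patch_um`, `mpp` and the derived
#'   integer `patch_px = round(patch_um / mpp)`.
#' @examples
#' tile_spec()$patch_px  # 172
#' @export
tile_spec <- function(patch_um = 87, mpp = 87 / 172) {
  if (is.null(mpp) || !is.finite(mpp) || mpp <= 0)
    stop("mpp (microns per pixel) must be a positive number")
  if (!is.finite(patch_um) || patch_um <= 0)
    stop("patch_um must be positive")
  patch_px <- as.integer(round(patch_um / mpp))
  if (patch_px < 1L) stop("patch size below one pixel at this resolution")
  structure(list(patch_um = patch_um, mpp = mpp, patch_px = patch_px),
            class = "tile_spec")
}

check_rgb <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("input must be an RGB raster: numeric array H x W x 3")
  if (any(image < 0 | image > 255, na.rm = TRUE))
    stop("channel values must lie in [0, 255]")
  invisible(image)
}

#' Tile a slide raster into non-overlapping square patches
#'
#' Patches are laid on a regular grid from the top-left origin; partial
#' tiles at the right/bottom edges are discarded. Coordinates are 0-based
#' `(row, col)` so that a label grid reassembled from patch results aligns
#' with the slide.
#'
#' @param image Numeric array `H x W x 3`, channel values in `[0, 255]`.
#' @param spec A [tile_spec()].
#' @return List of `list(row, col, patch)` of length
#'   `floor(H / patch_px) * floor(W / patch_px)`, in row-major order.
#' @export
tile_slide <- function(image, spec = tile_spec()) {
  check_rgb(image)
  px <- spec$patch_px
  nr <- nrow(image) %/% px
  nc <- ncol(image) %/% px
  if (nr == 0L || nc == 0L) return(list())
  out <- vector("list", nr * nc)
  k <- 1L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      out[[k]] <- list(
        row = i - 1L, col = j - 1L,
        patch = image[((i - 1L) * px + 1L):(i * px),
                      ((j - 1L) * px + 1L):(j * px), , drop = FALSE])
      k <- k + 1L
    }
  }
  out
}

#' Rec. 601 luma of RGB values
#'
#' `0.299 R + 0.587 G + 0.114 B`, unrounded. Accepts a length-3 vector
#' (one pixel) or an `H x W x 3` array (whole patch).
#'
#' @param rgb Numeric vector of length 3 or array `H x W x 3` in `[0, 255]`.
#' @return Scalar or `H x W` matrix of luma values in `[0, 255]`.
#' @examples
#' luma(c(255, 0, 0))  # 76.245
#' @export
luma <- function(rgb) {
  w <- c(0.299, 0.587, 0.114)
  if (is.array(rgb) && length(dim(rgb)) == 3L) {
    check_rgb(rgb)
    return(rgb[, , 1] * w[1] + rgb[, , 2] * w[2] + rgb[, , 3] * w[3])
  }
  if (length(rgb) != 3L) stop("rgb must be a length-3 pixel or H x W x 3 array")
  if (any(rgb < 0 | rgb > 255)) stop("channel values must lie in [0, 255]")
  sum(rgb * w)
}

#' Tissue-relevance filter for a patch
#'
#' Pixels are split into black (`luma < black_cut`) and white
#' (`luma >= black_cut`). A patch is relevant when the black/white ratio
#' strictly exceeds `ratio_cut`, i.e. when enough of its area is dark
#' (stained tissue) rather than empty glass. An all-black patch (no white
#' pixels) is declared relevant: it is tissue-dense and the ratio is
#' undefined there.
#'
#' @param patch RGB array `H x W x 3` in `[0, 255]`.
#' @param black_cut Luma threshold separating black from white (default 200).
#' @param ratio_cut Strict lower bound on black/white (default 0.05).
#' @return `TRUE` if the patch is tissue-relevant.
#' @export
is_relevant_patch <- function(patch, black_cut = 200, ratio_cut = 0.05) {
  lm <- luma(patch)
  if (length(lm) == 0L) stop("empty patch")
  black <- sum(lm < black_cut)
  white <- length(lm) - black
  if (white == 0L) return(TRUE)
  black / white > ratio_cut
}

## ---- Reinhard color normalization (Ruderman l-alpha-beta space) ----------

# RGB <-> LMS matrices of the original Reinhard transfer procedure; the
# decorrelated l-alpha-beta axes are log10-LMS rotated and scaled.
.rgb2lms <- matrix(c(0.3811, 0.5783, 0.0402,
                     0.1967, 0.7244, 0.0782,
                     0.0241, 0.1288, 0.8444), 3, 3, byrow = TRUE)
# exact numerical inverse of the forward matrix, so that the identity
# transform round-trips within floating-point error (the published inverse
# is rounded to 4 decimals and would cost up to ~2/255 per channel)
.lms2rgb <- solve(.rgb2lms)
.lms2lab <- diag(c(1 / sqrt(3), 1 / sqrt(6), 1 / sqrt(2))) %*%
  matrix(c(1, 1, 1, 1, 1, -2, 1, -1, 0), 3, 3, byrow = TRUE)
.lab2lms <- matrix(c(1, 1, 1, 1, 1, -1, 1, -2, 0), 3, 3, byrow = TRUE) %*%
  diag(c(sqrt(3) / 3, sqrt(6) / 6, sqrt(2) / 2))
.lab_eps <- 1e-4  # guards log10 of zero-intensity pixels

# n-pixel x 3 matrix of l-alpha-beta coordinates for an RGB raster in [0,255]
rgb_to_lab <- function(image) {
  check_rgb(image)
  rgb <- matrix(as.numeric(image), ncol = 3L) / 255
  lms <- rgb %*% t(.rgb2lms)
  log10(pmax(lms, .lab_eps)) %*% t(.lms2lab)
}

lab_to_rgb <- function(lab, dims) {
  lms <- 10 ^ (lab %*% t(.lab2lms))
  rgb <- pmin(pmax(lms %*% t(.lms2rgb), 0), 1) * 255
  array(rgb, dim = dims)
}

#' Reference color statistics for Reinhard normalization
#'
#' Per-channel mean and standard deviation (population form, so the stats
#' are invariant under duplicating the image) of the reference raster in
#' the Ruderman l-alpha-beta space: RGB -> LMS -> log10 -> rotated axes.
#'
#' @param reference RGB array `H x W x 3` in `[0, 255]`.
#' @param sd_floor Lower bound applied to each channel sd; a reference with
#'   any channel sd below the floor (e.g. a single-color image) is flagged
#'   `degenerate`.
#' @return A `reinhard_stats` list: `mean` (length 3), `sd` (length 3),
#'   `degenerate` flag.
#' @export
compute_reinhard_stats <- function(reference, sd_floor = 1e-8) {
  lab <- rgb_to_lab(reference)
  mu <- colMeans(lab)
  n <- nrow(lab)
  sdv <- sqrt(colSums(sweep(lab, 2, mu)^2) / n)
  degenerate <- any(sdv < sd_floor)
  structure(list(mean = mu, sd = pmax(sdv, sd_floor), degenerate = degenerate),
            class = "reinhard_stats")
}

#' Reinhard color normalization of a patch
#'
#' Shifts and scales each l-alpha-beta channel of the patch so its mean and
#' standard deviation match the reference statistics, then maps back to RGB
#' clipped to `[0, 255]`. A zero-variance patch channel is set to the
#' reference mean rather than divided by zero.
#'
#' @param patch RGB array `H x W x 3` in `[0, 255]`.
#' @param ref A `reinhard_stats` object from [compute_reinhard_stats()].
#' @param sd_floor Patch channel sds below this are treated as zero variance.
#' @return Normalized RGB array with the shape of `patch`.
#' @export
reinhard_normalize <- function(patch, ref, sd_floor = 1e-8) {
  if (!inherits(ref, "reinhard_stats")) stop("ref must be reinhard_stats")
  lab <- rgb_to_lab(patch)
  mu <- colMeans(lab)
  n <- nrow(lab)
  sdv <- sqrt(colSums(sweep(lab, 2, mu)^2) / n)
  out <- lab
  for (ch in 1:3) {
    if (sdv[ch] < sd_floor) {
      out[, ch] <- ref$mean[ch]
    } else {
      out[, ch] <- (lab[, ch] - mu[ch]) * (ref$sd[ch] / sdv[ch]) + ref$mean[ch]
    }
  }
  lab_to_rgb(out, dim(patch))
}

#' Read / write an RGB raster as PNG
#'
#' Thin wrappers around the png package that keep the package-wide
#' `[0, 255]` channel convention.
#'
#' @param path File path.
#' @param image RGB array `H x W x 3` in `[0, 255]`.
#' @return `read_image_png` returns an `H x W x 3` array in `[0, 255]`.
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
  img[, , 1:3, drop = FALSE] * 255
}

#' @rdname read_image_png
#' @export
write_image_png <- function(image, path) {
  check_rgb(image)
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}

#' Tile, filter and normalize a slide in one pass
#'
#' Convenience composition of [tile_slide()], [is_relevant_patch()] and
#' [reinhard_normalize()]: irrelevant patches are kept in the manifest but
#' not normalized.
#'
#' @param image RGB array `H x W x 3` in `[0, 255]`.
#' @param spec A [tile_spec()].
#' @param ref Optional `reinhard_stats`; when supplied, relevant patches are
#'   color-normalized against it.
#' @return List with `patches` (as [tile_slide()], normalized in place) and
#'   `manifest` data frame (`row`, `col`, `relevant`).
#' @export
process_slide <- function(image, spec = tile_spec(), ref = NULL) {
  tiles <- tile_slide(image, spec)
  relevant <- vapply(tiles, function(t) is_relevant_patch(t$patch), logical(1))
  if (!is.null(ref)) {
    for (k in seq_along(tiles)) {
      if (relevant[k])
        tiles[[k]]$patch <- reinhard_normalize(tiles[[k]]$patch, ref)
    }
  }
  manifest <- data.frame(
    row = vapply(tiles, `[[`, integer(1), "row"),
    col = vapply(tiles, `[[`, integer(1), "col"),
    relevant = relevant)
  list(patches = tiles, manifest = manifest)
}
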