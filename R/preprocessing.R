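#' Region-of-interest extraction
#'
#' Crops a raw finger image to the finger region. The image is thresholded
#' at Otsu's level; the foreground mask is morphologically closed (so dark
#' vein strokes reaching the finger boundary cannot split it), the largest
#' connected component is taken as the finger, and its tight bounding box
#' is returned. If the foreground mask is empty or covers the entire frame
#' (including the degenerate constant-image case) the detector cannot say
#' anything useful and the central crop occupying the middle 75% of each
#' dimension is returned instead, with a warning.
#'
#' @param raw numeric matrix in `[0, 1]`, at least 32x32.
#' @return the cropped sub-image (numeric matrix).
#' @seealso [normalize_size()], [normalize_gray()], [preprocess_image()]
#' @export
extract_roi <- function(raw) {
  check_gray_image(raw, min_dim = 32L)
  h <- nrow(raw); w <- ncol(raw)

  central <- function() {
    r0 <- floor(h / 8) + 1L; r1 <- r0 + floor(3 * h / 4) - 1L
    c0 <- floor(w / 8) + 1L; c1 <- c0 + floor(3 * w / 4) - 1L
    raw[r0:r1, c0:c1, drop = FALSE]
  }

  rng <- range(raw)
  if (rng[1] == rng[2]) {
    vp_warn("degenerate_roi", "constant image: falling back to central crop")
    return(central())
  }
  level <- EBImage::otsu(EBImage::Image(raw), range = rng)
  mask <- raw > level
  n_fg <- sum(mask)
  if (n_fg == 0L || n_fg == length(mask)) {
    vp_warn("degenerate_roi", "foreground mask empty or full-frame: falling back to central crop")
    return(central())
  }
  # close over dark vein strokes so they cannot split the finger region
  brush_size <- min(9L, 2L * (min(h, w) %/% 8L) + 1L)
  mask <- EBImage::closing(EBImage::Image(mask * 1), EBImage::makeBrush(brush_size, "disc")) > 0.5
  labels <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- as.integer(labels)
  counts <- tabulate(lab)
  best <- which.max(counts)
  sel <- matrix(lab == best, nrow = h)
  rows <- range(which(rowSums(sel) > 0))
  cols <- range(which(colSums(sel) > 0))
  raw[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
}

#' Size normalization by bilinear resampling
#'
#' Resamples an image to exactly `out_h` x `out_w` pixels using bilinear
#' interpolation with pixel-center alignment: output pixel centers are
#' mapped linearly onto input pixel centers, so resampling an image to its
#' own size reproduces it exactly and constant images stay constant.
#' Interpolated values are convex combinations of input pixels and
#' therefore remain inside the input's value range.
#'
#' @param img numeric matrix.
#' @param out_h,out_w target dimensions (each >= 3).
#' @return numeric `out_h` x `out_w` matrix.
#' @export
normalize_size <- function(img, out_h = 96L, out_w = 64L) {
  check_gray_image(img)
  out_h <- as.integer(out_h); out_w <- as.integer(out_w)
  if (is.na(out_h) || is.na(out_w) || out_h < 3L || out_w < 3L) {
    vp_stop("invalid_input", "target dimensions must be integers >= 3")
  }
  h <- nrow(img); w <- ncol(img)
  map_axis <- function(n_out, n_in) {
    # pixel-center mapping, clamped to the valid coordinate range
    x <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
    pmin(pmax(x, 1), n_in)
  }
  ry <- map_axis(out_h, h); rx <- map_axis(out_w, w)
  y0 <- pmin(floor(ry), h - 1L); x0 <- pmin(floor(rx), w - 1L)
  if (h == 1L) y0 <- rep(1L, out_h)
  if (w == 1L) x0 <- rep(1L, out_w)
  fy <- ry - y0; fx <- rx - x0
  y1 <- pmin(y0 + 1L, h); x1 <- pmin(x0 + 1L, w)
  a <- img[y0, x0, drop = FALSE]; b <- img[y0, x1, drop = FALSE]
  c_ <- img[y1, x0, drop = FALSE]; d <- img[y1, x1, drop = FALSE]
  wy <- matrix(fy, out_h, out_w); wx <- matrix(fx, out_h, out_w, byrow = TRUE)
  (1 - wy) * ((1 - wx) * a + wx * b) + wy * ((1 - wx) * c_ + wx * d)
}

#' Gray-level normalization
#'
#' Linear min-max stretch of the intensity range to `[0, 1]`. A constant
#' image carries no contrast information and maps to the neutral value
#' 0.5 everywhere. The map is affine, so the ordering of pixel values is
#' preserved and the result is invariant to global affine intensity
#' changes of the input.
#'
#' @param img numeric matrix.
#' @return numeric matrix with values spanning `[0, 1]` (or all 0.5).
#' @export
normalize_gray <- function(img) {
  check_gray_image(img)
  rng <- range(img)
  if (rng[1] == rng[2]) {
    return(matrix(0.5, nrow = nrow(img), ncol = ncol(img)))
  }
  (img - rng[1]) / (rng[2] - rng[1])
}

#' Full preprocessing chain
#'
#' Applies ROI extraction (optional), size normalization to the configured
#' feature-extraction resolution, and gray normalization — the pipeline a
#' raw captured finger image passes through before any binary-pattern
#' operator sees it.
#'
#' @param raw numeric matrix in `[0, 1]`.
#' @param roi if `FALSE` the image is assumed pre-cropped and ROI
#'   detection is skipped.
#' @param out_h,out_w normalized size (defaults 96 x 64).
#' @return numeric `out_h` x `out_w` matrix in `[0, 1]`.
#' @export
preprocess_image <- function(raw, roi = TRUE, out_h = 96L, out_w = 64L) {
  img <- if (roi) extract_roi(raw) else raw
  normalize_gray(normalize_size(img, out_h, out_w))
}
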