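# Run code under a local RNG state seeded deterministically, restoring
# the caller's stream afterwards.
.with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Synthetic binary-code population with controlled bit stability
#'
#' Generates the statistical structure that per-bit stability weighting
#' exploits: every class gets a uniform random template code, and each
#' sample of the class flips template bit `i` independently with that
#' position's flip probability. A fraction `f_stable` of positions are
#' stable (flip probability `q_low`); the rest are unstable
#' (`q_high`). Stable positions are drawn once and shared across classes,
#' mimicking operator bit positions that are intrinsically reliable or
#' noisy. Ground truth (templates, per-bit flip probabilities) is
#' returned for parameter-recovery tests.
#'
#' The default regime (20 classes, 16 samples, 256 bits, 30% stable
#' positions at `q_low = 0.05` against `q_high = 0.45`) is chosen to put
#' plain Hamming matching in the few-percent equal-error-rate range:
#' long codes concentrate so sharply that every matcher separates
#' perfectly and comparisons become vacuous, while this regime keeps the
#' matchers distinguishable at desk scale.
#'
#' @param n_classes number of classes.
#' @param n_samples samples per class.
#' @param code_length bits per code.
#' @param f_stable fraction of stable bit positions.
#' @param q_low,q_high flip probabilities of stable/unstable positions
#'   (`0 <= q_low <= q_high <= 0.5`).
#' @param seed integer seed; identical inputs give bit-identical output.
#' @param operator_tag tag stamped on the generated codes.
#' @return list: `gallery` (a [code_gallery()]), `templates` (named list
#'   of 0/1 vectors), `flip_probs` (per-bit vector), `stable_positions`.
#' @export
generate_code_population <- function(n_classes = 20L, n_samples = 16L,
                                     code_length = 256L, f_stable = 0.3,
                                     q_low = 0.05, q_high = 0.45,
                                     seed = 1L, operator_tag = "synthetic") {
  if (n_classes < 1L || n_samples < 1L || code_length < 1L) {
    vp_stop("invalid_input", "n_classes, n_samples and code_length must be positive")
  }
  if (!(q_low >= 0 && q_low <= q_high && q_high <= 0.5)) {
    vp_stop("invalid_input", "flip probabilities must satisfy 0 <= q_low <= q_high <= 0.5")
  }
  if (f_stable < 0 || f_stable > 1) vp_stop("invalid_input", "f_stable must lie in [0, 1]")
  .with_seed(seed, {
    n_stable <- round(f_stable * code_length)
    stable_positions <- sort(sample.int(code_length, n_stable))
    flip_probs <- rep(q_high, code_length)
    flip_probs[stable_positions] <- q_low
    ids <- sprintf("class%03d", seq_len(n_classes))
    templates <- list(); classes <- list()
    for (id in ids) {
      tmpl <- sample(0:1, code_length, replace = TRUE)
      templates[[id]] <- tmpl
      classes[[id]] <- lapply(seq_len(n_samples), function(s) {
        flips <- stats::runif(code_length) < flip_probs
        binary_code(ifelse(flips, 1L - tmpl, tmpl), operator_tag)
      })
    }
    list(gallery = code_gallery(classes), templates = templates,
         flip_probs = flip_probs, stable_positions = stable_positions)
  })
}

#' Specification of a synthetic vein-image class
#'
#' Parameters of the renderer behind [generate_vein_image_class()]:
#' image size, number of vein curves, stroke width and darkness, additive
#' pixel noise and per-sample geometric jitter. Per-class vein geometry
#' is fixed by the seed; jitter and noise are resampled per sample.
#'
#' @param height,width image size in pixels.
#' @param n_veins number of vein curves.
#' @param vein_width_px stroke width in pixels.
#' @param contrast how much darker a vein is than the finger tissue
#'   (intensity units on `[0, 1]`).
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param warp_sd standard deviation of the per-sample random translation
#'   (pixels).
#' @param seed integer seed fixing the class geometry.
#' @return a `vein_image_spec` list.
#' @export
vein_image_spec <- function(height = 120L, width = 160L, n_veins = 4L,
                            vein_width_px = 3, contrast = 0.35,
                            noise_sd = 0.04, warp_sd = 1.0, seed = 1L) {
  if (height < 32L || width < 32L) vp_stop("invalid_input", "images must be at least 32x32")
  if (n_veins < 1L) vp_stop("invalid_input", "need at least one vein")
  if (vein_width_px <= 0 || contrast < 0 || contrast > 1 || noise_sd < 0 || warp_sd < 0) {
    vp_stop("invalid_input", "invalid rendering parameters")
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_veins = as.integer(n_veins), vein_width_px = vein_width_px,
                 contrast = contrast, noise_sd = noise_sd, warp_sd = warp_sd,
                 seed = as.integer(seed)),
            class = "vein_image_spec")
}

# Superellipse finger mask: a bright rounded band with a dark border,
# the shape ROI extraction is expected to find.
.finger_mask <- function(h, w) {
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ry <- 0.36 * h; rx <- 0.42 * w
  r <- matrix(seq_len(h), h, w); c_ <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((r - cy) / ry)^4 + ((c_ - cx) / rx)^4 <= 1
}

# Sample smooth vein centerlines for one class: each vein is a spline
# through random control points running across the finger.
.sample_vein_curves <- function(spec, mask) {
  h <- spec$height; w <- spec$width
  inside <- which(rowSums(mask) > 0)
  y_lo <- min(inside) + 2; y_hi <- max(inside) - 2
  lapply(seq_len(spec$n_veins), function(v) {
    n_ctrl <- 5L
    cx <- seq(1, w, length.out = n_ctrl)
    cy <- stats::runif(n_ctrl, y_lo, y_hi)
    xs <- seq(1, w, length.out = 3L * w)
    ys <- stats::spline(cx, cy, xout = xs)$y
    cbind(y = ys, x = xs)
  })
}

# Paint dark strokes of the given width along curve points (after adding
# the sample's translation jitter), restricted to the finger mask.
.render_veins <- function(canvas, curves, mask, width_px, contrast, dy, dx) {
  h <- nrow(canvas); w <- ncol(canvas)
  r_px <- max(1, round(width_px / 2))
  disk <- expand.grid(dr = -r_px:r_px, dc = -r_px:r_px)
  disk <- disk[disk$dr^2 + disk$dc^2 <= r_px^2, ]
  vein <- matrix(FALSE, h, w)
  for (curve in curves) {
    yy <- round(curve[, "y"] + dy); xx <- round(curve[, "x"] + dx)
    keep <- !duplicated(cbind(yy, xx))
    yy <- yy[keep]; xx <- xx[keep]
    for (j in seq_len(nrow(disk))) {
      r <- yy + disk$dr[j]; c_ <- xx + disk$dc[j]
      ok <- r >= 1 & r <= h & c_ >= 1 & c_ <= w
      vein[cbind(r[ok], c_[ok])] <- TRUE
    }
  }
  vein <- vein & mask
  canvas[vein] <- canvas[vein] - contrast
  canvas
}

#' Generate one class of synthetic vein images
#'
#' Renders a class of near-infrared-like finger images: a bright
#' superelliptic finger region on a dark background, crossed by
#' `n_veins` smooth dark curves (the class's fixed vascular geometry).
#' Each sample then receives a random rigid translation of the vein
#' pattern (sd `warp_sd` pixels) and additive Gaussian pixel noise,
#' emulating repeated captures of one finger. Deterministic given
#' `spec$seed`.
#'
#' @param spec a [vein_image_spec()].
#' @param n_samples number of sample images.
#' @return list: `images` (list of `[0, 1]` matrices), `finger_mask`
#'   (logical ground-truth matrix), `spec`.
#' @export
generate_vein_image_class <- function(spec, n_samples = 10L) {
  stopifnot(inherits(spec, "vein_image_spec"))
  if (n_samples < 1L) vp_stop("invalid_input", "n_samples must be positive")
  .with_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    mask <- .finger_mask(h, w)
    base <- matrix(0.15, h, w)
    base[mask] <- 0.78
    curves <- .sample_vein_curves(spec, mask)
    images <- lapply(seq_len(n_samples), function(s) {
      dy <- stats::rnorm(1, 0, spec$warp_sd); dx <- stats::rnorm(1, 0, spec$warp_sd)
      img <- .render_veins(base, curves, mask, spec$vein_width_px, spec$contrast, dy, dx)
      if (spec$noise_sd > 0) img <- img + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
      pmin(pmax(img, 0), 1)
    })
    list(images = images, finger_mask = mask, spec = spec)
  })
}

#' Generate a multi-class synthetic vein-image gallery
#'
#' One [generate_vein_image_class()] call per class, with per-class
#' geometry seeds derived from the master seed.
#'
#' @param n_classes number of classes.
#' @param n_samples samples per class.
#' @param spec a [vein_image_spec()]; its seed field is overridden per class.
#' @param seed master seed.
#' @return named list: class id -> list of image matrices, with the
#'   per-class ground-truth masks in attribute `"finger_masks"`.
#' @export
generate_vein_gallery <- function(n_classes = 6L, n_samples = 8L,
                                  spec = vein_image_spec(), seed = 1L) {
  ids <- sprintf("class%03d", seq_len(n_classes))
  masks <- list(); out <- list()
  for (i in seq_along(ids)) {
    spec_i <- spec
    spec_i$seed <- (seed * 1009L + i) %% .Machine$integer.max
    cls <- generate_vein_image_class(spec_i, n_samples)
    out[[ids[i]]] <- cls$images
    masks[[ids[i]]] <- cls$finger_mask
  }
  attr(out, "finger_masks") <- masks
  out
}

#' Write a synthetic image gallery to disk
#'
#' Materializes a generated gallery in the on-disk layout consumed by
#' [read_image_gallery()] (`dir/<class_id>/<index>.png`, zero-padded
#' indices), plus a `ground_truth.json` sidecar recording the generator
#' settings.
#'
#' @param images named list from [generate_vein_gallery()].
#' @param dir destination directory.
#' @param meta optional metadata list stored in the sidecar.
#' @return `dir`, invisibly.
#' @export
write_image_gallery <- function(images, dir, meta = list()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (id in names(images)) {
    cls_dir <- file.path(dir, id)
    dir.create(cls_dir, showWarnings = FALSE)
    samples <- images[[id]]
    for (s in seq_along(samples)) {
      write_gray_image(samples[[s]], file.path(cls_dir, sprintf("%03d.png", s)))
    }
  }
  jsonlite::write_json(c(list(n_classes = length(images),
                              n_samples = lengths(images)[[1]]), meta),
                       file.path(dir, "ground_truth.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
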