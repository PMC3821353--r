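#' Sign threshold for binary-pattern operators
#'
#' The elementary comparison behind every binary-pattern bit: a gray-level
#' difference of zero or more yields 1, a negative difference yields 0.
#' The equality case belongs to 1, which is why a constant image produces
#' an all-ones code under every operator in this package.
#'
#' @param x numeric vector of finite differences.
#' @return integer vector of 0/1.
#' @export
threshold_sign <- function(x) {
  if (any(!is.finite(x))) vp_stop("invalid_input", "differences must be finite")
  as.integer(x >= 0)
}

# Interior-pixel neighbor offsets for the 3x3 LBP kernel, starting at the
# top-left neighbor and proceeding clockwise. Each row is (drow, dcol).
.lbp_offsets <- matrix(c(-1L, -1L,  -1L, 0L,  -1L, 1L,  0L, 1L,
                          1L, 1L,   1L, 0L,   1L, -1L,  0L, -1L),
                       ncol = 2L, byrow = TRUE)

# 8 x n_pixels matrix of LBP bits; pixels in row-major order.
.lbp_bitplanes <- function(img) {
  h <- nrow(img); w <- ncol(img)
  if (h < 3L || w < 3L) vp_stop("invalid_input", "LBP needs an image of at least 3x3")
  ctr <- img[2:(h - 1L), 2:(w - 1L), drop = FALSE]
  planes <- matrix(0L, nrow = 8L, ncol = (h - 2L) * (w - 2L))
  for (k in 1:8) {
    dr <- .lbp_offsets[k, 1]; dc <- .lbp_offsets[k, 2]
    nbr <- img[(2:(h - 1L)) + dr, (2:(w - 1L)) + dc, drop = FALSE]
    planes[k, ] <- as.integer(t(nbr >= ctr))  # row-major flatten
  }
  planes
}

#' LBP binary code of an image
#'
#' For every interior pixel (the one-pixel border is skipped — no padding
#' is invented) the eight neighbors of the 3x3 kernel are compared against
#' the center: neighbor minus center, sign-thresholded. The eight bits per
#' pixel start at the top-left neighbor and proceed clockwise; per-pixel
#' groups are concatenated in row-major pixel order. The code length is
#' `(h - 2) * (w - 2) * 8` bits.
#'
#' @param img numeric matrix, at least 3x3.
#' @return a [binary_code()] with operator tag `"lbp"`.
#' @export
lbp_code <- function(img) {
  check_gray_image(img)
  binary_code(as.vector(.lbp_bitplanes(img)), "lbp")
}

#' Decimal LBP view
#'
#' The per-pixel base-2 reading of the LBP bits, with bit k (in the same
#' top-left clockwise order as [lbp_code()]) weighted by `2^k`. This is a
#' diagnostic/visualization view; matching always uses the binary code.
#'
#' @param img numeric matrix, at least 3x3.
#' @return integer matrix of dimension `(h - 2) x (w - 2)`, values 0-255.
#' @export
lbp_decimal <- function(img) {
  planes <- .lbp_bitplanes(img)
  vals <- as.integer(colSums(planes * 2L^(0:7)))
  matrix(vals, nrow = nrow(img) - 2L, byrow = TRUE)
}

#' LLBP operator parameters
#'
#' The line local binary pattern compares pixels along a horizontal or
#' vertical line of odd length `N` against the line's center pixel
#' (position `c = (N + 1) / 2`), yielding `N - 1` bits per direction per
#' pixel.
#'
#' @param N odd integer >= 3, the line length in pixels (default 21).
#' @return a list with `N` and center index `c`.
#' @export
llbp_params <- function(N = 21L) {
  N <- as.integer(N)
  if (is.na(N) || N < 3L || N %% 2L == 0L) {
    vp_stop("invalid_input", "LLBP line length N must be an odd integer >= 3")
  }
  list(N = N, c = (N + 1L) %/% 2L)
}

# Shared engine for horizontal/vertical LLBP. Returns the (N-1) x n_pixels
# bit-plane matrix (bits in ascending line position n, skipping the
# center) plus the valid pixel domain; pixels row-major.
.llbp_bitplanes <- function(img, params, direction = c("h", "v")) {
  direction <- match.arg(direction)
  N <- params$N; cc <- params$c
  h <- nrow(img); w <- ncol(img)
  half <- (N - 1L) %/% 2L
  if (direction == "h") {
    if (w < N) vp_stop("invalid_input", sprintf("image width %d < line length N = %d", w, N))
    rows <- seq_len(h); cols <- (half + 1L):(w - half)
  } else {
    if (h < N) vp_stop("invalid_input", sprintf("image height %d < line length N = %d", h, N))
    rows <- (half + 1L):(h - half); cols <- seq_len(w)
  }
  ctr <- img[rows, cols, drop = FALSE]
  offsets <- setdiff(seq_len(N), cc) - cc
  planes <- matrix(0L, nrow = N - 1L, ncol = length(rows) * length(cols))
  for (k in seq_along(offsets)) {
    d <- offsets[k]
    nbr <- if (direction == "h") img[rows, cols + d, drop = FALSE]
           else                  img[rows + d, cols, drop = FALSE]
    planes[k, ] <- as.integer(t(nbr >= ctr))
  }
  planes
}

#' Horizontal-line LLBP code
#'
#' For every pixel whose horizontal line of length `N` fits inside the
#' image, emits the `N - 1` bits comparing each line pixel against the
#' center pixel, in ascending line position (the center itself is
#' skipped); per-pixel groups concatenate in row-major pixel order.
#' Code length: `h * (w - (N - 1)) * (N - 1)` bits.
#'
#' @param img numeric matrix with `ncol(img) >= N`.
#' @param params an [llbp_params()] list.
#' @return a [binary_code()] tagged `"llbp-h-N{N}"`.
#' @export
llbp_h_code <- function(img, params = llbp_params()) {
  check_gray_image(img)
  bits <- as.vector(.llbp_bitplanes(img, params, "h"))
  binary_code(bits, sprintf("llbp-h-N%d", params$N))
}

#' Vertical-line LLBP code
#'
#' The vertical counterpart of [llbp_h_code()]: lines of length `N` run
#' down each column. Code length: `(h - (N - 1)) * w * (N - 1)` bits.
#'
#' @inheritParams llbp_h_code
#' @return a [binary_code()] tagged `"llbp-v-N{N}"`.
#' @export
llbp_v_code <- function(img, params = llbp_params()) {
  check_gray_image(img)
  bits <- as.vector(.llbp_bitplanes(img, params, "v"))
  binary_code(bits, sprintf("llbp-v-N%d", params$N))
}

#' Concatenated LLBP code
#'
#' The full LLBP feature: the horizontal code followed by the vertical
#' code, each over its own valid-pixel domain. On the common domain every
#' pixel contributes `2 (N - 1)` bits.
#'
#' @inheritParams llbp_h_code
#' @return a [binary_code()] tagged `"llbp-N{N}"`.
#' @export
llbp_code <- function(img, params = llbp_params()) {
  check_gray_image(img)
  bh <- .llbp_bitplanes(img, params, "h")
  bv <- .llbp_bitplanes(img, params, "v")
  binary_code(c(as.vector(bh), as.vector(bv)), sprintf("llbp-N%d", params$N))
}

#' LLBP magnitude map
#'
#' Per-pixel magnitude `sqrt(LLBPh^2 + LLBPv^2)` of the decimal-weighted
#' line patterns, where a line bit at position `n` carries weight
#' `2^(|n - c| - 1)`. Computed over the intersection of the horizontal and
#' vertical valid domains. Diagnostic only: it characterizes local
#' intensity change (edges, corners); matching uses binary codes.
#'
#' @inheritParams llbp_h_code
#' @return numeric matrix of dimension `(h - (N - 1)) x (w - (N - 1))`.
#' @export
llbp_magnitude <- function(img, params = llbp_params()) {
  check_gray_image(img)
  N <- params$N; cc <- params$c
  h <- nrow(img); w <- ncol(img)
  if (h < N || w < N) vp_stop("invalid_input", "image smaller than the LLBP line length")
  half <- (N - 1L) %/% 2L
  rows <- (half + 1L):(h - half); cols <- (half + 1L):(w - half)
  ctr <- img[rows, cols, drop = FALSE]
  dec <- function(direction) {
    acc <- matrix(0, nrow = length(rows), ncol = length(cols))
    for (n in setdiff(seq_len(N), cc)) {
      d <- n - cc
      nbr <- if (direction == "h") img[rows, cols + d, drop = FALSE]
             else                  img[rows + d, cols, drop = FALSE]
      acc <- acc + (nbr >= ctr) * 2^(abs(d) - 1L)
    }
    acc
  }
  sqrt(dec("h")^2 + dec("v")^2)
}

#' Extract a binary code with a named operator
#'
#' Convenience dispatcher mapping an operator name to the corresponding
#' code extractor: `"lbp"`, `"llbp"`, `"llbp-h"`, or `"llbp-v"`.
#'
#' @param img numeric matrix.
#' @param operator operator name.
#' @param N LLBP line length (ignored for `"lbp"`).
#' @return a [binary_code()].
#' @export
extract_code <- function(img, operator = c("lbp", "llbp", "llbp-h", "llbp-v"), N = 21L) {
  operator <- match.arg(operator)
  switch(operator,
    "lbp"    = lbp_code(img),
    "llbp"   = llbp_code(img, llbp_params(N)),
    "llbp-h" = llbp_h_code(img, llbp_params(N)),
    "llbp-v" = llbp_v_code(img, llbp_params(N))
  )
}
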