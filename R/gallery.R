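#' A gallery of binary codes
#'
#' The container all evaluation protocols consume: a named list mapping
#' each class id to its ordered list of [binary_code()] samples. Sample
#' order is significant — the positional protocols ("first k as training",
#' "last n as test") index into it.
#'
#' @param classes named list; each element a list of [binary_code()]
#'   objects sharing one operator tag across the whole gallery.
#' @return a `code_gallery`.
#' @export
code_gallery <- function(classes) {
  if (!is.list(classes) || length(classes) == 0L) {
    vp_stop("invalid_input", "a gallery needs at least one class")
  }
  ids <- names(classes)
  if (is.null(ids) || anyNA(ids) || any(ids == "") || anyDuplicated(ids)) {
    vp_stop("invalid_input", "classes must be uniquely named by class id")
  }
  ref <- NULL
  for (id in ids) {
    samples <- classes[[id]]
    if (!is.list(samples) || length(samples) == 0L) {
      vp_stop("invalid_input", sprintf("class '%s' has no samples", id))
    }
    for (cd in samples) {
      if (!inherits(cd, "binary_code")) {
        vp_stop("invalid_input", sprintf("class '%s' contains a non-code sample", id))
      }
      if (is.null(ref)) ref <- cd else check_compatible(ref, cd, "gallery codes")
    }
  }
  structure(list(classes = classes, operator_tag = ref$operator_tag,
                 n_bits = ref$n_bits),
            class = "code_gallery")
}

#' @export
print.code_gallery <- function(x, ...) {
  ns <- lengths(x$classes)
  cat(sprintf("<code_gallery> %d classes, %s samples/class, %d-bit '%s' codes\n",
              length(x$classes),
              if (length(unique(ns)) == 1L) ns[1] else sprintf("%d-%d", min(ns), max(ns)),
              x$n_bits, x$operator_tag))
  invisible(x)
}

#' Read an image gallery from disk
#'
#' Expects the layout `dir/<class_id>/<sample>.png` (or `.pgm`/`.bmp`):
#' one subdirectory per class, samples ordered by file name, which is why
#' the writers in this package zero-pad sample indices.
#'
#' @param dir gallery root directory.
#' @return named list: class id -> character vector of sample paths.
#' @export
read_image_gallery <- function(dir) {
  if (!dir.exists(dir)) vp_stop("invalid_input", sprintf("no such gallery directory: '%s'", dir))
  class_dirs <- sort(list.dirs(dir, recursive = FALSE))
  if (length(class_dirs) == 0L) vp_stop("invalid_input", "gallery directory contains no class subdirectories")
  out <- lapply(class_dirs, function(d) {
    files <- sort(list.files(d, pattern = "\\.(png|pgm|bmp)$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0L) vp_stop("protocol_violation", sprintf("class directory '%s' holds no images", d))
    files
  })
  names(out) <- basename(class_dirs)
  out
}

#' Extract a code gallery from an image gallery
#'
#' Runs every sample of every class through the preprocessing chain and
#' the selected binary-pattern operator.
#'
#' @param images either a gallery directory path or the named list
#'   returned by [read_image_gallery()]; list elements may be file paths
#'   or in-memory image matrices.
#' @param operator one of `"lbp"`, `"llbp"`, `"llbp-h"`, `"llbp-v"`.
#' @param N LLBP line length.
#' @param roi run ROI detection (`FALSE` for pre-cropped inputs).
#' @param out_h,out_w normalized image size.
#' @return a [code_gallery()].
#' @export
gallery_codes <- function(images, operator = "lbp", N = 21L, roi = TRUE,
                          out_h = 96L, out_w = 64L) {
  if (is.character(images) && length(images) == 1L && dir.exists(images)) {
    images <- read_image_gallery(images)
  }
  classes <- lapply(images, function(samples) {
    if (is.character(samples)) samples <- lapply(samples, read_gray_image)
    if (is.matrix(samples)) samples <- list(samples)
    lapply(samples, function(img) {
      extract_code(preprocess_image(img, roi = roi, out_h = out_h, out_w = out_w),
                   operator = operator, N = N)
    })
  })
  code_gallery(classes)
}

# Split helper: per-class train/test indices for positional protocols.
.split_first_k <- function(gallery, k_train) {
  lapply(gallery$classes, function(samples) {
    n <- length(samples)
    if (n < k_train + 1L) NULL else list(train = seq_len(k_train), test = (k_train + 1L):n)
  })
}
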