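#' Enrolled-class template bundle
#'
#' Bundles everything matching needs for one enrolled class: the trained
#' weight map, the best-bit mask and template, and the enrollment codes
#' themselves (kept so any code can play the enrolled role at match time).
#'
#' @param codes list of [binary_code()] training codes (>= 2).
#' @param class_id class identifier.
#' @return a `class_template` object.
#' @export
class_template <- function(codes, class_id) {
  wm <- train_pwm(codes, class_id)
  pb <- withCallingHandlers(
    train_pbbm(codes, class_id),
    veinpwm_degenerate_template = function(w) invokeRestart("muffleWarning")
  )
  structure(
    list(class_id = class_id, operator_tag = wm$operator_tag,
         k_train = wm$k_train, n_bits = wm$n_bits,
         codes = codes, weight_map = wm,
         pbbm_mask = pb$mask, pbbm_template = pb$template),
    class = "class_template"
  )
}

#' @export
print.class_template <- function(x, ...) {
  cat(sprintf("<class_template> '%s': %d codes of %d bits (operator '%s'), %d best bits\n",
              x$class_id, length(x$codes), x$n_bits, x$operator_tag, sum(x$pbbm_mask$mask)))
  invisible(x)
}

.TEMPLATE_MAGIC <- charToRaw("PWMT")
.TEMPLATE_VERSION <- 1L

#' Write a class template to disk
#'
#' Serializes a [class_template()] as `<class_id>.pwm` — a little-endian
#' binary container (magic `PWMT`, version, operator tag, bit-packed
#' enrollment codes, best-bit mask and template, and the weight vector as
#' 64-bit IEEE doubles so that read/write round-trips are bit-exact) —
#' plus a human-readable `<class_id>.json` metadata sidecar.
#'
#' @param template a `class_template`.
#' @param dir destination directory (created if missing).
#' @return path to the `.pwm` file, invisibly.
#' @export
write_template <- function(template, dir) {
  stopifnot(inherits(template, "class_template"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, paste0(template$class_id, ".pwm"))
  con <- file(path, "wb")
  on.exit(close(con))
  wstr <- function(s) {
    b <- charToRaw(as.character(s))
    writeBin(length(b), con, size = 4L, endian = "little")
    writeBin(b, con)
  }
  writeBin(.TEMPLATE_MAGIC, con)
  writeBin(.TEMPLATE_VERSION, con, size = 4L, endian = "little")
  wstr(template$class_id)
  wstr(template$operator_tag)
  writeBin(template$n_bits, con, size = 4L, endian = "little")
  writeBin(template$k_train, con, size = 4L, endian = "little")
  writeBin(length(template$codes), con, size = 4L, endian = "little")
  for (cd in template$codes) writeBin(cd$bits, con)
  writeBin(template$weight_map$weights, con, size = 8L, endian = "little")
  writeBin(packBits(as.raw(c(template$pbbm_mask$mask,
                             integer((8L - template$n_bits %% 8L) %% 8L))), type = "raw"), con)
  writeBin(template$pbbm_template$bits, con)
  meta <- list(class_id = template$class_id, operator_tag = template$operator_tag,
               n_bits = template$n_bits, k_train = template$k_train,
               n_codes = length(template$codes), format_version = .TEMPLATE_VERSION,
               n_best_bits = sum(template$pbbm_mask$mask))
  jsonlite::write_json(meta, file.path(dir, paste0(template$class_id, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a class template from disk
#'
#' @param path path to a `.pwm` file written by [write_template()].
#' @return a `class_template`.
#' @export
read_template <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readBin(con, "raw", 4L), .TEMPLATE_MAGIC)) {
    vp_stop("invalid_input", sprintf("'%s' is not a template file (bad magic)", path))
  }
  version <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (version != .TEMPLATE_VERSION) {
    vp_stop("invalid_input", sprintf("unsupported template format version %d", version))
  }
  rstr <- function() {
    n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    rawToChar(readBin(con, "raw", n))
  }
  class_id <- rstr()
  tag <- rstr()
  n_bits <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  k_train <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  n_codes <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  n_bytes <- (n_bits + 7L) %/% 8L
  read_code <- function() {
    packed <- readBin(con, "raw", n_bytes)
    structure(list(bits = packed, n_bits = n_bits, operator_tag = tag),
              class = "binary_code")
  }
  codes <- lapply(seq_len(n_codes), function(i) read_code())
  weights <- readBin(con, "double", n_bits, size = 8L, endian = "little")
  mask_bits <- as.integer(rawToBits(readBin(con, "raw", n_bytes)))[seq_len(n_bits)]
  pbbm_template <- read_code()
  structure(
    list(class_id = class_id, operator_tag = tag, k_train = k_train,
         n_bits = n_bits, codes = codes,
         weight_map = structure(
           list(weights = weights, n_bits = n_bits, operator_tag = tag,
                k_train = k_train, class_id = class_id),
           class = "weight_map"),
         pbbm_mask = structure(
           list(mask = mask_bits, n_bits = n_bits, operator_tag = tag,
                k_train = k_train, class_id = class_id),
           class = "best_bit_mask"),
         pbbm_template = pbbm_template),
    class = "class_template"
  )
}
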