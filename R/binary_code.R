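#' Binary feature codes
#'
#' A `binary_code` is an ordered, fixed-length sequence of bits extracted
#' from one image by one binary-pattern operator. It is the matching
#' currency of the package: Hamming-type comparisons are defined only
#' between codes of equal length carrying the same `operator_tag`.
#'
#' Bits are stored packed eight-to-a-byte in a `raw` vector together with
#' the logical bit length; all operations address bits logically, so the
#' padding bits of the final byte are always zero and never observable.
#'
#' @param bits integer, logical or numeric vector of 0/1 values, in bit
#'   order (bit 1 first).
#' @param operator_tag identifier of the producing operator and its
#'   parameters, e.g. `"lbp"` or `"llbp-N21"`. Codes with different tags
#'   are never comparable.
#' @return An object of class `binary_code` with fields `bits` (packed
#'   raw), `n_bits` and `operator_tag`.
#' @examples
#' a <- binary_code(c(1, 0, 1, 1, 0), "demo")
#' code_bits(a)
#' @export
binary_code <- function(bits, operator_tag) {
  if (is.logical(bits)) bits <- as.integer(bits)
  bits <- as.integer(bits)
  if (length(bits) == 0L) vp_stop("invalid_input", "a binary code must contain at least one bit")
  if (anyNA(bits) || any(bits != 0L & bits != 1L)) {
    vp_stop("invalid_input", "bits must be 0/1 with no missing values")
  }
  if (!is.character(operator_tag) || length(operator_tag) != 1L || is.na(operator_tag)) {
    vp_stop("invalid_input", "operator_tag must be a single string")
  }
  n <- length(bits)
  pad <- (8L - n %% 8L) %% 8L
  packed <- packBits(as.raw(c(bits, integer(pad))), type = "raw")
  structure(
    list(bits = packed, n_bits = n, operator_tag = operator_tag),
    class = "binary_code"
  )
}

#' Unpack a binary code to an integer 0/1 vector
#'
#' @param code a [binary_code()].
#' @return integer vector of length `code$n_bits`.
#' @export
code_bits <- function(code) {
  stopifnot(inherits(code, "binary_code"))
  as.integer(rawToBits(code$bits))[seq_len(code$n_bits)]
}

#' @export
print.binary_code <- function(x, ...) {
  cat(sprintf("<binary_code> %d bits, operator '%s'\n", x$n_bits, x$operator_tag))
  head_n <- min(x$n_bits, 32L)
  cat(" first bits:", paste(code_bits(x)[seq_len(head_n)], collapse = ""),
      if (x$n_bits > head_n) "...\n" else "\n")
  invisible(x)
}

#' @export
length.binary_code <- function(x) x$n_bits

# Per-byte population count, indexed by byte value + 1.
.bitcount_table <- vapply(0:255, function(b) sum(bitwAnd(b, bitwShiftL(1L, 0:7)) != 0L), integer(1))

# Number of differing bits between two codes with identical packing
# (padding bits are zero in both, so they never contribute).
code_xor_count <- function(a, b) {
  sum(.bitcount_table[as.integer(xor(a$bits, b$bits)) + 1L])
}

# Stop unless two codes (or a code and a weight-like object with n_bits /
# operator_tag) are comparable.
check_compatible <- function(a, b, what = "codes") {
  if (a$n_bits != b$n_bits) {
    vp_stop("incompatible_codes",
            sprintf("%s differ in length (%d vs %d bits)", what, a$n_bits, b$n_bits))
  }
  if (!identical(a$operator_tag, b$operator_tag)) {
    vp_stop("incompatible_codes",
            sprintf("%s carry different operator tags ('%s' vs '%s')",
                    what, a$operator_tag, b$operator_tag))
  }
  invisible(TRUE)
}
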