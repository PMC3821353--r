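#' Normalized Hamming distance between two binary codes
#'
#' The fraction of bit positions at which two equal-length codes differ
#' (exclusive-OR count divided by code length). This is the plain,
#' unweighted dissimilarity that all binary-pattern matching builds on;
#' `1 - hamming_distance(a, b)` is the plain matching similarity.
#'
#' @param a,b [binary_code()] objects of equal length and operator tag.
#' @return a number in `[0, 1]`.
#' @export
hamming_distance <- function(a, b) {
  stopifnot(inherits(a, "binary_code"), inherits(b, "binary_code"))
  check_compatible(a, b)
  code_xor_count(a, b) / a$n_bits
}

#' Train a personalized weight map
#'
#' Measures the stability of every bit position across `k >= 2` training
#' codes of one enrolled class and converts it into a per-bit matching
#' weight. Conceptually all `k x k` ordered intraclass comparisons
#' (including self-comparisons) are averaged: at bit `i` the fraction of
#' comparisons that agree is
#' \deqn{p_i = (m_1^2 + m_0^2) / k^2}
#' where `m_1` codes carry a 1 at bit `i` and `m_0 = k - m_1` carry a 0.
#' `p_i` always lies in `[0.5, 1]`; the weight is the rescaling
#' `w_i = 2 p_i - 1` into `[0, 1]`. Perfectly stable bits get weight 1,
#' maximally interlaced bits get weight 0, and with `k` training codes the
#' weights are quantized to the `k + 1` values attainable by `m_1 = 0..k`.
#'
#' @param codes list of at least two [binary_code()] objects with equal
#'   length and operator tag.
#' @param class_id identifier of the enrolled class.
#' @return a `weight_map` object: numeric `weights` in `[0, 1]` plus
#'   `n_bits`, `operator_tag`, `k_train`, `class_id`.
#' @export
train_pwm <- function(codes, class_id = NA_character_) {
  k <- length(codes)
  if (k < 2L) {
    vp_stop("insufficient_training",
            "a weight map needs at least 2 training codes (a single code carries no stability signal)")
  }
  for (cd in codes) {
    stopifnot(inherits(cd, "binary_code"))
    check_compatible(codes[[1]], cd, "training codes")
  }
  m1 <- Reduce(`+`, lapply(codes, code_bits))
  m0 <- k - m1
  p <- (m1^2 + m0^2) / k^2
  structure(
    list(weights = 2 * p - 1, n_bits = codes[[1]]$n_bits,
         operator_tag = codes[[1]]$operator_tag, k_train = k,
         class_id = class_id),
    class = "weight_map"
  )
}

#' @export
print.weight_map <- function(x, ...) {
  cat(sprintf("<weight_map> class '%s': %d bits, k_train = %d, operator '%s'\n",
              x$class_id, x$n_bits, x$k_train, x$operator_tag))
  cat(sprintf(" mean weight %.4f, %d bits at weight 1\n",
              mean(x$weights), sum(x$weights == 1)))
  invisible(x)
}

#' Train a personalized best-bit map
#'
#' The best-bit restriction of weight-map training: a bit is "best" when
#' it is identical across all training codes, i.e. exactly when its
#' trained weight is 1. The result is a 0/1 mask plus a template code
#' carrying the constant bit value at masked positions (0 elsewhere,
#' unused in matching). If no bit is perfectly stable the mask is still
#' returned with a warning; using it at match time is an error.
#'
#' @inheritParams train_pwm
#' @return a list with `mask` (a `best_bit_mask`: integer 0/1 vector plus
#'   metadata) and `template` (a [binary_code()]).
#' @export
train_pbbm <- function(codes, class_id = NA_character_) {
  wm <- train_pwm(codes, class_id)
  mask <- as.integer(wm$weights == 1)
  if (sum(mask) == 0L) {
    vp_warn("degenerate_template", "no bit is constant across the training codes; empty best-bit mask")
  }
  template_bits <- code_bits(codes[[1]]) * mask
  list(
    mask = structure(
      list(mask = mask, n_bits = wm$n_bits, operator_tag = wm$operator_tag,
           k_train = wm$k_train, class_id = class_id),
      class = "best_bit_mask"
    ),
    template = binary_code(template_bits, codes[[1]]$operator_tag)
  )
}

#' Weight-map-modulated similarity
#'
#' The weighted matching score between the code of the enrolled class and
#' a probe code:
#' \deqn{S = 1 - \sum_i w_i \, xor(a_i, b_i) \, / \, \sum_i w_i}
#' Disagreements at stable (high-weight) positions are penalized fully;
#' disagreements at unstable positions barely count. The weight map is
#' the one trained for the ENROLLED class, so the score is asymmetric in
#' the roles of the two codes. With all weights equal to 1 the score
#' reduces exactly to one minus the plain Hamming distance.
#'
#' @param enrolled [binary_code()] playing the enrolled-class role.
#' @param probe [binary_code()] being tested.
#' @param w `weight_map` of the enrolled class (or a `best_bit_mask`,
#'   giving the best-bit score).
#' @return a number in `[0, 1]`.
#' @export
weighted_similarity <- function(enrolled, probe, w) {
  stopifnot(inherits(enrolled, "binary_code"), inherits(probe, "binary_code"))
  check_compatible(enrolled, probe)
  weights <- if (inherits(w, "best_bit_mask")) as.numeric(w$mask)
             else if (inherits(w, "weight_map")) w$weights
             else vp_stop("invalid_input", "w must be a weight_map or best_bit_mask")
  check_compatible(enrolled, w, "code and weight map")
  total <- sum(weights)
  if (total <= 0) vp_stop("degenerate_weights", "weight map sums to zero; no bit can contribute to matching")
  diffs <- as.integer(rawToBits(xor(enrolled$bits, probe$bits)))[seq_len(enrolled$n_bits)]
  1 - sum(weights * diffs) / total
}

#' Best-bit similarity
#'
#' Matching restricted to the best bits: one minus the fraction of
#' differing bits among masked positions. Identical to
#' [weighted_similarity()] with the 0/1 mask used as weight map.
#'
#' @param template [binary_code()] best-bit template of the enrolled class.
#' @param probe [binary_code()] being tested.
#' @param mask `best_bit_mask` of the enrolled class with at least one set bit.
#' @return a number in `[0, 1]`.
#' @export
pbbm_similarity <- function(template, probe, mask) {
  if (!inherits(mask, "best_bit_mask")) vp_stop("invalid_input", "mask must be a best_bit_mask")
  if (sum(mask$mask) == 0L) vp_stop("degenerate_template", "empty best-bit mask cannot be matched against")
  weighted_similarity(template, probe, mask)
}

#' Accept/reject decision
#'
#' A probe is accepted as belonging to the enrolled class exactly when
#' its similarity strictly exceeds the operating threshold.
#'
#' @param similarity,threshold numbers in `[0, 1]`.
#' @return logical.
#' @export
decide <- function(similarity, threshold) {
  if (similarity < 0 || similarity > 1 || threshold < 0 || threshold > 1) {
    vp_stop("invalid_input", "similarity and threshold must lie in [0, 1]")
  }
  similarity > threshold
}
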