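# Naive, unvectorized reference implementations. These are deliberately
# written as literal double loops over pixels and line positions so they
# stay independent of the vectorized package code they check.

oracle_lbp_bits <- function(img) {
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  bits <- integer((nrow(img) - 2) * (ncol(img) - 2) * 8)
  i <- 0L
  for (r in 2:(nrow(img) - 1)) for (c in 2:(ncol(img) - 1)) {
    for (o in offs) {
      i <- i + 1L
      bits[i] <- as.integer(img[r + o[1], c + o[2]] - img[r, c] >= 0)
    }
  }
  bits
}

oracle_lbp_decimal <- function(img) {
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  out <- matrix(0L, nrow(img) - 2L, ncol(img) - 2L)
  for (r in 2:(nrow(img) - 1)) for (c in 2:(ncol(img) - 1)) {
    v <- 0L
    for (n in 0:7) {
      o <- offs[[n + 1]]
      v <- v + as.integer(img[r + o[1], c + o[2]] - img[r, c] >= 0) * 2L^n
    }
    out[r - 1L, c - 1L] <- v
  }
  storage.mode(out) <- "integer"
  out
}

oracle_llbp_bits <- function(img, N, direction) {
  cc <- (N + 1) / 2
  half <- (N - 1) / 2
  h <- nrow(img); w <- ncol(img)
  rows <- if (direction == "h") 1:h else (half + 1):(h - half)
  cols <- if (direction == "h") (half + 1):(w - half) else 1:w
  bits <- integer(length(rows) * length(cols) * (N - 1))
  i <- 0L
  for (r in rows) for (c in cols) {
    for (n in setdiff(1:N, cc)) {
      nbr <- if (direction == "h") img[r, c + n - cc] else img[r + n - cc, c]
      i <- i + 1L
      bits[i] <- as.integer(nbr - img[r, c] >= 0)
    }
  }
  bits
}

oracle_llbp_magnitude <- function(img, N) {
  cc <- (N + 1) / 2
  half <- (N - 1) / 2
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h - N + 1L, w - N + 1L)
  for (r in (half + 1):(h - half)) for (c in (half + 1):(w - half)) {
    dh <- 0; dv <- 0
    for (n in 1:N) {
      if (n == cc) next
      wgt <- if (n < cc) 2^(cc - n - 1) else 2^(n - cc - 1)
      dh <- dh + as.integer(img[r, c + n - cc] - img[r, c] >= 0) * wgt
      dv <- dv + as.integer(img[r + n - cc, c] - img[r, c] >= 0) * wgt
    }
    out[r - half, c - half] <- sqrt(dh^2 + dv^2)
  }
  out
}

# Literal k x k double sum of per-bit XNOR averages (including a = b),
# then the [0, 1] rescaling — the definition the closed form must equal.
oracle_pwm_double_sum <- function(bit_rows) {
  k <- nrow(bit_rows)
  p <- rep(0, ncol(bit_rows))
  for (a in 1:k) for (b in 1:k) {
    p <- p + as.integer(bit_rows[a, ] == bit_rows[b, ])
  }
  2 * (p / (k * k)) - 1
}

random_codes <- function(k, n_bits, tag = "t") {
  lapply(seq_len(k), function(i) binary_code(sample(0:1, n_bits, replace = TRUE), tag))
}

# Assemble a score_set from raw similarity vectors.
make_score_set <- function(genuine, imposter) {
  structure(list(
    genuine = data.frame(class_id = rep("g", length(genuine)), similarity = genuine,
                         stringsAsFactors = FALSE),
    imposter = data.frame(enrolled_class = rep("a", length(imposter)),
                          probe_class = rep("b", length(imposter)),
                          similarity = imposter, stringsAsFactors = FALSE)),
    class = "score_set")
}

# Exhaustive-threshold EER oracle: brute-force sweep over candidate
# thresholds, returning the best achievable |FAR - FRR| midpoint.
oracle_eer <- function(genuine, imposter) {
  thr <- sort(unique(c(genuine, imposter, min(c(genuine, imposter)) - 1)))
  far <- vapply(thr, function(t) mean(imposter > t), numeric(1))
  frr <- vapply(thr, function(t) mean(genuine <= t), numeric(1))
  i <- which.min(abs(far - frr))
  if (far[i] == frr[i]) return(far[i])
  # linear interpolation between the bracketing sweep points
  d <- far - frr
  j <- which(d <= 0)[1]
  alpha <- d[j - 1] / (d[j - 1] - d[j])
  far[j - 1] + alpha * (far[j] - far[j - 1])
}
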