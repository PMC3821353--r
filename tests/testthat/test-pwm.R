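test_that("Hamming distance counts differing bit fractions", {
  a <- binary_code(c(1, 0, 1, 1, 0), "t")
  b <- binary_code(c(1, 1, 1, 0, 0), "t")
  expect_identical(hamming_distance(a, a), 0)
  expect_identical(hamming_distance(a, binary_code(1 - code_bits(a), "t")), 1)
  expect_identical(hamming_distance(a, b), 2 / 5)
  # symmetric, and robust across byte boundaries
  set.seed(31)
  x <- random_codes(2, 1003)
  expect_identical(hamming_distance(x[[1]], x[[2]]), hamming_distance(x[[2]], x[[1]]))
  expect_identical(hamming_distance(x[[1]], x[[2]]),
                   mean(code_bits(x[[1]]) != code_bits(x[[2]])))
})

test_that("weight-map training equals the literal k x k XNOR double sum", {
  set.seed(32)
  for (i in 1:30) {
    k <- sample(2:9, 1)
    n <- sample(5:40, 1)
    codes <- random_codes(k, n)
    wm <- train_pwm(codes, "c")
    bit_rows <- do.call(rbind, lapply(codes, code_bits))
    expect_equal(wm$weights, oracle_pwm_double_sum(bit_rows))
    expect_identical(wm$k_train, k)
  }
})

test_that("pre-normalization stability lies in [0.5, 1] and weights in [0, 1]", {
  set.seed(33)
  for (i in 1:30) {
    k <- sample(2:12, 1)
    codes <- random_codes(k, 64)
    w <- train_pwm(codes, "c")$weights
    p <- (w + 1) / 2
    expect_true(all(p >= 0.5 & p <= 1))
    expect_true(all(w >= 0 & w <= 1))
    # quantization: every weight in the finite set forced by m1 = 0..k
    m1 <- 0:k
    achievable <- (m1^2 + (k - m1)^2) * 2 / k^2 - 1
    expect_true(all(w %in% achievable))
  }
})

test_that("hand-checked weight values come out exactly", {
  mk <- function(bits) binary_code(bits, "t")
  # k = 2 disagreement -> 0; agreement -> 1
  w2 <- train_pwm(list(mk(c(1, 1)), mk(c(0, 1))), "c")$weights
  expect_identical(w2, c(0, 1))
  # k = 6 perfectly interlaced -> 0
  codes6 <- lapply(1:6, function(i) mk(c(as.integer(i <= 3), 1)))
  expect_identical(train_pwm(codes6, "c")$weights[1], 0)
  # identical codes -> all ones
  codes_same <- lapply(1:5, function(i) mk(c(1, 0, 1)))
  expect_identical(train_pwm(codes_same, "c")$weights, c(1, 1, 1))
})

test_that("training requires at least two compatible codes", {
  expect_error(train_pwm(list(binary_code(c(1, 0), "t")), "c"),
               class = "veinpwm_insufficient_training")
  expect_error(train_pwm(list(binary_code(c(1, 0), "t"), binary_code(c(1, 0, 1), "t")), "c"),
               class = "veinpwm_incompatible_codes")
  expect_error(train_pwm(list(binary_code(c(1, 0), "a"), binary_code(c(1, 1), "b")), "c"),
               class = "veinpwm_incompatible_codes")
})

test_that("best-bit mask marks exactly the bits constant across training codes", {
  set.seed(34)
  for (i in 1:10) {
    k <- sample(2:8, 1)
    codes <- random_codes(k, 48)
    pb <- suppressWarnings(train_pbbm(codes, "c"))
    bit_rows <- do.call(rbind, lapply(codes, code_bits))
    constant <- as.integer(apply(bit_rows, 2, function(col) length(unique(col)) == 1L))
    expect_identical(pb$mask$mask, constant)
    # mask == (weight == 1), and k = 2 mask == XNOR of the pair
    expect_identical(pb$mask$mask, as.integer(train_pwm(codes, "c")$weights == 1))
    if (k == 2L) {
      expect_identical(pb$mask$mask, as.integer(bit_rows[1, ] == bit_rows[2, ]))
    }
    # template carries the constant value at masked positions
    expect_identical(code_bits(pb$template)[constant == 1L], bit_rows[1, constant == 1L])
  }
})

test_that("an all-identical training set gives a full mask and its common code", {
  codes <- lapply(1:4, function(i) binary_code(c(1, 0, 1, 1), "t"))
  pb <- train_pbbm(codes, "c")
  expect_identical(pb$mask$mask, rep(1L, 4))
  expect_identical(code_bits(pb$template), c(1L, 0L, 1L, 1L))
})

test_that("weighted similarity reproduces the hand-evaluated example and reductions", {
  enrolled <- binary_code(c(1, 1, 0, 0), "t")
  probe <- binary_code(c(1, 0, 1, 0), "t")
  wm <- structure(list(weights = c(1.0, 0.5, 0.5, 0.0), n_bits = 4L,
                       operator_tag = "t", k_train = 2L, class_id = "c"),
                  class = "weight_map")
  expect_identical(weighted_similarity(enrolled, probe, wm), 0.5)
  expect_identical(weighted_similarity(enrolled, enrolled, wm), 1)
  # all-ones weights reduce to 1 - Hamming distance, exactly
  set.seed(35)
  for (i in 1:20) {
    n <- sample(8:64, 1)
    x <- random_codes(2, n)
    ones <- structure(list(weights = rep(1, n), n_bits = n, operator_tag = "t",
                           k_train = 2L, class_id = "c"), class = "weight_map")
    expect_identical(weighted_similarity(x[[1]], x[[2]], ones),
                     1 - hamming_distance(x[[1]], x[[2]]))
  }
})

test_that("best-bit similarity equals weighted similarity under the 0/1 mask", {
  set.seed(36)
  for (i in 1:20) {
    codes <- random_codes(sample(2:6, 1), 40)
    pb <- suppressWarnings(train_pbbm(codes, "c"))
    if (sum(pb$mask$mask) == 0L) next
    probe <- random_codes(1, 40)[[1]]
    s_mask <- pbbm_similarity(pb$template, probe, pb$mask)
    s_weighted <- weighted_similarity(pb$template, probe, pb$mask)
    expect_identical(s_mask, s_weighted)
    # and equals the direct masked-bit count
    on <- pb$mask$mask == 1L
    expect_equal(s_mask, 1 - mean(code_bits(pb$template)[on] != code_bits(probe)[on]))
  }
})

test_that("degenerate weight maps and masks are rejected at match time", {
  a <- binary_code(c(1, 0), "t"); b <- binary_code(c(0, 0), "t")
  zero_w <- structure(list(weights = c(0, 0), n_bits = 2L, operator_tag = "t",
                           k_train = 2L, class_id = "c"), class = "weight_map")
  expect_error(weighted_similarity(a, b, zero_w), class = "veinpwm_degenerate_weights")
  empty_mask <- structure(list(mask = c(0L, 0L), n_bits = 2L, operator_tag = "t",
                               k_train = 2L, class_id = "c"), class = "best_bit_mask")
  expect_error(pbbm_similarity(a, b, empty_mask), class = "veinpwm_degenerate_template")
  # training a fully unstable pair warns but still returns the mask
  expect_warning(pb <- train_pbbm(list(a, binary_code(c(0, 1), "t")), "c"),
                 class = "veinpwm_degenerate_template")
  expect_identical(sum(pb$mask$mask), 0L)
})

test_that("trained weights recover the squared-bias limit of a Bernoulli bit", {
  # a bit that is 1 with probability pi across codes converges to (2 pi - 1)^2
  set.seed(37)
  k <- 2000L
  pis <- c(0.5, 0.7, 0.9, 1.0)
  bit_rows <- vapply(pis, function(p) stats::rbinom(k, 1, p), integer(k))
  codes <- lapply(seq_len(k), function(i) binary_code(bit_rows[i, ], "t"))
  w <- train_pwm(codes, "c")$weights
  expect_true(all(abs(w - (2 * pis - 1)^2) <= 0.05))
})

test_that("more disagreement at positive-weight positions never raises the score", {
  set.seed(38)
  n <- 32L
  enrolled_bits <- sample(0:1, n, replace = TRUE)
  enrolled <- binary_code(enrolled_bits, "t")
  wm <- structure(list(weights = runif(n), n_bits = n, operator_tag = "t",
                       k_train = 4L, class_id = "c"), class = "weight_map")
  probe_bits <- enrolled_bits
  sims <- numeric(0)
  for (j in sample(which(wm$weights > 0))) {
    probe_bits[j] <- 1L - probe_bits[j]
    sims <- c(sims, weighted_similarity(enrolled, binary_code(probe_bits, "t"), wm))
  }
  expect_true(all(diff(sims) <= 1e-12))
})

test_that("strict-threshold decisions accept only above the threshold", {
  expect_true(decide(0.8, 0.7))
  expect_false(decide(0.7, 0.7))
  expect_false(decide(0.0, 0.0))
  expect_error(decide(1.2, 0.5), class = "veinpwm_invalid_input")
})

test_that("class templates round-trip bit-exactly through the .pwm container", {
  set.seed(39)
  codes <- random_codes(5, 77, tag = "llbp-N21")
  tpl <- class_template(codes, "finger_007")
  dir <- withr::local_tempdir()
  path <- write_template(tpl, dir)
  expect_true(file.exists(path))
  expect_true(file.exists(file.path(dir, "finger_007.json")))
  back <- read_template(path)
  expect_identical(back$class_id, tpl$class_id)
  expect_identical(back$operator_tag, tpl$operator_tag)
  expect_identical(back$k_train, tpl$k_train)
  expect_identical(back$weight_map$weights, tpl$weight_map$weights)
  expect_identical(back$pbbm_mask$mask, tpl$pbbm_mask$mask)
  expect_identical(lapply(back$codes, code_bits), lapply(tpl$codes, code_bits))
  expect_identical(code_bits(back$pbbm_template), code_bits(tpl$pbbm_template))
  # byte-identical on rewrite
  dir2 <- withr::local_tempdir()
  path2 <- write_template(back, dir2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))
  meta <- jsonlite::read_json(file.path(dir, "finger_007.json"))
  expect_identical(meta$n_bits, 77L)
})
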