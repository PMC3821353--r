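# Small deterministic gallery: class templates far apart, mild bit noise.
tiny_gallery <- function(n_classes = 3L, n_samples = 6L, n_bits = 120L,
                         flip_prob = 0.05, seed = 91L) {
  generate_code_population(n_classes, n_samples, n_bits, f_stable = 1,
                           q_low = flip_prob, q_high = flip_prob, seed = seed)$gallery
}

test_that("verification score counts follow the protocol combinatorics", {
  # C = 2 classes, 2 test samples, imposters from the first 2:
  # 1 genuine pair per class; 2 x 1 x 4 ordered cross pairs
  g <- tiny_gallery(n_classes = 2L, n_samples = 4L)
  ss <- verification_protocol(g, method = "plain", k_train = 2L,
                              n_test_all = 2L, n_test_imposter = 2L)
  expect_identical(nrow(ss$genuine), 2L)
  expect_identical(nrow(ss$imposter), 8L)
  # property: counts for random protocol shapes
  set.seed(92)
  for (i in 1:5) {
    C <- sample(2:5, 1); n_test <- sample(2:4, 1); n_imp <- sample(1:n_test, 1)
    g <- tiny_gallery(n_classes = C, n_samples = n_test + 2L)
    ss <- verification_protocol(g, method = "plain", k_train = 2L,
                                n_test_all = n_test, n_test_imposter = n_imp)
    expect_identical(nrow(ss$genuine), as.integer(C * choose(n_test, 2)))
    expect_identical(nrow(ss$imposter), as.integer(C * (C - 1) * n_imp^2))
  }
})

test_that("undersized classes are reported by name", {
  g <- tiny_gallery(n_classes = 3L, n_samples = 4L)
  g$classes[["class002"]] <- g$classes[["class002"]][1:3]
  err <- tryCatch(verification_protocol(g, method = "plain", k_train = 3L),
                  error = function(e) e)
  expect_s3_class(err, "veinpwm_protocol_violation")
  expect_match(conditionMessage(err), "class002")
})

test_that("a single-class gallery yields an empty imposter set with a warning", {
  g <- tiny_gallery(n_classes = 1L, n_samples = 5L)
  expect_warning(ss <- verification_protocol(g, method = "plain", k_train = 2L),
                 class = "veinpwm_single_class")
  expect_identical(nrow(ss$imposter), 0L)
  expect_gt(nrow(ss$genuine), 0L)
})

test_that("EER matches brute-force threshold sweeps on known score sets", {
  # perfect separation
  expect_identical(compute_eer(make_score_set(rep(1, 5), rep(0, 5)))$eer, 0)
  # identical genuine and imposter multisets -> 0.5
  s <- c(0.2, 0.5, 0.9)
  expect_equal(compute_eer(make_score_set(s, s))$eer, 0.5)
  # worked three-score example
  expect_equal(compute_eer(make_score_set(c(0.9, 0.8, 0.6), c(0.7, 0.5, 0.4)))$eer, 1 / 3)
  # random score sets against the exhaustive oracle
  set.seed(93)
  for (i in 1:10) {
    gen <- runif(sample(5:40, 1), 0.3, 1)
    imp <- runif(sample(5:40, 1), 0, 0.7)
    res <- compute_eer(make_score_set(gen, imp))
    expect_equal(res$eer, oracle_eer(gen, imp), tolerance = 1e-12)
    expect_gte(res$eer, 0); expect_lte(res$eer, 1)
  }
  expect_error(compute_eer(make_score_set(numeric(0), 0.5)), class = "veinpwm_invalid_input")
})

test_that("the swept ROC is monotone: FAR non-increasing, FRR non-decreasing", {
  set.seed(94)
  res <- compute_eer(make_score_set(runif(50, 0.4, 1), runif(80, 0, 0.6)))
  expect_true(all(diff(res$roc$far) <= 0))
  expect_true(all(diff(res$roc$frr) >= 0))
  expect_true(all(diff(res$roc$threshold) > 0))
})

test_that("operating points read the best achievable rate at the target", {
  # perfectly separable scores support FRR = 0 at FAR = 0.001 and vice versa
  res <- compute_eer(make_score_set(c(0.9, 0.95, 1), c(0.1, 0.2, 0.3)))
  expect_identical(res$frr_at_far, 0)
  expect_identical(res$far_at_frr, 0)
})

test_that("identification ranks probes pessimistically and builds a valid CMC", {
  # hand-built 3-class instance: one probe forced to rank 2
  mk <- function(bits) binary_code(bits, "t")
  tA <- rep(1L, 8); tB <- rep(0L, 8); tC <- c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L)
  pA <- c(0L, 0L, 0L, 0L, 0L, 1L, 1L, 1L)
  classes <- list(
    A = list(mk(tA), mk(tA), mk(tA), mk(pA)),
    B = list(mk(tB), mk(tB), mk(tB), mk(tB)),
    C = list(mk(tC), mk(tC), mk(tC), mk(tC))
  )
  # probe A4 = 00000111 scores 0.375 against A's template, 0.625 against
  # B's and 0.125 against C's, so it lands at rank 2; B and C probes
  # equal their templates and rank first
  g <- code_gallery(classes)
  res <- identification_protocol(g, method = "plain", k_train = 2L)
  expect_equal(res$cmc, c(2 / 3, 1, 1))
  expect_equal(res$rank_one, 2 / 3)
  expect_identical(res$lowest_perfect_rank, 2L)
  expect_identical(res$n_probes, 3L)
})

test_that("identification on a well-separated gallery is perfect at rank one", {
  g <- tiny_gallery(n_classes = 4L, n_samples = 6L, flip_prob = 0.01)
  res <- identification_protocol(g, method = "pwm", k_train = 3L)
  expect_equal(res$rank_one, 1)
  expect_identical(res$lowest_perfect_rank, 1L)
  expect_true(all(diff(res$cmc) >= 0))
  expect_equal(res$cmc[length(res$cmc)], 1)
  # probe count: (n_samples - k_train - 1) per class
  expect_identical(res$n_probes, 4L * 2L)
})

test_that("random split repetitions are seed-reproducible with a sane summary", {
  g <- tiny_gallery(n_classes = 3L, n_samples = 8L)
  r1 <- random_split_repetitions(g, method = "pwm", k_train = 4L, reps = 3L, seed = 7L)
  r2 <- random_split_repetitions(g, method = "pwm", k_train = 4L, reps = 3L, seed = 7L)
  expect_identical(vapply(r1$results, function(x) x$eer, numeric(1)),
                   vapply(r2$results, function(x) x$eer, numeric(1)))
  expect_identical(unname(r1$summary["min"]), min(vapply(r1$results, `[[`, numeric(1), "eer")))
  one <- random_split_repetitions(g, method = "plain", k_train = 4L, reps = 1L, seed = 7L)
  expect_identical(unname(one$summary["min"]), unname(one$summary["max"]))
  expect_identical(unname(one$summary["variance"]), 0)
  expect_error(random_split_repetitions(tiny_gallery(2L, 4L), k_train = 3L, reps = 2L, seed = 1L),
               class = "veinpwm_protocol_violation")
})

test_that("the training-size sweep runs all matchers on identical splits", {
  g <- tiny_gallery(n_classes = 3L, n_samples = 8L)
  tab <- training_size_sweep(g, k_values = c(2L, 4L), n_test = 3L)
  expect_identical(nrow(tab), 6L)  # 2 sizes x 3 matchers
  expect_setequal(unique(tab$method), c("plain", "pbbm", "pwm"))
  expect_true(all(tab$eer >= 0 & tab$eer <= 1))
  expect_true(all(tab$rank_one >= 0 & tab$rank_one <= 1))
  expect_error(training_size_sweep(g, k_values = 6L, n_test = 3L),
               class = "veinpwm_protocol_violation")
})

test_that("weighting helps when bit stability is heterogeneous and is neutral when it is not", {
  # heterogeneous: PWM strictly beats plain Hamming at a fixed seed
  pop <- generate_code_population(seed = 61L)
  tab <- training_size_sweep(pop$gallery, k_values = 10L, n_test = 6L,
                             methods = c("plain", "pwm"), identification = FALSE)
  eer <- function(m) tab$eer[tab$method == m]
  expect_lt(eer("pwm") + 0.005, eer("plain"))  # fixed margin
  # homogeneous all-stable bits: every weight is 1, so PWM and plain
  # produce identical score rankings
  hom <- generate_code_population(n_classes = 4L, n_samples = 6L, code_length = 64L,
                                  f_stable = 1, q_low = 0, q_high = 0, seed = 62L)
  sp <- verification_protocol(hom$gallery, method = "plain", k_train = 2L)
  sw <- verification_protocol(hom$gallery, method = "pwm", k_train = 2L)
  expect_identical(order(sp$genuine$similarity), order(sw$genuine$similarity))
  expect_identical(order(sp$imposter$similarity), order(sw$imposter$similarity))
})
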