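#' Build a matcher from per-class training codes
#'
#' Fits whatever the chosen matching rule needs (nothing for plain
#' Hamming, a best-bit mask for PBBM, a weight map for PWM) and returns a
#' scoring closure `score(enrolled, probe, class_id)` in which `class_id`
#' names the enrolled class whose personalization applies. All three
#' rules therefore run through an identical score pipeline and differ
#' only in the per-bit weights.
#'
#' @param train_codes named list: class id -> list of training
#'   [binary_code()] (ignored for `"plain"`).
#' @param method `"plain"`, `"pbbm"` or `"pwm"`.
#' @return a list with `method` and `score`.
#' @export
fit_matcher <- function(train_codes, method = c("pwm", "pbbm", "plain")) {
  method <- match.arg(method)
  if (method == "plain") {
    return(list(method = method,
                score = function(enrolled, probe, class_id) 1 - hamming_distance(enrolled, probe)))
  }
  models <- lapply(names(train_codes), function(id) {
    if (method == "pwm") train_pwm(train_codes[[id]], id)
    else withCallingHandlers(
      train_pbbm(train_codes[[id]], id)$mask,
      veinpwm_degenerate_template = function(w) invokeRestart("muffleWarning"))
  })
  names(models) <- names(train_codes)
  list(method = method,
       score = function(enrolled, probe, class_id) {
         weighted_similarity(enrolled, probe, models[[class_id]])
       },
       models = models)
}

#' Verification protocol: genuine and imposter score sets
#'
#' Splits every class into its first `k_train` samples (training) and the
#' remainder (test), then scores: all unordered pairs among each class's
#' first `n_test_all` test samples (genuine, `C * choose(n_test_all, 2)`
#' scores), and — to avoid flooding the imposter set — each class's first
#' `n_test_imposter` test samples against every other class's first
#' `n_test_imposter` test samples, both class orders counted
#' (`C * (C - 1) * n_test_imposter^2` imposter scores). The enrolled role
#' (whose weight map applies) is the first member of a genuine pair and
#' the first class of an ordered imposter pair.
#'
#' @param gallery a [code_gallery()].
#' @param method matching rule, see [fit_matcher()].
#' @param k_train training samples per class (first `k_train` in order).
#' @param n_test_all genuine-matching test samples per class; default all
#'   test samples (requires equal counts across classes).
#' @param n_test_imposter imposter-matching test samples per class.
#' @return a `score_set`: data frames `genuine` (class_id, similarity)
#'   and `imposter` (enrolled_class, probe_class, similarity).
#' @export
verification_protocol <- function(gallery, method = "pwm", k_train = 10L,
                                  n_test_all = NULL, n_test_imposter = 2L) {
  stopifnot(inherits(gallery, "code_gallery"))
  splits <- .split_first_k(gallery, k_train)
  bad <- names(splits)[vapply(splits, is.null, logical(1))]
  if (length(bad)) {
    vp_stop("protocol_violation",
            sprintf("classes with fewer than k_train + 1 = %d samples: %s",
                    k_train + 1L, paste(bad, collapse = ", ")))
  }
  test_sizes <- vapply(splits, function(s) length(s$test), integer(1))
  if (is.null(n_test_all)) n_test_all <- min(test_sizes)
  n_test_all <- as.integer(n_test_all)
  if (n_test_all < 2L) vp_stop("protocol_violation", "genuine matching needs at least 2 test samples per class")
  bad <- names(test_sizes)[test_sizes < n_test_all]
  if (length(bad)) {
    vp_stop("protocol_violation",
            sprintf("classes with fewer than %d test samples: %s",
                    n_test_all, paste(bad, collapse = ", ")))
  }
  n_test_imposter <- min(as.integer(n_test_imposter), n_test_all)
  ids <- names(gallery$classes)
  train_codes <- lapply(ids, function(id) gallery$classes[[id]][splits[[id]]$train])
  names(train_codes) <- ids
  test_codes <- lapply(ids, function(id) gallery$classes[[id]][splits[[id]]$test[seq_len(n_test_all)]])
  names(test_codes) <- ids
  matcher <- fit_matcher(train_codes, method)
  score_test_sets(test_codes, matcher, n_test_imposter)
}

#' Score pre-split test sets
#'
#' The scoring half of [verification_protocol()], usable directly when
#' train/test roles were assigned elsewhere (e.g. random splits).
#'
#' @param test_codes named list: class id -> list of test codes.
#' @param matcher a fitted matcher from [fit_matcher()].
#' @param n_test_imposter imposter samples per class.
#' @return a `score_set`.
#' @export
score_test_sets <- function(test_codes, matcher, n_test_imposter = 2L) {
  ids <- names(test_codes)
  if (length(ids) == 1L) vp_warn("single_class", "only one class: imposter score set is empty")
  genuine <- do.call(rbind, lapply(ids, function(id) {
    codes <- test_codes[[id]]
    n <- length(codes)
    if (n < 2L) return(NULL)
    pairs <- utils::combn(n, 2L)
    sims <- vapply(seq_len(ncol(pairs)), function(j) {
      matcher$score(codes[[pairs[1, j]]], codes[[pairs[2, j]]], id)
    }, numeric(1))
    data.frame(class_id = id, similarity = sims, stringsAsFactors = FALSE)
  }))
  imposter <- do.call(rbind, lapply(ids, function(enr) {
    e_codes <- test_codes[[enr]][seq_len(min(n_test_imposter, length(test_codes[[enr]])))]
    do.call(rbind, lapply(setdiff(ids, enr), function(prb) {
      p_codes <- test_codes[[prb]][seq_len(min(n_test_imposter, length(test_codes[[prb]])))]
      grid <- expand.grid(e = seq_along(e_codes), p = seq_along(p_codes))
      sims <- vapply(seq_len(nrow(grid)), function(j) {
        matcher$score(e_codes[[grid$e[j]]], p_codes[[grid$p[j]]], enr)
      }, numeric(1))
      data.frame(enrolled_class = enr, probe_class = prb, similarity = sims,
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(imposter)) {
    imposter <- data.frame(enrolled_class = character(), probe_class = character(),
                           similarity = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(genuine = genuine, imposter = imposter), class = "score_set")
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf("<score_set> %d genuine, %d imposter scores\n",
              nrow(x$genuine), nrow(x$imposter)))
  invisible(x)
}

#' Verification metrics from a score set
#'
#' Sweeps the acceptance threshold over the union of observed scores
#' (plus a sentinel below the minimum so the full operating range is
#' covered). Consistent with the strict-acceptance rule of [decide()],
#' `FAR(t)` is the fraction of imposter scores strictly above `t` and
#' `FRR(t)` the fraction of genuine scores at or below `t`, so FAR is
#' non-increasing and FRR non-decreasing along the sweep. The equal error
#' rate is read off by linear interpolation between the two adjacent
#' sweep points where FAR - FRR changes sign; the FRR at a target FAR
#' (default 0.1%) and the FAR at a target FRR are interpolated along the
#' same curve.
#'
#' @param scores a `score_set`.
#' @param far_target,frr_target operating-point targets (default 0.001).
#' @return a `verification_result`: `eer`, `frr_at_far`, `far_at_frr`,
#'   and the swept `roc` data frame (threshold, far, frr).
#' @export
compute_eer <- function(scores, far_target = 0.001, frr_target = 0.001) {
  stopifnot(inherits(scores, "score_set"))
  gen <- scores$genuine$similarity
  imp <- scores$imposter$similarity
  if (length(gen) == 0L || length(imp) == 0L) {
    vp_stop("invalid_input", "both genuine and imposter score sets must be nonempty")
  }
  thr <- sort(unique(c(gen, imp)))
  thr <- c(thr[1] - 1, thr)  # sentinel: accept everything
  sg <- sort(gen); si <- sort(imp)
  frr <- findInterval(thr, sg) / length(gen)        # P(genuine <= t)
  far <- 1 - findInterval(thr, si) / length(imp)    # P(imposter > t)
  d <- far - frr
  i <- which(d <= 0)[1]  # FAR starts at 1, FRR at 0; crossing must exist
  eer <- if (d[i] == 0) {
    far[i]
  } else {
    alpha <- d[i - 1L] / (d[i - 1L] - d[i])
    far[i - 1L] + alpha * (far[i] - far[i - 1L])
  }
  # interpolate one rate at a target value of the other along the sweep:
  # at each level of x the best (smallest) achievable y is the operating
  # point, then linear interpolation between levels
  rate_at <- function(x, y, target) {
    agg <- tapply(y, x, min)
    xs <- as.numeric(names(agg)); ys <- unname(agg)
    if (target <= xs[1]) return(ys[1])
    if (target >= xs[length(xs)]) return(ys[length(ys)])
    stats::approx(xs, ys, xout = target)$y
  }
  structure(
    list(eer = eer,
         frr_at_far = rate_at(far, frr, far_target),
         far_at_frr = rate_at(frr, far, frr_target),
         far_target = far_target, frr_target = frr_target,
         roc = data.frame(threshold = thr, far = far, frr = frr)),
    class = "verification_result"
  )
}

#' @export
print.verification_result <- function(x, ...) {
  cat(sprintf("<verification_result> EER = %.4f | FRR@%.1f%%FAR = %.4f | FAR@%.1f%%FRR = %.4f\n",
              x$eer, 100 * x$far_target, x$frr_at_far, 100 * x$frr_target, x$far_at_frr))
  invisible(x)
}

#' Identification protocol: CMC, rank-one rate, perfect rank
#'
#' Each class trains on its first `k_train` samples; among the remaining
#' samples one (at `template_index`) becomes the class template and the
#' rest become probes. Every probe is scored against every class template
#' with that template's own personalization, templates are sorted by
#' descending similarity, and the probe's rank is the position of its
#' true class. Ranking is pessimistic under ties: the true class is
#' placed after every template scoring at least as high.
#'
#' @inheritParams verification_protocol
#' @param template_index 1-based position of the template among each
#'   class's non-training samples.
#' @return an `identification_result`: `cmc` (cumulative recognition
#'   rate by rank), `rank_one`, `lowest_perfect_rank`, `n_probes`.
#' @export
identification_protocol <- function(gallery, method = "pwm", k_train = 10L,
                                    template_index = 1L) {
  stopifnot(inherits(gallery, "code_gallery"))
  splits <- .split_first_k(gallery, k_train)
  ids <- names(gallery$classes)
  bad <- ids[vapply(ids, function(id) {
    is.null(splits[[id]]) || length(splits[[id]]$test) < max(2L, template_index + 1L)
  }, logical(1))]
  if (length(bad)) {
    vp_stop("protocol_violation",
            sprintf("classes lacking a template plus at least one probe: %s",
                    paste(bad, collapse = ", ")))
  }
  train_codes <- lapply(ids, function(id) gallery$classes[[id]][splits[[id]]$train])
  names(train_codes) <- ids
  templates <- lapply(ids, function(id) gallery$classes[[id]][[splits[[id]]$test[template_index]]])
  names(templates) <- ids
  probes <- lapply(ids, function(id) {
    keep <- splits[[id]]$test[-template_index]
    gallery$classes[[id]][keep]
  })
  names(probes) <- ids
  matcher <- fit_matcher(train_codes, method)
  C <- length(ids)
  ranks <- unlist(lapply(ids, function(true_id) {
    vapply(probes[[true_id]], function(pr) {
      sims <- vapply(ids, function(tid) matcher$score(templates[[tid]], pr, tid), numeric(1))
      sum(sims >= sims[[true_id]])  # pessimistic tie handling; self counts once
    }, numeric(1))
  }))
  n_probes <- length(ranks)
  cmc <- cumsum(tabulate(ranks, nbins = C)) / n_probes
  structure(
    list(cmc = cmc, rank_one = cmc[1],
         lowest_perfect_rank = which(cmc >= 1 - 1e-12)[1],
         n_probes = n_probes),
    class = "identification_result"
  )
}

#' @export
print.identification_result <- function(x, ...) {
  cat(sprintf("<identification_result> rank-one = %.4f, perfect at rank %d (%d probes)\n",
              x$rank_one, x$lowest_perfect_rank, x$n_probes))
  invisible(x)
}

#' Repeated random training/test splits
#'
#' Re-runs the verification protocol `reps` times, each time drawing a
#' fresh uniform random `k_train`-subset of every class for training and
#' testing on the remainder. All randomness flows from `seed`, so equal
#' seeds give identical results.
#'
#' @inheritParams verification_protocol
#' @param reps number of repetitions.
#' @param seed integer seed.
#' @return list with `results` (one `verification_result` per repetition)
#'   and `summary` (min/max/mean/variance of the EER).
#' @export
random_split_repetitions <- function(gallery, method = "pwm", k_train = 10L,
                                     reps = 10L, seed = 1L, n_test_imposter = 2L) {
  stopifnot(inherits(gallery, "code_gallery"))
  if (reps < 1L) vp_stop("invalid_input", "reps must be >= 1")
  sizes <- lengths(gallery$classes)
  if (any(sizes < k_train + 2L)) {
    vp_stop("protocol_violation",
            sprintf("every class needs >= k_train + 2 = %d samples for a random split", k_train + 2L))
  }
  ids <- names(gallery$classes)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  results <- lapply(seq_len(reps), function(r) {
    train_codes <- list(); test_codes <- list()
    for (id in ids) {
      n <- length(gallery$classes[[id]])
      tr <- sort(sample.int(n, k_train))
      train_codes[[id]] <- gallery$classes[[id]][tr]
      test_codes[[id]] <- gallery$classes[[id]][setdiff(seq_len(n), tr)]
    }
    matcher <- fit_matcher(train_codes, method)
    compute_eer(score_test_sets(test_codes, matcher, n_test_imposter))
  })
  eers <- vapply(results, function(x) x$eer, numeric(1))
  list(results = results,
       summary = c(min = min(eers), max = max(eers), mean = mean(eers),
                   variance = if (reps > 1L) stats::var(eers) else 0))
}

#' Training-set-size sweep
#'
#' Fixes the LAST `n_test` samples of every class as the test set and
#' trains on the FIRST `k` samples for each `k` in `k_values`, evaluating
#' every requested matcher on identical score pipelines. This isolates
#' the effect of training-set size (and hence weight quantization) on
#' both verification and identification performance.
#'
#' @inheritParams verification_protocol
#' @param k_values integer vector of training sizes.
#' @param n_test test samples per class (taken from the end).
#' @param methods matchers to compare.
#' @param identification also run the identification protocol.
#' @return data frame with one row per (k, method): EER, operating
#'   points, and (optionally) rank-one rate and lowest perfect rank.
#' @export
training_size_sweep <- function(gallery, k_values, n_test = 6L,
                                methods = c("plain", "pbbm", "pwm"),
                                identification = TRUE, n_test_imposter = 2L) {
  stopifnot(inherits(gallery, "code_gallery"))
  sizes <- lengths(gallery$classes)
  if (any(sizes < max(k_values) + n_test)) {
    vp_stop("protocol_violation",
            sprintf("every class needs >= max(k) + n_test = %d samples", max(k_values) + n_test))
  }
  ids <- names(gallery$classes)
  rows <- list()
  for (k in sort(as.integer(k_values))) {
    train_codes <- list(); test_codes <- list()
    for (id in ids) {
      n <- length(gallery$classes[[id]])
      train_codes[[id]] <- gallery$classes[[id]][seq_len(k)]
      test_codes[[id]] <- gallery$classes[[id]][(n - n_test + 1L):n]
    }
    for (m in methods) {
      matcher <- fit_matcher(train_codes, m)
      ver <- compute_eer(score_test_sets(test_codes, matcher, n_test_imposter))
      row <- data.frame(k = k, method = m, eer = ver$eer,
                        frr_at_far = ver$frr_at_far, far_at_frr = ver$far_at_frr,
                        stringsAsFactors = FALSE)
      if (identification) {
        idr <- .identify_on_split(test_codes, matcher)
        row$rank_one <- idr$rank_one
        row$lowest_perfect_rank <- idr$lowest_perfect_rank
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

# Identification on an explicit test split: first test sample is the
# template, the rest are probes.
.identify_on_split <- function(test_codes, matcher, template_index = 1L) {
  ids <- names(test_codes)
  templates <- lapply(test_codes, function(s) s[[template_index]])
  probes <- lapply(test_codes, function(s) s[-template_index])
  C <- length(ids)
  ranks <- unlist(lapply(ids, function(true_id) {
    vapply(probes[[true_id]], function(pr) {
      sims <- vapply(ids, function(tid) matcher$score(templates[[tid]], pr, tid), numeric(1))
      sum(sims >= sims[[true_id]])
    }, numeric(1))
  }))
  cmc <- cumsum(tabulate(ranks, nbins = C)) / length(ranks)
  structure(list(cmc = cmc, rank_one = cmc[1],
                 lowest_perfect_rank = which(cmc >= 1 - 1e-12)[1],
                 n_probes = length(ranks)),
            class = "identification_result")
}
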