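# Centralisation, DLRS noise estimation, interval scoring and the
# recursive maximal-interval search.

test_that("mode centering recovers a small offset despite a CNV fraction", {
  probes <- make_probes(2000)
  # 5 percent of probes sit in a deletion; the diploid mode must win
  spec <- cnv_spec("chr1", probes$start[1901], max(probes$stop), 1L)
  sig <- simulate_signals(probes, spec,
                          sim_config(seed = 31, sigma = 0.2,
                                     outlier_prob = 0))
  centered <- center_signal(sig)
  expect_true(isTRUE(attr(centered, "centered")))
  expect_lt(abs(attr(centered, "centering_offset")), 0.02)
  # centering twice is idempotent up to one histogram bin
  twice <- center_signal(centered)
  expect_lt(abs(attr(twice, "centering_offset")), 0.011)
})

test_that("constant signal centers to all zeros and flags zero spread", {
  probes <- make_probes(20)
  sig <- simulate_signals(probes, NULL, sim_config(seed = 1, sigma = 1))
  sig$log2_ratio <- rep(0.37, 20)
  expect_warning(centered <- center_signal(sig), "zero spread")
  expect_equal(attr(centered, "centering_offset"), 0.37)
  expect_true(all(centered$log2_ratio == 0))
})

test_that("DLRS: closed forms and estimator consistency", {
  probes <- make_probes(100)
  sig <- simulate_signals(probes, NULL, sim_config(seed = 1))
  sig$log2_ratio <- rep(0.5, 100)
  expect_equal(dlrs(sig), 0)
  a <- 0.3
  sig$log2_ratio <- rep(c(a, -a), 50)
  expect_equal(dlrs(sig), 1.4826 * 2 * a / sqrt(2))
  big <- make_probes(10000)
  sigb <- simulate_signals(big, NULL,
                           sim_config(seed = 17, sigma = 0.2,
                                      outlier_prob = 0,
                                      probe_error_jitter = c(1, 1)))
  expect_lt(abs(dlrs(sigb) - 0.2), 0.01)
  expect_error(dlrs(sigb[1, ]), "at least 2")
})

test_that("interval scores: hand arithmetic and mode equivalence", {
  probes <- make_probes(20)
  sig <- simulate_signals(probes, NULL, sim_config(seed = 1))
  sig$log2_ratio <- rep(0, 20)
  expect_equal(score_interval(sig, 3, 10, "global", sigma_hat = 1), 0)
  sig$log2_ratio[1:9] <- 1
  expect_equal(score_interval(sig, 1, 9, "global", sigma_hat = 1), 3)
  # uniform per-probe errors make the weighted score equal the global one
  sig2 <- simulate_signals(probes, NULL, sim_config(seed = 2))
  sig2$probe_error <- rep(0.2, 20)
  withr::with_seed(8, {
    for (k in 1:100) {
      i <- sample(1:19, 1); j <- sample(i:20, 1)
      expect_equal(score_interval(sig2, i, j, "weighted"),
                   score_interval(sig2, i, j, "global", sigma_hat = 0.2),
                   tolerance = 1e-12)
    }
  })
  expect_error(score_interval(sig, 1, 5, "global", sigma_hat = 0),
               "sigma_hat")
})

test_that("find_aberrations refuses uncentered input and zero noise", {
  x <- make_segment_signals(n = 50, seg_len = 0)
  raw <- x$signals
  attr(raw, "centered") <- NULL
  expect_error(find_aberrations(raw), "centered")
})

test_that("null arrays produce no calls at the default threshold", {
  x <- make_segment_signals(n = 1000, seg_len = 0, seed = 41)
  calls <- find_aberrations(x$signals)
  expect_equal(nrow(calls), 0)
})

test_that("injected segments are found with the right type and copy number", {
  gain <- make_segment_signals(n = 400, seg_at = 200, seg_len = 10,
                               copy_number = 3L, seed = 51)
  calls <- find_aberrations(gain$signals)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$cnv_type, "gain")
  expect_equal(calls$cn_estimate, 3L)
  # expected score ~ (0.58/0.2) * sqrt(10) ~ 9.2
  expect_gt(calls$score, 6)
  loss <- make_segment_signals(n = 400, seg_at = 200, seg_len = 10,
                               copy_number = 1L, seed = 52)
  calls2 <- find_aberrations(loss$signals)
  expect_equal(nrow(calls2), 1)
  expect_equal(calls2$cnv_type, "loss")
  expect_equal(calls2$cn_estimate, 1L)
})

test_that("calls within one mode never overlap and search is recursive", {
  probes <- make_probes(600)
  specs <- cnv_spec(rep("chr1", 3),
                    probes$start[c(100, 300, 500)],
                    probes$stop[c(111, 309, 507)], c(3L, 1L, 3L))
  sig <- center_signal(simulate_signals(
    probes, specs, sim_config(seed = 61, sigma = 0.15, outlier_prob = 0)))
  calls <- find_aberrations(sig)
  expect_equal(nrow(calls), 3)
  calls <- calls[order(calls$start), ]
  if (nrow(calls) > 1) {
    expect_true(all(calls$start[-1] >= calls$stop[-nrow(calls)]))
  }
})

test_that("scores are invariant to rescaling signals and noise together", {
  x <- make_segment_signals(n = 300, seg_at = 150, seg_len = 8,
                            copy_number = 1L, seed = 71)
  sig <- x$signals
  s_hat <- dlrs(sig)
  calls1 <- find_aberrations(sig, sigma_hat = s_hat)
  sig2 <- sig
  sig2$log2_ratio <- sig2$log2_ratio * 3
  sig2$probe_error <- sig2$probe_error * 3
  calls2 <- find_aberrations(sig2, sigma_hat = 3 * s_hat)
  expect_equal(calls1$score, calls2$score, tolerance = 1e-10)
  expect_equal(calls1$start, calls2$start)
})

test_that("top call matches an independent exhaustive oracle", {
  for (case in list(c(n = 120, seed = 81, len = 6, cn = 1),
                    c(n = 250, seed = 82, len = 12, cn = 3),
                    c(n = 500, seed = 83, len = 9, cn = 1))) {
    x <- make_segment_signals(n = case[["n"]],
                              seg_at = floor(case[["n"]] / 3),
                              seg_len = case[["len"]],
                              copy_number = as.integer(case[["cn"]]),
                              seed = case[["seed"]])
    sig <- x$signals
    s_hat <- dlrs(sig)
    # a permissive threshold so the argmax is always emitted; the checked
    # property is the search itself, not the significance cut
    calls <- find_aberrations(sig, caller_config(threshold_t = 4),
                              sigma_hat = s_hat)
    top <- calls[which.max(calls$score), ]
    o <- oracle_top_interval(sig$log2_ratio / s_hat, min_probes = 3)
    expect_equal(top$score, o$score, tolerance = 1e-10)
    expect_equal(top$start, sig$start[o$i])
    expect_equal(top$stop, sig$stop[o$j])
  }
})

test_that("uniform per-probe errors collapse the two modes to one call set", {
  probes <- make_probes(500)
  specs <- cnv_spec(c("chr1", "chr1"), probes$start[c(100, 350)],
                    probes$stop[c(109, 364)], c(3L, 1L))
  sig <- center_signal(simulate_signals(
    probes, specs, sim_config(seed = 91, sigma = 0.2, outlier_prob = 0,
                              probe_error_jitter = c(1, 1))))
  s_hat <- sig$probe_error[1]
  adm1 <- find_aberrations(sig, mode = "global", sigma_hat = s_hat)
  adm2 <- find_aberrations(sig, mode = "weighted")
  expect_equal(nrow(adm1), nrow(adm2))
  expect_equal(adm1$start, adm2$start)
  expect_equal(adm1$stop, adm2$stop)
  expect_equal(adm1$score, adm2$score, tolerance = 1e-10)
})

test_that("detection probability rises with amplitude and segment length", {
  detect_rate <- function(mu, len, reps = 200, n = 150) {
    hits <- 0L
    for (r in seq_len(reps)) {
      probes <- make_probes(n)
      withr::with_seed(1000 + r, {
        lr <- rnorm(n, 0, 0.2)
      })
      at <- floor(n / 2)
      lr[at:(at + len - 1)] <- lr[at:(at + len - 1)] + mu
      sig <- data.frame(probe_id = probes$probe_id, chrom = probes$chrom,
                        start = probes$start, stop = probes$stop,
                        log2_ratio = lr, probe_error = 0.2)
      attr(sig, "centered") <- TRUE
      calls <- find_aberrations(sig, sigma_hat = 0.2)
      ov <- nrow(calls) > 0 &&
        any(calls$stop > probes$start[at] &
              calls$start < probes$stop[at + len - 1])
      hits <- hits + ov
    }
    hits / reps
  }
  rates <- outer(c(0.4, 0.58, 1.0), c(3, 5, 10),
                 Vectorize(function(mu, len) detect_rate(mu, len)))
  # non-decreasing along both axes
  expect_true(all(diff(rates[, 1]) >= 0))
  expect_true(all(diff(rates[, 2]) >= 0))
  expect_true(all(diff(rates[, 3]) >= 0))
  expect_true(all(diff(t(rates)[, 1]) >= 0))
  expect_true(all(diff(t(rates)[, 2]) >= 0))
  expect_true(all(diff(t(rates)[, 3]) >= 0))
  # the easiest case is essentially always detected, the hardest rarely
  expect_gt(rates[3, 3], 0.95)
  expect_lt(rates[1, 1], 0.3)
})

test_that("integration merges matched calls and keeps singletons", {
  a <- cnv_calls(c("chr1", "chr2"), c(100, 5000), c(1100, 6000),
                 c("gain", "loss"), c(10L, 8L), c(0.58, -1),
                 c(9.5, 12), algorithms = "ADM1-like")
  b <- cnv_calls("chr2", 5100, 6050, "loss", 9L, -0.95, 13,
                 algorithms = "ADM2-like")
  out <- integrate_calls(a, b)
  expect_equal(nrow(out), 2)
  expect_setequal(out$tier, c("single-algorithm", "both"))
  merged <- out[out$tier == "both", ]
  expect_equal(merged$start, 5000)
  expect_equal(merged$stop, 6050)
  expect_equal(merged$score, 13)
  expect_equal(merged$algorithms, "ADM1-like,ADM2-like")
  # identical lists: everything matches
  out2 <- integrate_calls(a, a)
  expect_equal(nrow(out2), 2)
  expect_true(all(out2$tier == "both"))
  # empty inputs
  empty <- cnv_calls()
  expect_equal(nrow(integrate_calls(empty, empty)), 0)
  expect_lte(nrow(out), nrow(a) + nrow(b))
})
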