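# Single-probe exon-level calling and disease-panel clustering.

# Small deterministic scaffold: one chromosome, n exons of 100 bp spaced
# 1 kb, k probes per exon (0 allowed), z-values set directly.
make_exon_case <- function(z_by_exon, panel_labels, causative,
                           sigma = 0.1) {
  n <- length(z_by_exon)
  exon_start <- seq(1000, by = 1000, length.out = n)
  genes <- sprintf("G%02d", seq_len(n))
  targets <- exon_targets(genes, 1L, "chr1", exon_start, exon_start + 100)
  rows <- list()
  for (i in seq_len(n)) {
    zs <- z_by_exon[[i]]
    if (!length(zs)) next
    starts <- exon_start[i] + seq(0, by = 40, length.out = length(zs))
    rows[[length(rows) + 1]] <- data.frame(
      probe_id = sprintf("e%02d_p%d", i, seq_along(zs)),
      chrom = "chr1", start = starts, stop = starts + 30,
      log2_ratio = zs * sigma, probe_error = sigma,
      stringsAsFactors = FALSE)
  }
  signals <- do.call(rbind, rows)
  attr(signals, "centered") <- TRUE
  panel <- gene_panel(genes, "chr1", exon_start - 10, exon_start + 110,
                      panels = panel_labels, causative = causative)
  list(signals = signals, targets = targets, panel = panel)
}

test_that("exon status partition: gain/loss/normal/uncovered", {
  cs <- make_exon_case(
    z_by_exon = list(c(5, 6), c(-8, -9), c(4, -4), c(1, -1), numeric()),
    panel_labels = rep("PD", 5), causative = rep(TRUE, 5))
  calls <- call_exons(cs$signals, cs$targets, cs$panel)
  expect_equal(calls$status,
               c("gain", "loss", "normal", "normal", "uncovered"))
  expect_equal(calls$n_probes, c(2L, 2L, 2L, 2L, 0L))
  # a zero-probe exon is never reported normal
  expect_false(any(calls$status == "normal" & calls$n_probes == 0))
  expect_true(all(calls$status[calls$n_probes == 0] == "uncovered"))
})

test_that("an all-quiet array reports every covered exon as normal", {
  cs <- make_exon_case(
    z_by_exon = list(c(0.3, -0.4), c(0.1, 0.2), c(-0.5, 0.5)),
    panel_labels = rep("PD", 3), causative = rep(TRUE, 3))
  calls <- call_exons(cs$signals, cs$targets, cs$panel)
  expect_true(all(calls$status == "normal"))
})

test_that("aberrant singles on non-causative genes are suppressed, logged", {
  cs <- make_exon_case(
    z_by_exon = list(c(5), c(5)),
    panel_labels = c("PD", "PD"), causative = c(TRUE, FALSE))
  expect_message(calls <- call_exons(cs$signals, cs$targets, cs$panel),
                 "suppressed")
  expect_equal(calls$status, c("gain", "gain"))
  expect_equal(calls$suppressed, c(FALSE, TRUE))
  ab <- aberrant_exon_calls(calls)
  expect_equal(ab$gene, "G01")
  # restriction never touches normal/uncovered statuses
  cs2 <- make_exon_case(
    z_by_exon = list(c(0.5), numeric()),
    panel_labels = c("PD", "PD"), causative = c(FALSE, FALSE))
  on_ <- call_exons(cs2$signals, cs2$targets, cs2$panel,
                    restrict_to_causative = TRUE)
  off_ <- call_exons(cs2$signals, cs2$targets, cs2$panel,
                     restrict_to_causative = FALSE)
  expect_equal(on_$status, off_$status)
  expect_false(any(on_$suppressed))
})

test_that("probes on chromosomes without targets are ignored with warning", {
  cs <- make_exon_case(z_by_exon = list(c(5, 5)),
                       panel_labels = "PD", causative = TRUE)
  stray <- data.frame(probe_id = "stray", chrom = "chrX", start = 100,
                      stop = 160, log2_ratio = 2, probe_error = 0.1,
                      stringsAsFactors = FALSE)
  sig <- rbind(cs$signals, stray)
  attr(sig, "centered") <- TRUE
  expect_warning(calls <- call_exons(sig, cs$targets, cs$panel), "chrX")
  expect_equal(calls$status, "gain")
})

test_that("panel clustering expands shared genes into every panel", {
  cs <- make_exon_case(
    z_by_exon = list(c(5, 5), c(-7, -6), c(9, 8), c(0.2, 0.1)),
    panel_labels = c("PD", "PD", "PD;epilepsy", "epilepsy"),
    causative = rep(TRUE, 4))
  calls <- call_exons(cs$signals, cs$targets, cs$panel)
  grouped <- cluster_by_panel(calls)
  counts <- attr(grouped, "panel_counts")
  expect_equal(counts$n_genes[counts$panel == "PD"], 3)
  expect_equal(counts$n_genes[counts$panel == "epilepsy"], 1)
  # every aberrant call appears in at least one group
  expect_gte(nrow(grouped), nrow(aberrant_exon_calls(calls)))
  # empty input gives an empty report
  none <- make_exon_case(z_by_exon = list(c(0.1)), panel_labels = "PD",
                         causative = TRUE)
  empty <- cluster_by_panel(call_exons(none$signals, none$targets,
                                       none$panel))
  expect_equal(nrow(empty), 0)
})

test_that("single-probe mode beats 3-probe calling on sensitivity but
           pays in false positives", {
  n <- 3000
  probes <- make_probes(n, spacing = 1000)
  genes <- sprintf("G%04d", seq_len(n))
  targets <- exon_targets(genes, 1L, "chr1", probes$start, probes$stop)
  panel <- gene_panel(genes, "chr1", probes$start, probes$stop,
                      panels = "PD", causative = TRUE)
  # 20 isolated single-probe heterozygous deletions
  hit_idx <- seq(100, by = 150, length.out = 20)
  specs <- cnv_spec(rep("chr1", 20), probes$start[hit_idx],
                    probes$stop[hit_idx], rep(1L, 20))
  sig <- center_signal(simulate_signals(
    probes, specs, sim_config(seed = 77, sigma = 0.2, outlier_prob = 0)))
  exon_calls <- call_exons(sig, targets, panel)
  interval_calls <- find_aberrations(sig)
  is_hit <- seq_len(n) %in% hit_idx
  # order statuses by target gene to index against probe positions
  status <- exon_calls$status[match(genes, exon_calls$gene)]
  sens_single <- mean(status[is_hit] == "loss")
  fp_single <- sum(status[!is_hit] %in% c("gain", "loss"))
  covered_hit <- function(calls) {
    vapply(hit_idx, function(i) {
      any(calls$cnv_type == "loss" & calls$stop > probes$start[i] &
            calls$start < probes$stop[i])
    }, TRUE)
  }
  sens_interval <- mean(covered_hit(interval_calls))
  fp_interval <- sum(!vapply(seq_len(nrow(interval_calls)), function(k) {
    any(interval_calls$stop[k] > probes$start[hit_idx] &
          interval_calls$start[k] < probes$stop[hit_idx])
  }, TRUE))
  expect_gt(sens_single, sens_interval)
  expect_gt(fp_single, fp_interval)
})
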