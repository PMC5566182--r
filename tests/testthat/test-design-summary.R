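# Coverage accounting, design comparison, and containment classification.

test_that("coverage arithmetic on a hand-computed three-target design", {
  targets <- exon_targets(c("A", "B", "C"), 1L, "chr1",
                          c(0, 1000, 3000), c(100, 1200, 3300))
  probes <- probe_set(c("p1", "p2"), "chr1", c(50, 1100), c(110, 1160))
  s <- compute_design_summary(targets, probes)
  expect_equal(s$covered_targets, 2)
  expect_equal(s$uncovered_targets, 1)
  expect_equal(s$coverage_pct, 67)  # 66.7 rounds half-up to 67
  expect_equal(s$mean_target_size_bp, 200)
  expect_equal(s$covered_targets + s$uncovered_targets, s$total_targets)
})

test_that("zero probes means zero coverage; empty targets are an error", {
  targets <- exon_targets("A", 1:2, "chr1", c(0, 500), c(100, 700))
  empty <- probe_set(character(), character(), numeric(), numeric())
  s <- compute_design_summary(targets, empty)
  expect_equal(s$coverage_pct, 0)
  expect_equal(s$uncovered_targets, s$total_targets)
  no_targets <- exon_targets(character(), integer(), character(),
                             numeric(), numeric())
  expect_error(compute_design_summary(no_targets, empty), "undefined")
})

test_that("coverage is monotone under probe subsetting", {
  withr::with_seed(7, {
    starts <- sort(sample(0:99999, 300))
  })
  targets <- exon_targets(sprintf("G%03d", 1:100), 1L, "chr1",
                          seq(0, by = 1000, length.out = 100),
                          seq(200, by = 1000, length.out = 100))
  full <- probe_set(sprintf("p%03d", 1:300), "chr1", starts, starts + 60)
  for (keep_n in c(250, 150, 50, 10)) {
    sub <- full[seq_len(keep_n), ]
    attr(sub, "assembly") <- attr(full, "assembly")
    expect_lte(compute_design_summary(targets, sub)$covered_targets,
               compute_design_summary(targets, full)$covered_targets)
  }
})

test_that("compare_designs: dense vs sparse on a 10-gene 80-exon panel", {
  genes <- rep(sprintf("G%02d", 1:10), each = 8)
  exons <- rep(1:8, times = 10)
  start <- seq(0, by = 500, length.out = 80)
  targets <- exon_targets(genes, exons, "chr1", start, start + 200)
  dense <- probe_set(sprintf("d%02d", 1:80), "chr1", start + 50,
                     start + 110)
  first_exon <- exons == 1
  sparse <- probe_set(sprintf("s%02d", 1:10), "chr1",
                      start[first_exon] + 50, start[first_exon] + 110)
  cmp <- compare_designs(targets, list(dense = dense, sparse = sparse))
  expect_equal(cmp$covered_targets[cmp$design == "dense"], 80)
  expect_equal(cmp$coverage_pct[cmp$design == "dense"], 100)
  expect_equal(cmp$covered_targets[cmp$design == "sparse"] / 80, 0.125)
  # identical sets under two names give identical summaries
  cmp2 <- compare_designs(targets, list(a = dense, b = dense))
  expect_equal(cmp2$coverage_pct[1], cmp2$coverage_pct[2])
  expect_equal(cmp2$total_probes[1], cmp2$total_probes[2])
})

test_that("compare_designs rejects mismatched assemblies", {
  targets <- exon_targets("A", 1L, "chr1", 0, 100)
  other <- probe_set("p", "chr1", 10, 70, assembly = "GRCh38/hg38")
  expect_error(compare_designs(targets, list(x = other)), "assembly")
})

test_that("containment classification covers the four categories", {
  db <- data.frame(chrom = "chr1", start = 0, stop = 100,
                   label = "nssv0001", stringsAsFactors = FALSE)
  contained <- classify_containment(list(chrom = "chr1", start = 10,
                                         stop = 20), db)
  expect_match(contained, "^completely contained within nssv0001$")
  # contained fraction 95/100
  almost <- classify_containment(list(chrom = "chr1", start = -5,
                                      stop = 95), db)
  expect_match(almost, "^almost completely contained within nssv0001$")
  partial <- classify_containment(list(chrom = "chr1", start = 50,
                                       stop = 250), db)
  expect_match(partial, "^overlaps nssv0001$")
  db2 <- data.frame(chrom = "chr2", start = 0, stop = 100, label = "x")
  expect_equal(classify_containment(list(chrom = "chr1", start = 10,
                                         stop = 20), db2), "not reported")
  expect_equal(classify_containment(list(chrom = "chr1", start = 10,
                                         stop = 20), NULL), "not reported")
})

test_that("containment categories are exhaustive and mutually exclusive", {
  db <- data.frame(chrom = "chr1", start = c(0, 500), stop = c(100, 900),
                   label = c("v1", "v2"), stringsAsFactors = FALSE)
  withr::with_seed(11, {
    for (k in 1:200) {
      a <- sample(-100:1000, 1)
      b <- a + sample(1:300, 1)
      status <- classify_containment(list(chrom = "chr1", start = a,
                                          stop = b), db)
      expect_equal(sum(startsWith(status, "completely contained"),
                       startsWith(status, "almost completely contained"),
                       startsWith(status, "overlaps"),
                       status == "not reported"), 1)
    }
  })
})
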