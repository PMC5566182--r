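# Shared in-code fixtures for the test suite.

# Evenly spaced probes along one chromosome.
make_probes <- function(n, chrom = "chr1", spacing = 100, width = 60,
                        start0 = 0, prefix = "p") {
  starts <- seq(start0, by = spacing, length.out = n)
  probe_set(sprintf("%s%05d", prefix, seq_len(n)), chrom, starts,
            starts + width)
}

# Random toy genome: named DNAStringSet of roughly balanced sequence.
make_genome <- function(chrom_lengths, seed = 42) {
  withr::with_seed(seed, {
    seqs <- vapply(chrom_lengths, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
            collapse = ""), "")
  })
  Biostrings::DNAStringSet(setNames(seqs, names(chrom_lengths)))
}

# Write a BED file from vectors; returns the path.
write_bed_tmp <- function(lines) {
  path <- tempfile(fileext = ".bed")
  writeLines(lines, path)
  path
}

# Simulated array with one injected segment; returns centered signals.
make_segment_signals <- function(n = 200, seg_at = NULL, seg_len = 10,
                                 copy_number = 3L, sigma = 0.2, seed = 1,
                                 jitter = c(0.8, 1.2)) {
  if (is.null(seg_at)) seg_at <- floor(n / 2)
  probes <- make_probes(n)
  specs <- if (seg_len > 0) {
    cnv_spec("chr1", probes$start[seg_at],
             probes$stop[seg_at + seg_len - 1], copy_number)
  } else {
    cnv_spec(character(), numeric(), numeric(), integer())
  }
  sig <- simulate_signals(probes, specs,
                          sim_config(seed = seed, sigma = sigma,
                                     outlier_prob = 0,
                                     probe_error_jitter = jitter))
  list(signals = center_signal(sig), specs = specs, probes = probes)
}

# Independent exhaustive all-pairs interval scorer (oracle). Scans every
# start index and accumulates sums directly; ties broken by score, then
# interval length, then leftmost start.
oracle_top_interval <- function(u, min_probes) {
  n <- length(u)
  best <- list(score = -Inf, len = 0L, i = NA_integer_, j = NA_integer_)
  for (i in seq_len(n - min_probes + 1)) {
    sums <- cumsum(u[i:n])
    lens <- seq_along(sums)
    sc <- abs(sums) / sqrt(lens)
    sc[lens < min_probes] <- -Inf
    for (k in which(sc > best$score - 1e-12)) {
      better <- sc[k] > best$score + 1e-12 ||
        (abs(sc[k] - best$score) <= 1e-12 && lens[k] > best$len)
      if (better) {
        best <- list(score = sc[k], len = lens[k], i = i, j = i + k - 1)
      }
    }
  }
  best
}
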