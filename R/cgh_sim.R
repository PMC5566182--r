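# Synthetic per-probe log2-ratio signals and qPCR Ct tables with the
# statistical structure the callers assume: probe i measures
# r_i ~ Normal(log2(c_i/2), sigma_i) around the copy-number mean, with
# optional uniform outliers and an optional sinusoidal wave artifact.

#' Simulation configuration
#'
#' @param seed integer RNG seed; every draw is reproducible under it.
#' @param sigma baseline probe noise SD in log2 units (default 0.2, a
#'   typical derivative-log-ratio-spread value for a decent array).
#' @param probe_error_jitter length-2 multiplicative range for per-probe
#'   sigma_i (default 0.8..1.2), emulating probe-to-probe error estimates.
#' @param outlier_prob probability a probe is replaced by an outlier draw
#'   (default 0.01).
#' @param outlier_range outliers are Uniform(-outlier_range, +outlier_range)
#'   in log2 units (default 2).
#' @param wave_amplitude,wave_period optional sinusoidal artifact
#'   `A sin(2 pi pos / lambda)` added to every probe; off by default.
#' @param homozygous_floor log2 value standing in for copy number 0, where
#'   log2(0/2) is undefined (default -4).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, sigma = 0.2,
                       probe_error_jitter = c(0.8, 1.2),
                       outlier_prob = 0.01, outlier_range = 2,
                       wave_amplitude = 0, wave_period = NA_real_,
                       homozygous_floor = -4) {
  stopifnot(sigma > 0, outlier_prob >= 0, outlier_prob <= 1,
            length(probe_error_jitter) == 2,
            probe_error_jitter[1] > 0,
            probe_error_jitter[1] <= probe_error_jitter[2])
  structure(list(seed = as.integer(seed), sigma = sigma,
                 probe_error_jitter = probe_error_jitter,
                 outlier_prob = outlier_prob, outlier_range = outlier_range,
                 wave_amplitude = wave_amplitude, wave_period = wave_period,
                 homozygous_floor = homozygous_floor),
            class = "sim_config")
}

#' Declare aberrant segments for simulation
#'
#' Only aberrations are listed; everything else is diploid (copy number 2).
#'
#' @param chrom,start,stop segment intervals (0-based half-open).
#' @param copy_number integer copy numbers >= 0, never 2.
#' @return data.frame of class `cnv_spec`.
#' @export
cnv_spec <- function(chrom, start, stop, copy_number) {
  df <- genomic_intervals(chrom, start, stop,
                          copy_number = as.integer(copy_number))
  if (nrow(df) && any(df$copy_number == 2L)) {
    stop("cnv_spec lists aberrations only; copy_number 2 is the reference")
  }
  if (nrow(df) && any(df$copy_number < 0L)) stop("cnv_spec: copy_number < 0")
  class(df) <- c("cnv_spec", class(df))
  df
}

#' @noRd
check_nonoverlapping <- function(specs) {
  for (chr in unique(specs$chrom)) {
    s <- specs[specs$chrom == chr, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1 && any(s$start[-1] < s$stop[-nrow(s)])) {
      stop("cnv specs overlap on ", chr)
    }
  }
}

#' Simulate per-probe log2-ratio signals
#'
#' Each probe draws `r_i ~ Normal(mu_i, sigma_i)` where `mu_i = log2(c_i/2)`
#' for the copy number `c_i` of the overlapping aberration (2 elsewhere;
#' copy number 0 maps to the homozygous floor) and
#' `sigma_i = sigma * jitter_i`. With probability `outlier_prob` the draw is
#' replaced by `Uniform(-outlier_range, outlier_range)`. The per-probe
#' `sigma_i` is recorded in the `probe_error` column, feeding the
#' probe-error-weighted caller.
#'
#' @param probes a [probe_set()] (or any interval table with `probe_id`).
#' @param cnv_specs a [cnv_spec()] table; segments must not overlap.
#' @param config a [sim_config()].
#' @return data.frame of class `probe_signals` with columns `probe_id`,
#'   `chrom`, `start`, `stop`, `log2_ratio`, `probe_error`.
#' @export
simulate_signals <- function(probes, cnv_specs = NULL,
                             config = sim_config()) {
  probes <- sort_by_position(probes)
  n <- nrow(probes)
  mu <- rep(0, n)
  if (!is.null(cnv_specs) && nrow(cnv_specs)) {
    check_nonoverlapping(cnv_specs)
    for (k in seq_len(nrow(cnv_specs))) {
      ov <- overlap_widths(cnv_specs$chrom[k], cnv_specs$start[k],
                           cnv_specs$stop[k], probes) > 0
      cn <- cnv_specs$copy_number[k]
      mu[ov] <- if (cn == 0) config$homozygous_floor else log2(cn / 2)
    }
  }
  withr::with_seed(config$seed, {
    jitter <- stats::runif(n, config$probe_error_jitter[1],
                           config$probe_error_jitter[2])
    sigma_i <- config$sigma * jitter
    r <- stats::rnorm(n, mu, sigma_i)
    is_outlier <- stats::runif(n) < config$outlier_prob
    if (any(is_outlier)) {
      r[is_outlier] <- stats::runif(sum(is_outlier),
                                    -config$outlier_range,
                                    config$outlier_range)
    }
    if (config$wave_amplitude != 0 && !is.na(config$wave_period)) {
      mid <- (probes$start + probes$stop) / 2
      r <- r + config$wave_amplitude * sin(2 * pi * mid / config$wave_period)
    }
  })
  out <- data.frame(probe_id = probes$probe_id, chrom = probes$chrom,
                    start = probes$start, stop = probes$stop,
                    log2_ratio = r, probe_error = sigma_i,
                    stringsAsFactors = FALSE)
  attr(out, "assembly") <- interval_assembly(probes)
  class(out) <- c("probe_signals", class(out))
  out
}

#' Write / read probe signal tables
#'
#' TSV dialect with 1-based inclusive coordinates: columns `probe_id`,
#' `chrom`, `start`, `stop`, `log2_ratio`, `probe_error`.
#' @param signals a `probe_signals` table.
#' @param path file path.
#' @export
write_signals <- function(signals, path) {
  out <- data.frame(probe_id = signals$probe_id, chrom = signals$chrom,
                    start = signals$start + 1, stop = signals$stop,
                    log2_ratio = signals$log2_ratio,
                    probe_error = signals$probe_error)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signals
#' @export
read_signals <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- data.frame(probe_id = x$probe_id, chrom = x$chrom,
                    start = x$start - 1, stop = x$stop,
                    log2_ratio = x$log2_ratio, probe_error = x$probe_error,
                    stringsAsFactors = FALSE)
  class(out) <- c("probe_signals", class(out))
  out
}

#' Simulate qPCR Ct triplicates encoding relative dosage
#'
#' Under ideal doubling, a locus at relative dosage `q` (vs the diploid
#' calibrator) crosses threshold `log2(q)` cycles earlier:
#' `Ct = baseline - log2(q) + noise`. The reference locus and every
#' calibrator-sample row are generated at `q = 1`.
#'
#' @param loci data.frame with `locus` and `dosage` (> 0) columns.
#' @param replicates replicate count per well (default 3).
#' @param noise_sd Ct noise SD in cycles (default 0.05).
#' @param seed RNG seed.
#' @param baseline_ct threshold-cycle baseline (default 24).
#' @param reference_locus name of the normalisation locus (default "REF2C").
#' @param sample,calibrator_sample sample labels.
#' @return long-format data.frame: `sample`, `locus`, `role`
#'   (`target`/`reference`), `replicate`, `ct`.
#' @export
simulate_qpcr <- function(loci, replicates = 3, noise_sd = 0.05, seed = 1L,
                          baseline_ct = 24, reference_locus = "REF2C",
                          sample = "sample1",
                          calibrator_sample = "calibrator") {
  stopifnot(replicates >= 1, all(c("locus", "dosage") %in% names(loci)))
  if (any(!is.finite(loci$dosage) | loci$dosage <= 0)) {
    stop("simulate_qpcr: dosage must be positive")
  }
  grid <- expand.grid(locus = c(loci$locus, reference_locus),
                      sample = c(sample, calibrator_sample),
                      replicate = seq_len(replicates),
                      stringsAsFactors = FALSE)
  q <- rep(1, nrow(grid))
  is_target_sample <- grid$sample == sample & grid$locus %in% loci$locus
  q[is_target_sample] <- loci$dosage[match(grid$locus[is_target_sample],
                                           loci$locus)]
  ct <- withr::with_seed(seed, {
    baseline_ct - log2(q) + stats::rnorm(nrow(grid), 0, noise_sd)
  })
  out <- data.frame(sample = grid$sample, locus = grid$locus,
                    role = ifelse(grid$locus == reference_locus,
                                  "reference", "target"),
                    replicate = grid$replicate, ct = ct,
                    stringsAsFactors = FALSE)
  out[order(out$sample, out$locus, out$replicate), ]
}

#' Write / read Ct tables
#' @param ct_table long-format Ct table from [simulate_qpcr()].
#' @param path file path.
#' @export
write_ct_table <- function(ct_table, path) {
  utils::write.table(ct_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_ct_table
#' @export
read_ct_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
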