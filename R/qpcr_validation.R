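# Delta-delta-Ct relative dosage from qPCR triplicates, three-way
# classification, and concordance against array calls.

#' Relative dosage by the delta-delta-Ct method
#'
#' Per sample, `dCt = Ct_target - mean(Ct_reference)`; the double delta
#' against the diploid calibrator is `ddCt = dCt_sample - dCt_calibrator`
#' and the relative quantity is `RQ = 2^-ddCt`. RQ is computed
#' replicate-wise (one value per target replicate in the test sample) and
#' reported as mean and SD. A machine offset added to every Ct cancels.
#'
#' The dosage thresholds are applied on the RQ scale (see
#' [classify_dosage()]): the normal diploid band 0.8-1.2 brackets 1 only on
#' the `2^-ddCt` scale on which results are reported.
#'
#' @param ct_table long-format Ct table: `sample`, `locus`, `role`,
#'   `replicate`, `ct` (see [simulate_qpcr()]).
#' @param locus target locus name.
#' @param reference_locus normalisation locus (a gene verified as normal
#'   diploid on the array).
#' @param calibrator_sample name of the healthy diploid calibrator sample.
#' @param sample test sample name; defaults to the unique non-calibrator
#'   sample in the table.
#' @return one-row data.frame: `locus`, `rq_mean`, `rq_sd`, `call`.
#' @export
relative_dosage <- function(ct_table, locus, reference_locus,
                            calibrator_sample, sample = NULL) {
  stopifnot(all(c("sample", "locus", "replicate", "ct") %in%
                  names(ct_table)))
  if (is.null(sample)) {
    others <- setdiff(unique(ct_table$sample), calibrator_sample)
    if (length(others) != 1) {
      stop("relative_dosage: specify `sample`; found ",
           length(others), " non-calibrator samples")
    }
    sample <- others
  }
  pick <- function(smp, loc) {
    ct <- ct_table$ct[ct_table$sample == smp & ct_table$locus == loc]
    if (!length(ct)) {
      stop("relative_dosage: no Ct rows for locus '", loc,
           "' in sample '", smp, "'")
    }
    if (any(!is.finite(ct))) {
      stop("relative_dosage: non-finite Ct for locus '", loc,
           "' in sample '", smp, "'")
    }
    ct
  }
  ct_t_s <- pick(sample, locus)
  ct_r_s <- pick(sample, reference_locus)
  ct_t_c <- pick(calibrator_sample, locus)
  ct_r_c <- pick(calibrator_sample, reference_locus)
  dct_s <- ct_t_s - mean(ct_r_s)              # replicate-wise in the sample
  dct_c <- mean(ct_t_c) - mean(ct_r_c)
  rq <- 2^(-(dct_s - dct_c))
  data.frame(locus = locus, rq_mean = mean(rq),
             rq_sd = if (length(rq) > 1) stats::sd(rq) else 0,
             call = classify_dosage(mean(rq)),
             stringsAsFactors = FALSE)
}

#' Classify a relative quantity into loss / normal / gain
#'
#' Thresholds on the `RQ = 2^-ddCt` scale: `loss` when `rq <= 0.6`,
#' `normal` when `0.8 <= rq <= 1.2`, `gain` when `rq >= 1.4`. Values in the
#' gaps (0.6, 0.8) and (1.2, 1.4) are `indeterminate` rather than forced
#' into a class.
#'
#' @param rq positive relative quantity (vectorised).
#' @return character vector of calls.
#' @export
classify_dosage <- function(rq) {
  if (any(!is.finite(rq) | rq <= 0)) {
    stop("classify_dosage: rq must be positive and finite")
  }
  ifelse(rq <= 0.6, "loss",
         ifelse(rq >= 0.8 & rq <= 1.2, "normal",
                ifelse(rq >= 1.4, "gain", "indeterminate")))
}

#' Concordance between array calls and qPCR dosage results
#'
#' Each assayed locus is matched to array calls by interval overlap. An
#' assay is concordant when an overlapping gain call meets a qPCR `gain`,
#' an overlapping loss call meets a qPCR `loss`, or no overlapping call
#' meets a qPCR `normal`. `indeterminate` dosage calls count as discordant.
#'
#' @param array_calls a [cnv_calls()] table.
#' @param dosage_results data.frame with `locus` and `call` columns (rows
#'   from [relative_dosage()]).
#' @param loci data.frame mapping `locus` to its amplicon interval:
#'   `locus`, `chrom`, `start`, `stop` (0-based half-open).
#' @return concordant fraction in `[0, 1]`.
#' @export
concordance <- function(array_calls, dosage_results, loci) {
  if (nrow(dosage_results) == 0) stop("concordance: zero assays")
  ok <- logical(nrow(dosage_results))
  for (i in seq_len(nrow(dosage_results))) {
    loc <- loci[loci$locus == dosage_results$locus[i], , drop = FALSE]
    if (nrow(loc) != 1) {
      stop("concordance: locus '", dosage_results$locus[i],
           "' missing from loci table")
    }
    ov <- overlap_widths(loc$chrom, loc$start, loc$stop, array_calls) > 0
    array_state <- if (!any(ov)) "normal" else array_calls$cnv_type[ov][1]
    ok[i] <- identical(array_state, dosage_results$call[i])
  }
  mean(ok)
}
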