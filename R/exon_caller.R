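# Single-probe exon-level analysis: flag significant individual exonic
# probes and cluster them by gene and disease panel. Sensitive to one- and
# two-probe events the multi-probe interval caller must ignore, at the cost
# of a higher false-positive rate — intended as a validation strategy over
# strongly linked causative genes.

#' Call per-exon status from individual probe z-values
#'
#' Each probe overlapping an exon contributes `z = r / sigma_i`. An exon is
#' a `gain` when every supporting probe has `z >= z_min`, a `loss` when
#' every probe has `z <= -z_min`, `uncovered` when no probe overlaps it
#' (never reported as normal), and `normal` otherwise. With
#' `restrict_to_causative`, aberrant statuses on genes not flagged
#' causative are retained in the output but marked `suppressed`; they are
#' excluded from aberrant reporting (see [cluster_by_panel()]) and logged.
#' The restriction never touches normal or uncovered exons.
#'
#' @param signals a centered `probe_signals` table.
#' @param targets an [exon_targets()] table.
#' @param panel a [gene_panel()] supplying panel labels and causative
#'   flags for the target genes.
#' @param z_min single-probe significance threshold in SD units
#'   (default 3).
#' @param restrict_to_causative report aberrant exons only for causative
#'   genes (default TRUE).
#' @return data.frame of class `exon_calls`: `gene`, `exon_index`,
#'   `status`, `n_probes`, `max_abs_z`, `panels`, `causative`,
#'   `suppressed`; the per-probe z-values are in the list column
#'   `probe_zs`.
#' @export
call_exons <- function(signals, targets, panel, z_min = 3,
                       restrict_to_causative = TRUE) {
  stopifnot(nrow(targets) > 0)
  unmapped <- setdiff(unique(signals$chrom), unique(targets$chrom))
  if (length(unmapped)) {
    warning("call_exons: ignoring probes on chromosome(s) without targets: ",
            paste(unmapped, collapse = ", "))
    signals <- signals[!(signals$chrom %in% unmapped), , drop = FALSE]
  }
  hits <- GenomicRanges::findOverlaps(as_granges(targets), as_granges(signals))
  by_target <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  panel_of <- panel$panels[match(targets$gene, panel$gene)]
  causative_of <- panel$causative[match(targets$gene, panel$gene)]
  causative_of[is.na(causative_of)] <- FALSE
  n <- nrow(targets)
  status <- character(n); n_probes <- integer(n)
  max_abs_z <- numeric(n); zs <- vector("list", n)
  for (i in seq_len(n)) {
    idx <- by_target[[as.character(i)]]
    if (is.null(idx) || !length(idx)) {
      status[i] <- "uncovered"; n_probes[i] <- 0L; max_abs_z[i] <- NA_real_
      zs[[i]] <- numeric()
      next
    }
    z <- signals$log2_ratio[idx] / signals$probe_error[idx]
    zs[[i]] <- z
    n_probes[i] <- length(z)
    max_abs_z[i] <- max(abs(z))
    status[i] <- if (all(z >= z_min)) "gain"
    else if (all(z <= -z_min)) "loss"
    else "normal"
  }
  suppressed <- rep(FALSE, n)
  if (restrict_to_causative) {
    suppressed <- status %in% c("gain", "loss") & !causative_of
    if (any(suppressed)) {
      message("call_exons: suppressed ", sum(suppressed),
              " aberrant exon call(s) on non-causative gene(s): ",
              paste(unique(targets$gene[suppressed]), collapse = ", "))
    }
  }
  out <- data.frame(gene = targets$gene, exon_index = targets$exon_index,
                    status = status, n_probes = n_probes,
                    max_abs_z = max_abs_z,
                    panels = ifelse(is.na(panel_of), "", panel_of),
                    causative = causative_of, suppressed = suppressed,
                    stringsAsFactors = FALSE)
  out$probe_zs <- zs
  class(out) <- c("exon_calls", class(out))
  out
}

#' Aberrant, non-suppressed exon calls
#' @param exon_calls output of [call_exons()].
#' @return the subset with reportable gain/loss status.
#' @export
aberrant_exon_calls <- function(exon_calls) {
  exon_calls[exon_calls$status %in% c("gain", "loss") &
               !exon_calls$suppressed, , drop = FALSE]
}

#' Cluster aberrant exon calls by disease panel
#'
#' Groups reportable aberrant exon calls by disease panel, then gene. A
#' gene shared across panels appears in every panel it belongs to, so the
#' total group membership can exceed the number of aberrant calls.
#'
#' @param exon_calls output of [call_exons()].
#' @return data.frame with one row per (panel, gene, exon) membership:
#'   `panel`, `gene`, `exon_index`, `status`, `max_abs_z`; per-panel counts
#'   in the `"panel_counts"` attribute.
#' @export
cluster_by_panel <- function(exon_calls) {
  ab <- aberrant_exon_calls(exon_calls)
  if (nrow(ab) == 0) {
    out <- data.frame(panel = character(), gene = character(),
                      exon_index = integer(), status = character(),
                      max_abs_z = numeric(), stringsAsFactors = FALSE)
    attr(out, "panel_counts") <- data.frame(panel = character(),
                                            n_genes = integer(),
                                            n_calls = integer())
    return(out)
  }
  labels <- split_panels(ab$panels)
  reps <- lengths(labels)
  out <- data.frame(panel = unlist(labels),
                    gene = rep(ab$gene, reps),
                    exon_index = rep(ab$exon_index, reps),
                    status = rep(ab$status, reps),
                    max_abs_z = rep(ab$max_abs_z, reps),
                    stringsAsFactors = FALSE)
  out <- out[order(out$panel, out$gene, out$exon_index), ]
  rownames(out) <- NULL
  counts <- do.call(rbind, lapply(split(out, out$panel), function(g) {
    data.frame(panel = g$panel[1], n_genes = length(unique(g$gene)),
               n_calls = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(counts) <- NULL
  attr(out, "panel_counts") <- counts
  out
}

#' Write per-exon and per-panel TSV reports
#' @param exon_calls output of [call_exons()].
#' @param path output TSV path.
#' @export
write_exon_report <- function(exon_calls, path) {
  out <- exon_calls[, c("gene", "exon_index", "status", "n_probes",
                        "max_abs_z", "panels", "causative", "suppressed")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
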