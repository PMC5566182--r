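# Coverage accounting for a probe design over its exon targets.

#' Summarise a probe design over exon targets
#'
#' A target counts as covered when at least one probe overlaps it by one or
#' more base pairs. Coverage percent is rounded half-up to the nearest whole
#' percent, matching how design reports print it. Median probe spacing is
#' the median of start-to-start distances between consecutive probes within
#' each chromosome, pooled across chromosomes.
#'
#' @param targets an [exon_targets()] table (non-empty).
#' @param probes a [probe_set()]; may be empty (coverage is then 0).
#' @return object of class `design_summary`: a list with `total_genes`,
#'   `total_targets`, `covered_targets`, `uncovered_targets`,
#'   `coverage_pct`, `total_probes`, `probes_by_source`,
#'   `median_probe_spacing_bp`, `mean_target_size_bp`.
#' @export
compute_design_summary <- function(targets, probes) {
  if (is.null(targets) || nrow(targets) == 0) {
    stop("design summary: coverage is undefined for an empty target list")
  }
  validate_intervals(targets, "targets")
  n_total <- nrow(targets)
  if (nrow(probes)) {
    validate_intervals(probes, "probes")
    hits <- GenomicRanges::countOverlaps(as_granges(targets),
                                         as_granges(probes))
    covered <- sum(hits > 0)
    spacing <- unlist(lapply(split(probes$start, probes$chrom), function(s) {
      if (length(s) < 2) numeric() else diff(sort(s))
    }), use.names = FALSE)
    med_spacing <- if (length(spacing)) stats::median(spacing) else NA_real_
    by_source <- table(factor(probes$source,
                              levels = c("HD_library", "tiling")))
  } else {
    covered <- 0L
    med_spacing <- NA_real_
    by_source <- table(factor(character(),
                              levels = c("HD_library", "tiling")))
  }
  out <- list(
    total_genes = length(unique(targets$gene)),
    total_targets = n_total,
    covered_targets = covered,
    uncovered_targets = n_total - covered,
    coverage_pct = round_half_up(100 * covered / n_total),
    total_probes = nrow(probes),
    probes_by_source = by_source,
    median_probe_spacing_bp = med_spacing,
    mean_target_size_bp = mean(interval_width(targets))
  )
  class(out) <- "design_summary"
  out
}

#' @export
print.design_summary <- function(x, ...) {
  cat("Exon-centric design summary\n")
  cat(sprintf("  genes: %d   exonic targets: %d\n",
              x$total_genes, x$total_targets))
  cat(sprintf("  covered: %d   uncovered: %d   coverage: %s%%\n",
              x$covered_targets, x$uncovered_targets,
              format(x$coverage_pct)))
  cat(sprintf("  probes: %d (%s)\n", x$total_probes,
              paste(sprintf("%s %d", names(x$probes_by_source),
                            as.integer(x$probes_by_source)),
                    collapse = ", ")))
  cat(sprintf("  median probe spacing: %s bp   mean target size: %s bp\n",
              format(x$median_probe_spacing_bp),
              format(round(x$mean_target_size_bp, 1))))
  invisible(x)
}

#' Compare several probe designs on the same targets
#'
#' @param targets an [exon_targets()] table.
#' @param probe_sets named list of [probe_set()] tables, all on the same
#'   assembly as the targets.
#' @return data.frame with one row per design and the design-summary
#'   columns.
#' @export
compare_designs <- function(targets, probe_sets) {
  stopifnot(is.list(probe_sets), length(probe_sets) >= 1,
            !is.null(names(probe_sets)), all(nzchar(names(probe_sets))))
  asm <- interval_assembly(targets)
  for (nm in names(probe_sets)) {
    if (!identical(interval_assembly(probe_sets[[nm]]), asm)) {
      stop("compare_designs: probe set '", nm, "' is on assembly '",
           interval_assembly(probe_sets[[nm]]), "' but targets are on '",
           asm, "'")
    }
  }
  rows <- lapply(names(probe_sets), function(nm) {
    s <- compute_design_summary(targets, probe_sets[[nm]])
    data.frame(design = nm, total_targets = s$total_targets,
               covered_targets = s$covered_targets,
               uncovered_targets = s$uncovered_targets,
               coverage_pct = s$coverage_pct,
               total_probes = s$total_probes,
               median_probe_spacing_bp = s$median_probe_spacing_bp,
               mean_target_size_bp = s$mean_target_size_bp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify a call against a structural-variant interval database
#'
#' Reproduces the containment wording used in CNV report tables:
#' `"completely contained within <labels>"` when the call lies entirely
#' inside at least one database interval, `"almost completely contained
#' within <labels>"` when the best contained fraction is >= 0.9 but < 1,
#' `"overlaps <labels>"` for any smaller positive overlap, and
#' `"not reported"` when disjoint from every database interval.
#'
#' @param call a single interval: list or one-row data.frame with `chrom`,
#'   `start`, `stop` (0-based half-open).
#' @param db data.frame with `chrom`, `start`, `stop`, `label`.
#' @param almost_fraction contained fraction boundary for the "almost"
#'   category (default 0.9).
#' @return a single status string.
#' @export
classify_containment <- function(call, db, almost_fraction = 0.9) {
  if (is.null(db) || nrow(db) == 0) return("not reported")
  len <- call$stop - call$start
  frac <- overlap_widths(call$chrom, call$start, call$stop, db) / len
  if (any(frac >= 1)) {
    lab <- db$label[frac >= 1]
    sprintf("completely contained within %s", paste(lab, collapse = ", "))
  } else if (max(frac) >= almost_fraction) {
    lab <- db$label[frac >= almost_fraction]
    sprintf("almost completely contained within %s",
            paste(lab, collapse = ", "))
  } else if (max(frac) > 0) {
    sprintf("overlaps %s", paste(db$label[frac > 0], collapse = ", "))
  } else {
    "not reported"
  }
}

#' Annotate calls with panel genes and database containment
#'
#' Genes are attached when their interval overlaps the call by at least one
#' base pair; the call inherits the union of the genes' disease-panel
#' labels. Database status comes from [classify_containment()].
#'
#' @param calls a calls table (see [find_aberrations()]).
#' @param panel optional [gene_panel()].
#' @param db optional database intervals with `label` column.
#' @return `calls` with `genes`, `panels`, `db_status` filled in.
#' @export
annotate_calls <- function(calls, panel = NULL, db = NULL) {
  if (nrow(calls) == 0) return(calls)
  for (i in seq_len(nrow(calls))) {
    if (!is.null(panel) && nrow(panel)) {
      ov <- overlap_widths(calls$chrom[i], calls$start[i], calls$stop[i],
                           panel) > 0
      calls$genes[i] <- paste(panel$gene[ov], collapse = ",")
      calls$panels[i] <- paste(sort(unique(unlist(
        split_panels(panel$panels[ov])))), collapse = ";")
    }
    calls$db_status[i] <- classify_containment(
      list(chrom = calls$chrom[i], start = calls$start[i],
           stop = calls$stop[i]), db)
  }
  calls
}
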