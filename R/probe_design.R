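# Isothermal probe selection over exon targets with a tiling fallback.

#' Probe design configuration
#'
#' @param probe_length probe length in bases (default 60).
#' @param tm_target_c isothermal melting-temperature target (default 80).
#' @param tm_tolerance_c accepted deviation for library-style selection
#'   (default 5; tiling doubles it).
#' @param max_probes_per_exon,min_probes_per_exon probes placed per exon
#'   (defaults 2 and 1).
#' @param step_bp candidate stride across the exon (default 1).
#' @param max_homopolymer longest tolerated single-base run (default 6).
#' @param gc_min,gc_max hard GC-content bounds (defaults 0.30/0.70).
#' @param max_selfcomp hard cap on the longest match between the probe and
#'   its own reverse complement (default 12 bases).
#' @param na_molar,oligo_molar ionic and total oligo concentrations used by
#'   the nearest-neighbor Tm model.
#' @return list of class `design_config`.
#' @export
design_config <- function(probe_length = 60, tm_target_c = 80,
                          tm_tolerance_c = 5, max_probes_per_exon = 2,
                          min_probes_per_exon = 1, step_bp = 1,
                          max_homopolymer = 6, gc_min = 0.30, gc_max = 0.70,
                          max_selfcomp = 12, na_molar = 0.1,
                          oligo_molar = 2.5e-7) {
  stopifnot(probe_length >= 20,
            min_probes_per_exon <= max_probes_per_exon,
            tm_tolerance_c > 0, step_bp >= 1)
  structure(list(probe_length = as.integer(probe_length),
                 tm_target_c = tm_target_c, tm_tolerance_c = tm_tolerance_c,
                 max_probes_per_exon = as.integer(max_probes_per_exon),
                 min_probes_per_exon = as.integer(min_probes_per_exon),
                 step_bp = as.integer(step_bp),
                 max_homopolymer = as.integer(max_homopolymer),
                 gc_min = gc_min, gc_max = gc_max,
                 max_selfcomp = as.integer(max_selfcomp),
                 na_molar = na_molar, oligo_molar = oligo_molar),
            class = "design_config")
}

#' @noRd
max_run_length <- function(bases) {
  if (!length(bases)) return(0L)
  max(rle(bases)$lengths)
}

# Longest common substring between the probe and its reverse complement: a
# sequence-intrinsic proxy for hairpin/self-dimer potential.
#' @noRd
selfcomp_length <- function(sequence) {
  a <- strsplit(sequence, "")[[1]]
  b <- strsplit(revcomp(sequence), "")[[1]]
  n <- length(a)
  best <- 0L
  prev <- integer(n)
  for (i in seq_len(n)) {
    cur <- integer(n)
    match_j <- which(b == a[i])
    for (j in match_j) {
      cur[j] <- if (j > 1) prev[j - 1] + 1L else 1L
    }
    if (length(match_j)) best <- max(best, max(cur[match_j]))
    prev <- cur
  }
  best
}

#' Quality score of a candidate probe sequence
#'
#' A product of smooth penalty factors for GC deviation from 50 percent,
#' melting-temperature deviation from the isothermal target, homopolymer
#' runs, and self-complementarity. The score is exactly 0 when any hard
#' filter fails: a non-ACGT base, a homopolymer run longer than
#' `max_homopolymer`, GC content outside `[gc_min, gc_max]`, or a
#' self-complementary stretch of `max_selfcomp` bases or more.
#'
#' @param sequence candidate DNA string.
#' @param config a [design_config()].
#' @return quality score in `[0, 1]`.
#' @export
score_candidate <- function(sequence, config = design_config()) {
  sequence <- toupper(sequence)
  bases <- strsplit(sequence, "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T"))) return(0)
  run <- max_run_length(bases)
  if (run > config$max_homopolymer) return(0)
  gc <- mean(bases %in% c("G", "C"))
  if (gc < config$gc_min || gc > config$gc_max) return(0)
  sc <- selfcomp_length(sequence)
  if (sc >= config$max_selfcomp) return(0)
  tm <- melting_temperature(sequence, config)
  f_gc <- 1 - (abs(gc - 0.5) / 0.5)^2
  f_tm <- max(0, 1 - abs(tm - config$tm_target_c) / (2 * config$tm_tolerance_c))
  f_hp <- 1 - max(0, run - 2) / (2 * config$max_homopolymer)
  f_sc <- 1 - max(0, sc - 4) / config$max_selfcomp
  f_gc * f_tm * f_hp * f_sc
}

#' @noRd
fetch_sequence <- function(genome, chrom, start, stop) {
  # genome: Biostrings::DNAStringSet keyed by chromosome name
  as.character(Biostrings::subseq(genome[[chrom]], start + 1, stop))
}

# Candidate window starts for a target, extending symmetrically into the
# flanks when the target is shorter than one probe length.
#' @noRd
candidate_starts <- function(start, stop, probe_length, step_bp, chrom_len) {
  if (stop - start < probe_length) {
    mid <- floor((start + stop) / 2)
    s <- mid - floor(probe_length / 2)
    s <- min(max(s, 0), chrom_len - probe_length)
    return(s)
  }
  seq(start, stop - probe_length, by = step_bp)
}

#' Place probes end-to-end across a target (genomic tiling fallback)
#'
#' Tiling places probes at a fixed stride of one probe length from the
#' target start, with the quality filters relaxed (the Tm tolerance is
#' doubled). Windows failing a hard filter are skipped; their neighbors are
#' kept. A target shorter than one probe length receives a single probe
#' extending symmetrically into the flanking sequence.
#'
#' @param target one-row [exon_targets()] slice (or list with `gene`,
#'   `exon_index`, `chrom`, `start`, `stop`).
#' @param genome a `Biostrings::DNAStringSet` containing the chromosome.
#' @param config a [design_config()].
#' @return a [probe_set()] (possibly empty) with `source = "tiling"`.
#' @export
tile_region <- function(target, genome, config = design_config()) {
  if (!(target$chrom %in% names(genome))) {
    stop("tile_region: chromosome '", target$chrom, "' absent from genome")
  }
  L <- config$probe_length
  chrom_len <- length(genome[[target$chrom]])
  width <- target$stop - target$start
  starts <- if (width < L) {
    candidate_starts(target$start, target$stop, L, config$step_bp, chrom_len)
  } else {
    seq(target$start, target$stop - L, by = L)
  }
  keep <- c(); seqs <- c(); tms <- c()
  relaxed <- 2 * config$tm_tolerance_c
  for (s in starts) {
    sq <- fetch_sequence(genome, target$chrom, s, s + L)
    if (!hard_filters_pass(sq, config)) next
    tm <- melting_temperature(sq, config)
    if (abs(tm - config$tm_target_c) > relaxed) next
    keep <- c(keep, s); seqs <- c(seqs, sq); tms <- c(tms, tm)
  }
  if (!length(keep)) {
    return(probe_set(character(), character(), numeric(), numeric()))
  }
  probe_set(sprintf("%s_e%d_t%d", target$gene, target$exon_index,
                    seq_along(keep)),
            target$chrom, keep, keep + L, seqs, tms,
            source = "tiling", error = 0.2)
}

#' @noRd
hard_filters_pass <- function(sequence, config) {
  sequence <- toupper(sequence)
  bases <- strsplit(sequence, "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T"))) return(FALSE)
  if (max_run_length(bases) > config$max_homopolymer) return(FALSE)
  gc <- mean(bases %in% c("G", "C"))
  if (gc < config$gc_min || gc > config$gc_max) return(FALSE)
  if (selfcomp_length(sequence) >= config$max_selfcomp) return(FALSE)
  TRUE
}

#' Select isothermal probes over exon targets
#'
#' For each exon, candidate windows are scored with [score_candidate()] and
#' filtered to the Tm window `tm_target_c +/- tm_tolerance_c`. Up to
#' `max_probes_per_exon` non-identical candidates are kept, spread across
#' the exon: the candidate start range is split into `max_probes_per_exon`
#' equal bins and the highest-scoring candidate in each bin wins (ties go to
#' the leftmost start). Exons with no passing candidate fall back to
#' [tile_region()]; exons where even tiling yields nothing are returned as
#' uncovered. Selection is deterministic given genome and configuration.
#'
#' @param targets an [exon_targets()] table.
#' @param genome a `Biostrings::DNAStringSet` (or path to a FASTA file)
#'   containing every target chromosome.
#' @param config a [design_config()].
#' @return list with `probes` (a [probe_set()]) and `uncovered` (the subset
#'   of `targets` that received no probe).
#' @export
select_probes <- function(targets, genome, config = design_config()) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  missing_chr <- setdiff(unique(targets$chrom), names(genome))
  if (length(missing_chr)) {
    stop("select_probes: chromosome(s) absent from genome FASTA: ",
         paste(missing_chr, collapse = ", "))
  }
  L <- config$probe_length
  all_probes <- list()
  uncovered_idx <- integer()
  for (i in seq_len(nrow(targets))) {
    t <- targets[i, ]
    chrom_len <- length(genome[[t$chrom]])
    starts <- candidate_starts(t$start, t$stop, L, config$step_bp, chrom_len)
    seqs <- vapply(starts, function(s)
      fetch_sequence(genome, t$chrom, s, s + L), "")
    scores <- vapply(seqs, score_candidate, 0, config = config)
    tms <- rep(NA_real_, length(seqs))
    ok <- scores > 0
    tms[ok] <- vapply(seqs[ok], melting_temperature, 0, config = config)
    pass <- ok & abs(tms - config$tm_target_c) <= config$tm_tolerance_c
    if (any(pass)) {
      sel <- pick_spread(starts[pass], scores[pass], seqs[pass],
                         config$max_probes_per_exon)
      probes <- probe_set(sprintf("%s_e%d_p%d", t$gene, t$exon_index,
                                  seq_along(sel)),
                          t$chrom, starts[pass][sel],
                          starts[pass][sel] + L, seqs[pass][sel],
                          tms[pass][sel], source = "HD_library",
                          error = 0.2,
                          assembly = interval_assembly(targets))
      all_probes[[length(all_probes) + 1]] <- probes
    } else {
      tiled <- tile_region(t, genome, config)
      if (nrow(tiled)) {
        attr(tiled, "assembly") <- interval_assembly(targets)
        all_probes[[length(all_probes) + 1]] <- tiled
      } else {
        uncovered_idx <- c(uncovered_idx, i)
      }
    }
  }
  probes <- if (length(all_probes)) {
    combined <- do.call(rbind, lapply(all_probes, as.data.frame))
    probe_set(combined$probe_id, combined$chrom, combined$start,
              combined$stop, combined$sequence, combined$tm_c,
              combined$source, combined$error,
              assembly = interval_assembly(targets))
  } else {
    probe_set(character(), character(), numeric(), numeric(),
              assembly = interval_assembly(targets))
  }
  list(probes = probes, uncovered = targets[uncovered_idx, , drop = FALSE])
}

# Spread selection: split the candidate start range into k equal bins and
# take the best-scoring candidate per bin (ties: leftmost). Identical
# sequences are de-duplicated.
#' @noRd
pick_spread <- function(starts, scores, seqs, k) {
  if (length(starts) == 1 || k == 1) {
    return(order(-scores, starts)[1])
  }
  rng <- range(starts)
  if (rng[1] == rng[2]) return(order(-scores, starts)[1])
  edges <- seq(rng[1], rng[2] + 1, length.out = k + 1)
  bin <- findInterval(starts, edges, rightmost.closed = TRUE)
  sel <- integer()
  for (b in sort(unique(bin))) {
    in_bin <- which(bin == b)
    best <- in_bin[order(-scores[in_bin], starts[in_bin])[1]]
    if (!(seqs[best] %in% seqs[sel])) sel <- c(sel, best)
  }
  sel[seq_len(min(length(sel), k))]
}
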