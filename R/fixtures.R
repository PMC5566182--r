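# Bundled synthetic case-study fixtures. Probe layouts, gene intervals and
# disease-panel assignments are reconstructions built around the published
# call coordinates and amplitudes; they are synthetic stand-ins for the
# unpublished design files and are labelled as such in the metadata.

# The ten CNV records of the first case study, as printed (1-based
# inclusive coordinates, GRCh37/hg19).
#' @noRd
patient1_records <- function() {
  data.frame(
    cnv_type = c("gain", "gain", "gain", "loss", "loss", "gain", "gain",
                 "loss", "gain", "loss"),
    chrom = c("chr1", "chr1", "chr2", "chr3", "chr3", "chr5", "chr9",
              "chr9", "chr12", "chr17"),
    start1 = c(6579851, 54704828, 179541928, 142216000, 178922270,
               70307077, 131012433, 139903473, 56615423, 44701610),
    stop1 = c(8021801, 54747170, 179542606, 142222244, 178927435,
              70308602, 131314975, 139904058, 56615694, 44771900),
    n_probes = c(33L, 12L, 3L, 6L, 23L, 4L, 16L, 4L, 7L, 114L),
    gene = c("PARK7", "SSBP3", "TTN", "ATR", "PIK3CA", "NAIP", "DNM1",
             "ABCA2", "RNF41", "NSF"),
    stringsAsFactors = FALSE)
}

#' Table of the bundled first case study's printed CNV records as calls
#'
#' Returns the ten printed CNV records (six gains, four losses) as a
#' [cnv_calls()] table, with heterozygous amplitudes (+0.58 for a 3-copy
#' gain, -1 for a 1-copy loss) standing in for the unpublished per-call
#' means.
#' @return a [cnv_calls()] table of 10 records.
#' @export
patient1_printed_calls <- function() {
  rec <- patient1_records()
  mean_log2 <- ifelse(rec$cnv_type == "gain", log2(3 / 2), -1)
  cnv_calls(rec$chrom, rec$start1 - 1, rec$stop1, rec$cnv_type,
            rec$n_probes, mean_log2,
            score = NA_real_, algorithms = "ADM1-like",
            tier = "single-algorithm",
            cn_estimate = estimate_copy_number(mean_log2),
            genes = rec$gene)
}

# Evenly spread k probe starts inside [start, stop) (0-based), 60-mers.
#' @noRd
spread_probes <- function(start, stop, k, width = 60) {
  if (k == 1) return(floor((start + stop) / 2) - width / 2)
  round(seq(start, stop - width, length.out = k))
}

#' @noRd
build_patient1 <- function() {
  rec <- patient1_records()
  rec$start <- rec$start1 - 1  # to internal 0-based
  rec$stop <- rec$stop1
  width <- 60
  probe_rows <- list()
  for (chr in unique(rec$chrom)) {
    sub <- rec[rec$chrom == chr, , drop = FALSE]
    lo <- min(sub$start) - 2e6
    hi <- max(sub$stop) + 2e6
    bg <- round(seq(lo, hi - width, length.out = 150))
    inside <- rep(FALSE, length(bg))
    for (k in seq_len(nrow(sub))) {
      inside <- inside | (bg + width > sub$start[k] & bg < sub$stop[k])
    }
    bg <- bg[!inside]
    probe_rows[[length(probe_rows) + 1]] <-
      data.frame(chrom = chr, start = bg, stringsAsFactors = FALSE)
    for (k in seq_len(nrow(sub))) {
      probe_rows[[length(probe_rows) + 1]] <-
        data.frame(chrom = chr,
                   start = spread_probes(sub$start[k], sub$stop[k],
                                         sub$n_probes[k], width),
                   stringsAsFactors = FALSE)
    }
  }
  pr <- do.call(rbind, probe_rows)
  pr <- pr[order(pr$chrom, pr$start), ]
  probes <- probe_set(sprintf("p1_%05d", seq_len(nrow(pr))), pr$chrom,
                      pr$start, pr$start + width)
  specs <- cnv_spec(rec$chrom, rec$start, rec$stop,
                    ifelse(rec$cnv_type == "gain", 3L, 1L))
  # Reconstructed gene intervals: the central half of each call. Panel
  # labels follow the diseases the printed annotations associate with each
  # gene; the four PD genes are flagged causative.
  g_start <- round(rec$start + 0.25 * (rec$stop - rec$start))
  g_stop <- round(rec$start + 0.75 * (rec$stop - rec$start))
  panel_labels <- c(PARK7 = "PD;ALS", SSBP3 = "PD", TTN = "LGMD",
                    ATR = "epilepsy", PIK3CA = "epilepsy", NAIP = "ALS",
                    DNM1 = "epilepsy", ABCA2 = "AD", RNF41 = "PD",
                    NSF = "PD")
  panel <- gene_panel(rec$gene, rec$chrom, g_start, g_stop,
                      panels = unname(panel_labels[rec$gene]),
                      causative = rec$gene %in%
                        c("PARK7", "SSBP3", "RNF41", "NSF"))
  # One exon per gene spanning the first two probes inside its call.
  ex_start <- ex_stop <- numeric(nrow(rec))
  for (k in seq_len(nrow(rec))) {
    ps <- sort(spread_probes(rec$start[k], rec$stop[k], rec$n_probes[k],
                             width))
    n_ex <- min(2, length(ps))
    ex_start[k] <- ps[1]
    ex_stop[k] <- ps[n_ex] + width
  }
  targets <- exon_targets(rec$gene, 1L, rec$chrom, ex_start, ex_stop)
  # Annotation database reproducing the printed containment categories for
  # the first two calls (synthetic variant intervals).
  db <- data.frame(
    chrom = c("chr1", "chr1", "chr3"),
    start = c(rec$start[1] + round(0.05 * (rec$stop[1] - rec$start[1])),
              rec$start[2] - 1e4, rec$start[4] - 5e3),
    stop = c(rec$stop[1], rec$stop[2] + 1e4, rec$stop[4] + 5e3),
    label = c("nssv1602095", "nssv578523", "nssv583804"),
    stringsAsFactors = FALSE)
  qpcr_loci <- data.frame(
    locus = c("PARK7_ex1", "NSF_ex11"),
    dosage = c(1.5, 0.5),
    chrom = c("chr1", "chr17"),
    start = c(g_start[1], g_start[10]),
    stop = c(g_start[1] + 120, g_start[10] + 120),
    stringsAsFactors = FALSE)
  list(name = "patient1", panel = panel, targets = targets, probes = probes,
       cnv_specs = specs, db = db, qpcr_loci = qpcr_loci,
       printed_calls = patient1_printed_calls(),
       sim = sim_config(seed = 11L, sigma = 0.1, outlier_prob = 0),
       provenance = "synthetic reconstruction at printed coordinates")
}

#' @noRd
build_patient2 <- function() {
  # PARK2 with 12 exons of 100 bp spaced 10 kb; two probes per exon except
  # exon 4, which has no probe coverage (it missed the design's optimum
  # probe parameters). A heterozygous deletion spans exons 4 and 5, so the
  # single-probe analysis sees exon 5 through its two probes while exon 4
  # is reported uncovered.
  width <- 60
  exon_start <- 161768590 + (0:11) * 10000
  exon_stop <- exon_start + 100
  targets <- exon_targets("PARK2", 1:12, "chr6", exon_start, exon_stop)
  del_start <- exon_start[4] - 500
  del_stop <- exon_stop[5] + 500
  exon_probe_starts <- unlist(lapply(seq_len(12), function(i) {
    if (i == 4) NULL else c(exon_start[i] - 10, exon_start[i] + 50)
  }))
  # Background probes emulate other targets on the chromosome; none fall
  # inside the deletion, so the only aberrant probes there are exon 5's
  # two (below the multi-probe caller's minimum run).
  bg <- round(seq(161500000, 162100000, length.out = 120))
  bg <- bg[!(bg + width > del_start & bg < del_stop)]
  bg <- bg[!vapply(bg, function(s) any(s + width > exon_start &
                                         s < exon_stop), TRUE)]
  starts <- sort(unique(c(exon_probe_starts, bg)))
  probes <- probe_set(sprintf("p2_%04d", seq_along(starts)), "chr6",
                      starts, starts + width)
  specs <- cnv_spec("chr6", del_start, del_stop, 1L)
  panel <- gene_panel("PARK2", "chr6", min(exon_start) - 1000,
                      max(exon_stop) + 1000, panels = "PD",
                      causative = TRUE)
  qpcr_loci <- data.frame(locus = "PARK2_ex5", dosage = 0.5,
                          chrom = "chr6", start = exon_start[5],
                          stop = exon_stop[5], stringsAsFactors = FALSE)
  list(name = "patient2", panel = panel, targets = targets, probes = probes,
       cnv_specs = specs, db = NULL, qpcr_loci = qpcr_loci,
       printed_calls = NULL,
       sim = sim_config(seed = 22L, sigma = 0.1, outlier_prob = 0),
       provenance = "synthetic reconstruction of the exon 4+5 deletion case")
}

#' @noRd
build_null <- function() {
  width <- 60
  starts <- round(seq(1e6, 5e7, length.out = 500))
  probes <- probe_set(sprintf("n_%04d", seq_len(500)), "chr1", starts,
                      starts + width)
  targets <- exon_targets("GENE0", 1L, "chr1", starts[1], starts[1] + width)
  panel <- gene_panel("GENE0", "chr1", starts[1] - 1000,
                      starts[1] + 2000, panels = "PD", causative = TRUE)
  list(name = "null", panel = panel, targets = targets, probes = probes,
       cnv_specs = cnv_spec(character(), numeric(), numeric(), integer()),
       db = NULL, qpcr_loci = NULL, printed_calls = NULL,
       sim = sim_config(seed = 33L, sigma = 0.2, outlier_prob = 0),
       provenance = "negative control, no aberrations")
}

#' Load a bundled case-study fixture
#'
#' Fixtures reconstruct the package's two worked case studies plus a
#' negative control, entirely in code: `"patient1"` (ten CNVs — six gains
#' and four losses — at the printed coordinates, with qPCR validation loci
#' at dosages 1.5 and 0.5), `"patient2"` (a PARK2 exon 4+5 heterozygous
#' deletion where exon 4 has no probe coverage), and `"null"` (no
#' aberrations).
#'
#' @param name one of `"patient1"`, `"patient2"`, `"null"`.
#' @return list with `panel`, `targets`, `probes`, `cnv_specs`, `db`,
#'   `qpcr_loci`, `printed_calls`, `sim` (a [sim_config()]) and
#'   `provenance`.
#' @export
load_fixture <- function(name) {
  builders <- list(patient1 = build_patient1, patient2 = build_patient2,
                   null = build_null)
  if (!name %in% names(builders)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(names(builders), collapse = ", "))
  }
  builders[[name]]()
}
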