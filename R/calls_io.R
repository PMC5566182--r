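# CNV call container and TSV/BED/VCF writers.

#' Construct a CNV call table
#'
#' @param chrom,start,stop call intervals (0-based half-open).
#' @param cnv_type `"gain"` or `"loss"`.
#' @param n_probes supporting probe count (>= 1).
#' @param mean_log2 mean centered log2 ratio over the interval.
#' @param score interval score S.
#' @param algorithms comma-separated subset of
#'   `ADM1-like`, `ADM2-like`, `single-probe`.
#' @param tier `"both"`, `"single-algorithm"` or `"single-probe"`.
#' @param cn_estimate integer copy-number estimate in 0..8.
#' @param genes,panels,db_status annotation strings (may be empty).
#' @param assembly assembly label.
#' @return data.frame of class `cnv_calls`, sorted by position.
#' @export
cnv_calls <- function(chrom = character(), start = numeric(),
                      stop = numeric(), cnv_type = character(),
                      n_probes = integer(), mean_log2 = numeric(),
                      score = numeric(), algorithms = "ADM1-like",
                      tier = "single-algorithm", cn_estimate = NA_integer_,
                      genes = "", panels = "", db_status = "not reported",
                      assembly = DEFAULT_ASSEMBLY) {
  if (length(chrom) == 0) {
    df <- data.frame(chrom = character(), start = numeric(),
                     stop = numeric(), cnv_type = character(),
                     n_probes = integer(), mean_log2 = numeric(),
                     score = numeric(), algorithms = character(),
                     tier = character(), cn_estimate = integer(),
                     genes = character(), panels = character(),
                     db_status = character(), stringsAsFactors = FALSE)
  } else {
    df <- genomic_intervals(chrom, start, stop,
                            cnv_type = as.character(cnv_type),
                            n_probes = as.integer(n_probes),
                            mean_log2 = as.numeric(mean_log2),
                            score = as.numeric(score),
                            algorithms = as.character(algorithms),
                            tier = as.character(tier),
                            cn_estimate = as.integer(cn_estimate),
                            genes = as.character(genes),
                            panels = as.character(panels),
                            db_status = as.character(db_status),
                            assembly = assembly)
    stopifnot(all(df$cnv_type %in% c("gain", "loss")),
              all(df$n_probes >= 1),
              all(df$tier %in% c("both", "single-algorithm", "single-probe")))
    bad <- (df$cnv_type == "gain" & df$mean_log2 < 0) |
      (df$cnv_type == "loss" & df$mean_log2 > 0)
    if (any(bad)) stop("cnv calls: cnv_type inconsistent with mean_log2 sign")
    df <- sort_by_position(df)
    rownames(df) <- NULL
  }
  attr(df, "assembly") <- assembly
  class(df) <- c("cnv_calls", class(df))
  df
}

#' Copy-number estimate from a mean log2 ratio
#'
#' `round(2 * 2^mean_log2)` clamped to 0..8; maps +0.58 to 3 copies and
#' -1 to 1 copy against a diploid reference.
#' @param mean_log2 numeric vector.
#' @return integer vector.
#' @export
estimate_copy_number <- function(mean_log2) {
  as.integer(pmin(8, pmax(0, round_half_up(2 * 2^mean_log2))))
}

#' Write CNV calls to TSV, BED or VCF
#'
#' The TSV report uses 1-based inclusive coordinates and a printed size in
#' kb computed as `(stop - start + 1)/1000` rounded to the nearest integer.
#' BED uses native 0-based half-open coordinates with `cnv_type` in the
#' name field. VCF 4.2 uses symbolic `<DUP>`/`<DEL>` alleles with `END`,
#' `SVTYPE`, `NPROBES`, `SCORE`, `TIER` and `CN` INFO fields.
#'
#' @param calls a [cnv_calls()] table.
#' @param path output path.
#' @param format one of `"tsv"`, `"bed"`, `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path, format = c("tsv", "bed", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    out <- data.frame(cnv_type = calls$cnv_type, chrom = calls$chrom,
                      start = calls$start + 1, stop = calls$stop,
                      size_kb = size_kb_1based(calls$start + 1, calls$stop),
                      n_probes = calls$n_probes,
                      mean_log2 = calls$mean_log2, score = calls$score,
                      algorithms = calls$algorithms, tier = calls$tier,
                      cn_estimate = calls$cn_estimate, genes = calls$genes,
                      panels = calls$panels, db_status = calls$db_status)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "bed") {
    lines <- sprintf("%s\t%d\t%d\t%s\t%s\t+", calls$chrom,
                     as.integer(calls$start), as.integer(calls$stop),
                     calls$cnv_type, format(calls$score, digits = 10))
    writeLines(lines, path)
  } else {
    writeLines(format_vcf(calls), path)
  }
  invisible(path)
}

#' @noRd
format_vcf <- function(calls) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=exonCGH",
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=DUP,Description=\"Duplication\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=NPROBES,Number=1,Type=Integer,Description=\"Number of supporting array probes\">",
    "##INFO=<ID=SCORE,Number=1,Type=Float,Description=\"Interval score\">",
    "##INFO=<ID=TIER,Number=1,Type=String,Description=\"Calling tier\">",
    "##INFO=<ID=CN,Number=1,Type=Integer,Description=\"Copy-number estimate\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(calls) == 0) return(header)
  svtype <- ifelse(calls$cnv_type == "gain", "DUP", "DEL")
  body <- sprintf(
    "%s\t%d\tcnv%d\tN\t<%s>\t%.2f\tPASS\tEND=%d;SVTYPE=%s;NPROBES=%d;SCORE=%.4f;TIER=%s;CN=%d",
    calls$chrom, as.integer(calls$start + 1), seq_len(nrow(calls)), svtype,
    calls$score, as.integer(calls$stop), svtype, calls$n_probes, calls$score,
    calls$tier, calls$cn_estimate)
  c(header, body)
}

#' Read CNV calls written by [write_calls()]
#'
#' @param path input path.
#' @param format `"tsv"` or `"bed"`.
#' @param assembly assembly label.
#' @return a [cnv_calls()] table.
#' @export
read_calls <- function(path, format = c("tsv", "bed"),
                       assembly = DEFAULT_ASSEMBLY) {
  format <- match.arg(format)
  if (format == "tsv") {
    x <- utils::read.delim(path, stringsAsFactors = FALSE)
    for (col in c("genes", "panels", "db_status", "algorithms")) {
      x[[col]][is.na(x[[col]])] <- ""
    }
    cnv_calls(x$chrom, x$start - 1, x$stop, x$cnv_type, x$n_probes,
              x$mean_log2, x$score, x$algorithms, x$tier, x$cn_estimate,
              x$genes, x$panels, x$db_status, assembly = assembly)
  } else {
    x <- read_bed(path, min_fields = 4)
    fields <- strsplit(readLines(path, warn = FALSE), "\t", fixed = TRUE)
    score <- vapply(fields, function(f)
      if (length(f) >= 5) as.numeric(f[[5]]) else NA_real_, 0)
    cnv_calls(x$chrom, x$start, x$stop, x$name,
              n_probes = 1L, mean_log2 = ifelse(x$name == "gain", 1, -1),
              score = score, assembly = assembly)
  }
}
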