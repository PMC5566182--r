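# Readers and domain containers for gene panels, exon targets and probes.

#' Construct a gene panel
#'
#' A gene panel lists the genes the array interrogates, the disease panels
#' each gene belongs to (a gene may belong to several, e.g. Parkinson's
#' disease plus epilepsy), and whether the gene is a strongly linked
#' causative gene (as opposed to a susceptibility factor).
#'
#' @param gene character vector of unique gene symbols.
#' @param chrom,start,stop gene intervals (0-based half-open).
#' @param panels character vector; disease labels separated by `";"`.
#' @param causative logical vector.
#' @param assembly assembly label.
#' @return data.frame of class `gene_panel`.
#' @export
gene_panel <- function(gene, chrom, start, stop, panels,
                       causative = FALSE, assembly = DEFAULT_ASSEMBLY) {
  df <- genomic_intervals(chrom, start, stop,
                          gene = as.character(gene),
                          panels = as.character(panels),
                          causative = as.logical(causative),
                          assembly = assembly)
  if (anyDuplicated(df$gene)) {
    stop("gene panel: duplicated gene symbol(s): ",
         paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "))
  }
  if (any(!nzchar(df$panels) | is.na(df$panels))) {
    stop("gene panel: every gene needs at least one disease panel label")
  }
  class(df) <- c("gene_panel", class(df))
  df
}

#' @noRd
split_panels <- function(x) strsplit(as.character(x), ";", fixed = TRUE)

#' Read a gene panel definition from TSV or JSON
#'
#' TSV columns: `gene`, `chrom`, `start`, `stop` (1-based inclusive),
#' `panels` (";"-separated), `causative` (TRUE/FALSE). JSON: an array of
#' objects with the same fields (`panels` may be an array of strings).
#'
#' @param path file path; format chosen by extension (`.json` vs tabular).
#' @return a [gene_panel()].
#' @export
load_panel <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    panels <- if (is.list(x$panels)) {
      vapply(x$panels, paste, "", collapse = ";")
    } else as.character(x$panels)
    gene_panel(x$gene, x$chrom, as.numeric(x$start) - 1, x$stop,
               panels = panels, causative = x$causative)
  } else {
    x <- utils::read.delim(path, stringsAsFactors = FALSE)
    gene_panel(x$gene, x$chrom, x$start - 1, x$stop,
               panels = x$panels, causative = x$causative)
  }
}

#' Panel gene accounting relative to a primary disease
#'
#' Splits the panel's genes into those specific to the primary disease
#' (no other panel membership) and those shared with other disease panels.
#'
#' @param panel a [gene_panel()].
#' @param primary disease label of the primary panel (default `"PD"`).
#' @return list with `total`, `specific`, `shared` gene counts and the
#'   per-panel gene counts in `by_panel`.
#' @export
panel_gene_counts <- function(panel, primary = "PD") {
  labels <- split_panels(panel$panels)
  in_primary <- vapply(labels, function(p) primary %in% p, TRUE)
  n_labels <- lengths(labels)
  by_panel <- table(unlist(labels))
  list(total = sum(in_primary),
       specific = sum(in_primary & n_labels == 1L),
       shared = sum(in_primary & n_labels > 1L),
       by_panel = by_panel)
}

# ---------------------------------------------------------------------------
# Exon targets

#' Construct exon targets
#'
#' @param gene gene symbols.
#' @param exon_index exon ordinal within the gene (>= 1).
#' @param chrom,start,stop exon intervals (0-based half-open).
#' @param assembly assembly label.
#' @return data.frame of class `exon_targets`, sorted by position.
#' @export
exon_targets <- function(gene, exon_index, chrom, start, stop,
                         assembly = DEFAULT_ASSEMBLY) {
  if (length(gene) == 0) {
    df <- data.frame(chrom = character(), start = numeric(),
                     stop = numeric(), gene = character(),
                     exon_index = integer(), stringsAsFactors = FALSE)
    attr(df, "assembly") <- assembly
    class(df) <- c("exon_targets", class(df))
    return(df)
  }
  df <- genomic_intervals(chrom, start, stop,
                          gene = as.character(gene),
                          exon_index = as.integer(exon_index),
                          assembly = assembly)
  if (nrow(df) && any(df$exon_index < 1L)) {
    stop("exon targets: exon_index must be >= 1")
  }
  key <- paste(df$gene, df$exon_index)
  if (anyDuplicated(key)) {
    stop("exon targets: duplicated exon index within a gene: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  df <- sort_by_position(df)
  rownames(df) <- NULL
  attr(df, "assembly") <- assembly
  class(df) <- c("exon_targets", class(df))
  df
}

# Minimal validating BED reader. BED is 0-based half-open; errors name the
# offending line so malformed design files are easy to fix.
#' @noRd
read_bed <- function(path, min_fields = 3) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  idx <- which(keep)
  if (!length(idx)) {
    warning("BED file '", path, "' contains no records")
    return(data.frame(chrom = character(), start = numeric(),
                      stop = numeric(), name = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < min_fields)) {
    bad <- idx[which(nf < min_fields)[1]]
    stop(sprintf("malformed BED line %d in '%s': expected >= %d fields",
                 bad, path, min_fields))
  }
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  stop_ <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  if (anyNA(start) || anyNA(stop_)) {
    bad <- idx[which(is.na(start) | is.na(stop_))[1]]
    stop(sprintf("malformed BED line %d in '%s': non-numeric coordinates",
                 bad, path))
  }
  if (any(stop_ <= start)) {
    bad <- idx[which(stop_ <= start)[1]]
    stop(sprintf("invalid BED line %d in '%s': stop must exceed start",
                 bad, path))
  }
  name <- if (min_fields >= 4 || all(nf >= 4)) {
    vapply(fields, function(f) if (length(f) >= 4) f[[4]] else NA_character_, "")
  } else rep(NA_character_, length(fields))
  data.frame(chrom = chrom, start = start, stop = stop_, name = name,
             stringsAsFactors = FALSE)
}

#' Load exon targets from a BED file
#'
#' Requires at least four columns; the name field encodes the target as
#' `gene|exon_index` (e.g. `PINK1|3`). Coordinates follow the BED standard
#' (0-based half-open), which is also the package's internal convention.
#'
#' @param path BED file path.
#' @param assembly assembly label to attach.
#' @return an [exon_targets()] table sorted by chromosome and start.
#' @export
load_targets <- function(path, assembly = DEFAULT_ASSEMBLY) {
  bed <- read_bed(path, min_fields = 4)
  if (nrow(bed) == 0) {
    return(exon_targets(character(), integer(), character(), numeric(),
                        numeric(), assembly = assembly))
  }
  parts <- strsplit(bed$name, "|", fixed = TRUE)
  ok <- lengths(parts) == 2
  if (any(!ok)) {
    stop("target BED '", path, "': name field must be 'gene|exon_index' (",
         bed$name[!ok][1], ")")
  }
  gene <- vapply(parts, `[[`, "", 1)
  exon <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2)))
  if (anyNA(exon)) stop("target BED '", path, "': non-integer exon index")
  exon_targets(gene, exon, bed$chrom, bed$start, bed$stop, assembly = assembly)
}

# ---------------------------------------------------------------------------
# Probes

#' Construct a probe set
#'
#' @param probe_id unique identifiers.
#' @param chrom,start,stop probe placements (0-based half-open).
#' @param sequence optional DNA sequences (or `NA`).
#' @param tm_c melting temperatures in degrees Celsius.
#' @param source `"HD_library"` (scored library pick) or `"tiling"`.
#' @param error per-probe log2-ratio error sigma_i (> 0).
#' @param assembly assembly label.
#' @return data.frame of class `probe_set`, sorted by position.
#' @export
probe_set <- function(probe_id, chrom, start, stop, sequence = NA_character_,
                      tm_c = NA_real_, source = "HD_library", error = 0.2,
                      assembly = DEFAULT_ASSEMBLY) {
  if (length(probe_id) == 0) {
    df <- data.frame(chrom = character(), start = numeric(),
                     stop = numeric(), probe_id = character(),
                     sequence = character(), tm_c = numeric(),
                     source = character(), error = numeric(),
                     stringsAsFactors = FALSE)
    attr(df, "assembly") <- assembly
    class(df) <- c("probe_set", class(df))
    return(df)
  }
  df <- genomic_intervals(chrom, start, stop,
                          probe_id = as.character(probe_id),
                          sequence = as.character(sequence),
                          tm_c = as.numeric(tm_c),
                          source = as.character(source),
                          error = as.numeric(error),
                          assembly = assembly)
  if (nrow(df)) {
    if (anyDuplicated(df$probe_id)) stop("probe set: duplicated probe_id")
    if (!all(df$source %in% c("HD_library", "tiling"))) {
      stop("probe set: source must be 'HD_library' or 'tiling'")
    }
    if (any(!is.na(df$error) & df$error <= 0)) {
      stop("probe set: per-probe error must be > 0")
    }
  }
  df <- sort_by_position(df)
  rownames(df) <- NULL
  attr(df, "assembly") <- assembly
  class(df) <- c("probe_set", class(df))
  df
}

#' Write / read probes as TSV
#'
#' Columns: probe_id, chrom, start, stop (1-based inclusive), sequence,
#' tm_c, source, error.
#' @param probes a [probe_set()].
#' @param path output file.
#' @export
write_probes <- function(probes, path) {
  out <- data.frame(probe_id = probes$probe_id, chrom = probes$chrom,
                    start = probes$start + 1, stop = probes$stop,
                    sequence = probes$sequence, tm_c = probes$tm_c,
                    source = probes$source, error = probes$error)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_probes
#' @export
read_probes <- function(path, assembly = DEFAULT_ASSEMBLY) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  probe_set(x$probe_id, x$chrom, x$start - 1, x$stop, x$sequence,
            x$tm_c, x$source, x$error, assembly = assembly)
}
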