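# Nearest-neighbor DNA duplex melting temperature (unified parameter set,
# SantaLucia 1998), used to enforce the isothermal 80 degC probe spec.

# Enthalpy (kcal/mol) and entropy (cal/mol/K) per nearest-neighbor stack.
# Ten unique stacks; a dimer absent from the table is looked up via its
# reverse complement, which has identical thermodynamics in duplex DNA.
.NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
            CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
.NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
            CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)
# Duplex initiation with a terminal G.C vs terminal A.T pair.
.INIT_DH <- c(GC = 0.1, AT = 2.3)
.INIT_DS <- c(GC = -2.8, AT = 4.1)
.GAS_CONSTANT <- 1.9872  # cal/mol/K

#' @noRd
revcomp <- function(sequence) {
  chartr("ACGT", "TGCA",
         vapply(sequence, function(s)
           paste(rev(strsplit(s, "")[[1]]), collapse = ""), ""))
}

#' Nearest-neighbor melting temperature of a DNA oligo
#'
#' Two-state nearest-neighbor model with the unified thermodynamic
#' parameter set, duplex-initiation terms for the terminal base pairs, an
#' entropic salt correction of `0.368 (N-1) ln[Na+]`, and the
#' non-self-complementary total-strand-concentration term `R ln(Ct/4)`.
#' The ionic and oligo concentrations are fixed design constants carried in
#' the [design_config()] (defaults 0.1 M Na+ and 0.25 uM oligo) so that a
#' balanced 60-mer melts near the 80 degC isothermal design point.
#'
#' @param sequence DNA string over `A`, `C`, `G`, `T`; length >= 8.
#' @param config a [design_config()] supplying `na_molar` and
#'   `oligo_molar`.
#' @return melting temperature in degrees Celsius.
#' @export
melting_temperature <- function(sequence, config = design_config()) {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 8) stop("melting_temperature: sequence shorter than 8")
  bases <- strsplit(sequence, "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop("melting_temperature: ambiguous or non-ACGT base in sequence")
  }
  n <- length(bases)
  dimers <- paste0(bases[-n], bases[-1])
  miss <- !(dimers %in% names(.NN_DH))
  dimers[miss] <- revcomp(dimers[miss])
  dh <- sum(.NN_DH[dimers])
  ds <- sum(.NN_DS[dimers])
  ends <- ifelse(bases[c(1, n)] %in% c("G", "C"), "GC", "AT")
  dh <- dh + sum(.INIT_DH[ends])
  ds <- ds + sum(.INIT_DS[ends])
  ds <- ds + 0.368 * (n - 1) * log(config$na_molar)
  tm_k <- 1000 * dh / (ds + .GAS_CONSTANT * log(config$oligo_molar / 4))
  tm_k - 273.15
}
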