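# Nearest-neighbor melting temperature, Sugimoto et al. (1996) parameter
# set, with the salt and primer-concentration correction used by Oligo Calc:
#
#   Tm = dH*1000 / (dS + R*ln(C/x)) - 273.15 + 16.6*log10([Na+])
#
# dH (kcal/mol) and dS (cal/mol/K) are summed over dinucleotide stacks plus
# the initiation term; R = 1.987 cal/mol/K; x = 4 for non-self-complementary
# oligos and 1 for self-complementary ones. Tm is computed on the primer as
# synthesized annealed to a perfectly complementary strand, i.e. engineered
# mismatch thermodynamics are deliberately ignored (an approximation, noted
# in the vignette).

.NN_DH <- c(AA = -8.0, TT = -8.0, AT = -5.6, TA = -6.6,
            CA = -8.2, TG = -8.2, GT = -9.4, AC = -9.4,
            CT = -6.6, AG = -6.6, GA = -8.8, TC = -8.8,
            CG = -11.8, GC = -10.5, GG = -10.9, CC = -10.9)
.NN_DS <- c(AA = -21.9, TT = -21.9, AT = -15.2, TA = -18.4,
            CA = -21.0, TG = -21.0, GT = -25.5, AC = -25.5,
            CT = -16.4, AG = -16.4, GA = -23.5, TC = -23.5,
            CG = -29.0, GC = -26.4, GG = -28.4, CC = -28.4)
.NN_INIT_DH <- 0.6
.NN_INIT_DS <- -9.0
.GAS_CONSTANT <- 1.987

#' Melting-temperature parameters
#'
#' Defaults are Oligo Calc's: 50 nM primer, 50 mM Na+.
#'
#' @param primer_conc Primer concentration in mol/L (default `50e-9`).
#' @param na_conc Sodium ion concentration in mol/L (default `50e-3`).
#' @return A list of class `tm_parameters`.
#' @export
tm_parameters <- function(primer_conc = 50e-9, na_conc = 50e-3) {
  if (!is.numeric(primer_conc) || primer_conc <= 0 ||
      !is.numeric(na_conc) || na_conc <= 0) {
    stop_dcaps("invalid_tm_parameters", "concentrations must be strictly positive")
  }
  structure(list(primer_conc = primer_conc, na_conc = na_conc),
            class = "tm_parameters")
}

#' Nearest-neighbor melting temperature
#'
#' @param primer Concrete (non-degenerate) sequence, length >= 8.
#' @param params A [tm_parameters()] object.
#' @return Melting temperature in degrees Celsius.
#' @examples
#' melting_temperature("AGCGTAGCTAGCTAGCTAGC")
#' @export
melting_temperature <- function(primer, params = tm_parameters()) {
  primer <- normalize_sequence(primer)
  if (!is_concrete(primer)) {
    stop_dcaps("degenerate_base_in_primer",
               "primer contains degenerate bases; Tm requires a concrete sequence")
  }
  n <- nchar(primer)
  if (n < 8L) stop_dcaps("primer_too_short", "primer shorter than 8 nt (%d)", n)
  chars <- strsplit(primer, "", fixed = TRUE)[[1L]]
  stacks <- paste0(chars[-n], chars[-1L])
  dH <- .NN_INIT_DH + sum(.NN_DH[stacks])
  dS <- .NN_INIT_DS + sum(.NN_DS[stacks])
  x <- if (identical(primer, reverse_complement(primer))) 1 else 4
  dH * 1000 / (dS + .GAS_CONSTANT * log(params$primer_conc / x)) -
    273.15 + 16.6 * log10(params$na_conc)
}
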