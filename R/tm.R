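# Oligonucleotide melting temperature.
#
# Two estimators: the Wallace 2+4 rule (fast, concentration-free) and a
# nearest-neighbor duplex model using the unified DNA/DNA parameter set
# (enthalpy kcal/mol, entropy cal/mol/K per stacked dinucleotide, plus
# terminal-base initiation terms), with the standard entropic monovalent
# salt correction 0.368*(N-1)*ln[Na+] and a two-state duplex transition at
# oligo concentration CT (factor CT/4 for non-self-complementary strands).

# unified nearest-neighbor table; rows named by the 5'->3' top-strand step
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
# initiation with a terminal G.C / A.T pair
INIT_GC <- c(dh = 0.1, ds = -2.8)
INIT_AT <- c(dh = 2.3, ds = 4.1)
GAS_R <- 1.9872  # cal / mol / K

#' Primer melting temperature
#'
#' @param primer Primer sequence.
#' @param method `"nearest_neighbor"` (default): unified-parameter duplex
#'   model with salt and oligo-concentration terms. `"wallace"`: the
#'   2(A+T) + 4(G+C) rule.
#' @param Na Monovalent cation concentration, mol/L (default 0.05).
#' @param oligo_conc Total single-strand concentration, mol/L (default
#'   240e-9, i.e. 240 nM per primer in the reaction these features model).
#' @return Melting temperature in degrees Celsius.
#' @export
#' @examples
#' melting_temperature("ACGT", method = "wallace")  # 12
#' melting_temperature("AGCGTAGCTGATCGATTAGC")
melting_temperature <- function(primer,
                                method = c("nearest_neighbor", "wallace"),
                                Na = 0.05, oligo_conc = 240e-9) {
  if (length(method) == 1L && !method %in% c("nearest_neighbor", "wallace"))
    qe_stop(sprintf("unknown Tm method '%s'", method), "qe_config_error")
  method <- match.arg(method)
  primer <- dna_validate(primer, "primer")
  b <- strsplit(primer, "", fixed = TRUE)[[1]]
  n <- length(b)
  if (method == "wallace")
    return(2 * sum(b %in% c("A", "T")) + 4 * sum(b %in% c("G", "C")))
  if (n < 2L)
    qe_stop("nearest-neighbor Tm needs at least 2 nt", "qe_invalid_input")
  if (Na <= 0 || oligo_conc <= 0)
    qe_stop("Na and oligo_conc must be positive", "qe_config_error")
  steps <- paste0(b[-n], b[-1L])
  dh <- sum(NN_DH[steps])
  ds <- sum(NN_DS[steps])
  for (term in b[c(1L, n)]) {
    init <- if (term %in% c("G", "C")) INIT_GC else INIT_AT
    dh <- dh + init[["dh"]]
    ds <- ds + init[["ds"]]
  }
  ds <- ds + 0.368 * (n - 1) * log(Na)
  dh * 1000 / (ds + GAS_R * log(oligo_conc / 4)) - 273.15
}
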