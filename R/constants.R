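# Pinned physical constants. Everything m/z-related in the package derives from
# this one table so that masses are bit-reproducible across platforms.

#' Monoisotopic residue masses and mass-spectrometry constants
#'
#' Monoisotopic masses (Da) of the 20 canonical amino-acid residues, i.e. the
#' mass each residue contributes inside a peptide chain (water excluded).
#' These values, together with the proton and water masses below, are the only
#' mass constants used anywhere in the package.
#'
#' @return A named numeric vector over the 20 one-letter residue codes.
#' @examples
#' residue_masses()[["G"]]
#' @export
residue_masses <- function() {
  c(
    G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
    V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
    I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
    K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
    F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
  )
}

# proton mass (Da) used for charging; water for the peptide termini
PROTON_MASS <- 1.007276
WATER_MASS <- 18.010565

# carbamidomethylation of cysteine (iodoacetamide alkylation), the fixed
# modification assumed for all cysteines unless the caller overrides it
CARBAMIDOMETHYL <- c(C = 57.02146)

AMINO_ACIDS <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)
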