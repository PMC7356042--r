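# Monoisotopic peptide masses and precursor m/z. All arithmetic flows from the
# pinned residue-mass table in constants.R.

#' Monoisotopic mass of peptide sequences
#'
#' Neutral monoisotopic mass: the sum of residue masses plus one water, plus
#' any fixed modification deltas for residues present in the sequence.
#'
#' @param sequences Character vector of peptide sequences (canonical alphabet).
#' @param fixed_mods Named numeric vector mapping residue letters to mass
#'   deltas in Da. Default: carbamidomethylation of cysteine (+57.02146 Da).
#'   Deltas for residues absent from a peptide are ignored.
#' @return Numeric vector of masses in Da.
#' @examples
#' peptide_mass("GG") # 2 x glycine + water
#' @export
peptide_mass <- function(sequences, fixed_mods = carbamidomethyl()) {
  masses <- residue_masses()
  vapply(sequences, function(s) {
    res <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- setdiff(res, names(masses))
    if (length(bad) > 0L) {
      abort(paste0("non-canonical residue '", bad[1L], "' in peptide '", s, "'"))
    }
    m <- sum(masses[res]) + WATER_MASS
    if (length(fixed_mods) > 0L) {
      m <- m + sum(fixed_mods[res], na.rm = TRUE)
    }
    m
  }, numeric(1), USE.NAMES = FALSE)
}

#' The default fixed-modification set
#'
#' Carbamidomethylation of cysteine (+57.02146 Da), the universal fixed
#' modification after iodoacetamide alkylation. Variable modifications such as
#' oxidation (M, +15.994915) or phosphorylation (S/T, +79.966331) can be added
#' for mass computation but are excluded from default MRM planning, where
#' quantified peptides are assumed unmodified.
#'
#' @return Named numeric vector of residue mass deltas (Da).
#' @export
carbamidomethyl <- function() CARBAMIDOMETHYL

#' Compute precursor m/z for peptides
#'
#' Adds monoisotopic mass and precursor (Q1) m/z columns to a peptide table:
#' `mz = (mass + charge * 1.007276) / charge`.
#'
#' @param peptides A data frame with a `sequence` column (e.g. from
#'   [digest()]).
#' @param charge Precursor charge state (positive integer, default 2 — the
#'   typical charge of tryptic peptides in electrospray).
#' @param fixed_mods Named residue -> mass-delta map; see [peptide_mass()].
#' @return `peptides` with columns `charge`, `mass` (neutral monoisotopic, Da)
#'   and `mz` (Th) appended.
#' @examples
#' tibble::tibble(sequence = "GQNQPVLNITNK") |> precursor_mz(charge = 2)
#' @export
precursor_mz <- function(peptides, charge = 2, fixed_mods = carbamidomethyl()) {
  if (!is.numeric(charge) || length(charge) != 1L || charge < 1) {
    abort("`charge` must be a single integer >= 1")
  }
  charge <- as.integer(charge)
  peptides$charge <- charge
  peptides$mass <- peptide_mass(peptides$sequence, fixed_mods)
  peptides$mz <- (peptides$mass + charge * PROTON_MASS) / charge
  peptides
}

#' Recover the neutral mass from an m/z value
#'
#' @param mz m/z in Th.
#' @param charge Charge state.
#' @return Neutral monoisotopic mass in Da.
#' @export
neutral_mass <- function(mz, charge) {
  mz * charge - charge * PROTON_MASS
}

#' Write a peptide table to TSV
#'
#' Fixed column set (`protein_id`, `start`, `end`, `sequence`,
#' `missed_cleavages`, `tryptic_status`, `mass`, `charge`, `mz`), masses and
#' m/z printed with six decimal places.
#'
#' @param peptides Peptide table carrying the columns above.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(peptides, path) {
  cols <- c(
    "protein_id", "start", "end", "sequence", "missed_cleavages",
    "tryptic_status", "mass", "charge", "mz"
  )
  out <- peptides[, cols]
  out$mass <- sprintf("%.6f", out$mass)
  out$mz <- sprintf("%.6f", out$mz)
  readr::write_tsv(out, path)
  invisible(path)
}
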