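# In silico proteolysis. Trypsin cleaves C-terminally of K/R except before
# proline; the trypsin+LysC mix additionally cleaves after K even before P
# (LysC is proline-tolerant). Coordinates are 1-based inclusive throughout.

# positions p such that the bond after residue p is cleaved
cleavage_sites <- function(sequence, enzyme = c("trypsin", "trypsin_lysc")) {
  enzyme <- match.arg(enzyme)
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  if (n < 2L) {
    return(integer(0))
  }
  p <- seq_len(n - 1L)
  cut <- res[p] %in% c("K", "R") & res[p + 1L] != "P"
  if (enzyme == "trypsin_lysc") {
    cut <- cut | (res[p] == "K")
  }
  p[cut]
}

#' Digest proteins in silico
#'
#' Generates all fully tryptic peptides with up to `max_missed` missed
#' cleavages for every protein in the table. With `max_missed = 0` the
#' peptides tile each sequence without gaps or overlaps.
#'
#' @param proteins A protein table as returned by [read_fasta()] (columns
#'   `protein_id`, `sequence`).
#' @param enzyme `"trypsin"` (cleave after K/R, not before P) or
#'   `"trypsin_lysc"` (additionally cleave after K even before P, the standard
#'   behaviour of the trypsin/LysC mix).
#' @param max_missed Maximum number of internal missed cleavage sites
#'   (default 2, the usual database-search setting).
#' @return A tibble with one row per peptide: `protein_id`, `start`, `end`
#'   (1-based inclusive), `sequence`, `missed_cleavages`, `preceding_residue`
#'   and `following_residue` (`"-"` at the protein termini), and
#'   `tryptic_status` (always `"fully_tryptic"` for digest products).
#' @examples
#' prot <- tibble::tibble(protein_id = "toy", sequence = "AKAKPLR")
#' digest(prot, max_missed = 1)
#' @export
digest <- function(proteins, enzyme = c("trypsin", "trypsin_lysc"), max_missed = 2) {
  enzyme <- match.arg(enzyme)
  stopifnot(is.numeric(max_missed), max_missed >= 0)
  max_missed <- as.integer(max_missed)
  purrr::map2_dfr(proteins$protein_id, proteins$sequence, function(id, seq) {
    if (is.na(seq) || nchar(seq) == 0L) {
      abort(paste0("protein '", id, "' has an empty sequence"))
    }
    n <- nchar(seq)
    sites <- cleavage_sites(seq, enzyme)
    # peptide boundaries: starts follow a cleavage site (or the N-terminus),
    # ends sit on a cleavage site (or the C-terminus)
    bounds <- c(0L, sites, n)
    k <- length(bounds) - 1L
    idx <- purrr::map_dfr(seq_len(k), function(i) {
      j <- i:min(k, i + max_missed)
      tibble::tibble(start = bounds[i] + 1L, end = bounds[j + 1L], missed = j - i)
    })
    res <- strsplit(seq, "", fixed = TRUE)[[1]]
    tibble::tibble(
      protein_id = id,
      start = idx$start,
      end = idx$end,
      sequence = substring(seq, idx$start, idx$end),
      missed_cleavages = idx$missed,
      preceding_residue = ifelse(idx$start == 1L, "-", res[pmax(idx$start - 1L, 1L)]),
      following_residue = ifelse(idx$end == n, "-", res[pmin(idx$end + 1L, n)]),
      tryptic_status = "fully_tryptic"
    )
  })
}

# does a cleavage-conforming junction exist after position p (0 = N-terminus)?
conforming_junction <- function(res, p, enzyme) {
  n <- length(res)
  if (p == 0L || p == n) {
    return(TRUE)
  }
  ok <- res[p] %in% c("K", "R") & res[p + 1L] != "P"
  if (enzyme == "trypsin_lysc") {
    ok <- ok || res[p] == "K"
  }
  ok
}

#' Classify the tryptic status of peptide spans
#'
#' Labels each peptide `fully_tryptic` when both termini conform to the
#' cleavage rule (or coincide with the protein termini), `semi_tryptic` when
#' exactly one does, and `non_tryptic` otherwise. In a t-LiP experiment the
#' limited protease produces semi-tryptic termini, and only fully tryptic
#' peptides are carried into targeted quantification.
#'
#' @param peptides A data frame with columns `protein_id`, `start`, `end`.
#' @param proteins The protein table the spans refer to.
#' @inheritParams digest
#' @return `peptides` with a `tryptic_status` column (added or replaced).
#' @export
annotate_tryptic_status <- function(peptides, proteins,
                                    enzyme = c("trypsin", "trypsin_lysc")) {
  enzyme <- match.arg(enzyme)
  seqs <- setNames(proteins$sequence, proteins$protein_id)
  status <- purrr::pmap_chr(
    list(peptides$protein_id, peptides$start, peptides$end),
    function(id, s, e) {
      seq <- seqs[[id]]
      if (is.null(seq)) {
        abort(paste0("unknown protein '", id, "'"))
      }
      n <- nchar(seq)
      if (is.na(s) || is.na(e) || s < 1L || e > n || s > e) {
        abort(paste0(
          "peptide span [", s, ", ", e, "] out of range for protein '",
          id, "' (length ", n, ")"
        ))
      }
      res <- strsplit(seq, "", fixed = TRUE)[[1]]
      nt <- conforming_junction(res, s - 1L, enzyme)
      ct <- conforming_junction(res, e, enzyme)
      if (nt && ct) "fully_tryptic" else if (nt || ct) "semi_tryptic" else "non_tryptic"
    }
  )
  peptides$tryptic_status <- status
  peptides
}

#' Count internal missed cleavage sites of peptide spans
#'
#' @inheritParams annotate_tryptic_status
#' @return `peptides` with a `missed_cleavages` column (added or replaced).
#' @export
annotate_missed_cleavages <- function(peptides, proteins,
                                      enzyme = c("trypsin", "trypsin_lysc")) {
  enzyme <- match.arg(enzyme)
  seqs <- setNames(proteins$sequence, proteins$protein_id)
  peptides$missed_cleavages <- purrr::pmap_int(
    list(peptides$protein_id, peptides$start, peptides$end),
    function(id, s, e) {
      sites <- cleavage_sites(seqs[[id]], enzyme)
      sum(sites >= s & sites < e)
    }
  )
  peptides
}
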