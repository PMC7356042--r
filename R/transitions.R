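# Deterministic MRM method building. Spectral libraries report measured
# fragment intensities; here "intensity" is emulated by a fixed heuristic
# score so that a method built from sequence alone is fully reproducible.

default_planner_filters <- function() {
  list(
    length_range = c(7L, 25L),
    mz_range = c(300, 1250),
    max_missed = 0L,
    charge = 2L,
    k = 3L
  )
}

make_precursor_id <- function(peptides) {
  if (all(c("protein_id", "start", "end") %in% names(peptides))) {
    paste0(
      peptides$protein_id, "_", peptides$start, "-", peptides$end,
      "/", peptides$charge
    )
  } else {
    paste0(peptides$sequence, "/", peptides$charge)
  }
}

#' Enumerate b- and y-series fragment ions of precursors
#'
#' Generates all b and y ions at charge 1 (and additionally charge 2 when the
#' precursor charge is 3 or more). Fixed-modification deltas are carried into
#' every fragment containing the modified residue.
#'
#' @param precursors A peptide table with `sequence`, `charge`, `mass` and
#'   `mz` columns, e.g. from [precursor_mz()]. A `precursor_id` column is
#'   added if missing.
#' @param fixed_mods Residue -> mass-delta map; see [peptide_mass()].
#' @return A tibble with one row per fragment: the precursor identifier
#'   columns plus `series` ("b"/"y"), `ordinal`, `fragment_charge` and
#'   `fragment_mz`. Length-1 peptides yield no fragments.
#' @export
enumerate_fragments <- function(precursors, fixed_mods = carbamidomethyl()) {
  if (!"precursor_id" %in% names(precursors)) {
    precursors$precursor_id <- make_precursor_id(precursors)
  }
  masses <- residue_masses()
  purrr::pmap_dfr(
    precursors[, c("precursor_id", "sequence", "charge", "mz")],
    function(precursor_id, sequence, charge, mz) {
      res <- strsplit(sequence, "", fixed = TRUE)[[1]]
      n <- length(res)
      if (n < 2L) {
        return(tibble::tibble())
      }
      r <- unname(masses[res])
      if (length(fixed_mods) > 0L) {
        delta <- fixed_mods[res]
        delta[is.na(delta)] <- 0
        r <- r + unname(delta)
      }
      ord <- seq_len(n - 1L)
      b_neutral <- cumsum(r)[ord]
      y_neutral <- rev(cumsum(rev(r)))[ord + 1L] + WATER_MASS
      frag_charges <- if (charge >= 3L) c(1L, 2L) else 1L
      purrr::map_dfr(frag_charges, function(z) {
        tibble::tibble(
          precursor_id = precursor_id,
          sequence = sequence,
          charge = charge,
          precursor_mz = mz,
          series = rep(c("b", "y"), each = n - 1L),
          ordinal = c(ord, ord),
          fragment_charge = z,
          fragment_mz = (c(b_neutral, rev(y_neutral)) + z * PROTON_MASS) / z
        )
      })
    }
  )
}

# the deterministic intensity surrogate: favour y ions, fragments above the
# precursor m/z, and mid-sequence ordinals
transition_score <- function(series, fragment_mz, precursor_mz, ordinal, peptide_length) {
  2 * (series == "y") +
    1 * (fragment_mz > precursor_mz) +
    0.5 * (ordinal >= 3 & ordinal <= peptide_length - 2)
}

#' Rank fragment ions and keep the best k transitions per precursor
#'
#' Orders fragments by a deterministic intensity surrogate (see
#' [transition_score()]); ties break y before b, then higher ordinal, then
#' lower m/z, giving a total, reproducible ordering.
#'
#' @param fragments Fragment table from [enumerate_fragments()].
#' @param k Number of transitions to keep per precursor (default 3, the usual
#'   "three most intense daughter ions" convention).
#' @return The top-`k` fragments per precursor with `score` and `rank`
#'   columns. Precursors with fewer than `k` eligible fragments return all of
#'   them, flagged in the logical `underfilled` column (with a warning).
#' @export
rank_transitions <- function(fragments, k = 3) {
  stopifnot(k >= 1)
  if (nrow(fragments) == 0L) {
    abort("no fragments to rank")
  }
  ranked <- fragments |>
    dplyr::mutate(
      score = transition_score(
        .data$series, .data$fragment_mz, .data$precursor_mz,
        .data$ordinal, nchar(.data$sequence)
      )
    ) |>
    dplyr::arrange(
      .data$precursor_id, dplyr::desc(.data$score),
      .data$series != "y", dplyr::desc(.data$ordinal), .data$fragment_mz
    ) |>
    dplyr::group_by(.data$precursor_id) |>
    dplyr::mutate(rank = dplyr::row_number(), underfilled = dplyr::n() < k) |>
    dplyr::filter(.data$rank <= k) |>
    dplyr::ungroup()
  if (any(ranked$underfilled)) {
    warn(paste0(
      dplyr::n_distinct(ranked$precursor_id[ranked$underfilled]),
      " precursor(s) had fewer than ", k, " eligible fragments"
    ))
  }
  ranked
}

#' Build a deterministic MRM method from protein sequences
#'
#' Digests the proteins, keeps fully tryptic, unmodified peptides passing the
#' length and precursor m/z windows, and selects the `k` best fragment
#' transitions per precursor. This emulates, from sequence alone, the
#' spectral-library query step of targeted-method design; the result depends
#' only on the inputs and configuration, never on external databases.
#'
#' @param proteins Protein table from [read_fasta()].
#' @param enzyme,charge,fixed_mods See [digest()] and [precursor_mz()].
#' @param length_range Allowed peptide length (residues), default 7–25.
#' @param mz_range Allowed precursor m/z window, default 300–1250 Th.
#' @param max_missed Missed cleavages allowed in the method (default 0).
#' @param k Transitions per precursor (default 3).
#' @return An `mrm_method`: a tibble of transitions (one row per precursor ×
#'   transition) with the planner parameters in `attr(, "params")`. If no
#'   peptide passes the filters an empty method is returned with a warning.
#' @examples
#' fa <- system.file("extdata", "cps1_tlip.fasta", package = "lipmrm")
#' method <- build_method(read_fasta(fa))
#' glance(method)
#' @export
build_method <- function(proteins,
                         enzyme = c("trypsin", "trypsin_lysc"),
                         length_range = c(7, 25),
                         mz_range = c(300, 1250),
                         max_missed = 0,
                         charge = 2,
                         k = 3,
                         fixed_mods = carbamidomethyl()) {
  enzyme <- match.arg(enzyme)
  params <- list(
    enzyme = enzyme, length_range = length_range, mz_range = mz_range,
    max_missed = max_missed, charge = charge, k = k, fixed_mods = fixed_mods
  )
  peptides <- digest(proteins, enzyme = enzyme, max_missed = max_missed) |>
    dplyr::filter(
      nchar(.data$sequence) >= length_range[1],
      nchar(.data$sequence) <= length_range[2]
    ) |>
    precursor_mz(charge = charge, fixed_mods = fixed_mods) |>
    dplyr::filter(.data$mz >= mz_range[1], .data$mz <= mz_range[2])
  if (nrow(peptides) == 0L) {
    warn("no peptide passes the planner filters; returning an empty method")
    out <- tibble::tibble(
      precursor_id = character(), protein_id = character(),
      sequence = character(), start = integer(), end = integer(),
      charge = integer(), precursor_mz = numeric(), series = character(),
      ordinal = integer(), fragment_charge = integer(),
      fragment_mz = numeric(), score = numeric(), rank = integer(),
      underfilled = logical()
    )
    return(structure(out, class = c("mrm_method", class(out)), params = params))
  }
  peptides$precursor_id <- make_precursor_id(peptides)
  transitions <- peptides |>
    enumerate_fragments(fixed_mods = fixed_mods) |>
    rank_transitions(k = k) |>
    dplyr::left_join(
      peptides[, c("precursor_id", "protein_id", "start", "end")],
      by = "precursor_id"
    ) |>
    dplyr::arrange(.data$protein_id, .data$start, .data$end, .data$rank)
  structure(
    transitions,
    class = c("mrm_method", class(transitions)),
    params = params
  )
}

#' @method glance mrm_method
#' @export
glance.mrm_method <- function(x, ...) {
  p <- attr(x, "params")
  tibble::tibble(
    n_precursors = dplyr::n_distinct(x$precursor_id),
    n_transitions = nrow(x),
    k = p$k,
    enzyme = p$enzyme,
    charge = p$charge,
    length_min = p$length_range[1],
    length_max = p$length_range[2],
    mz_min = p$mz_range[1],
    mz_max = p$mz_range[2]
  )
}

#' @method tidy mrm_method
#' @export
tidy.mrm_method <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Export an MRM method as a vendor-neutral transition list
#'
#' Fixed column names (`protein_id`, `peptide_sequence`, `start`, `end`,
#' `precursor_charge`, `precursor_mz`, `fragment_series`, `fragment_ordinal`,
#' `fragment_charge`, `product_mz`, `rank`); m/z printed with six decimals so
#' repeated exports of the same method are byte-identical.
#'
#' @param method An `mrm_method` from [build_method()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transition_list <- function(method, path) {
  out <- tibble::tibble(
    protein_id = method$protein_id,
    peptide_sequence = method$sequence,
    start = method$start,
    end = method$end,
    precursor_charge = method$charge,
    precursor_mz = sprintf("%.6f", method$precursor_mz),
    fragment_series = method$series,
    fragment_ordinal = method$ordinal,
    fragment_charge = method$fragment_charge,
    product_mz = sprintf("%.6f", method$fragment_mz),
    rank = method$rank
  )
  readr::write_tsv(out, path)
  invisible(path)
}
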