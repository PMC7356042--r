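# DARTS protection scoring. Ligand binding shields a target from limited
# proteolysis, so its spectral-match count in a treated lane rises from the
# digested-control level back toward the undigested level. The protection
# percentage places the treated count on that control-to-undigested scale.

#' DARTS protection percentage
#'
#' `100 * (treated - control) / (undigested - control)`, computed from
#' spectral-match counts. 0% means no protection (treated equals the digested
#' control), 100% means complete protection (treated equals the undigested
#' lysate). Vectorised over its arguments.
#'
#' @param treated,control,undigested Non-negative spectral-match counts for
#'   the ligand-treated, vehicle-control and mock-digested samples.
#' @return A tibble with columns `protection_pct`, `denominator_invalid`
#'   (`TRUE` and `protection_pct = NA` when `undigested <= control`, where the
#'   scale is undefined) and `out_of_range` (`TRUE` when sampling noise pushes
#'   the value outside `[0, 100]`; the value is reported, not clamped).
#' @examples
#' protection_percentage(treated = 15, control = 10, undigested = 30) # 25%
#' @export
protection_percentage <- function(treated, control, undigested) {
  n <- max(length(treated), length(control), length(undigested))
  treated <- rep_len(treated, n)
  control <- rep_len(control, n)
  undigested <- rep_len(undigested, n)
  if (any(c(treated, control, undigested) < 0, na.rm = TRUE)) {
    abort("spectral-match counts must be non-negative")
  }
  denom <- undigested - control
  invalid <- !is.na(denom) & denom <= 0
  pct <- ifelse(invalid, NA_real_, 100 * (treated - control) / denom)
  tibble::tibble(
    protection_pct = pct,
    denominator_invalid = invalid,
    out_of_range = !invalid & !is.na(pct) & (pct < 0 | pct > 100)
  )
}

#' Nominate gel regions whose intensity rises with ligand concentration
#'
#' Scans a densitometric lane profile and returns the molecular-weight bins
#' whose intensity is non-decreasing from the control lane through the ordered
#' treatment lanes, with a total relative increase of at least `threshold` —
#' the numeric counterpart of cutting the bands that darken as ligand
#' concentration rises.
#'
#' @param profiles A data frame with a `mw_bin_kda` column and one intensity
#'   column per lane.
#' @param lanes Lane column names, control first then increasing
#'   concentrations, e.g. `c("CTRL", "PXA_1uM", "PXA_10uM", "PXA_100uM")`.
#' @param threshold Minimum total relative increase (last vs control lane),
#'   default 0.2 (20%). A bin rising from zero counts as nominated.
#' @return A tibble of nominated bins with their `total_increase`.
#' @export
nominate_bands <- function(profiles, lanes, threshold = 0.2) {
  missing_lanes <- setdiff(lanes, names(profiles))
  if (length(missing_lanes) > 0L) {
    abort(paste0("lane column(s) not found: ", paste(missing_lanes, collapse = ", ")))
  }
  mat <- as.matrix(profiles[, lanes])
  if (any(mat < 0, na.rm = TRUE)) {
    abort("lane intensities must be non-negative")
  }
  monotone <- apply(mat, 1L, function(x) all(diff(x) >= 0))
  first <- mat[, 1L]
  last <- mat[, length(lanes)]
  increase <- ifelse(first > 0, (last - first) / first, ifelse(last > 0, Inf, 0))
  keep <- monotone & increase >= threshold
  tibble::tibble(
    mw_bin_kda = profiles$mw_bin_kda[keep],
    total_increase = increase[keep]
  )
}

#' Rank proteins by DARTS protection
#'
#' Computes the protection percentage of every protein at every ligand
#' concentration and ranks putative targets: descending protection at the
#' highest concentration, proteins with an invalid denominator last, ties
#' broken by protein id. A `dose_consistent` flag marks proteins whose
#' protection is non-decreasing with concentration.
#'
#' @param counts A long count table with columns `protein_id`, `condition`,
#'   `count` (and optionally `band_mw_kda`, summed over per protein).
#'   `condition` must contain `"undigested"`, `"control"` and one level per
#'   treated concentration.
#' @param concentrations Character vector naming the treated condition levels
#'   in increasing concentration order, e.g. `c("1", "10", "100")`.
#' @param drop_out_of_range Exclude proteins whose protection falls outside
#'   `[0, 100]` at any concentration from the ranking (default `TRUE`; they
#'   are kept in the table, flagged, ranked last).
#' @return A `darts_ranking` tibble: `protein_id`, one `protection_<c>`
#'   column per concentration, `dose_consistent`, `denominator_invalid`,
#'   `out_of_range`, `rank`.
#' @export
rank_targets <- function(counts, concentrations, drop_out_of_range = TRUE) {
  needed <- c("undigested", "control", concentrations)
  missing_cond <- setdiff(needed, unique(counts$condition))
  if (length(missing_cond) > 0L) {
    abort(paste0("conditions missing from count table: ", paste(missing_cond, collapse = ", ")))
  }
  wide <- counts |>
    dplyr::group_by(.data$protein_id, .data$condition) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "count", values_fill = 0)

  prot <- purrr::map(concentrations, function(cc) {
    protection_percentage(wide[[cc]], wide$control, wide$undigested)
  })
  res <- tibble::tibble(protein_id = wide$protein_id)
  for (i in seq_along(concentrations)) {
    res[[paste0("protection_", concentrations[i])]] <- prot[[i]]$protection_pct
  }
  pmat <- sapply(prot, function(p) p$protection_pct)
  pmat <- matrix(pmat, nrow = nrow(res))
  res$dose_consistent <- apply(pmat, 1L, function(x) !anyNA(x) && all(diff(x) >= 0))
  res$denominator_invalid <- prot[[1L]]$denominator_invalid
  res$out_of_range <- Reduce(`|`, purrr::map(prot, "out_of_range"))

  top <- pmat[, length(concentrations)]
  excluded <- res$denominator_invalid | (drop_out_of_range & res$out_of_range)
  ord <- order(excluded, -ifelse(is.na(top), -Inf, top), res$protein_id)
  res <- res[ord, ]
  res$rank <- seq_len(nrow(res))
  structure(
    res,
    class = c("darts_ranking", class(res)),
    concentrations = concentrations
  )
}

#' @method glance darts_ranking
#' @export
glance.darts_ranking <- function(x, ...) {
  tibble::tibble(
    n_proteins = nrow(x),
    n_dose_consistent = sum(x$dose_consistent),
    n_invalid_denominator = sum(x$denominator_invalid),
    n_out_of_range = sum(x$out_of_range),
    top_target = x$protein_id[1L]
  )
}

#' @method tidy darts_ranking
#' @export
tidy.darts_ranking <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Read a DARTS spectral-match count table
#'
#' Expected columns: `protein_id`, optionally `band_mw_kda`, `condition`,
#' `count` (non-negative integers).
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_match_counts <- function(path) {
  counts <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("protein_id", "condition", "count") %in% names(counts)))
  if (any(counts$count < 0)) {
    abort("spectral-match counts must be non-negative")
  }
  counts
}

#' Read a gel-lane densitometry profile
#'
#' Expected columns: `mw_bin_kda`, then one intensity column per lane.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_lane_profiles <- function(path) {
  profiles <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot("mw_bin_kda" %in% names(profiles))
  profiles
}
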