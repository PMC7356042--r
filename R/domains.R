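# Peptide-to-domain mapping. Protected peptides are placed onto region
# annotations (domains, loops) and checked against active-site residue lists:
# a peptide containing at least one catalytic residue is classified
# orthosteric, the rest report region-level (allosteric-proximal) protection.

#' Read region annotations
#'
#' Expected columns: `protein_id`, `name`, `start`, `end`, `category`
#' (`"domain"` or `"loop"`). Coordinates are 1-based inclusive; regions may
#' abut or overlap.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_region_annotations <- function(path) {
  regions <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("protein_id", "name", "start", "end", "category") %in% names(regions)))
  if (any(regions$start > regions$end)) {
    abort("region start must not exceed end")
  }
  regions
}

#' Read an active-site residue list
#'
#' Expected columns: `protein_id`, `set_name`, `residue_letter`,
#' `residue_index`. When a protein table is supplied, every listed letter is
#' checked against the sequence at its index and any mismatch is a hard
#' error — this guards against residue-numbering drift between the annotation
#' and the sequence actually analysed.
#'
#' @param path TSV path.
#' @param proteins Optional protein table for letter-index validation.
#' @return A tibble.
#' @export
read_active_sites <- function(path, proteins = NULL) {
  sites <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("protein_id", "set_name", "residue_letter", "residue_index") %in% names(sites)))
  if (!is.null(proteins)) {
    validate_site_letters(sites, proteins)
  }
  sites
}

validate_site_letters <- function(sites, proteins) {
  seqs <- setNames(proteins$sequence, proteins$protein_id)
  for (i in seq_len(nrow(sites))) {
    seq <- seqs[[sites$protein_id[i]]]
    if (is.null(seq)) next
    idx <- sites$residue_index[i]
    if (idx < 1L || idx > nchar(seq)) {
      abort(paste0(
        "active-site residue ", sites$residue_letter[i], idx,
        " is outside protein '", sites$protein_id[i], "'"
      ))
    }
    actual <- substr(seq, idx, idx)
    if (actual != sites$residue_letter[i]) {
      abort(paste0(
        "active-site residue mismatch in '", sites$protein_id[i], "': annotation says ",
        sites$residue_letter[i], idx, " but the sequence has ", actual, idx,
        " (possible numbering drift)"
      ))
    }
  }
  invisible(sites)
}

#' Overlap peptide spans with region annotations
#'
#' A peptide maps to a region when the two spans share at least `min_overlap`
#' residues; the overlap length (residues) is reported.
#'
#' @param peptides Data frame with `protein_id`, `start`, `end`.
#' @param regions Region table as from [read_region_annotations()].
#' @param min_overlap Minimum shared residues (default 1).
#' @return A tibble with one row per (peptide, overlapped region):
#'   the peptide span, `region`, `category`, `region_start`, `region_end`,
#'   `overlap`.
#' @export
map_peptide_to_regions <- function(peptides, regions, min_overlap = 1) {
  dplyr::inner_join(
    dplyr::mutate(peptides, .pep = dplyr::row_number()),
    dplyr::rename(regions,
      region = "name", region_start = "start", region_end = "end"
    ),
    by = "protein_id", relationship = "many-to-many"
  ) |>
    dplyr::mutate(
      overlap = pmax(
        0L,
        pmin(.data$end, .data$region_end) - pmax(.data$start, .data$region_start) + 1L
      )
    ) |>
    dplyr::filter(.data$overlap >= min_overlap) |>
    dplyr::select(-".pep")
}

#' Classify peptides as orthosteric
#'
#' A peptide is orthosteric when its span contains at least one active-site
#' residue index; the residues hit are returned (e.g. `"T502;E503;R505"`).
#' Extending a span can only add hits, never remove them.
#'
#' @param peptides Data frame with `protein_id`, `start`, `end`.
#' @param sites Active-site table as from [read_active_sites()].
#' @param proteins Optional protein table; when given, site letters are
#'   validated against the sequences first.
#' @return `peptides` with `orthosteric` (logical), `n_site_residues` and
#'   `site_residues` columns appended.
#' @export
classify_orthosteric <- function(peptides, sites, proteins = NULL) {
  if (!is.null(proteins)) {
    validate_site_letters(sites, proteins)
  }
  hits <- purrr::pmap(
    list(peptides$protein_id, peptides$start, peptides$end),
    function(id, s, e) {
      hit <- sites[sites$protein_id == id &
        sites$residue_index >= s &
        sites$residue_index <= e, ]
      hit <- hit[order(hit$residue_index), ]
      paste0(hit$residue_letter, hit$residue_index)
    }
  )
  peptides$orthosteric <- lengths(hits) > 0L
  peptides$n_site_residues <- lengths(hits)
  peptides$site_residues <- purrr::map_chr(hits, paste, collapse = ";")
  peptides
}

#' Protection map: peptides against regions and active sites
#'
#' One report row per peptide: the regions it overlaps (collapsed,
#' `;`-separated, with overlap lengths), the active-site residues it
#' contains, and the orthosteric flag. The set of regions carrying at least
#' one protected peptide is available through [glance()].
#'
#' @param peptides Protected peptide spans (`protein_id`, `start`, `end`).
#' @param regions Region annotation table.
#' @param sites Active-site table (optional; omit for region mapping only).
#' @param proteins Optional protein table for site-letter validation.
#' @return A `mapping_report` tibble.
#' @export
protection_map_report <- function(peptides, regions, sites = NULL, proteins = NULL) {
  if (nrow(peptides) == 0L) {
    out <- tibble::tibble(
      protein_id = character(), start = integer(), end = integer(),
      regions = character(), overlaps = character(),
      orthosteric = logical(), site_residues = character()
    )
    return(structure(out, class = c("mapping_report", class(out)), region_summary = tibble::tibble(region = character(), n_peptides = integer())))
  }
  mapped <- map_peptide_to_regions(peptides, regions)
  collapsed <- mapped |>
    dplyr::group_by(.data$protein_id, .data$start, .data$end) |>
    dplyr::summarise(
      regions = paste(.data$region, collapse = ";"),
      overlaps = paste(.data$overlap, collapse = ";"),
      .groups = "drop"
    )
  out <- peptides |>
    dplyr::left_join(collapsed, by = c("protein_id", "start", "end")) |>
    dplyr::mutate(
      regions = dplyr::coalesce(.data$regions, ""),
      overlaps = dplyr::coalesce(.data$overlaps, "")
    )
  if (!is.null(sites)) {
    out <- classify_orthosteric(out, sites, proteins = proteins)
  }
  summary <- mapped |>
    dplyr::group_by(region = .data$region) |>
    dplyr::summarise(n_peptides = dplyr::n_distinct(paste(.data$protein_id, .data$start, .data$end)), .groups = "drop")
  structure(
    out,
    class = c("mapping_report", class(out)),
    region_summary = summary
  )
}

#' @method glance mapping_report
#' @export
glance.mapping_report <- function(x, ...) {
  s <- attr(x, "region_summary")
  tibble::tibble(
    n_peptides = nrow(x),
    n_orthosteric = if ("orthosteric" %in% names(x)) sum(x$orthosteric) else NA_integer_,
    protected_regions = paste(sort(s$region), collapse = ",")
  )
}

#' @method tidy mapping_report
#' @export
tidy.mapping_report <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Regions carrying at least one protected peptide
#'
#' @param report A `mapping_report` from [protection_map_report()].
#' @return A tibble with `region` and `n_peptides`.
#' @export
protected_regions <- function(report) {
  attr(report, "region_summary")
}
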