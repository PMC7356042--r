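# FASTA input/output. A deliberately small reader: unlike the usual parsers it
# reports the line number of the first malformed header or non-canonical
# residue, which matters when hand-edited sequence files enter the pipeline.

#' Read protein sequences from a FASTA file
#'
#' Parses a (multi-entry, wrapped or unwrapped) FASTA file into a protein
#' table. Residues must come from the 20-letter canonical amino-acid alphabet;
#' anything else (including B, J, O, U, X, Z) aborts with the offending line
#' number, so that ambiguity codes never silently enter mass calculations.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with one row per entry and columns `protein_id`,
#'   `description`, `sequence`, `length`. Residue coordinates used elsewhere in
#'   the package are 1-based positions into `sequence`.
#' @examples
#' fa <- system.file("extdata", "cps1_tlip.fasta", package = "lipmrm")
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    abort(paste0("FASTA file is empty: ", path))
  }
  is_header <- startsWith(lines, ">")
  if (!is_header[1L]) {
    abort(paste0(
      "line ", line_no[1L], ": expected a FASTA header ('>') but found sequence"
    ))
  }
  entry <- cumsum(is_header)
  headers <- lines[is_header]
  ids <- sub("^>\\s*(\\S+).*$", "\\1", headers)
  bad_header <- which(!grepl("^>\\S", headers))
  if (length(bad_header) > 0L) {
    abort(paste0(
      "line ", line_no[is_header][bad_header[1L]],
      ": malformed FASTA header (no identifier after '>')"
    ))
  }
  desc <- sub("^>\\s*\\S+\\s*", "", headers)

  seq_lines <- toupper(gsub("\\s", "", lines))
  ok <- is_header | grepl(paste0("^[", paste(AMINO_ACIDS, collapse = ""), "]+$"), seq_lines)
  if (any(!ok)) {
    first <- which(!ok)[1L]
    bad <- gsub(paste0("[", paste(AMINO_ACIDS, collapse = ""), "]"), "", seq_lines[first])
    abort(paste0(
      "line ", line_no[first], ": non-canonical residue(s) '",
      substr(bad, 1L, 5L), "' (only the 20 standard amino acids are accepted)"
    ))
  }

  sequences <- vapply(
    split(seq_lines[!is_header], entry[!is_header]),
    paste0, character(1), collapse = ""
  )
  # entries with no sequence lines at all
  missing <- setdiff(as.character(seq_len(length(headers))), names(sequences))
  if (length(missing) > 0L) {
    abort(paste0(
      "line ", line_no[is_header][as.integer(missing[1L])],
      ": FASTA entry has a header but no sequence"
    ))
  }
  sequences <- sequences[as.character(seq_len(length(headers)))]

  tibble::tibble(
    protein_id = ids,
    description = desc,
    sequence = unname(sequences),
    length = nchar(unname(sequences))
  )
}

#' Write a protein table to a FASTA file
#'
#' @param proteins A data frame with columns `protein_id`, `sequence` and
#'   optionally `description`.
#' @param path Output path.
#' @param width Line-wrap width for sequences (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60) {
  stopifnot(all(c("protein_id", "sequence") %in% names(proteins)))
  desc <- if ("description" %in% names(proteins)) proteins$description else ""
  header <- ifelse(
    is.na(desc) | desc == "",
    paste0(">", proteins$protein_id),
    paste0(">", proteins$protein_id, " ", desc)
  )
  chunks <- purrr::map2(header, proteins$sequence, function(h, s) {
    starts <- seq(1L, nchar(s), by = width)
    c(h, substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  })
  writeLines(unlist(chunks), path)
  invisible(path)
}
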