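# End-to-end orchestration: DARTS ranking -> candidate selection -> digest +
# MRM planning -> t-LiP quantification -> domain mapping, driven by a plain
# key = value configuration file so a whole run is auditable and repeatable.

pipeline_config_spec <- function() {
  list(
    fasta = list(type = "path", required = TRUE),
    darts_counts = list(type = "path", required = TRUE),
    lip_areas = list(type = "path", required = TRUE),
    lane_profiles = list(type = "path", required = FALSE),
    regions = list(type = "path", required = FALSE),
    active_sites = list(type = "path", required = FALSE),
    enzyme = list(type = "choice", choices = c("trypsin", "trypsin_lysc"), default = "trypsin"),
    max_missed = list(type = "int", default = 2L, min = 0),
    alpha = list(type = "num", default = 0.05, min = 0, max = 1, open = TRUE),
    transitions_per_precursor = list(type = "int", default = 3L, min = 1),
    charge = list(type = "int", default = 2L, min = 1),
    concentrations = list(type = "list", default = c("1", "10")),
    test_method = list(
      type = "choice",
      choices = c("student", "welch", "log_student", "log_welch"),
      default = "student"
    ),
    band_threshold = list(type = "num", default = 0.2, min = 0, max = Inf),
    lanes = list(type = "list", default = NULL),
    n_candidates = list(type = "int", default = 1L, min = 1),
    seed = list(type = "int", default = 1L, min = NA),
    out_dir = list(type = "string", default = "lipmrm_out")
  )
}

#' Validate a pipeline configuration file
#'
#' Reads a plain-text configuration in `key = value` form (one pair per line,
#' `#` comments and blank lines ignored) and returns a typed, defaulted
#' configuration. Unknown keys, duplicated keys (both line numbers reported),
#' out-of-range values and missing input files are all collected and reported
#' together.
#'
#' Recognised keys: `fasta`, `darts_counts`, `lip_areas` (required input
#' paths); `lane_profiles`, `regions`, `active_sites` (optional paths);
#' `enzyme`, `max_missed`, `alpha`, `transitions_per_precursor`, `charge`,
#' `concentrations` (comma-separated), `test_method`, `band_threshold`,
#' `lanes` (comma-separated, control lane first), `n_candidates`, `seed`,
#' `out_dir`.
#'
#' @param path Path to the configuration file.
#' @return A `pipeline_config` list.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path))
  }
  spec <- pipeline_config_spec()
  lines <- readLines(path, warn = FALSE)
  content <- sub("#.*$", "", lines)
  idx <- which(!grepl("^\\s*$", content))
  errors <- character()
  seen <- list()
  for (i in idx) {
    ln <- content[i]
    if (!grepl("=", ln, fixed = TRUE)) {
      errors <- c(errors, paste0("line ", i, ": expected 'key = value', got '", trimws(lines[i]), "'"))
      next
    }
    key <- trimws(sub("=.*$", "", ln))
    value <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(spec)) {
      errors <- c(errors, paste0("line ", i, ": unknown key '", key, "'"))
      next
    }
    if (!is.null(seen[[key]])) {
      errors <- c(errors, paste0(
        "duplicated key '", key, "' (lines ", seen[[key]]$line, " and ", i, ")"
      ))
      next
    }
    seen[[key]] <- list(line = i, value = value)
  }

  config <- purrr::imap(spec, function(s, key) {
    if (is.null(seen[[key]])) {
      if (isTRUE(s$required)) {
        errors <<- c(errors, paste0("missing required key '", key, "'"))
      }
      return(s$default)
    }
    raw <- seen[[key]]$value
    line <- seen[[key]]$line
    switch(s$type,
      path = {
        if (!file.exists(raw)) {
          errors <<- c(errors, paste0("line ", line, ": file for '", key, "' not found: ", raw))
        }
        raw
      },
      string = raw,
      list = trimws(strsplit(raw, ",", fixed = TRUE)[[1]]),
      choice = {
        if (!raw %in% s$choices) {
          errors <<- c(errors, paste0(
            "line ", line, ": '", key, "' must be one of ",
            paste(s$choices, collapse = ", ")
          ))
        }
        raw
      },
      int = ,
      num = {
        v <- suppressWarnings(as.numeric(raw))
        if (is.na(v)) {
          errors <<- c(errors, paste0("line ", line, ": '", key, "' must be numeric, got '", raw, "'"))
          return(s$default)
        }
        lo <- s$min
        hi <- if (is.null(s$max)) Inf else s$max
        open <- isTRUE(s$open)
        if (!is.na(lo)) {
          bad <- if (open) (v <= lo || v >= hi) else (v < lo || v > hi)
          if (bad) {
            errors <<- c(errors, paste0(
              "line ", line, ": '", key, "' = ", raw, " out of range ",
              if (open) "(" else "[", lo, ", ", hi, if (open) ")" else "]"
            ))
          }
        }
        if (s$type == "int") as.integer(v) else v
      }
    )
  })
  if (length(errors) > 0L) {
    abort(paste0(
      "invalid pipeline configuration:\n",
      paste0("  - ", errors, collapse = "\n")
    ))
  }
  structure(config, class = "pipeline_config")
}

run_stage <- function(name, code) {
  message("[lipmrm] stage ", name)
  tryCatch(code, error = function(e) {
    abort(paste0("stage ", name, ": ", conditionMessage(e)), parent = e)
  })
}

#' Run the full target-deconvolution pipeline
#'
#' Executes DARTS ranking, band nomination (when lane profiles are given),
#' digestion and MRM planning for the candidate target(s), t-LiP
#' quantification with the dual-concentration protection rule, and domain
#' mapping (when annotations are given). All stage tables are written as TSV
#' under `out_dir`, together with a human-readable `summary.txt`; a run with
#' the same configuration and inputs reproduces the same bytes.
#'
#' @param config A `pipeline_config` from [validate_config()], or the path to
#'   a configuration file.
#' @param out_dir Output directory; overrides the configured one.
#' @return Invisibly, a list with `darts`, `bands`, `method`, `lip`,
#'   `protected`, `mapping`, `candidates`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    config <- validate_config(config)
  }
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- out_dir %||% config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  message(
    "[lipmrm] enzyme=", config$enzyme, " max_missed=", config$max_missed,
    " alpha=", config$alpha, " k=", config$transitions_per_precursor,
    " concentrations=", paste(config$concentrations, collapse = ",")
  )

  proteins <- run_stage("read_fasta", read_fasta(config$fasta))

  darts <- run_stage("darts_scoring", {
    counts <- read_match_counts(config$darts_counts)
    treated <- setdiff(unique(counts$condition), c("undigested", "control"))
    treated <- treated[order(suppressWarnings(as.numeric(treated)))]
    rank_targets(counts, treated)
  })
  readr::write_tsv(format_num(tibble::as_tibble(darts)), file.path(out_dir, "darts_ranking.tsv"))

  bands <- NULL
  if (!is.null(config$lane_profiles)) {
    bands <- run_stage("band_nomination", {
      profiles <- read_lane_profiles(config$lane_profiles)
      lanes <- config$lanes %||% setdiff(names(profiles), "mw_bin_kda")
      nominate_bands(profiles, lanes, threshold = config$band_threshold)
    })
    readr::write_tsv(format_num(bands), file.path(out_dir, "nominated_bands.tsv"))
  }

  candidates <- head(darts$protein_id[!darts$denominator_invalid], config$n_candidates)

  method <- run_stage("transition_planner", {
    build_method(
      proteins[proteins$protein_id %in% candidates, , drop = FALSE],
      enzyme = config$enzyme,
      charge = config$charge,
      k = config$transitions_per_precursor
    )
  })
  write_transition_list(method, file.path(out_dir, "transition_list.tsv"))

  lip <- run_stage("lip_quant", {
    areas <- read_area_matrix(config$lip_areas)
    lip_quantify(
      areas, config$concentrations,
      alpha = config$alpha, method = config$test_method
    )
  })
  readr::write_tsv(format_num(tibble::as_tibble(lip)), file.path(out_dir, "lip_stats.tsv"))
  protected <- select_protected(lip, alpha = config$alpha)
  readr::write_tsv(format_num(tibble::as_tibble(protected)), file.path(out_dir, "protected_peptides.tsv"))

  mapping <- NULL
  if (!is.null(config$regions) && all(c("protein_id", "start", "end") %in% names(protected))) {
    mapping <- run_stage("domain_mapping", {
      regions <- read_region_annotations(config$regions)
      sites <- if (!is.null(config$active_sites)) {
        read_active_sites(config$active_sites, proteins = proteins)
      }
      protection_map_report(
        tibble::as_tibble(protected)[, c("protein_id", "start", "end", "peptide")],
        regions, sites,
        proteins = proteins
      )
    })
    readr::write_tsv(tibble::as_tibble(mapping), file.path(out_dir, "protection_map.tsv"))
  }

  summary_lines <- c(
    "lipmrm pipeline summary",
    "=======================",
    "",
    "Candidate targets (DARTS ranking):",
    sprintf(
      "  %d. %s%s", seq_len(min(5L, nrow(darts))),
      darts$protein_id[seq_len(min(5L, nrow(darts)))],
      ifelse(darts$dose_consistent[seq_len(min(5L, nrow(darts)))], " (dose-consistent)", "")
    ),
    "",
    sprintf("Planned precursors: %d", dplyr::n_distinct(method$precursor_id)),
    sprintf(
      "Protected peptides (fc > 1 and p < %s at all concentrations): %d / %d",
      format(config$alpha), nrow(protected), nrow(lip)
    )
  )
  if (!is.null(mapping)) {
    rs <- protected_regions(mapping)
    summary_lines <- c(
      summary_lines,
      sprintf(
        "Regions with protected peptides: %s",
        if (nrow(rs) > 0) paste(sort(rs$region), collapse = ", ") else "(none)"
      )
    )
    if ("orthosteric" %in% names(mapping)) {
      summary_lines <- c(
        summary_lines,
        sprintf("Orthosteric peptides (contain active-site residues): %d", sum(mapping$orthosteric))
      )
    }
  }
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))

  invisible(list(
    darts = darts, bands = bands, method = method, lip = lip,
    protected = protected, mapping = mapping, candidates = candidates
  ))
}

# stable numeric formatting so repeated runs are byte-identical
format_num <- function(df) {
  dplyr::mutate(df, dplyr::across(
    dplyr::where(is.double),
    ~ ifelse(is.na(.x), NA_character_, sprintf("%.6g", .x))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
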