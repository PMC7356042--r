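# t-LiP-MRM quantification: replicate peak areas -> per-concentration fold
# changes and p-values -> dual-concentration protection calls. A peptide is
# called protected only when its area rises (fold change > 1) significantly
# (p < alpha) at EVERY tested ligand concentration.

#' Fold change of mean peak areas
#'
#' Ratio of the mean treated area to the mean control area.
#'
#' @param treated_areas,control_areas Positive replicate peak-area vectors.
#' @return A single ratio.
#' @examples
#' fold_change(c(200, 220, 180), c(100, 110, 90)) # 2
#' @export
fold_change <- function(treated_areas, control_areas) {
  if (length(treated_areas) == 0L || length(control_areas) == 0L) {
    abort("replicate area vectors must be non-empty")
  }
  if (any(treated_areas <= 0) || any(control_areas <= 0)) {
    abort("peak areas must be strictly positive")
  }
  mean(treated_areas) / mean(control_areas)
}

#' Two-sample test on replicate peak areas
#'
#' Two-sided two-sample t-test of treated versus control areas. The default
#' is the equal-variance Student test on raw areas; Welch and log-area
#' variants are available. Degenerate inputs follow the conventions p = 1
#' when both groups are constant and equal, p = 0 (with a warning) when both
#' are constant but different.
#'
#' @inheritParams fold_change
#' @param method `"student"` (default), `"welch"`, `"log_student"` or
#'   `"log_welch"`.
#' @return A two-sided p-value.
#' @export
test_difference <- function(treated_areas, control_areas,
                            method = c("student", "welch", "log_student", "log_welch")) {
  method <- match.arg(method)
  if (length(treated_areas) < 2L || length(control_areas) < 2L) {
    abort("at least two replicates per group are required")
  }
  if (any(treated_areas <= 0) || any(control_areas <= 0)) {
    abort("peak areas must be strictly positive")
  }
  x <- treated_areas
  y <- control_areas
  if (startsWith(method, "log")) {
    x <- log(x)
    y <- log(y)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      return(1)
    }
    warn("zero variance in both groups with different means; returning p = 0")
    return(0)
  }
  t.test(x, y, var.equal = method %in% c("student", "log_student"))$p.value
}

# vectorised two-sided two-sample t p-value from group moments; degenerate
# zero-variance cases follow the test_difference() conventions
two_sample_p <- function(m1, v1, n1, m2, v2, n2, equal_var = TRUE) {
  if (equal_var) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  p <- 2 * stats::pt(-abs((m1 - m2) / se), df)
  degenerate <- v1 == 0 & v2 == 0
  ifelse(degenerate, ifelse(abs(m1 - m2) < 1e-12 * pmax(abs(m1), 1), 1, 0), p)
}

#' Per-peptide fold changes and p-values across concentrations
#'
#' Summarises a long replicate area table into one row per precursor with a
#' fold change and p-value per ligand concentration, plus the protection call
#' (`fold change > 1` and `p < alpha` at all concentrations).
#'
#' @param areas Long table with columns `precursor_id`, `condition`,
#'   `replicate`, `area` (plus any precursor annotation columns such as
#'   `peptide`, `start`, `end`, `charge`, `q1_mz`, carried through).
#' @param concentrations Treated condition levels, e.g. `c("1", "10")`.
#' @param control Name of the shared vehicle-control condition
#'   (default `"control"`); fold changes at every concentration are taken
#'   against this one control.
#' @param alpha Significance level for the protection call (default 0.05).
#' @param method Test variant, see [test_difference()].
#' @return A `lip_stats` tibble: annotation columns, `fc_<c>` and `p_<c>` per
#'   concentration, and `protected`.
#' @export
lip_quantify <- function(areas, concentrations, control = "control",
                         alpha = 0.05, method = "student") {
  needed <- c(control, concentrations)
  missing_cond <- setdiff(needed, unique(areas$condition))
  if (length(missing_cond) > 0L) {
    abort(paste0("conditions missing from area table: ", paste(missing_cond, collapse = ", ")))
  }
  anno_cols <- intersect(
    c("precursor_id", "protein_id", "peptide", "start", "end", "charge", "q1_mz", "rt"),
    names(areas)
  )
  anno <- dplyr::distinct(areas[, anno_cols])
  if (anyDuplicated(anno$precursor_id) > 0L) {
    abort("inconsistent annotation columns within a precursor_id")
  }
  if (any(areas$area <= 0)) {
    abort("peak areas must be strictly positive")
  }
  # vectorised over all precursors at once: per-group moments, then the
  # two-sample t computed in closed form (test_difference() is the scalar
  # reference implementation; the two agree and are tested against each other)
  on_log <- startsWith(method, "log")
  equal_var <- method %in% c("student", "log_student")
  moments <- areas |>
    dplyr::group_by(.data$precursor_id, .data$condition) |>
    dplyr::summarise(
      n = dplyr::n(),
      m_raw = mean(.data$area),
      m = if (on_log) mean(log(.data$area)) else mean(.data$area),
      v = if (on_log) stats::var(log(.data$area)) else stats::var(.data$area),
      .groups = "drop"
    )
  expected <- tidyr::expand_grid(
    precursor_id = anno$precursor_id, condition = needed
  )
  missing_entry <- dplyr::anti_join(expected, moments, by = c("precursor_id", "condition"))
  if (nrow(missing_entry) > 0L) {
    abort(paste0(
      "missing condition '", missing_entry$condition[1L], "' for precursor '",
      missing_entry$precursor_id[1L], "'"
    ))
  }
  if (any(moments$n < 2L)) {
    abort("at least two replicates per condition are required")
  }
  ctrl <- moments[moments$condition == control, ]
  rows <- tibble::tibble(precursor_id = ctrl$precursor_id)
  for (cc in concentrations) {
    trt <- moments[moments$condition == cc, ]
    stopifnot(identical(trt$precursor_id, ctrl$precursor_id))
    rows[[paste0("fc_", cc)]] <- trt$m_raw / ctrl$m_raw
    rows[[paste0("p_", cc)]] <- two_sample_p(
      trt$m, trt$v, trt$n, ctrl$m, ctrl$v, ctrl$n,
      equal_var = equal_var
    )
  }
  fc_cols <- paste0("fc_", concentrations)
  p_cols <- paste0("p_", concentrations)
  rows$protected <-
    rowSums(as.matrix(rows[, fc_cols, drop = FALSE]) > 1) == length(concentrations) &
    rowSums(as.matrix(rows[, p_cols, drop = FALSE]) < alpha) == length(concentrations)
  res <- dplyr::left_join(anno, rows, by = "precursor_id") |>
    dplyr::arrange(dplyr::across(dplyr::any_of(c("protein_id", "start", "end"))))
  structure(
    res,
    class = c("lip_stats", class(res)),
    concentrations = concentrations,
    alpha = alpha,
    method = method
  )
}

#' Keep peptides protected at every concentration
#'
#' Applies the dual-concentration rule: fold change above 1 and p below
#' `alpha` at all tested concentrations.
#'
#' @param stats A `lip_stats` table from [lip_quantify()], or any data frame
#'   with `fc_<c>` and `p_<c>` columns.
#' @param alpha Significance level (default 0.05).
#' @param concentrations Concentration levels; defaults to those recorded on
#'   `stats`.
#' @return The protected subset, with `protected` recomputed at `alpha`.
#' @export
select_protected <- function(stats, alpha = 0.05, concentrations = NULL) {
  if (is.null(concentrations)) {
    concentrations <- attr(stats, "concentrations")
  }
  if (is.null(concentrations)) {
    abort("`concentrations` must be supplied when `stats` does not record them")
  }
  fc_cols <- paste0("fc_", concentrations)
  p_cols <- paste0("p_", concentrations)
  missing_cols <- setdiff(c(fc_cols, p_cols), names(stats))
  if (length(missing_cols) > 0L) {
    abort(paste0("missing per-concentration columns: ", paste(missing_cols, collapse = ", ")))
  }
  keep <-
    rowSums(as.matrix(stats[, fc_cols, drop = FALSE]) > 1) == length(concentrations) &
    rowSums(as.matrix(stats[, p_cols, drop = FALSE]) < alpha) == length(concentrations)
  out <- stats[keep, , drop = FALSE]
  out$protected <- rep(TRUE, nrow(out))
  out
}

#' @method glance lip_stats
#' @export
glance.lip_stats <- function(x, ...) {
  tibble::tibble(
    n_precursors = nrow(x),
    n_protected = sum(x$protected),
    alpha = attr(x, "alpha"),
    method = attr(x, "method"),
    concentrations = paste(attr(x, "concentrations"), collapse = ",")
  )
}

#' @method tidy lip_stats
#' @export
tidy.lip_stats <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Read a long replicate peak-area table
#'
#' Expected columns: `precursor_id`, `condition`, `replicate`, `area`
#' (positive), plus optional precursor annotations (`peptide`, `start`,
#' `end`, `charge`, `q1_mz`).
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_area_matrix <- function(path) {
  areas <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("precursor_id", "condition", "replicate", "area") %in% names(areas)))
  if (any(areas$area <= 0)) {
    abort("peak areas must be strictly positive")
  }
  areas
}

#' Write a per-peptide statistics table
#'
#' @param stats A `lip_stats` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lip_stats <- function(stats, path) {
  readr::write_tsv(tibble::as_tibble(stats), path)
  invisible(path)
}
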