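# ggplot2 displays for the main result types.

#' @method autoplot darts_ranking
#' @export
autoplot.darts_ranking <- function(object, ...) {
  concs <- attr(object, "concentrations")
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(
      dplyr::all_of(paste0("protection_", concs)),
      names_to = "concentration", values_to = "protection_pct",
      names_prefix = "protection_"
    ) |>
    dplyr::mutate(concentration = factor(.data$concentration, levels = concs))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$concentration, y = .data$protection_pct,
    group = .data$protein_id, colour = .data$protein_id
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "ligand concentration", y = "protection (%)",
      colour = "protein",
      title = "DARTS protection by concentration"
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot lip_stats
#' @export
autoplot.lip_stats <- function(object, ...) {
  concs <- attr(object, "concentrations")
  alpha <- attr(object, "alpha") %||% 0.05
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(
      dplyr::all_of(paste0("fc_", concs)),
      names_to = "concentration", values_to = "fc", names_prefix = "fc_"
    ) |>
    tidyr::pivot_longer(
      dplyr::all_of(paste0("p_", concs)),
      names_to = "p_conc", values_to = "p", names_prefix = "p_"
    ) |>
    dplyr::filter(.data$concentration == .data$p_conc)
  ggplot2::ggplot(long, ggplot2::aes(
    x = log2(.data$fc), y = -log10(.data$p), colour = .data$protected
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~concentration, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = "log2 fold change (treated / control)", y = "-log10 p",
      colour = "protected",
      title = "t-LiP peptide protection"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a protection map along the protein sequence
#'
#' Region annotations as a backbone track with protected peptide spans drawn
#' above it; orthosteric peptides (containing active-site residues) are
#' highlighted when the report carries the classification.
#'
#' @param report A `mapping_report` from [protection_map_report()].
#' @param regions The region annotation table used for the report.
#' @return A ggplot object.
#' @export
plot_protection_map <- function(report, regions) {
  pep <- tibble::as_tibble(report)
  pep$y <- 1 + (seq_len(nrow(pep)) %% 3) * 0.15
  has_ortho <- "orthosteric" %in% names(pep)
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = regions,
      ggplot2::aes(x = .data$start, xend = .data$end, y = 0.5, yend = 0.5, colour = .data$name),
      linewidth = 4
    ) +
    ggplot2::geom_segment(
      data = pep,
      if (has_ortho) {
        ggplot2::aes(x = .data$start, xend = .data$end, y = .data$y, yend = .data$y, linetype = .data$orthosteric)
      } else {
        ggplot2::aes(x = .data$start, xend = .data$end, y = .data$y, yend = .data$y)
      },
      linewidth = 2
    ) +
    ggplot2::scale_y_continuous(limits = c(0, 2), breaks = NULL) +
    ggplot2::labs(
      x = "residue position", y = NULL, colour = "region",
      linetype = if (has_ortho) "orthosteric" else NULL,
      title = "Protected peptides mapped onto protein regions"
    ) +
    ggplot2::theme_minimal()
  p
}

#' Plot gel-lane densitometry profiles
#'
#' @param profiles Wide lane-profile table (`mw_bin_kda` + lane columns).
#' @param lanes Lane column names, control first.
#' @return A ggplot object.
#' @export
plot_lane_profiles <- function(profiles, lanes) {
  long <- tidyr::pivot_longer(
    profiles, dplyr::all_of(lanes),
    names_to = "lane", values_to = "intensity"
  ) |>
    dplyr::mutate(lane = factor(.data$lane, levels = lanes))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$mw_bin_kda, y = .data$intensity, colour = .data$lane
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "molecular weight (kDa)", y = "densitometric intensity",
      title = "Lane profiles by ligand concentration"
    ) +
    ggplot2::theme_minimal()
}
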