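# Synthetic-data generation with planted ground truth. The generator emulates
# the study design of a DARTS + t-LiP-MRM campaign: three replicates, two
# ligand concentrations for targeted quantification (1 and 10 uM) and three
# for DARTS (1/10/100 uM), multiplicative protection of a planted peptide
# set, log-normal area noise, and Poisson spectral counts bounded between the
# digested-control and undigested levels. Ligand occupancy follows a
# single-site binding curve occ(c) = c / (c + K_D).

with_sim_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  withr::with_seed(
    seed, code,
    .rng_kind = "Mersenne-Twister",
    .rng_normal_kind = "Inversion",
    .rng_sample_kind = "Rejection"
  )
}

occupancy <- function(concentration, kd) {
  concentration / (concentration + kd)
}

#' Simulate a protein sequence with region annotations
#'
#' Draws a random sequence whose combined K+R frequency is `kr_freq`
#' (default 0.11, the approximate proteome-wide value), so tryptic peptides
#' have realistic lengths, and tiles it into `n_regions` contiguous,
#' equally-sized named regions.
#'
#' @param length Sequence length in residues (minimum 50).
#' @param n_regions Number of tiled region annotations (default 5).
#' @param kr_freq Combined frequency of K and R (default 0.11).
#' @param protein_id Identifier for the generated protein.
#' @param seed Optional integer seed; the same seed and parameters always
#'   reproduce the same sequence.
#' @return A list with `proteins` (one-row tibble) and `regions` (tibble of
#'   `protein_id`, `name`, `start`, `end`, `category`).
#' @export
simulate_protein <- function(length = 500, n_regions = 5, kr_freq = 0.11,
                             protein_id = "SIM1", seed = NULL) {
  if (length < 50) {
    abort("simulated proteins must be at least 50 residues long")
  }
  stopifnot(kr_freq > 0, kr_freq < 1, n_regions >= 1)
  others <- setdiff(AMINO_ACIDS, c("K", "R"))
  probs <- setNames(rep((1 - kr_freq) / length(others), length(others)), others)
  probs <- c(probs, K = kr_freq / 2, R = kr_freq / 2)
  seq <- with_sim_seed(seed, {
    paste(sample(names(probs), length, replace = TRUE, prob = probs), collapse = "")
  })
  bounds <- floor(seq(0, length, length.out = n_regions + 1))
  regions <- tibble::tibble(
    protein_id = protein_id,
    name = paste0("R", seq_len(n_regions)),
    start = as.integer(bounds[-(n_regions + 1)] + 1),
    end = as.integer(bounds[-1]),
    category = "domain"
  )
  list(
    proteins = tibble::tibble(
      protein_id = protein_id,
      description = "synthetic protein",
      sequence = seq,
      length = nchar(seq)
    ),
    regions = regions
  )
}

#' Simulate replicate t-LiP peak areas with planted protection
#'
#' Each precursor gets a control expected area drawn log-uniformly from
#' `area_range`. For planted (ligand-protected) precursors the treated
#' expected area at concentration c is `A * (1 + (phi - 1) * occ(c))` with
#' `occ(c) = c / (c + kd)`; unprotected precursors keep `A`. Observed areas
#' multiply the expectation by `exp(e)`, `e ~ Normal(0, sigma_log)`.
#'
#' @param peptides Precursor table with a `precursor_id` column (e.g. an
#'   [build_method()] precursor set or any digest with ids).
#' @param protected_ids Precursor ids carrying planted protection.
#' @param phi Planted fold factor at full occupancy (> 0, default 2).
#' @param kd Dissociation constant in concentration units (default 0.1, so
#'   occupancy is near-saturated at 1 uM as in a sub-micromolar binder).
#' @param sigma_log Log-scale noise sd (default 0.15, a typical MRM area CV).
#' @param n_replicates Replicates per condition (default 3, minimum 2).
#' @param concentrations Numeric treated concentrations (default `c(1, 10)`).
#' @param area_range Control-area range, log-uniform (default 1e4–1e7).
#' @param seed Optional integer seed.
#' @return A long tibble: precursor annotations, `condition` (`"control"` or
#'   the concentration as character), `replicate`, `area`, and the planted
#'   truth columns `planted` and `true_fc_<c>`.
#' @export
simulate_lip_areas <- function(peptides, protected_ids = character(),
                               phi = 2, kd = 0.1, sigma_log = 0.15,
                               n_replicates = 3, concentrations = c(1, 10),
                               area_range = c(1e4, 1e7), seed = NULL) {
  if (phi <= 0) abort("`phi` must be > 0")
  if (sigma_log < 0) abort("`sigma_log` must be >= 0")
  if (n_replicates < 2) abort("`n_replicates` must be >= 2")
  if (kd <= 0) abort("`kd` must be > 0")
  if (!"precursor_id" %in% names(peptides)) {
    peptides$precursor_id <- make_precursor_id(peptides)
  }
  anno_cols <- intersect(
    c("precursor_id", "protein_id", "peptide", "sequence", "start", "end", "charge", "mz"),
    names(peptides)
  )
  anno <- dplyr::distinct(peptides[, anno_cols])
  if ("sequence" %in% names(anno) && !"peptide" %in% names(anno)) {
    anno <- dplyr::rename(anno, peptide = "sequence")
  }
  if ("mz" %in% names(anno) && !"q1_mz" %in% names(anno)) {
    anno <- dplyr::rename(anno, q1_mz = "mz")
  }
  n <- nrow(anno)
  planted <- anno$precursor_id %in% protected_ids
  conditions <- c("control", as.character(concentrations))
  fold <- matrix(1, nrow = length(conditions), ncol = n)
  for (j in seq_along(concentrations)) {
    fold[j + 1L, ] <- ifelse(
      planted, 1 + (phi - 1) * occupancy(concentrations[j], kd), 1
    )
  }
  with_sim_seed(seed, {
    base <- 10^runif(n, log10(area_range[1]), log10(area_range[2]))
    grid <- tidyr::expand_grid(
      i = seq_len(n),
      condition = conditions,
      replicate = seq_len(n_replicates)
    )
    ci <- match(grid$condition, conditions)
    expected <- base[grid$i] * fold[cbind(ci, grid$i)]
    area <- expected * exp(rnorm(nrow(grid), 0, sigma_log))
    out <- dplyr::bind_cols(anno[grid$i, ], tibble::tibble(
      condition = grid$condition,
      replicate = grid$replicate,
      area = area
    ))
    out$planted <- planted[grid$i]
    for (j in seq_along(concentrations)) {
      out[[paste0("true_fc_", concentrations[j])]] <- fold[j + 1L, grid$i]
    }
    out
  })
}

#' Simulate DARTS spectral-match counts with planted protection
#'
#' Per protein, the undigested count is Poisson with mean `lambda_u`, the
#' digested control is Poisson with mean `r * lambda_u`, and the treated
#' count at concentration c is Poisson with mean
#' `lambda_c + pi * occ(c) * (lambda_u - lambda_c)` — protection `pi` moves
#' the treated mean from the control level toward (never beyond) the
#' undigested level.
#'
#' @param protein_ids Character vector of protein identifiers.
#' @param pi Planted protection per protein in `[0, 1]` (recycled).
#' @param lambda_u Undigested mean count per protein; `NULL` (default) draws
#'   log-uniformly from 50–1000.
#' @param r Control-to-undigested ratio in (0, 1), default 0.3.
#' @param kd Dissociation constant (default 0.1 concentration units).
#' @param concentrations Numeric treated concentrations, default 1/10/100.
#' @param counts `"poisson"` (sampled) or `"expected"` (noise-free means,
#'   for identity checks).
#' @param seed Optional integer seed.
#' @return A long tibble `protein_id`, `condition`, `count` plus the truth
#'   columns `true_pi`, `lambda_u`, `r`.
#' @export
simulate_darts_counts <- function(protein_ids, pi = 0, lambda_u = NULL,
                                  r = 0.3, kd = 0.1,
                                  concentrations = c(1, 10, 100),
                                  counts = c("poisson", "expected"),
                                  seed = NULL) {
  counts <- match.arg(counts)
  n <- length(protein_ids)
  pi <- rep_len(pi, n)
  if (any(pi < 0 | pi > 1)) abort("`pi` must lie in [0, 1]")
  if (r <= 0 || r >= 1) abort("`r` must lie in (0, 1)")
  if (kd <= 0) abort("`kd` must be > 0")
  with_sim_seed(seed, {
    if (is.null(lambda_u)) {
      lambda_u <- 10^runif(n, log10(50), log10(1000))
    }
    lambda_u <- rep_len(lambda_u, n)
    lambda_c <- r * lambda_u
    draw <- function(lam) if (counts == "poisson") rpois(length(lam), lam) else lam
    rows <- list(
      tibble::tibble(protein_id = protein_ids, condition = "undigested", count = draw(lambda_u)),
      tibble::tibble(protein_id = protein_ids, condition = "control", count = draw(lambda_c))
    )
    for (cc in concentrations) {
      lam <- lambda_c + pi * occupancy(cc, kd) * (lambda_u - lambda_c)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        protein_id = protein_ids, condition = as.character(cc), count = draw(lam)
      )
    }
    out <- dplyr::bind_rows(rows)
    truth <- tibble::tibble(protein_id = protein_ids, true_pi = pi, lambda_u = lambda_u, r = r)
    dplyr::left_join(out, truth, by = "protein_id")
  })
}

#' Simulate gel-lane densitometry profiles
#'
#' Flat baseline intensities across lanes for background bins; bins listed in
#' `target_bins` rise monotonically across lanes by `increase` in total.
#'
#' @param mw_bins Molecular-weight bin labels (kDa), default 25 bins from
#'   10–250 kDa.
#' @param target_bins Bins that should rise with concentration.
#' @param lanes Lane names, control first.
#' @param increase Total relative increase of target bins (default 1 = 100%).
#' @param noise Multiplicative jitter sd on intensities (default 0.02).
#' @param seed Optional integer seed.
#' @return A wide tibble: `mw_bin_kda` plus one column per lane.
#' @export
simulate_lane_profiles <- function(mw_bins = seq(10, 250, by = 10),
                                   target_bins = numeric(),
                                   lanes = c("CTRL", "PXA_1uM", "PXA_10uM", "PXA_100uM"),
                                   increase = 1, noise = 0.02, seed = NULL) {
  n <- length(mw_bins)
  with_sim_seed(seed, {
    base <- runif(n, 50, 200)
    out <- tibble::tibble(mw_bin_kda = mw_bins)
    steps <- seq(0, increase, length.out = length(lanes))
    for (j in seq_along(lanes)) {
      v <- base
      is_target <- mw_bins %in% target_bins
      v[is_target] <- base[is_target] * (1 + steps[j])
      if (noise > 0) {
        # jitter background only; target bins stay exactly monotone
        v[!is_target] <- base[!is_target] * exp(rnorm(sum(!is_target), 0, noise))
      }
      out[[lanes[j]]] <- v
    }
    out
  })
}

#' Simulate a complete DARTS + t-LiP study with ground truth
#'
#' Generates a small synthetic proteome, plants one target protein with DARTS
#' protection `pi_target` and a set of ligand-protected peptides inside one
#' of its regions (the "binding region"), and emits every table the pipeline
#' consumes: FASTA, DARTS counts, lane profiles, replicate t-LiP areas,
#' region annotations, a small active-site list inside the binding region,
#' and the planted truth.
#'
#' @param seed Integer seed; the whole bundle is a deterministic function of
#'   it and the parameters.
#' @param n_proteins Number of proteins (default 6; the first is the target).
#' @param protein_length Residues per protein (default 500).
#' @param pi_target Planted DARTS protection of the target (default 0.8).
#' @param pi_background Protection of non-targets (default 0.02).
#' @param binding_region Index of the target region that carries the planted
#'   peptides (default 2).
#' @param phi,kd,sigma_log,n_replicates See [simulate_lip_areas()].
#' @param lip_concentrations,darts_concentrations Treated concentrations for
#'   the two assays (defaults 1/10 and 1/10/100).
#' @return A list: `proteins`, `regions`, `active_sites`, `darts_counts`,
#'   `lane_profiles`, `lip_areas`, `method` (the planner output for the
#'   target), and `truth` (planted parameters, protected precursor ids).
#' @export
simulate_study <- function(seed, n_proteins = 6, protein_length = 500,
                           pi_target = 0.8, pi_background = 0.02,
                           binding_region = 2, phi = 2, kd = 0.1,
                           sigma_log = 0.15, n_replicates = 3,
                           lip_concentrations = c(1, 10),
                           darts_concentrations = c(1, 10, 100)) {
  sims <- purrr::map(seq_len(n_proteins), function(i) {
    simulate_protein(
      length = protein_length, protein_id = sprintf("SIMP%02d", i),
      seed = seed + 1000L * i
    )
  })
  proteins <- purrr::map_dfr(sims, "proteins")
  regions <- purrr::map_dfr(sims, "regions")
  target <- proteins$protein_id[1L]
  target_regions <- regions[regions$protein_id == target, ]
  bind_reg <- target_regions[min(binding_region, nrow(target_regions)), ]

  method <- build_method(proteins[1L, ])
  precursors <- dplyr::distinct(
    tibble::as_tibble(method)[, c("precursor_id", "protein_id", "sequence", "start", "end", "charge", "precursor_mz")]
  ) |> dplyr::rename(mz = "precursor_mz")
  in_region <- precursors$start <= bind_reg$end & precursors$end >= bind_reg$start
  protected_ids <- precursors$precursor_id[in_region]

  # a few catalytic residues inside the binding region (not P, to keep the
  # letter check simple against any sequence)
  target_seq <- proteins$sequence[1L]
  idx <- seq(bind_reg$start, bind_reg$end, length.out = min(4L, bind_reg$end - bind_reg$start + 1L))
  idx <- unique(as.integer(round(idx)))
  active_sites <- tibble::tibble(
    protein_id = target,
    set_name = "synthetic_site",
    residue_letter = substring(target_seq, idx, idx),
    residue_index = idx
  )

  darts_counts <- simulate_darts_counts(
    proteins$protein_id,
    pi = c(pi_target, rep(pi_background, n_proteins - 1L)),
    kd = kd, concentrations = darts_concentrations, seed = seed + 1L
  )
  lane_profiles <- simulate_lane_profiles(
    target_bins = 160,
    lanes = c("CTRL", paste0("PXA_", darts_concentrations, "uM")),
    seed = seed + 2L
  )
  lip_areas <- simulate_lip_areas(
    precursors, protected_ids,
    phi = phi, kd = kd, sigma_log = sigma_log,
    n_replicates = n_replicates, concentrations = lip_concentrations,
    seed = seed + 3L
  )
  list(
    proteins = proteins,
    regions = regions,
    active_sites = active_sites,
    darts_counts = darts_counts,
    lane_profiles = lane_profiles,
    lip_areas = lip_areas,
    method = method,
    truth = list(
      seed = seed,
      target_protein = target,
      pi_target = pi_target,
      pi_background = pi_background,
      binding_region = bind_reg$name,
      protected_precursors = protected_ids,
      phi = phi, kd = kd, sigma_log = sigma_log,
      n_replicates = n_replicates,
      lip_concentrations = lip_concentrations,
      darts_concentrations = darts_concentrations
    )
  )
}

#' Write a simulated study bundle to disk
#'
#' Emits the exact file dialects the pipeline reads: `proteins.fasta`,
#' `darts_counts.tsv`, `lane_profiles.tsv`, `lip_areas.tsv`, `regions.tsv`,
#' `active_sites.tsv` and `truth.json`.
#'
#' @param study A bundle from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(study$proteins, file.path(dir, "proteins.fasta"))
  readr::write_tsv(
    study$darts_counts[, c("protein_id", "condition", "count")],
    file.path(dir, "darts_counts.tsv")
  )
  readr::write_tsv(study$lane_profiles, file.path(dir, "lane_profiles.tsv"))
  lip <- study$lip_areas
  lip <- lip[, setdiff(names(lip), c("planted", grep("^true_fc_", names(lip), value = TRUE)))]
  readr::write_tsv(lip, file.path(dir, "lip_areas.tsv"))
  readr::write_tsv(study$regions, file.path(dir, "regions.tsv"))
  readr::write_tsv(study$active_sites, file.path(dir, "active_sites.tsv"))
  jsonlite::write_json(
    study$truth, file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
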