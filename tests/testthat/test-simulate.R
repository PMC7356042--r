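test_that("generation is deterministic under a fixed seed", {
  a <- simulate_protein(length = 200, seed = 1)
  b <- simulate_protein(length = 200, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a$proteins$sequence, simulate_protein(length = 200, seed = 2)$proteins$sequence))

  pep <- tibble::tibble(precursor_id = paste0("p", 1:5))
  x <- simulate_lip_areas(pep, protected_ids = "p1", seed = 9)
  y <- simulate_lip_areas(pep, protected_ids = "p1", seed = 9)
  expect_identical(x, y)

  cx <- simulate_darts_counts(c("a", "b"), pi = 0.5, seed = 4)
  cy <- simulate_darts_counts(c("a", "b"), pi = 0.5, seed = 4)
  expect_identical(cx, cy)
})

test_that("simulated sequences have realistic lysine/arginine content", {
  sim <- simulate_protein(length = 10000, seed = 12)
  res <- strsplit(sim$proteins$sequence, "")[[1]]
  kr <- mean(res %in% c("K", "R"))
  expect_gt(kr, 0.09)
  expect_lt(kr, 0.13)
  expect_error(simulate_protein(length = 10), "at least 50")
})

test_that("a generated 500-mer yields a workable quantifiable peptide set", {
  sim <- simulate_protein(length = 500, seed = 3)
  dig <- digest(sim$proteins, max_missed = 0)
  quant <- dig[nchar(dig$sequence) >= 7 & nchar(dig$sequence) <= 25, ]
  expect_gte(nrow(quant), 10L)
  # regions tile the sequence
  expect_equal(sim$regions$start[1], 1L)
  expect_equal(dplyr::last(sim$regions$end), 500L)
  expect_true(all(sim$regions$start[-1] == head(sim$regions$end, -1) + 1L))
})

test_that("noise-free areas reproduce the planted occupancy-scaled fold changes", {
  pep <- tibble::tibble(precursor_id = paste0("p", 1:4))
  # c >> kd: plateau at phi
  a <- simulate_lip_areas(pep,
    protected_ids = c("p1", "p2"), phi = 2, kd = 1e-12,
    sigma_log = 0, seed = 5
  )
  s <- lip_quantify(a, c("1", "10"))
  expect_equal(s$fc_1[s$precursor_id %in% c("p1", "p2")], c(2, 2), tolerance = 1e-9)
  expect_equal(s$fc_10[s$precursor_id %in% c("p3", "p4")], c(1, 1), tolerance = 1e-9)
  # c = kd: half occupancy -> fold 1.5
  b <- simulate_lip_areas(pep,
    protected_ids = "p1", phi = 2, kd = 1,
    sigma_log = 0, concentrations = 1, seed = 6
  )
  sb <- lip_quantify(b, "1")
  expect_equal(sb$fc_1[sb$precursor_id == "p1"], 1.5, tolerance = 1e-9)
})

test_that("log-area noise has the configured spread", {
  pep <- tibble::tibble(precursor_id = paste0("p", 1:2000))
  a <- simulate_lip_areas(pep,
    phi = 2, sigma_log = 0.15, n_replicates = 5,
    concentrations = 1, seed = 8
  )
  ctl <- a[a$condition == "control", ]
  resid <- log(ctl$area) - stats::ave(log(ctl$area), ctl$precursor_id)
  # sd of within-peptide log residuals, corrected for the per-group centering
  sd_hat <- sqrt(sum(resid^2) / (nrow(ctl) - 2000))
  expect_gt(sd_hat, 0.14)
  expect_lt(sd_hat, 0.16)
})

test_that("unprotected DARTS counts are distributionally indistinguishable from control", {
  counts <- simulate_darts_counts(paste0("p", 1:5000),
    pi = 0, lambda_u = 300, r = 0.4,
    concentrations = 10, seed = 21
  )
  trt <- counts$count[counts$condition == "10"]
  ctl <- counts$count[counts$condition == "control"]
  ks <- suppressWarnings(stats::ks.test(trt, ctl))
  expect_gt(ks$p.value, 0.01)
})

test_that("full protection at saturating ligand recovers 100% exactly without noise", {
  counts <- simulate_darts_counts("tgt",
    pi = 1, lambda_u = 500, r = 0.3, kd = 1e-9,
    concentrations = 100, counts = "expected"
  )
  wide <- tidyr::pivot_wider(counts[, c("protein_id", "condition", "count")],
    names_from = "condition", values_from = "count"
  )
  expect_equal(
    protection_percentage(wide$`100`, wide$control, wide$undigested)$protection_pct,
    100,
    tolerance = 1e-9
  )
})

test_that("parameter validation rejects out-of-domain settings", {
  pep <- tibble::tibble(precursor_id = "p1")
  expect_error(simulate_lip_areas(pep, phi = 0), "phi")
  expect_error(simulate_lip_areas(pep, sigma_log = -1), "sigma_log")
  expect_error(simulate_lip_areas(pep, n_replicates = 1), "n_replicates")
  expect_error(simulate_darts_counts("p", pi = 1.2), "pi")
  expect_error(simulate_darts_counts("p", r = 1.5), "r")
})

test_that("study bundles are written in the dialects the readers accept", {
  study <- simulate_study(seed = 42)
  dir <- withr::local_tempdir()
  write_study(study, dir)
  prot <- read_fasta(file.path(dir, "proteins.fasta"))
  expect_equal(prot$sequence, study$proteins$sequence)
  counts <- read_match_counts(file.path(dir, "darts_counts.tsv"))
  expect_setequal(unique(counts$condition), c("undigested", "control", "1", "10", "100"))
  areas <- read_area_matrix(file.path(dir, "lip_areas.tsv"))
  expect_true(all(areas$area > 0))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$target_protein, study$truth$target_protein)
  sites <- read_active_sites(file.path(dir, "active_sites.tsv"), proteins = prot)
  expect_gt(nrow(sites), 0L)
})
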