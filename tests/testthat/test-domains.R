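test_that("peptide-region overlap length matches the set-intersection oracle", {
  pep <- tibble::tibble(protein_id = "p", start = c(275L, 1L), end = c(286L, 5L))
  reg <- tibble::tibble(
    protein_id = "p", name = c("S2", "far"),
    start = c(213L, 6L), end = c(400L, 10L), category = "domain"
  )
  got <- map_peptide_to_regions(pep, reg)
  expect_equal(nrow(got), 1L)
  expect_equal(got$region, "S2")
  expect_equal(got$overlap, 12L)

  set.seed(41)
  for (i in 1:50) {
    ps <- sort(sample(1:200, 2))
    rs <- sort(sample(1:200, 2))
    pep <- tibble::tibble(protein_id = "p", start = ps[1], end = ps[2])
    reg <- tibble::tibble(
      protein_id = "p", name = "r", start = rs[1], end = rs[2], category = "domain"
    )
    got <- map_peptide_to_regions(pep, reg)
    want <- length(intersect(seq(ps[1], ps[2]), seq(rs[1], rs[2])))
    if (want == 0) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$overlap, want)
    }
  }
})

test_that("orthosteric classification finds contained active-site residues", {
  prot <- cps1_proteins()
  sites <- cps1_sites()
  pep <- tibble::tibble(protein_id = "CPS1_HUMAN", start = 491L, end = 505L)
  got <- classify_orthosteric(pep, sites, proteins = prot)
  expect_true(got$orthosteric)
  expect_equal(got$site_residues, "T502;E503;R505")

  pep2 <- tibble::tibble(protein_id = "CPS1_HUMAN", start = 275L, end = 286L)
  expect_false(classify_orthosteric(pep2, sites)$orthosteric)
})

test_that("exactly two reference protected peptides contain catalytic residues", {
  tab <- cps1_table1()
  got <- classify_orthosteric(tab, cps1_sites(), proteins = cps1_proteins())
  expect_equal(sum(got$orthosteric), 2L)
  expect_setequal(
    paste0(got$start[got$orthosteric], "-", got$end[got$orthosteric]),
    c("491-505", "534-545")
  )
})

test_that("extending a peptide span never unsets the orthosteric flag", {
  sites <- cps1_sites()
  set.seed(43)
  for (i in 1:30) {
    s <- sample(400:700, 1)
    e <- s + sample(5:20, 1)
    pep <- tibble::tibble(protein_id = "CPS1_HUMAN", start = s, end = e)
    ext <- tibble::tibble(
      protein_id = "CPS1_HUMAN",
      start = max(1L, s - sample(0:10, 1)), end = e + sample(0:10, 1)
    )
    base_flag <- classify_orthosteric(pep, sites)$orthosteric
    ext_flag <- classify_orthosteric(ext, sites)$orthosteric
    expect_true(!base_flag || ext_flag)
  }
})

test_that("a residue-letter mismatch against the sequence is a hard error", {
  prot <- cps1_proteins()
  bad <- tibble::tibble(
    protein_id = "CPS1_HUMAN", set_name = "s",
    residue_letter = "W", residue_index = 502L # actually T502
  )
  expect_error(classify_orthosteric(
    tibble::tibble(protein_id = "CPS1_HUMAN", start = 1L, end = 10L),
    bad,
    proteins = prot
  ), "mismatch")
  out_of_range <- tibble::tibble(
    protein_id = "CPS1_HUMAN", set_name = "s",
    residue_letter = "T", residue_index = 99999L
  )
  expect_error(
    classify_orthosteric(
      tibble::tibble(protein_id = "CPS1_HUMAN", start = 1L, end = 10L),
      out_of_range,
      proteins = prot
    ),
    "outside"
  )
})

test_that("the protection map assigns the reference peptides to S2, L1 and L3", {
  tab <- cps1_table1()
  report <- protection_map_report(
    tab[, c("protein_id", "start", "end", "peptide")],
    cps1_regions(), cps1_sites(),
    proteins = cps1_proteins()
  )
  rs <- protected_regions(report)
  expect_setequal(rs$region, c("S2", "L1", "L3"))
  expect_equal(rs$n_peptides[rs$region == "S2"], 1L)
  expect_equal(rs$n_peptides[rs$region == "L1"], 4L)
  expect_equal(rs$n_peptides[rs$region == "L3"], 3L)
  expect_equal(glance(report)$n_orthosteric, 2L)

  # region set equals the brute-force union of per-peptide overlaps
  want <- unique(map_peptide_to_regions(tab, cps1_regions())$region)
  expect_setequal(rs$region, want)
})

test_that("an empty peptide list yields an empty report", {
  report <- protection_map_report(
    tibble::tibble(protein_id = character(), start = integer(), end = integer()),
    cps1_regions()
  )
  expect_equal(nrow(report), 0L)
  expect_equal(nrow(protected_regions(report)), 0L)
})
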