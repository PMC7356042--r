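# Shared fixtures and independent oracles for the test suite.

cps1_fasta <- function() system.file("extdata", "cps1_tlip.fasta", package = "lipmrm")
cps1_proteins <- function() read_fasta(cps1_fasta())
cps1_regions <- function() {
  read_region_annotations(system.file("extdata", "cps1_regions.tsv", package = "lipmrm"))
}
cps1_sites <- function() {
  read_active_sites(system.file("extdata", "cps1_active_sites.tsv", package = "lipmrm"))
}
cps1_table1 <- function() {
  readr::read_tsv(
    system.file("extdata", "cps1_protected_peptides.tsv", package = "lipmrm"),
    show_col_types = FALSE
  )
}

random_protein_seq <- function(n, kr_freq = 0.25) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M",
          "N", "P", "Q", "S", "T", "V", "W", "Y")
  probs <- c(rep((1 - kr_freq) / length(aa), length(aa)), kr_freq / 2, kr_freq / 2)
  paste(sample(c(aa, "K", "R"), n, replace = TRUE, prob = probs), collapse = "")
}

# letter-level predicate for a conforming cleavage junction after position p
# (0 = N-terminus, n = C-terminus); written independently of the digestion code
oracle_junction <- function(res, p, lysc = FALSE) {
  n <- length(res)
  if (p == 0 || p == n) {
    return(TRUE)
  }
  (res[p] %in% c("K", "R") && res[p + 1] != "P") || (lysc && res[p] == "K")
}

# brute-force digestion oracle: enumerate every (start, end) substring pair and
# keep those whose termini both conform and whose internal missed-cleavage
# count is within the limit; vectorised so whole sequences stay feasible
oracle_digest <- function(sequence, max_missed = 0, lysc = FALSE) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  cut_after <- vapply(seq_len(n), function(p) oracle_junction(res, p, lysc), logical(1))
  start_ok <- c(TRUE, cut_after[-n]) # start s conforms iff junction after s-1
  csum <- cumsum(cut_after)
  grid <- expand.grid(start = seq_len(n), end = seq_len(n))
  grid <- grid[grid$start <= grid$end, ]
  keep <- start_ok[grid$start] & cut_after[grid$end]
  grid <- grid[keep, ]
  # internal unused cleavage sites strictly inside [start, end):
  # csum0[p + 1] counts junctions at positions <= p
  csum0 <- c(0L, csum)
  missed <- csum0[grid$end] - csum0[grid$start]
  grid <- grid[missed <= max_missed, ]
  grid <- grid[order(grid$start, grid$end), ]
  tibble::tibble(
    start = as.integer(grid$start), end = as.integer(grid$end),
    sequence = substring(sequence, grid$start, grid$end)
  )
}

# independent t p-value from the textbook pooled-variance formula + pt()
oracle_student_p <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * pt(-abs(tt), n1 + n2 - 2)
}
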