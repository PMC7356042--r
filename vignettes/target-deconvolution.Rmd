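---
title: "Target deconvolution from DARTS and t-LiP-MRM data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Target deconvolution from DARTS and t-LiP-MRM data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipmrm)
```

## The experimental logic this package models

When a small molecule binds a protein, the complex breathes less and resists
proteolysis. Two readouts exploit this:

* **DARTS** (drug affinity responsive target stability): a native lysate is
  mildly digested with a broad-specificity protease (subtilisin) with and
  without ligand. A ligand-stabilised protein keeps more of its intact band on
  a gel, and more spectral matches in the subsequent in-gel identification.
  DARTS answers *which protein* is the target.
* **t-LiP-MRM** (targeted limited proteolysis with multiple reaction
  monitoring): after the limited native-state digestion, the sample is
  denatured and fully digested with trypsin. Fully tryptic peptides survive
  only where subtilisin did *not* cut in the native state, so their abundances
  report local conformational protection. Quantifying them by MRM answers
  *where on the protein* the ligand acts.

The package implements the complete computational chain for both readouts,
plus a synthetic-data generator with planted ground truth so the chain can be
validated end to end without any instrument data.

## Scores and statistics

**DARTS protection percentage.** For spectral-match counts of a protein in
the treated, vehicle-control and undigested (mock-proteolysis) samples,

$$\mathrm{protection} = 100 \cdot
  \frac{\mathrm{treated} - \mathrm{control}}
       {\mathrm{undigested} - \mathrm{control}}\ \%$$

0% means the ligand changed nothing; 100% means proteolysis was fully
blocked. Counts are sampled quantities, so noisy values can fall outside
[0, 100]: such values are reported and flagged (`out_of_range`) rather than
clamped, and proteins whose denominator is non-positive (undigested not above
control, an uninterpretable experiment) are flagged `denominator_invalid` and
ranked last. Ranking uses protection at the highest concentration, with a
`dose_consistent` flag for proteins whose protection rises monotonically with
concentration; ties break alphabetically so output order is total and
reproducible.

**Band nomination.** Densitometric lane profiles (molecular-weight bin ×
lane intensity) stand in for the visual step of cutting bands that darken
with increasing ligand. A bin is nominated when its intensity is
non-decreasing from the control lane through the ordered concentration lanes
*and* the total relative increase reaches a threshold (default 20%). No
numeric criterion exists in the field for this visual call; both the
threshold and strict monotonicity are configurable.

**t-LiP fold change and protection call.** Per precursor and concentration,
the fold change is the ratio of mean treated to mean control peak area, and
significance comes from a two-sided two-sample t-test. A peptide is called
*protected* only when fold change > 1 **and** p < α (default 0.05) at
**every** tested concentration — the dual-concentration rule guards against
single-condition flukes at n = 3. The default test is the equal-variance
Student t on raw areas, the smallest-assumption choice for triplicate MRM
areas; Welch and log-area variants are provided (`method = "welch"`,
`"log_student"`, `"log_welch"`) because MRM noise is closer to
multiplicative. No multiple-testing correction is applied by default, to
match the conventional raw p < 0.05 reporting of the assay; with ~50
precursors per target and the dual-concentration AND-rule, the family-wise
null selection rate is already far below α (the test suite measures ≤ 1% at
10,000 null peptides). `p.adjust`-based correction can be layered on by the
caller.

**Domain mapping.** Protected peptides are intersected with 1-based inclusive
region annotations (minimum overlap 1 residue — published assignments are
full containments, so the threshold is not load-bearing) and with active-site
residue lists. A peptide containing at least one catalytic residue is
*orthosteric*; others report region-level, allosteric-proximal protection.
Every active-site annotation carries its expected residue letter, and any
letter/index mismatch against the supplied sequence is a hard error: this is
the guard that catches residue-numbering drift between annotation sources,
the classic failure mode of this analysis.

## In silico digestion and mass arithmetic

Trypsin cleaves after K/R but not before P; the trypsin/LysC mix
(`enzyme = "trypsin_lysc"`) additionally cleaves after K even before P,
the standard behaviour of LysC. `digest()` emits all fully tryptic peptides
with up to `max_missed` missed cleavages (default 2, the usual search
setting); at zero missed cleavages the peptides tile the sequence exactly.
Semi- and non-tryptic spans can be classified after the fact with
`annotate_tryptic_status()`.

Monoisotopic masses derive from a single pinned residue-mass table
(`residue_masses()`), water 18.010565 Da, proton 1.007276 Da, and
carbamidomethylation of cysteine (+57.02146 Da) as the default fixed
modification, so every m/z in the package is bit-reproducible from sequence,
charge and modification set alone. The default precursor charge is 2: all
eight reference protected peptides' printed Q1 values are consistent with
doubly protonated masses for their span lengths (verified to within
±0.006 Th by the test suite), and tryptic peptides of 7–15 residues
overwhelmingly electrospray at 2+. Variable modifications (oxidised M,
phospho-S/T) are accepted for mass computation but excluded from default MRM
planning, where quantified peptides are assumed unmodified.

## Deterministic MRM planning

Spectral libraries rank transitions by measured intensity; a desk pipeline
cannot reproduce library content, so `build_method()` replaces intensity
with a fixed heuristic score: +2 for y-series ions (which dominate CID
spectra of tryptic peptides), +1 for fragments above the precursor m/z
(cleaner of low-mass chemical noise), +0.5 for mid-sequence ordinals
(ordinal 3 to n−2), with ties broken y before b, higher ordinal first, then
lower m/z. The ordering is total, so the same input always yields a
byte-identical transition list. Default filters — fully tryptic, zero missed
cleavages, length 7–25, precursor m/z 300–1250 Th, three transitions per
precursor — mirror common targeted-method practice. The number of precursors
a public library returns for a protein is database-version dependent and is
deliberately *not* treated as a reproducible quantity; the planner records
its own count in `glance()`.

## The synthetic-data generator

`simulate_study()` emulates the study design the pipeline is meant for:
three replicates, two ligand concentrations (1 and 10 µM) for targeted
quantification and three (1/10/100 µM) for DARTS, one planted target protein
among background proteins, and a planted "binding region" whose fully
tryptic peptides are protected.

* **Occupancy model.** Protection scales with fractional occupancy
  $occ(c) = c/(c + K_D)$ — the simplest single-site mechanism linking a
  two-concentration design to graded protection. Default $K_D = 0.1$ µM:
  reference fold changes plateau between 1 and 10 µM, so the emulated binder
  is near-saturated at the lower concentration. This is a modelling choice,
  not an empirical claim.
* **Areas.** Control expected areas are log-uniform on $10^4$–$10^7$
  (typical MRM dynamic range); planted peptides scale by
  $1 + (\varphi - 1)\,occ(c)$ with fold factor $\varphi = 2$; observed areas
  multiply by $e^\varepsilon$, $\varepsilon \sim N(0, \sigma_{\log})$ with
  $\sigma_{\log} = 0.15$, matching a ~15% CV — ordinary for scheduled MRM.
* **Counts.** Per protein, undigested counts are Poisson($\lambda_u$) with
  $\lambda_u$ log-uniform on 50–1000, the digested control is
  Poisson($r\lambda_u$) with $r = 0.3$, and the treated mean is
  $\lambda_c + \pi\,occ(c)(\lambda_u - \lambda_c)$, encoding that protection
  can only move counts from the control level toward, never beyond, the
  undigested level.
* **Determinism.** Every generator takes a seed and pins the RNG kind
  (Mersenne–Twister / inversion / rejection), so a seed plus parameters maps
  to byte-identical output across platforms.

What the generator does **not** emulate: retention-time drift, interference
and transition-level signal processing, shared-peptide protein inference,
semi-tryptic background in the quantified set, batch effects, or correlated
noise between concentrations (conditions are simulated independently).
Passing recovery tests therefore demonstrates that the statistical chain is
correct and calibrated under its stated noise model — not that it is robust
to every pathology of real chromatography.

## Calibration and recovery properties (measured by the test suite)

The acceptance suite re-measures, at fixed seeds, the properties the chain
must have under the generator's study conditions; problem sizes were chosen
to give tight binomial/Monte-Carlo error while keeping the default test run
fast (10,000 peptides for null rates, 1,000 for sensitivity, 1,000
simulations for DARTS recovery, 1,000 random sequences for the digestion
oracle):

* null single-concentration rejection at α = 0.05 within [0.035, 0.065],
  and dual-concentration selection ≤ 0.01;
* sensitivity ≥ 0.90 for a planted twofold change at σ_log = 0.15, n = 3;
* mean recovered DARTS protection within 50 ± 5 points at π = 0.5,
  λ_u = 500, r = 0.3;
* digestion identical to a brute-force substring oracle, and m/z identities
  (charge-state algebra, fragment complementarity) to 10⁻⁹.

## The bundled CPS1 reference fixture

The package ships a reference instance: human carbamoyl-phosphate synthase 1
(CPS1, UniProt P31327), the 160-kDa multi-domain mitochondrial urea-cycle
enzyme, in the residue numbering used by the t-LiP study of its xanthone
ligand (the full-precursor sequence minus the 42 N-terminal residues, so
that bundled annotations such as T502 or the T'-loop at 1269–1291 index
directly into the sequence). The bundled sequence is a reconstruction
rather than a database download, and is therefore verified against 33
independent printed values: the eight
doubly-charged precursor m/z of the protected peptides (all within
±0.006 Th), the 25 active-site residue letters, the T'-loop end points, and
the flanking residues of every peptide span. Positions outside those spans
are not independently checksummed; the m/z-bearing analyses never touch
them. `cps1_regions.tsv` holds the S1/S2/L1/L2/L3 domain boundaries; exact
boundaries are not printed anywhere in the t-LiP report (its domain cartoon
derives from the 5DOU crystallography literature), so the file is an
editable fixture constrained by the published containments (peptide 275–286
in S2; the 491–709 spans in L1; the 1033–1115 spans in L3; T'-loop
1269–1291). The flanking letters in span notation like "G-[275-286]-K" were
resolved to be the peptide's own termini: every reconstructed span starts
and ends with exactly those letters.

## Degenerate inputs and numerical conventions

* Zero variance in both groups with equal means gives p = 1; with unequal
  means p = 0 plus a warning (a measured zero-variance difference is either
  meaningless or infinitely significant; both deserve attention).
* Protection with `undigested <= control` is NA + flag, never ±Inf.
* A band rising from zero intensity counts as nominated (relative increase
  is undefined; absolute evidence of appearance is taken at face value).
* Fold changes are always ratios of raw-area means, even when the test runs
  on log areas, so the reported effect size matches the conventional
  definition.
* All coordinates are 1-based inclusive; the TSV interfaces keep them that
  way (converters to other conventions belong at I/O boundaries, not inside
  the pipeline).

## Known limitations

* "Spectral matches" are consumed as given; no protein inference or search
  emulation is performed, and gel images must arrive pre-digitised as
  numeric lane profiles.
* The transition score is a heuristic stand-in for intensity: methods built
  here are reproducible and reasonable, not optimal.
* The t-test defaults assume approximate normality of triplicate areas; at
  n = 3 the log-variants are safer when CVs exceed ~30%.
* Sequence-level domain mapping cannot see 3-D proximity: a peptide adjacent
  to a functional loop in space but distant in sequence (as for the
  1109–1115 span and the T'-loop) maps only to its sequence region.
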