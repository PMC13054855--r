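---
title: "Assessing subcellular fraction purity with PRM: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing subcellular fraction purity with PRM: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(prmfrac)
library(dplyr)
```

## The problem

Subcellular fractionation — separating a lysate into cytosolic (C),
mitochondrial (M) and nuclear (N) fractions — is only as useful as the
purity of the fractions it yields. The classical purity check,
immunoblotting of organelle marker proteins, is low-throughput and
semi-quantitative. `prmfrac` implements the targeted mass-spectrometry
alternative: a parallel reaction monitoring (PRM) assay that quantifies a
small panel of compartment-restricted marker proteins in every fraction
and turns the replicate measurements into enrichment ratios, coefficients
of variation, and formal significance tests.

The package covers the whole desk-side workflow: designing proteotypic
peptide panels from protein sequence, computing the precursor and
fragment masses a PRM method needs, quantifying transitions from
centroided mzML runs, scoring enrichment, and — because real acquisitions
are expensive — simulating PRM runs with known ground truth so every
stage can be validated end to end.

## Mass model

All masses are monoisotopic. A peptide's neutral mass is the sum of its
residue masses plus one water (18.010565 Da), plus fixed-modification
shifts; the default fixed modification is carbamidomethyl cysteine
(+57.021464 Da), matching chloroacetamide alkylation in standard sample
preparation. Protonated species use the proton mass 1.007276 Da as the
charge carrier:

$$ m/z = \frac{M + z \cdot 1.007276}{z} $$

b ions are the first $i$ residues plus $z$ protons; y ions the last $i$
residues plus water plus $z$ protons. This yields the complementarity
identity $b_i^{+} + y_{n-i}^{+} = M + 2 \times 1.007276$, which the test
suite verifies for every panel peptide at every ordinal to $10^{-6}$ Da.

Reported m/z values are rounded half-up to 3 decimals
(`round_half_up()`), the convention of printed transition tables.
Published panel tables mix rounding and truncation in the last digit, so
panel validation compares printed to recomputed m/z with a ±0.005 hard
failure threshold while reporting the exact deviation (`mz_delta`);
deviations up to ±0.001 are expected and harmless. Average masses,
a/c/z ions, neutral losses and isotope envelopes are out of scope.

```{r}
precursor_mz("EGDLIAAQAR", 2) |> round_half_up()
```

## The marker panel

The packaged panel (`load_panel()`) monitors 8 marker proteins through 16
peptide ions and 76 transitions: prelamin A/C (LMNA) and nucleophosmin
(NPM) for the nucleus; ATP synthase subunit alpha (ATP5F1A),
carbamoyl-phosphate synthase 1 (CPS1) and complex-I assembly factor
NDUFAF4 for mitochondria; HSP90AB1, adenosylhomocysteinase (AHCY) and
methionine adenosyltransferase 2A (MAT2A) for the cytosol. Loading
revalidates every entry: peptide length 8–25, at least 3 transitions, and
precursor m/z recomputation.

```{r}
panel <- load_panel()
panel |> count(compartment, gene)
```

## Panel design rules

`digest_trypsin()` implements the classic trypsin rule — cleave after K
or R unless the next residue is proline — and enumerates missed-cleavage
products as concatenations of adjacent fully tryptic fragments. The
KR-not-before-P form was chosen because it is the default of virtually
all proteomics search engines; a digest oracle test (brute-force scan and
join enumeration over 1000 random sequences) pins the behaviour.

`filter_candidates()` encodes the proteotypic selection criteria: length
8–25 residues, zero missed cleavages, and avoidance of methionine and
tryptophan. The avoidance is *soft*: Met/Trp-containing peptides are kept
only when their protein has fewer than `min_clean = 2` clean candidates,
since oxidation-prone residues are acceptable when nothing better exists.
The packaged panel itself shows the limits of sequence-only rules: MAT2A
contributes two clean peptides *and* a Met-containing one, which survives
only at `min_clean = 3` — in practice such peptides earn their place
through prior experimental evidence, which the optional `evidence`
argument models as a restriction list. Ties in the candidate ranking are
broken by length then lexicographically, so design output is
deterministic.

## Quantification model

`read_prm_run()` loads centroided MS2 scans with their isolation windows
from mzML (rejecting profile-mode data). `extract_xic()` builds one trace
point per scan whose isolation window contains the precursor: the sum of
centroid intensities within ±10 ppm (default) of the product m/z. The
tolerance is deliberately generous for Orbitrap-class accuracy; widening
it can only add intensity, a monotonicity property the tests check.

`integrate_peak()` finds the global apex and walks outward until the
trace drops below 1% of the apex or a persistent local minimum signals a
neighbouring feature, then integrates trapezoidally
(intensity·seconds). On a noise-free Gaussian peak the 1% cut plus
quadrature loses under 2% of the analytic area at the default sampling
(sigma 4 s, 1.5 s scan interval) — the error budget the round-trip tests
enforce. Background subtraction is off: the simulator emits no baseline
by default, and on real data boundary choice dominates.

Peptide abundance is the *total area*: the sum of the peptide's unflagged
transition areas. Missing totals stay missing — no imputation — and
propagate as reduced replicate counts.

Interference exclusion, a manual curation step at the bench, is automated
as a two-pass co-elution screen (`interference_check()`): transitions
whose apex deviates from the consensus (median) apex by more than half
the consensus FWHM are flagged first; the rest must reach a median
Pearson correlation of 0.8 with the apex-consistent traces. The two
passes keep a single shifted interferent from dragging down the good
transitions' pairwise correlations, which matters at the panel's minimum
of three transitions. Flags are always reported rather than silently
dropped, so a human can override the screen.

## Statistics

For each peptide and fraction, replicate spread is summarised as
CV% = 100·sd/mean (sample sd, n−1). Enrichment ratios are ratios of
replicate means, ER(A/B) = mean(A)/mean(B), reported for all ordered
fraction pairs so ER(A/B)·ER(B/A) = 1 by construction.

Differences across fractions use classical one-way ANOVA on raw total
areas (the conventional scale for these plots; a log-transform option
exists), followed by Tukey's HSD with the Tukey–Kramer standard error so
unequal replicate counts — e.g. after a missing total — are handled:

$$ q_{ij} = \frac{|\bar y_i - \bar y_j|}
  {\sqrt{\tfrac{MS_{within}}{2}\left(\tfrac{1}{n_i}+\tfrac{1}{n_j}\right)}} $$

Adjusted p-values come from the studentized-range distribution
(`stats::ptukey`); the test suite cross-checks them against an
independent numeric-integration oracle of that distribution to 1e−4.
Degenerate layouts are resolved explicitly rather than returned as NaN:
identical data in all groups give F = 0, p = 1; zero within-group
variance with real separation gives an infinite F and a p → 0 sentinel.
No multiple-testing correction is applied across markers, matching
common practice for small QC panels; both ANOVA and Tukey p-values are
reported so the user can choose the stricter one.

A marker's verdict (`classify_enrichment()`) is **enriched** when its
home-fraction mean is the highest and both Tukey comparisons against the
other fractions fall below alpha = 0.05; **indeterminate** when the
direction is right but significance fails (the typical outcome for a
genuinely enriched marker measured with high biological CV);
**failed** when another fraction wins. A total-proteome (PT) channel, when
present, is treated as a reference for ER/CV reporting and excluded from
the three-fraction ANOVA.

## What the simulator emulates — and what it does not

`simulation_design()` encodes the study conditions the package is
validated under: 3 fractions × 3 biological replicates, a 10-fold
home-fraction enrichment over a base area of 1e5 intensity·seconds, and
log-normal replicate noise at 15% CV. The log-normal was chosen because
fraction-preparation variability is multiplicative and right-skewed (real
marker CVs range from a few percent to well over 50%), and it keeps areas
positive. Elution peaks are Gaussian (sigma 4 s), apexes spaced 30 s
(> 6 sigma) apart so peptides cannot cross-talk unless an interference is
injected explicitly, and each transition's profile integrates exactly to
its share of the peptide total under linearly decreasing weights. A PT
channel, when simulated, gets the mean of the three fraction means.

The simulator deliberately omits isotope envelopes, chimeric spectra,
retention-time drift, detector saturation and baseline structure. Passing
the round-trip and power tests therefore demonstrates that the
*computational* pipeline is unbiased and correctly calibrated under its
own generative model — not that any particular wet-lab fractionation will
achieve 10-fold enrichment or 15% CV. Real acquisitions remain the only
test of the biology.

Under those study conditions the package's operating characteristics,
recomputed by the test suite on every run, are: noise-free simulated runs
re-quantified within 2% for all 76 transitions; a 10-fold enriched marker
classified "enriched" in at least 95% of 500 simulation repeats; and a
null (1-fold) marker "enriched" in no more than 5% plus Monte-Carlo
margin — i.e. the verdict rule holds its nominal type-I level.

## Numerical and design choices

- Proton mass 1.007276 Da (not the hydrogen atom's 1.007825): this is
  the targeted-proteomics convention and reproduces printed panel m/z.
- Isolation-window matching is inclusive of the window edges; files
  lacking a stated half-width get ±0.85 m/z, a common PRM default.
- Integration boundaries and the 1%-of-apex rule are configurable; the
  defaults favour slight over-integration of clean peaks rather than
  truncation of tailing ones.
- Problem sizes in the test suite (1000-sequence digest oracle, 500
  Monte-Carlo repeats, single-fraction noise-free round trips) were
  chosen as the smallest sizes at which the checked properties are
  statistically meaningful.
- Seeds are explicit everywhere randomness exists; identical seeds give
  identical area tables and numerically identical quantification.

## Known limitations

- No retention-time scheduling or iRT calibration; XICs default to the
  full run, which is safe for the simulator's spaced apexes but wasteful
  on crowded real runs (pass `rt_window`).
- The interference screen is a heuristic stand-in for expert curation;
  it cannot detect an interferent that co-elutes exactly and scales all
  transitions equally.
- MS1-level quantification, cross-run alignment and DIA deconvolution
  are out of scope.
- Verdicts treat peptides independently; no protein-level rollup beyond
  the optional per-protein sum is attempted.

## A worked example

```{r, fig.width = 7, fig.height = 5}
panel3 <- load_panel() |> filter(peptide %in%
  c("EGDLIAAQAR", "VLSIGDGIAR", "IILLAEGR"))
design <- simulation_design(panel3, cv = 0.10, replicates = 3)
sim <- simulate_experiment(design, tempfile("vig"), seed = 7)
res <- run_pipeline(sim$sample_sheet, panel3)
res$report$verdicts
autoplot(res$report)
```
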