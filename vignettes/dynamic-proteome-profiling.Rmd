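---
title: "Dynamic proteome profiling: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic proteome profiling: model, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement and the model

During metabolic labeling with deuterium oxide, deuterium from the culture
medium is incorporated into non-essential amino acids and, from there, into
newly synthesized protein. For a peptide observed by LC-MS, this shifts
signal from the monoisotopic mass isotopomer (m0) into the first heavy
isotopomer (m1). The package works on the *relative isotopomer abundance*

$$\mathrm{RIA} = \frac{m_1}{m_0 + m_1},$$

which rises from its natural baseline toward a plateau as labeled protein
copies replace unlabeled ones.

The plateau is set by the peptide's capacity to carry deuterium — the number
$N$ of exchangeable H–C bonds, summed from per-residue values shipped in
`inst/extdata/exchangeable_hydrogens.csv` — and by the excess D:H ratio of
the precursor pool:

$$\mathrm{RIA}_{\infty} = 1 - \cfrac{1}{\cfrac{1}{1-\mathrm{RIA}_{t_0}} +
  N\,(\mathrm{DH}_{exp} - \mathrm{DH}_{nat})}.$$

Two limits pin the parenthesization of this expression: with $N = 0$ or with
no excess enrichment ($\mathrm{DH}_{exp} = \mathrm{DH}_{nat}$) the plateau
must equal the baseline, which the form above satisfies exactly (and the
test suite asserts over randomized grids).

Between two time points $t_0$ and $t_1$ the rise toward the plateau follows
first-order kinetics. Because a growing or shrinking protein pool dilutes or
concentrates the label, the fractional rise is adjusted by the protein
abundance ratio $P_{t_1}/P_{t_0}$:

$$k_{deg} = -\frac{1}{t_1-t_0}\,
  \ln\!\left(1 - \frac{\mathrm{RIA}_{t_1}-\mathrm{RIA}_{t_0}}
  {\mathrm{RIA}_{\infty}-\mathrm{RIA}_{t_0}}\cdot\frac{P_{t_1}}{P_{t_0}}\right).$$

With a stable pool ($P_{t_1}/P_{t_0}=1$) this reduces to the classic
rise-to-plateau rate $-\ln(1-f)/\Delta t$, the second limit that pins the
formula. The fractional synthesis rate is $\mathrm{FSR} = 100\,k_{deg}$ in
percent per hour, and protein-level FSR is the median over the protein's
valid *unique* peptides (peptide sequences observed under more than one
accession are excluded from the roll-up).

## Defaults and why

| Parameter | Default | Rationale |
|---|---|---|
| `dh_exp` | 0.04 | 4% D2O culture media; the nominal molar fraction is taken as precursor enrichment because no measured enrichment accompanies the tables |
| `dh_nat` | 1.5576e-4 | natural deuterium abundance of hydrogen |
| `t0`, `t1` | 12 h, 36 h | the analysis window of the 36-h labeling design; FSR is quantified across 12–36 h |
| `ria_t0_mode` | `"control"` | baseline RIA from unlabeled (H2O) control samples, which measure natural isotopic abundance directly; peptides lacking control measurements fall back to the labeled 12-h sample, and the source is recorded per record |
| `abundance_pairing` | `"replicate"` | the abundance ratio pairs the 12-h and 36-h samples of the same condition and replicate; a condition-mean pairing is available when replicate pairing is not meaningful |
| `cluster_k` | 5 | interaction-profile cluster count |
| `alpha` | 0.05 | the condition-effect gate for downstream sets; Storey q-values are reported alongside, not used as gates |

Numerical and degenerate-input choices:

* Records whose kinetics leave the valid log domain are *flagged* — `"RIA
  decreased"` when the end-of-window RIA fell below baseline, `"labeling
  at/above plateau"` when the adjusted fractional rise reaches 1 — and
  excluded from medians. Nothing is imputed.
* Missing abundance cells are missing, never zero; zeros are measured values.
  Proteins without a usable abundance ratio get ratio 1 with a flag.
* One-way and two-way ANOVAs resolve degenerate variance structure
  explicitly: zero between- and within-group variance gives $F=0, p=1$;
  distinct means with zero within-group variance give $p=0$. The zero
  threshold is relative to the data's scale so constant inputs are not
  misread as infinitely significant.
* The Storey $\pi_0$ estimate uses the $\lambda$-grid $0.05, 0.10, \dots,
  0.95$ with a cubic smoothing spline extrapolated to $\lambda = 1$, clipped
  to $(0,1]$; with fewer than ten p-values $\pi_0$ falls back to 1, making
  the q-values exactly Benjamini–Hochberg. The smoother was chosen over the
  bootstrap variant for determinism.
* Interaction-profile clustering is Ward linkage (`ward.D2`) on Euclidean
  distances between row-standardized condition-by-time mean profiles — a
  conventional default, since no algorithm is canonical for this step. Rows
  are sorted by accession before clustering and cluster ids are relabeled by
  descending size (ties by smallest member accession), which makes the
  partition independent of input order.
* Inter-sample normalization scales each sample so its median protein-wise
  ratio to a reference sample (the sample whose median log-abundance is
  closest to the median of sample medians) equals one. This emulates the
  inter-sample abundance-ratio normalization of upstream LFQ software
  without claiming bit-exactness. When samples share one abundance profile
  up to scaling, a second pass is an exact no-op; with per-cell measurement
  noise the re-estimated factors differ from one by ordinary sampling error.
  Note that a *global* abundance shift shared by all proteins is absorbed by
  these factors by construction; only relative (protein-specific) abundance
  changes survive normalization, which is why the synthetic generator keeps
  its window-wide drift at 1 by default and plants treatment effects on a
  protein subset.
* Ribosomal classification is a case-insensitive substring match on
  `"ribosom"` (so "ribosome" and "ribosomal" both hit), with the subunit
  taken from the first `40S`/`60S`/`28S`/`39S` token. Candidates without a
  subunit token — typically biogenesis factors — remain unclassified and are
  excluded from subunit summaries. "Total abundance" of a subunit is the sum
  over members; a median variant is available.
* Tukey post hoc comparisons for subunit contrasts run on replicate-level
  summaries (median FSR and total abundance per condition and replicate).

## What the synthetic generator emulates

`sim_config()` defaults encode the study conditions: three conditions (VC,
IBU, PEA) × three biological replicates × two time points (12/36 h), 4%
D2O, unlabeled control replicates at both time points, protein FSR
log-normal around a median of 0.88 %/h, a ribosomal subset (5% of proteins,
roughly the proportion observed in a complete-case muscle proteome) whose
FSR is multiplied by 1.8 under both treatments, ribosomal abundance gains
of 17–18% at 36 h, and multiplicative log-normal measurement noise of 5%
CV applied independently to m0, m1 and abundances.

The forward model is the exact algebraic inverse of the two-point estimator:
labeled 12-h samples sit at the peptide's natural baseline RIA and 36-h
samples at the model-implied RIA. This makes estimator correctness testable
independently of model misspecification — with noise switched off the
pipeline must recover every true rate to numerical precision, and does
(max relative error below 1e-8 in the test suite). An ODE-based labeling
simulator with continuous uptake between 0 and 12 h is deliberately out of
scope; consequently the generator does not probe the (real) ambiguity of
whether the baseline RIA should be the unlabeled-control value or the 12-h
labeled value — in the generator the two coincide.

Each peptide's natural baseline RIA grows with its length through the
average m1:m0 contribution of the natural isotope envelope (about 0.0586
per residue, from ~5 carbons and ~1.3 nitrogens per average residue), so
7–25-residue tryptic peptides start at RIA ≈ 0.29–0.59, as real peptides
do. Sequences are random tryptic-like strings (7–25 residues ending in K or
R), peptide counts per protein are uniform on 2–8, and structure (sequences,
membership, true rates) and measurement noise draw from separate seeded
streams so that re-running with different noise preserves the proteome.

Features of real data the generator does not emulate: m2+ isotopomers,
chromatographic interference, charge states, missed-cleavage isotope
effects, peptide-level missingness (missingness is injected at the
protein-abundance level only), and biological replicate-to-replicate
variation in true rates. Passing tests therefore demonstrate correctness of
the estimator and statistics under the stated noise model, not robustness
to every artifact of real LC-MS data.

## Precision of the two-point estimator

The measurement physics deserve a frank statement. At 4% enrichment, the
plateau lies only 0.2–0.3 RIA units above a realistic baseline, and over a
24-h window at ~0.9 %/h the observed rise is just 0.04–0.07 RIA units. An
intensity CV of 5% applied independently to m0 and m1 perturbs a single RIA
measurement by roughly $r(1-r) \times 0.05\sqrt{2} \approx 0.017$ — a third
to a half of the expected rise. A single peptide-replicate rate therefore
carries ~35–45% relative error, and the median over up to 8 peptides × 3
replicates still leaves a median condition-level relative error of ~14%
(about 36% of proteins within 10% of truth, 90th percentile error ~0.42;
these pilot-measured figures are pinned at fixed seeds in the test suite).
Reliable per-protein rates at this design need either more peptides, more
time points, or isotopomer ratios measured to better than ~1% — which
integrated chromatographic peak areas in practice provide. Group-level
quantities are far more forgiving: planted 1.8× ribosomal effects are
detected by the subunit contrasts in ≥95% of simulations, with the percent
change recovered to ~10 percentage points, and the per-protein ANOVA layer
stays calibrated (5.3% of null proteins at p < 0.05 in a 2000-protein
simulation).

## Problem sizes used in validation

The test suite simulates 200–800 proteins per run (2000 for the
null-calibration check; 50 independent seeds for detection-rate and
null-centering properties), and the acceptance script uses 1200 proteins for
its main experiment. These sizes keep subunit memberships (~13 cytosolic
ribosomal proteins per subunit at 800 proteins) close enough to the
real complete-case proteome (33/47) for the group-level statistics to behave
comparably.

## Known limitations

* The two-point closed form cannot separate degradation from dilution when
  the abundance ratio itself is noisy; abundance measurement error
  propagates into $k_{deg}$ with a gain of about 1.1.
* $\pi_0$ estimation needs hundreds of p-values to be stable; below ten it
  deliberately degrades to Benjamini–Hochberg.
* The normalization emulates, but is not bit-identical to, the inter-sample
  ratio normalization of commercial LFQ software.
* Whether the nominal media D2O fraction equals the effective precursor
  enrichment is an assumption; both `dh_exp` and `dh_nat` are overridable
  everywhere they appear.
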