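---
title: "Quantifying isotope incorporation from paired density gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying isotope incorporation from paired density gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement

Stable isotope probing (SIP) asks which members of a microbial community
incorporate carbon from a particular substrate. A community is amended
with a \eqn{^{13}}C-labeled substrate (here naphthalene, a model
polycyclic aromatic hydrocarbon), and in parallel with the identical
unlabeled substrate as a control. Organisms that assimilate
substrate-derived carbon build it into their DNA; \eqn{^{13}}C-DNA is
denser than \eqn{^{12}}C-DNA, so after isopycnic CsCl
ultracentrifugation a labeled taxon's DNA bands at a higher buoyant
density than the same taxon's DNA from the control incubation.

The quantitative (Tag-SIP / qSIP) variant sequences 16S-rRNA amplicons
from *every* density fraction of both gradients, so each taxon gets a
full density distribution in each gradient, rather than a binary
"heavy"/"light" call. This is what makes the method robust to GC
content: high-GC DNA is intrinsically dense, but GC affects both
gradients equally, so the *paired difference* of a taxon's distributions
isolates isotope incorporation.

```{r setup}
library(tagsip)
```

## From refractometer to density axis

Each fraction's buoyant density is measured by refractometry and
converted with the linear calibration

$$\rho = 10.927\, n_c - 13.593 \;\; \mathrm{g/ml},$$

implemented in `refraction_to_density()`. `read_gradient_table()`
applies it when a table carries only `n_c`. Densities must be strictly
monotone along the fraction order; a heavy-to-light collection order is
accepted and reordered. No temperature correction is applied to the
refractometry — input readings are assumed instrument-corrected.

## The shift statistic

For one gradient and one OTU, `build_distribution()` converts counts to
a DNA-mass distribution over fractions. In fraction $f$ with total reads
$N_f$ and DNA mass $d_f$, the OTU's estimated DNA mass is
$(c_{f}/N_f)\,d_f$ — relative amplicon abundance scaled by how much DNA
the fraction actually held — and the masses are normalized to sum to 1
over the gradient. Scaling by DNA mass before the final normalization
matters: fractions at band tails hold little DNA, and treating their
relative abundances at face value would over-weight them.

The taxon's location in each gradient is the weighted mean density
$WM = \sum_f \rho_f\, p_f$ (`weighted_mean_density()`), and the
statistic is the paired difference
$\mathrm{delWM} = WM_{13C} - WM_{12C}$. A shift is called significant
when

* $\mathrm{delWM} > 0.005$ g/ml (one-sided — labeling can only increase
  density), and
* the OTU's distribution is indistinguishable from a normal band in
  **both** gradients (Kolmogorov–Smirnov filter at $\alpha = 0.05$).

The one-sided threshold of 0.005 g/ml corresponds to roughly 9 atom
percent excess across realistic marine GC contents (next section), so
calls below it would be within gradient-to-gradient technical noise.
OTUs with fewer than 10 reads summed over both gradients are removed,
and only the 200 most abundant OTUs (ranked on the union of the pair,
ties broken by OTU id) are analyzed; both cutoffs follow standard
amplicon-SIP practice and are configurable in `analysis_config()`. No
multiple-testing correction is applied; the output table carries the raw
KS p-values so users can re-filter.

### The KS normality filter, concretely

A per-fraction weighted distribution is not a sample, so the classical
KS recipe needs a stated construction. `ks_normality()` compares the
weighted step CDF against a normal CDF with the distribution's own
weighted mean and SD, evaluated at the fraction densities (both sides of
each step), and converts the largest discrepancy $D$ to a p-value with
the asymptotic Kolmogorov distribution using effective
$n$ = number of fractions carrying weight. This is deterministic — no
pseudo-sampling — and conservative at a typical 10–30 supporting
fractions. Distributions with fewer than 4 supporting fractions are
"untestable" and fail the filter (they cannot support a normality
claim), as does a zero-variance point mass.

## Shift to excess atom fraction

`excess_atom_fraction()` converts delWM to the excess atom fraction
(EAF) of \eqn{^{13}}C in the taxon's DNA carbon, via the GC-dependent
molecular-weight model of the qSIP framework:

1. GC from the unlabeled position: $G = (WM_{12C} - b_G)/m_G$ with
   defaults $m_G = 0.083506$, $b_G = 1.646057$ g/ml;
2. light molecular weight $M_{light} = 0.496\,G + 307.691$ g/mol;
3. labeled molecular weight
   $M_{lab} = M_{light}\,(1 + \mathrm{delWM}/WM_{12C})$;
4. $EAF = \dfrac{M_{lab} - M_{light}}{N_C(G)\,\Delta m}\,(1 - a_{nat})$,
   with $N_C(G) = 10 - 0.5\,G$ carbons per average nucleotide (A, T, G
   carry 10 carbons; C carries 9), $\Delta m = 1.003355$ g/mol and
   natural abundance $a_{nat} = 0.011112$.

All constants are arguments of `labeling_model()` and are logged with
every pipeline run. EAF is exactly linear in delWM at fixed light
density, negative shifts map to negative EAF (control–control
comparisons stay centered on 0), and the conversion is insensitive to
GC over the marine density range:

```{r}
m <- labeling_model()
round(100 * excess_atom_fraction(c(1.68, 1.70, 1.72), 0.005, m), 2)
```

A shift right at the significance threshold is ~9 atom percent excess
regardless of the GC assumption, which is why no per-taxon GC input is
required. `density_shift_for_eaf()` is the exact inverse and drives the
simulator.

## The gradient simulator

`simulate_pair()` is the package's testbed: every claim the analysis
makes is checked against gradients whose truth is known.

* **Band shape.** Each taxon bands as a Gaussian in density — the
  diffusion–sedimentation equilibrium approximation — centered at
  `gc_to_density(gc)` in the control and shifted by
  `density_shift_for_eaf()` in the labeled gradient. The default band
  SD of 0.006 g/ml is an assumption (no in-gradient measurement of band
  spread exists to calibrate it) and is per-taxon configurable.
* **Fraction masses** integrate the band over each fraction's half-open
  density interval rather than point-sampling midpoints, so mass is
  conserved exactly.
* **Sequencing** is a per-fraction multinomial of 20,000 reads (each
  fraction is its own library); **DNA quantification** gets lognormal
  noise at 5% CV; **refractometry** gets Gaussian noise of 1e-4
  refractive-index units (~1.1e-3 g/ml). Because fraction order is
  known from collection, the noisy density readings are sorted into
  increasing order — the minimal monotone repair of measurement noise.
* A small uniform **carryover mass** (1e-4 of the total) is smeared
  across all fractions, reflecting that real fraction libraries always
  yield some reads; its effect on weighted means is below 1e-5 g/ml.

`study_community()` draws the default ground truth: 200 taxa, lognormal
relative abundances (sdlog 1.5, giving ~20 taxa above 1%), GC uniform on
[0.32, 0.62], 30 labeled taxa at EAF uniform on [0.09, 0.55], with the
two most abundant taxa heavily labeled (0.53 and 0.47) in the image of
dominant primary degraders. `make_study_fixture()` writes the pair plus
its truth table deterministically.

What the simulator does **not** emulate: PCR/primer bias, chimeras,
compositional coupling between taxa beyond the multinomial, gradient
smile/curvature, or partial labeling heterogeneity within a taxon.
Passing the recovery tests therefore demonstrates correctness of the
statistics under the stated noise model, not immunity to amplicon
artifacts — the KS filter exists precisely because real data contain
distribution shapes the simulator never produces.

Performance of the full loop at study scale (50 fractions, 200 taxa,
2 × 10⁶ reads per gradient pair) is a fraction of a second per
replicate, so the validation suites run 20-seed batteries by default.

## Tracer uptake rates

`uptake_rate()` computes substrate-carbon incorporation from bulk
particulate-carbon isotope ratios by two-pool mixing:

$$\mathrm{rate} =
 \frac{POC\,(AF_t - AF_{t0})}{(AF_{sub} - AF_{t0})\,\Delta t}
 \Big/ \; \mathrm{carbons\ per\ molecule}.$$

Inputs are assumed to be instrument-corrected atom fractions; the
substrate lot's atom fraction defaults to 0.99 and is configurable.
Negative enrichment is reported as rate 0 with a below-detection flag.
Filter-retention losses are not corrected, so rates are conservative
(likely underestimates). `check_amendment()` converts a solubility in
mg/l to μM and confirms the amendment stays well below it (400 nM
naphthalene vs ~234 μM solubility, a ~585-fold margin).

## Coverage response of MAGs

`q2q3_mean_coverage()` summarizes a genome's per-base coverage by the
mean of the middle two quartiles of positions (`floor(n/4)` trimmed per
tail, ties broken by position), which ignores conserved genes and
genomic islands. `normalize_and_test()` normalizes to library depth
(per million reads), log-transforms with a pseudocount of 1 (both
configurable), and applies a one-sided rank-sum test (amended > t0):
exact null for groups up to 8 (via the Wilcoxon distribution, or
midrank permutation enumeration under ties), normal approximation
beyond. With 3 amended vs 3 baseline samples the best achievable
p-value is exactly 0.05, which does not pass a strict p < 0.05 bar —
at least 4 samples in one group are needed for a call.

`gene_cell_fraction()` estimates how many cells carry a gene from its
read fraction against a benchmark fraction (default 0.1%, a
conservative 16S-like single-copy benchmark): assuming one copy per
cell and one read per copy, the cell fraction is read fraction /
benchmark fraction. Dropping either assumption lowers the estimate.

## Numerical choices and edge cases

* Fractions holding less than 0.1 ng DNA (configurable) are excluded
  from distributions but kept in files, mirroring "fractions with
  detectable DNA".
* `delta_wm` uses each gradient's own density axis; weighted means need
  no inter-gradient alignment or interpolation.
* The Kolmogorov survival function is evaluated as its alternating
  series truncated at k = 101, with p clamped to [0, 1] and p = 1 below
  λ = 0.05; it agrees with `stats::ks.test`'s asymptotic p to ~1e-5.
* OTUs absent from one gradient of a pair are reported with `NA`
  statistics and `significant = FALSE`, never dropped silently.
* The EAF↔shift conversion round-trips to 1e-12 relative precision for
  EAF ≥ 0.01; below that, double-precision cancellation dominates.
* All randomness flows through explicit integer seeds;
  `make_study_fixture()` and `run_pipeline()` are byte-reproducible.

## Limitations

The pipeline takes OTU tables and coverage summaries as inputs: read
QC, clustering, assembly, binning and annotation live upstream. EAF
assumes complete equilibrium banding and a single labeling state per
taxon; partially labeled subpopulations bias EAF toward their
abundance-weighted mean. \eqn{^{18}}O and \eqn{^{15}}N labeling use
different molecular-weight arithmetic and are out of scope. No
bootstrap confidence intervals on EAF are provided yet.
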