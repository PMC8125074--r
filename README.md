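# tagsip

Quantitative stable isotope probing (Tag-SIP / qSIP) analysis of paired
¹³C/¹²C isopycnic CsCl gradient fractionations, for microbial ecologists
asking *which taxa incorporate carbon from a labeled substrate* — e.g.
which rare members of a harbor seawater community degrade naphthalene.

Organisms that assimilate ¹³C build it into their DNA, which then bands
at a higher buoyant density. Sequencing amplicons from every density
fraction of a labeled gradient and its unlabeled control gives each
taxon a density distribution in each; `tagsip` computes, per OTU:

- the DNA-mass-normalized density distribution
  `p_f ∝ (count_f / total_reads_f) · dna_f`, summing to 1;
- the weighted mean density `WM = Σ ρ_f p_f` in each gradient and the
  paired shift `delWM = WM(¹³C) − WM(¹²C)`;
- a significance call: `delWM > 0.005 g/ml` with the distribution
  indistinguishable from a Gaussian band in both gradients
  (Kolmogorov–Smirnov filter, α = 0.05);
- the excess atom fraction (EAF) of ¹³C implied by the shift, via the
  GC-dependent DNA molecular-weight model
  `EAF = (M_lab − M_light) / (N_C(G)·Δm) · (1 − a_nat)` with
  `M_lab = M_light (1 + delWM/WM₁₂C)` — the 0.005 g/ml threshold
  corresponds to ≈9 atom percent excess across marine GC contents.

Because GC-driven density differences affect both gradients equally,
the paired shift is immune to GC bias: a high-GC unlabeled taxon bands
denser than a low-GC labeled one, yet only the latter shows a shift.

The package also covers the study-level side computations — tracer
mass-balance substrate uptake rates from particulate-carbon isotope
ratios, quartile-trimmed (Q2Q3) MAG coverage response tests, and
single-copy-gene cell-fraction estimates — plus a forward simulator of
paired gradients (`simulate_pair()`) that backs every statistical claim
with known-truth data.

## Worked example

Simulate a study-like community (200 taxa, 30 labeled, two dominant
heavily labeled degraders) and analyze it:

```r
library(tagsip)

fx  <- make_study_fixture(seed = 20210515, dir = "results/fixture")
out <- run_pipeline(list(labeled = fx$paths[["labeled"]],
                         control = fx$paths[["control"]],
                         out_dir = "results/shift", seed = 20210515))
summary(out$results)
#> $n_analyzed          [1] 200
#> $n_passed_normality  [1] 200
#> $n_significant       [1] 30
```

All 30 truly labeled taxa are recovered with no false positives among
the 170 unlabeled taxa, and the two dominant degraders come back at
their true enrichment:

```
Dominant degraders: OTU095 delWM 0.0288 g/ml -> 53 APE (truth 53);
                    OTU141 delWM 0.0256 g/ml -> 47 APE (truth 47)
Mean |EAF error| for taxa >= 1% abundance: 0.0059
```

`delWM 0.0288 g/ml` is the dominant degrader's buoyant-density shift;
at its unlabeled density that converts to 53 atom percent excess —
over half of its DNA carbon was substrate-derived. The same sequence of
steps, with narrative output, lives in the numbered drivers under
`analysis/`:

```sh
Rscript analysis/01_simulate_gradients.R   # paired-gradient fixture + truth
Rscript analysis/02_shift_analysis.R       # shift statistic, EAF, figure
Rscript analysis/03_uptake_rates.R         # tracer mass-balance rates
Rscript analysis/04_coverage_response.R    # Q2Q3 coverage response calls
```

For instance step 3 computes, from a synthetic IRMS measurement table
emulating the study design (400 nM amendment, 3 replicates/site):

```
POLA: 34.6 nM naphthalene/day (SD 14.34, n = 3) -> 9% of the 400 nM amendment per day.
SPOT: below detection (all replicates at baseline).
Amendment check: 400 nM vs 234 uM solubility (ratio 585) -> fully dissolved.
```

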