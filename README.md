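# memoryswitch

Kinetic modeling and single-cell inference of hormone-induced
transcriptional memory.

Ecdysone-inducible genes in *Drosophila* S2 cells respond to a second
hormone exposure much more strongly than to the first, a Nup98-dependent
behavior called transcriptional memory. `memoryswitch` implements the
quantitative pipeline used to dissect this behavior from bulk qPCR and
single-molecule FISH (smFISH) data, for computational biologists who want
to simulate, fit and interrogate promoter-state models of inducible
transcription:

* **Promoter models** — a two-state telegraph model with slow activation
  (rate *k_A*, constant loading rate *k_pol*), a two-state model with
  immediate activation and linearly accelerating loading attempts
  (*α·t*, capped by a Pol II footprint *s* at elongation speed *v*:
  effective rate *λ/(1+λs/v)*), and the four-state **memory switch**:
  Uninduced/Induced × Default/Memory, with slow default→memory conversion
  *k_C* that continues after hormone withdrawal and loading rates
  *k_polB* (uninduced), *k_polL* (induced default) and *k_polH* (induced
  memory, 15-fold above default at the fitted values).
* **Monte Carlo simulator** — per-nucleotide Pol II traffic with steric
  exclusion on a probe-tiled gene, rendered as smFISH "cytoplasmic units"
  (C.U., single-mRNA equivalents); event-driven and fixed-step
  (dt = 1/1500 min) engines that agree in distribution; mixed-ploidy
  populations (half 4, half 8 loci per cell) with Poisson initial mRNA
  counts, first-order decay, and an analytic shortcut for the 24-hr
  recovery between inductions.
* **Bulk models** — closed-form and ODE mean-accumulation curves,
  exponential-decay lifetime fits, and nonlinear regression of production
  parameters with 95% confidence intervals.
* **Absolute qPCR calibration** — standard curves (Ct vs log10 copies,
  fixed-slope variant), mass→copies via the RNA standard molecular weight,
  and per-cell normalization with extraction-loss correction.
* **Distribution inference** — Jaccard-index overlap of log(C.U.)
  histograms as the goodness-of-fit score, two-stage grid search with
  edge-aware refinement, and bootstrap confidence intervals.
* **Memory metrics** — Calibrated Memory Index (CMI = F·M_I/R with
  F = 1 − M_N/M_C, R = M_C − M_N), induction slopes, nascent-site
  classification on spot tables (3 C.U. threshold with random rescue),
  active-loci fractions, cytoplasmic mRNA fraction.
* **Synthetic data** — generators for qPCR series, standard dilutions and
  smFISH populations/spot tables with known ground truth, so the whole
  pipeline is testable without external data.

## Worked example

Simulate the standard two-induction protocol (4 hr hormone, 24 hr
recovery, 4 hr re-induction) under the fitted memory-switch parameters and
look at the population's nascent activity:

```r
library(memoryswitch)

spec   <- promoter_model_spec("memory_switch")
params <- kinetic_params()        # fitted E74 values
gene   <- default_gene()          # 4500 nt, 67 probes

pop <- simulate_population(spec, params, gene, standard_protocol(),
                           n_cells = 2000,
                           sample_times = c(60, 120, 240, 1740, 1800, 1920),
                           seed = 3)
aggregate(nascent_cu ~ induction + time_min, pop, mean)
#>   induction time_min nascent_cu
#> 1         1       60   2.293955
#> 2         1      120   4.019075
#> 3         1      240   6.645082
#> 4         2     1740  13.375485
#> 5         2     1800  18.577858
#> 6         2     1920  21.599440
```

The second induction (time points 1740/1800/1920 = 1/2/4 hr after
re-exposure) is several-fold more active than the first at matched times:
74% of loci converted to the high-expressing memory state during the
first induction plus recovery,

```r
round(100 * memory_fraction(params$k_C, 1680))   # 4 hr + 24 hr, in minutes
#> [1] 74
```

and converted loci load Pol II at `k_polH = 4.5` instead of
`k_polL = 0.3` per minute. Fitting the conversion rate back from such a
population by Jaccard-overlap grid search (`grid_search()`) recovers
`k_C` within the reference confidence width; see the vignette for the
inference design.

Memory metrics work on plain slope inputs:

```r
cmi(m_c = 3, m_n = 1, m_i = 2)
#> $F        0.6666667
#> $R        2
#> $cmi      0.6666667
#> $cmi_alt  0.5
```

A thin command-line wrapper over the same functions is installed with the
package (`system.file("cli", "memoryswitch.R", package = "memoryswitch")`)
with subcommands `simulate`, `synth`, `fit-bulk`, `fit-dist`, `calibrate`
and `metrics`.

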