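---
title: "Kinetic models of hormone-induced transcriptional memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic models of hormone-induced transcriptional memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memoryswitch)
```

## The biological problem

Ecdysone-responsive genes in *Drosophila* S2 cells respond to a second
hormone exposure faster and more strongly than to the first. This
*transcriptional memory* depends on the nuclear pore component Nup98 and
persists through a 24-hr hormone-free recovery. `memoryswitch` implements
the quantitative machinery needed to study this behavior: stochastic
simulation of promoter states and RNA Pol II traffic rendered in
single-molecule FISH units, bulk mRNA accumulation models for qPCR time
series, absolute qPCR calibration, distribution-overlap inference, and
derived memory statistics.

## Promoter models

Three promoter models are supported (`promoter_model_spec()`):

* **Two-state Model 1** — loci switch from inactive to active at rate
  $k_A$ (irreversibly while hormone is present, since $k_{-A} \ll k_A$),
  and active loci load Pol II at a constant rate $k_{pol}$. The mean
  per-locus production rate is $k_{pol}\,(1 - e^{-k_A t})$.
* **Two-state Model 2** — activation is effectively immediate
  ($k_A$ = 1000/min) and the Pol II *attempt* rate grows linearly,
  $\lambda(t) = \alpha t$. Loading is limited by a minimum spacing $s$
  between elongating polymerases (the footprint), giving the mean-field
  successful rate $\lambda/(1 + \lambda s/v)$, capped at $v/s$.
* **Memory switch** — four states from two independent binary coordinates:
  Uninduced/Induced (rate $k_A$, hormone-gated) and Default/Memory (rate
  $k_C$, started by the first hormone exposure and, in control cells,
  continuing after withdrawal). Loading rates are $k_{polB}$ (uninduced),
  $k_{polL}$ (induced default) and $k_{polH}$ (induced memory). Because
  activation and conversion are independent per locus, occupancies
  factorize and the mean rate is
  $f_A (f_M k_{polH} + (1-f_M) k_{polL}) + (1-f_A) k_{polB}$.

Default parameter values (`kinetic_params()`) are the fitted E74 values:
$k_A = 17\times10^{-3}$/min, $k_C = 0.8\times10^{-3}$/min,
$k_{polL} = 0.3$ and $k_{polH} = 4.5$ Pol II/min (a 15-fold memory
speed-up), $k_{pol} = 2.0$ Pol II/min and
$\alpha = 11.7\times10^{-3}$ Pol II/min² for the two-state fits,
elongation $v = 1500$ nt/min. The closed-form conversion fraction
$1 - e^{-k_C t}$ then implies 62% of loci converted after 20 hr, 74%
after a 4-hr induction plus 24-hr recovery, and 90% after 48 hr:

```{r memory-fractions}
round(100 * memory_fraction(0.8e-3, c(1200, 1680, 2880)))
```

Nup98 is modeled through the reversion rate $k_{-C}$: in control cells
$k_C \gg k_{-C}$ and memory persists; under Nup98 depletion, withdrawal of
hormone makes $k_{-C} \gg k_C$, which we implement as instantaneous
reversion of all memory at washout. Transcription inhibitors (flavopiridol,
triptolide) zero every Pol II loading rate but leave $k_A$ and $k_C$
untouched — the model's central claim is that memory conversion is
independent of transcription itself. `tpl_kc_factor` optionally scales
$k_C$ under triptolide (default 1, i.e. no effect), since initiation
blocking empirically removes a minor part of memory.

## The simulator and its two engines

`simulate_locus()` and `simulate_population()` evolve Pol II positions on a
gene (`gene_model()`), loading new polymerases at position 0 when no
polymerase occupies the first `footprint_nt` nucleotides, elongating
deterministically at $v$, and evicting polymerases (and crediting one
completed mRNA) at the gene end. Two engines share this contract:

* a **fixed-step** engine updating every $1/v$ min (the time to transcribe
  one nucleotide) with Bernoulli transition draws — the transparent
  reference implementation, used as the oracle on short runs;
* an **event-driven** engine drawing exponential waiting times for promoter
  transitions and loading attempts (with thinning for the time-varying
  Model 2 rate) — equivalent in distribution and much faster, the default.

Both use R's RNG, so seeded runs are exactly reproducible. The test suite
checks Little's law (mean Pol II occupancy $k_{pol} L / v$ for a forced
active locus with negligible footprint), the packing bound $L/s$, minimum
spacing, and distributional agreement between the engines.

Nascent signal is rendered in *cytoplasmic units* (C.U.): each Pol II
contributes the number of probe binding sites already transcribed divided
by the probe count of a finished mRNA, so one fully synthesized transcript
equals exactly 1 C.U. The default synthetic gene is 4500 nt with 67
uniformly spaced exonic probes; the true probe coordinates are not public
and only the relative layout matters, so both are configurable.

Populations mix ploidy: half the cells carry 4 loci (G1) and half 8 (G2),
i.e. 6 per cell on average, the same assumption used by the bulk fits.
Mature mRNA counts start from a Poisson draw (uninduced mean 2 puncta by
default; the true value is not tightly constrained and is configurable) and decay
with a configurable lifetime `tau` (default 600 min; measured E74
lifetimes are not pinned to a single value, so this is a setting, not a
constant). Hormone-free recovery periods
are not simulated at nucleotide resolution: `apply_recovery_shortcut()`
reassigns memory per locus as a Bernoulli draw with the closed-form
converted fraction at the total elapsed time since the first hormone
addition, resets the active state, clears nascent polymerases and decays
mature pools analytically.

## Bulk accumulation models

For qPCR time series the package provides closed forms for constant
(`mean_constant_production()`) and linearly increasing
(`mean_linear_production()`) production, and `mean_model_curve()`
integrates $dm/dt = n_{loci}\, r(t) - m/\tau$ for any promoter model.
Fitting is two-stage, as in standard practice: the lifetime $\tau$ comes
from a post-shutoff decay fit (`fit_degradation()`), then production
parameters are estimated with $\tau$ fixed (`fit_accumulation()`).
Because qPCR replicate noise is multiplicative, `fit_degradation()` refits
with $1/\hat m^2$ weights (relative least squares) so that the asymptotic
Jacobian confidence intervals are calibrated; the test suite verifies
≥ 90% empirical coverage over 200 seeded replicates at 5% noise.
Confidence intervals are $\pm 1.96\,\mathrm{SE}$ from the Gauss–Newton
covariance throughout.

## Distribution fitting by histogram overlap

Single-cell inference compares per-cell total nascent activity
distributions on the $\log_{10}$(C.U.) axis. `cu_histogram()` uses
identical-width bins plus an underflow pseudo-bin for inactive cells
(default domain: 30 bins from $\log_{10} 0.5$ to the pooled observed
maximum — bin edges are shared between simulation and observation because
the score depends on them). `jaccard_score()` sums intersection areas over
all time points and divides by the summed unions (a per-time average is
available via `pooled = FALSE`; the pooled reading was adopted as the more
literal one, and the choice does not change the location of the optimum in
our tests).

`grid_search()` maximizes the score over free kinetic parameters in two
phases: a coarse log-spaced grid across the canonical search bounds
($10^{-8}$–$1$/min for first-order rates, $10^{-7}$–$10$/min for loading
rates), then local linear grids around the running optimum. Each
refinement halves its relative span, and a stage whose optimum lands on
the boundary of its local grid is re-centered at constant span before
shrinking — the coarse grid's decade-scale spacing can otherwise strand
the refinement short of the optimum. An optional mean-rate constraint
discards candidates whose analytic production-rate curve deviates more
than 15% RMS from a target curve (emulating the use of prior bulk fits to
cut the search space). `bootstrap_ci()` resamples cells with replacement
within each (induction, time) group and reruns a narrowed search per
resample; 1000 resamples is the canonical default, and examples in this
package use far fewer for speed.

Problem sizes were chosen to keep a desk-scale analysis comfortable while
preserving the inference behavior: observed populations of 10,000 cells
(60,000 loci), 2,000 cells per candidate during coarse search and 8,000
during refinement (the original design used 10,000 and 100,000). At these
sizes the acceptance-level check recovers $k_A$ within $\pm 1\times10^{-3}$
and $k_C$ within $\pm 0.2\times10^{-3}$/min of their generating values —
the reference confidence half-widths for these rates.

## qPCR calibration and memory metrics

Absolute quantification follows the standard-curve route: `fit_log_linear()`
(or `fit_fixed_slope()` when the slope is taken from a DNA standard,
−3.566 for the reference assay) maps Ct to copies (`ct_to_copies()`),
`mass_to_copies()` converts standard masses using the 126,060 g/mol RNA
standard, and `copies_per_cell()` corrects for extraction losses
(recovery 0.44, i.e. 56% losses — "losses" is read as the lost fraction,
and the value is exposed as an argument). A slope of −3.566 is only
meaningful on the canonical Ct-versus-$\log_{10}$(copies) scale, which is
what is implemented.

The Calibrated Memory Index compares second-induction slopes
(`fit_induction_slope()`, OLS over the full 0–240 min window) in control
($M_C$), Nup98-depleted ($M_N$) and inhibitor-treated ($M_I$) cells. The
reference formula compresses to $CMI = F \cdot M_I / R$ with
$F = 1 - M_N/M_C$ and $R = M_C - M_N$; this literal form is exactly 1
when $M_I = M_C$ but equals $M_N/M_C$ (not 0) when $M_I = M_N$, which
conflicts with the stated "zero under Nup98-depletion" anchor. Rather than
guess the intended algebra, `cmi()` returns the literal form as `cmi` and
the anchored alternative $(M_I - M_N)/R$ as `cmi_alt`.

Spot-table utilities reproduce the image-analysis conventions on tabular
input: `classify_nascent_sites()` flags nuclear spots at ≥ 3 C.U. and, in
nuclei with fewer than three supra-threshold spots, randomly promotes one
or two further nuclear spots (count uniform on {1, 2}, spots uniform —
the distribution of the rescue is a convention); `active_loci_fractions()`
and `cytoplasmic_fraction()` summarize flagged tables.

## Synthetic data and what passing tests do (and do not) show

`synthetic_scenario()` bundles model, protocol and noise settings;
generators return data plus ground truth. qPCR replicates apply unit-mean
log-normal noise (default CV 10%, 2% in the parameter-recovery checks);
smFISH spot intensities are log-normal around 1 C.U. with sdlog 0.25; a
mature mRNA is cytoplasmic with probability 0.87. The generators emulate
the data-generating assumptions of the models themselves — mixed ploidy,
Poisson initial counts, exponential decay, footprint-limited loading. They
do not emulate segmentation errors, spot-detection misses, optical
crowding at high expression, cell-to-cell extrinsic variability beyond
ploidy, or cell division during recovery. Parameter-recovery results
therefore demonstrate the correctness and identifiability of the inference
machinery under the stated model, not robustness to real-image artifacts.

## Numerical choices and limitations

* Fixed-step transition probabilities must satisfy rate·dt ≤ 1; the engine
  stops with an error naming the offending rate.
* The ODE integrator (`deSolve::lsoda`, rtol = atol = 1e-9) agrees with
  the closed forms to < 1e-6 relative error.
* The mean production rate ignores footprint exclusion for Model 1 and the
  memory switch (their fitted rates are ≤ 4.5 Pol II/min against a packing
  cap of 10/min, and the analytic forms are defined that way); Model 2
  applies the mean-field saturation by construction. Analytic-vs-simulated
  mean comparisons in the tests therefore use a negligible footprint.
* The Pol II footprint is not well constrained by available estimates; the
  default is 150 nt and it is configurable everywhere.
* Ties in the Jaccard grid search resolve to the first maximum in grid
  order; the surface is reproducible bit-for-bit under a fixed seed.
* Homologous loci are modeled as independent; chromosome pairing affects
  image-based site counting but not per-cell summed activity.
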