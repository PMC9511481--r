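---
title: "Quantifying ligand bias from kinetic recruitment assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ligand bias from kinetic recruitment assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligandbias)
```

## The problem

Agonists of G-protein-coupled receptors can activate different intracellular
transducers to different extents: at the serotonin 2A receptor (5-HT2AR), a
ligand may recruit β-arrestin-2 (βarr2) more strongly than the Gαq pathway,
or vice versa. This *functional selectivity* (biased agonism) is measured
with two parallel split-luciferase (NanoBiT-style) recruitment assays — one
with βarr2 and one with a miniGαq sensor — in which receptor activation
reconstitutes a luciferase and produces a kinetic luminescence signal.
`ligandbias` implements the complete numeric path from raw plate traces to
bias factors with significance calls, plus a synthetic study generator that
provides ground-truth data for validating every stage.

## From traces to responses

Each well yields a time–luminescence trace spanning an equilibration phase
and a 2 h post-agonist window. Processing has a fixed, enforced order:

1. **Interwell correction** (`correct_interwell()`): every reading is
   divided by the well's mean pre-injection signal, removing multiplicative
   well-to-well differences (cell number, substrate, optics). After this
   step all wells have pre-injection mean exactly 1. Wells with a
   non-positive pre-injection mean cannot be scaled and are dropped with a
   warning.
2. **AUC** (`compute_auc()`): the trapezoid rule on the observed time points
   over the post-injection window (default 7200 s). The quadrature rule is
   not dictated by the assay; the trapezoid is standard, exact for
   piecewise-linear signals, and matches the simulator's analytic integral
   to 0.1% at 60 s reads.
3. **Solvent subtraction** (`subtract_solvent()`): the mean AUC of the
   matched agonist-free control wells (same experiment, pathway and
   receptor variant) is subtracted; control wells are consumed. Negative
   corrected AUCs are retained — clipping would bias the fitted bottom
   upward.
4. **Normalization** (`normalize_to_reference()`): within each experiment
   (and pathway and variant), the reference agonist's maximal response is
   set to 100%. "Maximal response" is the mean corrected AUC at the
   reference's plateau concentration, taken as its highest tested
   concentration unless the configuration designates another; if plateau
   wells are missing, the maximum per-concentration mean is used with a
   warning. Normalization is per experiment because the reference agonist
   is included in every experiment precisely to anchor it.

The stage of a table is tracked internally; calling a step out of order is
an error rather than a silent misuse, while re-normalizing an already
normalized table is idempotent.

## Concentration–response model

Potency and efficacy come from the three-parameter logistic with Hill slope
fixed at 1, the standard agonist model when fitting a single transducer
assay:

$$ y(c) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
         {1 + \mathrm{EC_{50}}/c}. $$

The three parameters are bottom, top (= Emax) and $\log_{10}\mathrm{EC_{50}}$,
fitted by least squares in log-concentration space. For fixed
$g = \log_{10}\mathrm{EC_{50}}$ the model is linear in (bottom, top), so the
optimizer scans a deterministic grid of $g$ values (0.25-log steps spanning
the tested range ± 2 decades), solves the other two parameters in closed
form at every grid point, and refines the best point with a 1-D minimizer.
By construction the result can never be worse than a grid search, and on
noiseless data it recovers generating parameters to better than $10^{-6}$
relative error.

A fit is reported **n.d.** (not determined) when

* the response is not distinguishable from flat — operationalized as the
  profile-likelihood interval of the span (top − bottom) including 0 at the
  95% level, checked via the equivalent F-threshold comparison of the flat
  model's RSS; or
* the fitted EC50 exceeds the highest tested concentration, i.e. no plateau
  was reached inside the tested range (the situation of very weak partial
  agonists).

n.d. propagates: every quantity derived from an n.d. fit is n.d., never a
silent number.

**Confidence intervals** are profile-likelihood intervals: parameter values
whose profiled RSS stays below
$\mathrm{RSS}_{\min}\,(1 + F_{1-\alpha}(1, n-3)/(n-3))$. They are
asymmetric, which matters for EC50s whose printed intervals routinely span
an order of magnitude; Wald intervals would misrepresent that. A bound not
reached within the search range (± 15 decades for EC50) is reported as
n.d. rather than extrapolated. Pooled ("combined") fits use all
experiments' points with equal weight; per-experiment fits feed the bias
statistics.

## Bias statistics

For each pathway the intrinsic relative activity versus the reference
agonist is

$$ \mathrm{RA_i} = \frac{E_{\max}\cdot \mathrm{EC_{50}^{ref}}}
                        {E_{\max}^{ref}\cdot \mathrm{EC_{50}}}, $$

and the bias factor combines the two pathways:

$$ \beta = \log_{10}\frac{\mathrm{RA_i^{\beta arr2}}}{\mathrm{RA_i^{miniG\alpha_q}}}. $$

The base-10 logarithm is fixed by validating recomputed β values against
the published per-compound bias factors (the natural log would be off by a
factor of 2.3). β is 0 for the reference by construction, positive for
βarr2 preference, antisymmetric under pathway exchange, and invariant to
any common rescaling of the normalized response axis.

The reported β is the **mean of per-experiment values**, each experiment's
compound fits compared against the *same experiment's* reference fits — this
within-experiment pairing is what distinguishes the averaged β from the
combined-fit β and makes it robust to inter-experiment scale drift. The
combined β from pooled fits is reported alongside; the two coincide exactly
when there is no inter-experiment heterogeneity. A compound needs at least
3 experiments with determined fits in both pathways, else its β is n.d.

**Significance** versus the reference uses the nonparametric route: an
omnibus Kruskal–Wallis test across all compounds' per-experiment β sets
(midranks with tie correction; the degenerate all-tied case is defined as
p = 1), then Dunn's post hoc rank comparison of each compound against the
reference group. Dunn's test is implemented directly (pairwise z statistics
on joint mean ranks with the standard tie-corrected variance). The
multiplicity adjustment over the compound-vs-reference family is Holm by
default and configurable — the adjustment behind published Dunn p-values is
rarely stated, and Holm is uniformly valid without independence
assumptions. Stars follow the usual tiers (`*` p < 0.05, `**` p < 0.01).
With n = 3 experiments per group the rank tests are extremely conservative;
that is a property of the design, not of the implementation.

**Mutant comparisons** (`compare_variants()`) summarize a receptor mutation
as the potency fold-change EC50(mutant)/EC50(WT) and the efficacy drop
Emax(WT) − Emax(mutant) in percentage points. These use point estimates:
a fit whose confidence interval is undetermined can still contribute its
reported EC50/Emax, matching how such fold-changes are quoted in practice.

**Bias plots** pair the per-concentration mean normalized responses of the
two assays at equimolar concentrations (βarr2 on x, miniGαq on y, SEM per
point) and draw a centered quadratic
$y = a + b\,(x-\bar x) + c\,(x-\bar x)^2$ fitted by ordinary least squares.
The quadratic is a descriptive smoother, not a model; the numeric series is
the tested artifact and plotting is a thin optional layer.

## The synthetic study generator

`simulate_study()` emulates the assay design: a nine-point decade dilution
series from 1 pM to 10 µM topped with 25 µM, duplicate wells, at least
three independent experiments, solvent controls per condition, reference
agonist in every experiment, and 2 h of post-injection monitoring. The
noise-free trace of a well is

$$ L(t) = B e^{-k_d t} + B\,\frac{E_{\max}}{100}\,\mathrm{occ}(c)\,
   \bigl(1 - e^{-k_r (t - t_{inj})}\bigr) e^{-k_d (t - t_{inj})},
   \quad t \ge t_{inj}, $$

with occupancy $\mathrm{occ}(c) = c^{h}/(c^{h} + \mathrm{EC_{50}}^{h})$
(Hill $h = 1$ by default). The rise–decay envelope reproduces the shape of
live-cell luciferase signals — fast complementation rise against slow
substrate-consumption decay — while keeping every AUC analytically
checkable. Defaults: baseline $B = 10^4$ counts, rise $k_r = 1/300$ s⁻¹
(signal develops over minutes), decay $k_d = 10^{-4}$ s⁻¹ (half-life
roughly two hours, the scale over which such assays stay usable).

Noise has three components chosen to mirror what the processing stages
exist to remove: a per-well multiplicative lognormal scale (sdlog 0.10 —
interwell variability, removed exactly by the correction step), additive
Gaussian read noise (sd 100 counts, 1% of baseline — what survives into the
responses), and a per-experiment multiplicative lognormal scale (sdlog
0.15 — why normalization is per experiment). Both lognormals have unit
mean. Equilibration duration (600 s) and read interval (60 s) are not
dictated by the assay description and are configurable assumptions.

Randomness is split counter-based: each well's stream is derived from the
master seed and structural indices (pathway, compound, concentration,
replicate), so identical specs and seeds are bitwise-reproducible and
extending a design never perturbs existing wells.

What the simulator deliberately does **not** model: receptor/transducer
kinetics (no operational model of agonism — the generating curve is exactly
the logistic the fitting stage assumes), substrate chemistry, plate-edge or
drift effects, and non-Gaussian outliers. Passing the recovery and coverage
studies therefore shows the pipeline is correct and calibrated *under its
own assumptions*; it does not certify robustness to real-data pathologies
such as systematic drift or misdispensed wells.

## Validation choices and problem sizes

The test suite validates each stage against independent oracles: closed-form
integrals for AUCs, a dense grid search for the optimizer, direct
re-evaluation of profile thresholds at reported CI endpoints, exact
permutation enumeration for the rank tests, and hand arithmetic on the
packaged published parameter tables for RAi/β/fold-change values. The
Monte-Carlo studies use 200 seeded three-experiment studies for EC50
recovery (median absolute log10 error below 0.1), 1000 seeded fits for
profile-CI coverage (93–97% band around the nominal 95%), and 250 seeded
studies (500 compound calls) for the type-I error of the bias call —
sizes at which Monte-Carlo error is small relative to the tested margins
while the whole suite runs in minutes on one core. Simulated validation
studies use coarser read intervals (240–480 s) than the 60 s default, which
leaves AUCs and downstream statistics essentially unchanged.

## Known limitations

* The Hill slope is fixed at 1 in both generator and fit; strongly
  cooperative responses would need the four-parameter extension.
* RAi-based bias factors are transducer-amplification-agnostic only to the
  extent the reference agonist shares the compounds' amplification; like
  all ΔΔ-style bias metrics they are relative to the chosen reference
  (switching reference shifts every β by a per-study constant, which the
  suite verifies exactly).
* Per-experiment β values with n = 3 give rank tests little power; the
  significance machinery is faithful to that design rather than an attempt
  to improve on it.
* The plate CSV schema is the only ingestion path; vendor exports must be
  converted externally.

## A worked run

```{r, eval = FALSE}
library(ligandbias)

cfg <- default_config()        # LSD reference + one arrestin-biased compound
res <- run_pipeline(cfg, output_dir = "out", seed = 1)
res$report
res$bias[, c("compound", "beta_mean", "beta_combined", "p_vs_reference")]
```

The report table prints EC50s in nM with 95% CIs, Emax with CIs, the
averaged β to three decimals (`n.d.` where undetermined) and significance
stars — the layout of a functional-characterization table.
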