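---
title: "Modeling rib proximal-distal patterning: simulator and measurement model"
author: "ribsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling rib proximal-distal patterning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribsim)
```

## The biological question

Mammalian ribs consist of two skeletal elements: a proximal, bony segment
near the vertebrae and a distal, cartilaginous segment near the sternum.
Both derive from the sclerotome compartment of the somites. `ribsim`
implements a minimal mechanistic account of how the two segments could be
specified and grown: sclerotome progenitors read a graded Hedgehog (Hh)
signal emanating from the axial midline early in development, adopt a
proximal or distal bias at cell division with Hh-dose-dependent
probabilities, and the resulting salt-and-pepper pattern is refined into
two coherent domains by local fate reinforcement (a community effect)
while the field expands under proliferation, transient early cell death,
and crowding-driven spreading inside a bounded space.

The package has two computational halves:

1. **`run_simulation()`** — a stochastic agent-based simulator of the
   outgrowing sclerotome field on a rectangular patch grid.
2. **`fit_measurement_model()`** — a hierarchical Bayesian model that
   estimates, from litter-structured somite measurements, the
   genotype-relative size and proliferation-rate ratios that parameterize
   the genotype presets of the simulator.

A third, supporting piece (`generate_measurements()`) generates synthetic
measurement tables with known ground truth so the estimator can be
validated by parameter recovery, and `expected_genotype_frequency()`
computes exact Mendelian yields for the breeding schemes that produce the
double-knockout embryos.

## The agent-based model

Each cell is an agent with a continuous position `(x, y)` and a fate
state: *undecided*, *proximal*, or *distal*. Space is a bounded
rectangle, by default `x` in `[-16, 40]` and `y` in `[-16, 16]` patch
units, with the Hh source off to the left (peak at `x = -10`) and
outgrowth proceeding to the right. One tick applies four phases in order:
death, division (with fate decisions), community effect, redistribution.
The clock stops when any cell reaches the farthest patch column
(`x >= world_x_max - 1`) or after `nticks` ticks.

### Hh profile and fate decisions

The Hh concentration is static in time and Gaussian in space:

$$C(x) = 10^{\texttt{shh\_intensity\_log}}
  \exp\!\left(-\frac{(x - x_{\text{peak}})^2}{2\,\sigma^2}\right),
  \qquad \sigma = \texttt{shh\_xport}.$$

At division, an undecided cell converts with probabilities governed by
the saturating bias $g = C/(C + K)$, with half-saturation constant
$K = 1$: proximal with probability $p_{\text{red}} \cdot g$, distal with
$p_{\text{blue}} \cdot (1 - g)$, otherwise remaining undecided (a single
categorical draw). Decided cells ignore Hh thereafter — the window of
competence closes at the decision. Daughters inherit the parent's
post-decision state.

The width choice $\sigma = \texttt{shh\_xport}$ deserves a note. With the
normal-genotype settings (amplitude $10^{0.6} \approx 3.98$, extent 12),
the concentration crosses $K$ near $x \approx 10$ — inside the initial
progenitor block, which spans $x \in [0, 14]$. That is the property that
matters: the fate-balance point must fall within the field for a mixed,
two-domain pattern to arise at all. A substantially narrower profile
(e.g. half this width) places the balance point at the very left edge of
the block, biases essentially every progenitor distal, and no setting of
the genotype-level dials can then produce the balanced normal phenotype.

### Proliferation and death

Every agent divides with probability
$0.05 \times \texttt{proliferatemult}$ per tick; daughters are placed at
the parent position plus uniform jitter of at most half a patch per axis.
Death is early and transient: the per-tick death probability is

$$d(t) = 0.05 \times \texttt{celldeathmult} \times
  \exp\!\left(-\tfrac12 \left(\frac{t}{\texttt{cdduration}/2}\right)^2\right),$$

a half-Gaussian peaking at tick 0 with SD `cdduration/2`, so death is
effectively over after about `cdduration` ticks. This encodes the
biology of sclerotome apoptosis: prominent early, waning before
differentiation. `celldeathmult = 0` (the Apaf1-null conditions) switches
death off exactly.

### Community effect

Each decided cell inspects the decided cells within radius 1.5 patches.
If at least 3 are decided and the fraction holding the opposite fate is
at least 0.75 (a supermajority), the cell flips. Updates are synchronous
within the phase, and undecided cells are unaffected — late deciders are
converted by Hh at division, not by neighbors (this choice is
configurable via `community_threshold`, and setting the threshold above 1
disables the rule entirely). The effect of the rule is to erode
salt-and-pepper mixing and sharpen the proximal-distal border; its
bistable character means a run occasionally fixes a single color, which
is visible in the tails of the proximal-fraction distribution across
seeds.

### Crowding-driven spreading

Local density at a point is estimated as the number of cells within
radius 1 patch divided by the disc area $\pi$ — i.e. cells per patch.
Cells above `density_max = 6` cells/patch take one unit step toward the
adjacent patch-direction (of the eight) with the lowest local density,
ties broken uniformly at random. Cells are visited sequentially in a
freshly shuffled order and move immediately, so decompression waves can
propagate outward within a sweep; up to `spread_sweeps = 3` sweeps run
per tick. A sequential update is essential here: with simultaneous
updates, whole crowded clusters chase the same density minima and
translate without decompressing, and the field never reaches its working
density. The initial placement formula (1200 cells in a 14 x 14 block,
about 6.1 cells/patch) starts the field at the top of the 4-6 cells/patch
working band, and spreading holds it near that band as the population
grows. Positions are clamped to the world bounds, so crowding can never
push a cell through the boundary.

### Genotype presets

`genotype_presets()` carries the four calibrated parameter columns:

```{r presets}
t(sapply(genotype_presets(), function(p) {
  unlist(p[c("initsizemult", "shh_intensity_log", "celldeathmult",
             "proliferatemult")])
}))
```

Initial-size and proliferation multipliers are the posterior medians of
the measurement model below; Shh-null genotypes collapse the Hh amplitude
(log10 intensity $-2$, a ~400-fold reduction), and Apaf1-null genotypes
set death to zero.

### What the simulator reproduces

Run across $\ge 20$ seeds per condition, the simulator reproduces the
study-level observations as quantitative properties (these are exactly
the checks in the package's acceptance tests):

- the normal preset forms two contiguous domains with the proximal domain
  at lower `x` and a mean proximal fraction near one half;
- Shh-null presets are essentially all distal (mean proximal fraction
  below 5%);
- final cell counts order as DKO < Shh KO < normal on matched seeds;
- the mean proximal fraction is monotone nondecreasing in Hh intensity
  over log-intensities $\{-2, -1, 0, 0.6, 1\}$;
- disabling the community effect broadens the boundary (larger
  `boundary_sharpness()` width);
- varying `celldeathmult` over $\{0, 0.3, 1\}$ moves the proximal
  fraction by less than 10 percentage points — death reshapes size, not
  proportions.

## Pattern summaries

`fate_fractions()` reports the undecided/proximal/distal composition.
`boundary_profile()` bins agents by `x` (default one patch column) and
reports the proximal fraction among decided agents per bin.
`boundary_sharpness()` reduces a profile to a single width: after
isotonic (decreasing-in-x) smoothing, the x-distance between the 0.75 and
0.25 crossings, linearly interpolated. A perfect step has width at most
one bin; wider is blurrier. The isotonic pre-fit makes the metric robust
to single-bin noise; profiles that never cross both thresholds (single
color, or no pattern) raise an error rather than returning a number.

## The hierarchical measurement model

The measurements are per-somite: a cross-sectional ROI size in pixels,
and a pHH3-positive count out of a total nucleus count, with embryo,
litter and genotype labels. Embryos recorded as heterozygous controls are
labeled `normal` (the reference). Two models are fit by MCMC (JAGS, 4
chains, 2000 iterations each with the first half as warm-up, by
default):

**Size** — log-normal with litter random effects:

$$\log(\text{size}_i) \sim \mathcal N(\mu_{\ell(i)} + \beta_{g(i)},
  \sigma_w^2), \qquad \mu_\ell \sim \mathcal N(\mu_0, \sigma_L^2),
  \qquad \beta_{\text{normal}} = 0,$$

with the genotype size ratio defined as $e^{\beta_g}$ — ratios are
invariant to the measurement scale (pixel size cancels).

**Proliferation** — binomial with embryo and litter effects on the logit
scale:

$$\text{pHH3}_i \sim \mathrm{Bin}(\text{nuclei}_i, p_i), \quad
  \mathrm{logit}(p_i) = \theta_{e(i)}, \quad
  \theta_e \sim \mathcal N(\mu_{\ell(e)} + \gamma_{g(e)}, \sigma_E^2),
  \quad \mu_\ell \sim \mathcal N(a_0, \sigma_L^2),$$

with $\gamma_{\text{normal}} = 0$. The proliferation ratio is a ratio of
proportions (not odds) at the population level:
$\mathrm{logit}^{-1}(\bar\mu + \gamma_g) / \mathrm{logit}^{-1}(\bar\mu)$,
where $\bar\mu$ is the mean of the litter means. Priors are weakly
informative — $\mathcal N(0,1)$ on genotype effects, half-$\mathcal
N(0,1)$ on all SDs — and configurable through the `priors` argument.

Numerical notes. Both models use the centered (hierarchical-mean)
parameterization, which mixes far better under Gibbs sampling than the
grand-mean-plus-offsets form; the reported grand mean is the average of
litter means, which is well identified even with few litters. Convergence
is assessed by the potential scale reduction factor over all monitored
parameters (scale parameters on the log scale); fits with any PSRF at or
above 1.01 carry a warning and `converged = FALSE`. With only four
litters the litter-level SD is weakly identified and its PSRF can sit
near 1.01-1.05 at the default run length; longer chains (`draws = 4000`
or more) settle it, and the genotype ratios themselves converge quickly
regardless.

`posterior_summary()` reports the posterior median, the central 50%
interval (the "box" of a box plot), and $P(\text{ratio} < 1)$ per
genotype. `ratio_of_averages()` computes the model-free descriptive
statistic — each embryo's somite average over the pooled somite average
of its litter's controls — which displays the raw data but does not
propagate uncertainty; the Bayesian model exists precisely to do that.

## The synthetic generator

`generate_measurements()` emulates the structure the measurement model
assumes: log-normal sizes with litter and genotype effects, binomial
pHH3 counts with litter, embryo and genotype effects on the logit scale
(the genotype effect back-solved so the *proportion* ratio equals the
target), nucleus counts uniform on 200-1000, and 6-8 measured somites
per embryo by default (a `somite_range` of `c(2, 8)` emulates partially
recovered embryos). Defaults place the baseline ROI at 50,000 pixels and
the baseline mitotic index at 10%, with between-litter and within-embryo
SDs of 0.1-0.15 on the log/logit scales — magnitudes a practitioner
would call realistic for E9.0 somite sections. The default ratios are
the calibrated genotype effects (size 1/0.92/0.59/0.57; proliferation
1/0.71/1.1/0.32).

What the generator does *not* emulate: somite-position trends along the
axis, measurement error in the ROI outline, genotyping errors, or
embryonic lethality distorting observed genotype frequencies. Passing
parameter-recovery tests therefore validates the estimator under the
model's own assumptions — it does not certify the model against every
way real sections can deviate.

Validation is by recovery: generate at the study scale (4 litters x 6
embryos x 6 somites), fit, and check that the 95% posterior intervals
cover the generating ratios in at least 90% of replicates (pooled over
the six genotype-by-quantity ratios), and that posterior medians
averaged over replicates sit at the generating values.

## Mendelian cross frequencies

`cross_spec()` describes each locus by per-parent allele transmission
distributions and computes target genotype frequencies by exact
enumeration (independent loci; transmission probabilities of 1/2 are
exact in binary floating point, so the results are exact). The two
preset schemes: a Shh-floxed mother heterozygous for Apaf1 crossed to a
CRE-deleter sire heterozygous for both genes yields double knockouts at
1/8 when every scored offspring inherits CRE (`cre_transmission = 1`;
a hemizygous sire, 0.5, would halve this to 1/16), and the standard
Shh;Casp3 double-heterozygote intercross yields 1/16.

## Reproducibility and problem sizes

Every stochastic entry point takes a `seed`; a simulation run is
bit-identical for identical `(params, seed)`, MCMC chains derive their
generator seeds from the fit's `seed`, and `run_manifest()` records
parameters, seed, stop reason and output hashes so any run can be
reproduced from its manifest alone. The test-suite problem sizes — 20
seeds per simulated condition, 20 replicate fits at the 4 x 6 x 6 design,
2-4 chains of 4000-6000 iterations — were chosen so the full suite
exercises every claim at study scale in a few minutes on one CPU.

## Known limitations

- The simulator is two-dimensional and ends before chondrogenic
  differentiation; there is no tissue mechanics beyond density-driven
  stepping, and no attempt at visual parity with any particular
  simulation environment.
- The Hh profile is static; decided cells never re-read it. Temporal
  dynamics of the gradient are out of scope.
- Several simulator constants (world bounds, community-effect radius and
  threshold, half-saturation constant, sweep cap) are design choices
  exposed in `sim_params()` rather than measured quantities; the
  qualitative conclusions above are robust to moderate changes, but the
  quantitative fractions shift with them.
- The measurement model's exact likelihood/prior structure is this
  package's own specification of the hierarchy; the printed posterior
  medians it is calibrated against could differ slightly under other
  reasonable specifications.
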