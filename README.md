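# ribsim

Agent-based simulation of rib proximal–distal patterning, with the
hierarchical Bayesian measurement model that calibrates it.

Mammalian ribs have two skeletal elements — a proximal bone near the
vertebrae and a distal cartilage near the sternum — both derived from
the somites. `ribsim` implements a minimal mechanistic model of how the
two segments are specified and grown: sclerotome progenitors read a
static Gaussian Hedgehog (Hh) gradient at cell division and adopt a
proximal or distal fate with dose-dependent probabilities

    C(x) = 10^intensity · exp(−(x − x_peak)² / (2σ²)),   g = C/(C+K),
    P(proximal) = p_red · g,    P(distal) = p_blue · (1 − g),

while the field expands under proliferation (base probability 0.05 per
tick), early transient apoptosis (half-Gaussian in time), a
supermajority *community effect* that sharpens the fate boundary, and
density-driven spreading inside a bounded space (working density 4–6
cells per patch). Four genotype presets — normal, *Apaf1* KO, *Shh* KO,
and *Shh;Apaf1* double knockout — reproduce the corresponding skeletal
phenotypes as differences in final size and proximal/distal allocation.

The genotype-level size and proliferation dials are estimated from
litter-structured somite measurements (ROI pixel counts; pHH3⁺ nuclei
out of total nuclei) by a hierarchical Bayesian model: log-normal sizes
with litter random effects and binomial pHH3 counts with litter and
embryo effects on the logit scale, genotype ratios defined relative to
litter-matched controls. A synthetic-data generator with known ground
truth validates the estimator by parameter recovery, and an exact
Mendelian calculator reproduces the breeding-scheme frequencies (1/8
and 1/16) of the double-knockout crosses.

Intended users: developmental biologists and modelers who want a
reproducible, scriptable version of this class of patterning model, and
statisticians interested in the litter-matched ratio estimation.

## Worked example

```r
library(ribsim)

# simulate the normal genotype
res <- run_simulation(load_preset("normal"), seed = 1)
res
#> <rib_result> stopped at tick 46 (max_ticks): 8160 cells,
#>   4425 proximal / 2409 distal / 1326 undecided

fate_fractions(res)
#> $f_undecided 0.163   $f_proximal 0.542   $f_distal 0.295
```

About half the anlage commits to the proximal (vertebral) fate, the
proximal domain sitting at lower x (nearer the Hh source); an *Shh* KO
run instead comes out essentially all distal with far fewer cells.

```r
# estimate genotype size ratios from (here, synthetic) measurements
m <- generate_measurements(ground_truth(),
                           measurement_design(somite_range = c(6, 6)),
                           seed = 1)
fit <- fit_measurement_model(m, "size", draws = 4000, seed = 1)
posterior_summary(fit)
#>        genotype   quantity median lower_50 upper_50 p_less_than_1
#> 1        normal size_ratio  1.000    1.000    1.000         0.000
#> 2      apaf1_ko size_ratio  0.923    0.905    0.941         0.998
#> 3        shh_ko size_ratio  0.582    0.568    0.595         1.000
#> 4 shh_apaf1_dko size_ratio  0.573    0.560    0.586         1.000
```

The medians recover the generating ratios (0.92 / 0.59 / 0.57): *Shh*-null
somites are ~40% smaller than litter-matched controls, with posterior
certainty (`p_less_than_1` ≈ 1), while the *Apaf1* KO size deficit is
marginal.

```r
expected_genotype_frequency(cross_shh_apaf1_dko())   # 0.125  (1 in 8)
expected_genotype_frequency(cross_shh_casp3_dko())   # 0.0625 (1 in 16)
```

A thin command-line wrapper (`exec/ribsim`) exposes `simulate`, `sweep`,
`summarize`, `fit`, `synth` and `cross` subcommands over the same
functions; every run writes a YAML manifest (parameters, seed, stop
reason, output hashes) from which it can be reproduced exactly.

## Package layout

- `R/` — simulator (`abm`), pattern summaries, measurement model
  (`bayes`), synthetic generator and cross calculator, presets/config/IO
- `src/` — Rcpp spatial-hash kernels for neighbor counts and the
  redistribution sweep
- `vignettes/rib-patterning-model.Rmd` — the model, its assumptions,
  parameter meanings, and design decisions
- `tests/testthat/` — unit, property and acceptance suites
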