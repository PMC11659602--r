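# covrapid

Analytics for covalent macrocyclic peptide discovery against enzyme
targets such as peptidyl arginine deiminase 4 (PADI4). The package
implements the three computational stages of such a campaign and ships
seeded synthetic-data generators for every input, so the whole pipeline
runs and is tested without any external data:

1. **Covalent inhibition kinetics** — per-quench-time four-parameter
   logistic IC50 fits and the implicit time-dependent IC50 model

   IC50(t) = K_I (1 + S/K_M) · ( (2 − 2 e^(−η·k_inact·t)) / (η·k_inact·t) − 1 ),
   η = IC50(t) / (K_I (1 + S/K_M) + IC50(t)),

   solved by bracketed bisection and fitted by log-parameterised least
   squares to give K_I (µM), k_inact (min⁻¹) and the second-order
   efficiency constant k_inact/K_I (M⁻¹ min⁻¹).
2. **SPR two-state covalent kinetics** — simulation and fitting of
   single-cycle sensorgrams under A + B ⇌ AB → AB* with the reverse
   second step fixed at zero, yielding K_i = k₋₁/k₊₁ and
   k_inact = k₊₂; the non-returning post-dissociation baseline is the
   covalent signature the model captures.
3. **Selection NGS deconvolution** — translation of per-round FASTQ
   reads under a reprogrammed genetic code (initiator → chloroacetyl-
   D-tyrosine `y`, internal Met → electrophilic warhead `2`,
   `CGSGSGS` linker = cyclization point), ranked peptide counting,
   warhead-content fractions, enrichment trajectories, and greedy
   family clustering.

## Worked example

Fit covalent parameters from a simulated quench-time plate at the lead
peptide's parameters (K_I = 0.78 µM, k_inact = 0.17 min⁻¹, PADI4/BAEE
substrate context):

```r
library(covrapid)
ctx   <- substrate_context(S = 10, K_M = 1.36)        # mM
truth <- krippendorff_model(covalent_params(0.78, 0.17), ctx)
plate <- simulate_colder_plate(truth)                 # noise-free
series <- ic50_timecourse(plate)                      # 4PL per quench time
fit <- fit_krippendorff(series, ctx)
fit
#> Krippendorff fit (5 points): K_I = 0.7925 +/- 0.0063 uM, k_inact = 0.1743 +/- 0.0019 min^-1
#>   k_inact/K_I = 2.199e+05 M^-1 min^-1; RSS = 5.07e-05
```

The recovered K_I and k_inact sit within ~2% of the generating truth;
the small bias is the documented mismatch between the 4PL curve
midpoint and the implicit-model IC50 (the direct IC50-series round
trip is exact to <0.1%). The efficiency constant, ~2.2 × 10⁵
M⁻¹ min⁻¹, is the number by which covalent inhibitors are ranked.

The same loop for SPR:

```r
p   <- two_state_params(k_plus1 = 1e5, k_minus1 = 0.016,
                        k_plus2 = 0.25/60, Rmax = 100)
g   <- simulate_two_state(p, default_scheme(0.16e-6), seq(0, 3600, 2))
fit <- fit_two_state(g)
derive_covalent_constants(fit$params)$K_i_uM
#> [1] 0.16
```

And a five-round covalent selection:

```r
sim <- evolve_selection(strong_selection_config(seed = 1))
cnt <- tabulate_rounds(sim$reads)
sapply(seq_along(cnt$rounds), warhead_missing_fraction, counts = cnt)
#> [1] 71.96  2.42  0.03  0.00  0.00  0.00   # input, rounds 1-5
```

The warhead-free read fraction collapses below 1% from round 2 on —
the hallmark of a selection with denaturing washes — while winner
trajectories from `enrichment_trajectory()` climb round over round.

## Analysis workflow

The numbered scripts under `analysis/` are thin narrative drivers over
the package functions:

```sh
Rscript analysis/01_simulate_data.R      # plates, sensorgram, selection FASTQs
Rscript analysis/02_kinetics_fits.R      # 4PL + Krippendorff fits, constants table
Rscript analysis/03_spr_fits.R           # two-state sensorgram fit
Rscript analysis/04_selection_analysis.R # decode, rank, enrich, cluster
```

Each writes its tables and JSON reports under `results/` and prints a
summary of what it found.

## Methods

See `vignettes/covalent-peptide-analytics.Rmd` for the models, their
assumptions, the synthetic-data generators' scope, and the numerical
design choices.
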