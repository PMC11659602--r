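---
title: "Covalent peptide discovery analytics: models, generators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covalent peptide discovery analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covrapid)
```

covrapid implements the computational backbone of a covalent macrocyclic
peptide discovery campaign: (1) covalent enzyme-inhibition kinetics from
quench-time activity plates, (2) surface plasmon resonance (SPR) kinetics
under a two-state reaction model with an irreversible second step, and
(3) deconvolution of mRNA-display selection sequencing into cyclic
peptides under a reprogrammed genetic code, with per-round enrichment
statistics. Because raw assay data from such campaigns are rarely
portable, every input has a seeded synthetic generator whose outputs the
analysis functions consume, so the full pipeline is exercised end to end
without downloads. This vignette explains the models, the parameters that
matter, and the choices made where the methodology was genuinely open.

## Covalent inhibition kinetics

A covalent inhibitor is characterised by two parameters rather than a
single IC50: the reversible affinity $K_I$ (µM) of the initial binding
step and the maximal inactivation rate $k_{inact}$ (min⁻¹) of the
chemical step. Their ratio $k_{inact}/K_I$ (M⁻¹ min⁻¹) is the
second-order efficiency constant by which covalent inhibitors are
ranked; `kinact_over_KI()` computes it with the µM→M conversion
centralised in the package's unit helpers.

At inhibitor concentration $I$ with a competing substrate at
concentration $S$ (Michaelis constant $K_M$), the observed
pseudo-first-order inactivation rate is

$$k_{obs} = \frac{k_{inact}\, I}{K_I\left(1 + S/K_M\right) + I},$$

and the generative model for an activity plate is the standard
covalent-competition progress curve: reversible binding equilibrates
fast and scales the initial velocity by $1/(1 + I/K_I^{app})$, while
active enzyme decays exponentially at $k_{obs}$, so product accumulates
as $P(t) = (v_0/k_{obs})(1 - e^{-k_{obs} t})$ (`progress_curve()`; the
$k_{obs}\to 0$ branch is series-expanded to avoid 0/0). The assay
itself never measures rate constants directly: it quenches reactions at
a handful of times, normalises to a DMSO control, and reads out an
apparent IC50 per time point.

This yields the implicit time-dependent IC50 relation

$$\mathrm{IC}_{50}(t) = K_I\left(1+\frac{S}{K_M}\right)
  \left(\frac{2 - 2e^{-\eta\, k_{inact} t}}{\eta\, k_{inact} t} - 1\right),
  \qquad
  \eta = \frac{\mathrm{IC}_{50}(t)}{K_I(1+S/K_M) + \mathrm{IC}_{50}(t)},$$

whose two limit laws anchor the numerics: as $t \to 0$ the IC50 tends
to the apparent affinity $K_I(1+S/K_M)$, and at long times it decays
like $1/t$. `krippendorff_ic50()` solves the relation by bisection on
the guaranteed bracket $(0, K_I(1+S/K_M)]$ (200 iterations, then one
Newton polish); the returned root satisfies the relation to better than
$10^{-9}$ relative, and the test suite cross-checks it against an
independent damped fixed-point iteration. `fit_krippendorff()`
minimises the unweighted squared error between observed and model IC50
values on the linear scale, with both parameters log-parameterised (so
positivity is structural) and a deterministic multistart grid derived
from the data; standard errors come from the Jacobian at the optimum.
Unweighted linear-scale least squares is a deliberate default — the
conventional practice for these fits — and the residual-bootstrap and
grid-search oracles in the tests quantify what it recovers under 10%
lognormal noise on the IC50 values.

Per-time IC50 values come from four-parameter logistic (4PL) fits
(`fit_four_pl()`): `top` and `bottom` are left free by default (started
near the control-normalised 1 and 0, with an option to pin them),
because control normalisation makes values near those limits likely but
not exact. Two situations are flagged rather than fitted through:

* **Incomplete curves.** When the fitted IC50 exceeds the highest
  tested concentration, or the fitted dynamic range `top - bottom`
  falls below 0.2 (a weak inhibitor leaving activity near 1
  everywhere), the point is reported as "> cmax" and excluded from the
  Krippendorff fit. Weak inhibitors can thereby yield an entirely
  unfittable series, which the kinetics workflow reports as a flagged
  result with no parameters.
* **Tight binding.** The model assumes $[I] \gg [E]$. With 50 nM
  enzyme in the assay, fitted IC50 values below $5\times[E]$ violate
  that assumption; the package warns (and the workflow records a
  `tight_binding` flag) but does not correct, since no depletion
  correction is part of the standard analysis.

Two systematic points deserve note. First, the 4PL midpoint is a close
but not exact stand-in for the implicit-model IC50 (the activity ratio
is not exactly logistic in $I$), so a plate-level round trip carries a
few-percent bias even without noise, whereas the direct IC50-series
round trip recovers parameters to machine-level accuracy — the test
suite asserts both at their own tolerances. Second, published
efficiency constants are computed from unrounded fits, so recomputing
them from rounded table values reproduces them to about 1%, not
exactly.

Defaults: substrate context $S = 10$ mM, $K_M = 1.36$ mM (the
PADI4/BAEE assay; 10.8 mM applies to PADI3 with BAME). The final
in-well substrate dilution is not fully specified in the source
protocols, so the nominal 10 mM is used and exposed as a parameter. The
simulated plate design uses the nine final concentrations of the
two interleaved 5-fold dilution series (50 to 0.08 µM) plus a
zero-concentration control, quenched at 15-minute intervals for five
timepoints.

## SPR two-state covalent kinetics

Covalent analytes leave an SPR signature: the baseline after the final
dissociation does not return to zero, because converted complex cannot
dissociate. The two-state reaction model

$$A + B \underset{k_{-1}}{\overset{k_{+1}}{\rightleftharpoons}} AB
  \overset{k_{+2}}{\longrightarrow} AB^{*}$$

with the reverse of the second step fixed at zero captures this; the
reversible affinity is $K_i = k_{-1}/k_{+1}$ and the covalent rate is
$k_{inact} = k_{+2}$ (reported per minute; seconds are used
internally). `simulate_two_state()` integrates the corresponding ODE
system under a piecewise-constant analyte concentration from a
single-cycle injection scheme. Because the system is linear within each
constant-concentration segment, the package solves each segment in
closed form (2×2 eigen-decomposition, with dedicated branches for the
Langmuir limit $k_{+2}=0$ and for zero-analyte segments) and restarts
at segment boundaries, which keeps injection edges exact and makes the
simulator fast enough to sit inside a least-squares loop; a numerical
stiff integrator backs the rare near-degenerate eigenvalue case and any
$k_{-2} > 0$ use. The test suite verifies the closed-form path against
both the analytic Langmuir solution and an independent adaptive ODE
integration of the full system.

`fit_two_state()` fits $(k_{+1}, k_{-1}, k_{+2}, R_{max})$ by
Levenberg–Marquardt on log-parameters from a deterministic multistart
grid. Joint identifiability of the reversible and covalent steps needs
both association curvature at several concentrations and a long final
dissociation, so the default single-cycle scheme
(`default_scheme()`) injects five ascending concentrations spanning
0.1–10 × $K_i$ for 120 s each, with 300 s between injections and a
1800 s final dissociation. The actual schemes used in published
campaigns live in supplementary material; these defaults are synthetic
and chosen for identifiability, not provenance. Mass-transport
limitation, reference-channel subtraction and bulk refractive-index
jumps are out of scope. For reversible analytes,
`fit_steady_state()` fits the binding isotherm
$R_{eq} = R_{max} C/(K_D + C)$ and flags affinities beyond the tested
range as lower bounds.

## Selection NGS deconvolution under a reprogrammed code

The display library encodes cyclic peptides: an initiator codon
reassigned to N-chloroacetyl-D-tyrosine (written `y`), 6–10 random NNK
codons, and a `CGSGSGS` linker whose first cysteine closes the
macrocycle with the initiator's chloroacetyl group. All internal Met
(ATG) codons are reassigned to the electrophilic warhead amino acid
(written `2`), so warhead content is readable from the DNA.
`decode_reads()` translates each read from its initiator, locates the
linker by translated match, and derives the random-region length,
warhead flag and validity flags; reads are assumed already trimmed to
start at the initiator codon (adapter and UMI handling is out of
scope), and base qualities are ignored throughout.

Three decoding policies are deliberate choices. Amber (TAG) codons —
one of the 32 NNK codons — are vacant in the reprogrammed translation
system; reads carrying one in the random region are flagged
`premature_stop` and excluded from peptide statistics, the conservative
reading. When the canonical linker is absent (linker-variant clones are
a real occurrence), the first Cys after at least six random codons is
taken as the cyclization point and the record flagged `linker_lost`;
such reads are likewise excluded from the valid set. A `cys_rich` flag
marks random regions with more than 3 Cys — "a very large proportion"
is not quantified anywhere, so the threshold is a documented constant.

`tabulate_rounds()` counts identical peptide strings among valid reads,
ranking by count with a lexicographic tie-break so ranked tables are
byte-reproducible. `warhead_missing_fraction()` is read-weighted by
default (a unique-sequence weighting is exposed as an option; the two
can differ substantially and published figures do not say which was
used). Enrichment trajectories report per-round frequency and
round-over-round fold change, with add-one smoothing on counts when the
earlier round is zero. `cluster_families()` groups top sequences by
greedy single-linkage under a distance threshold (Hamming for
equal-length pairs, edit distance otherwise), merging families that a
new sequence connects — which makes the result exactly the connected
components of the distance-threshold graph, as the brute-force oracle
in the tests confirms.

## What the generators emulate — and what they do not

`sample_library()` draws the random-region length from the normalized
sub-library mixing ratio 0.0018 : 0.032 : 1 : 32 : 80 (lengths 6–10; a
97% majority of 9- and 10-mers) and each codon uniformly from the 32
NNK codons. `evolve_selection()` models selection as deterministic
multiplicative fitness plus multinomial sequencing noise: each round
multiplies a sequence's template mass by its fitness and — when
denaturing washes are enabled — by a wash-survival factor (default
0.01) if its peptide lacks the warhead; reads are then drawn
multinomially (50,000 per round at desk scale) and a truth ledger of
exact frequencies and recovery fractions is written alongside the
FASTQ files. Under this model the warhead-free mass fraction has a
closed form (its odds shrink by the survival factor each round), which
the tests check against the ledger; with the default survival of 0.01
the read-level fraction falls from ~72% in the naive pool (the chance
that 6–10 NNK codons contain no ATG) to below 1% after two rounds.

The preset winner fitnesses are moderate (2.5–3× per round). This is
the regime covalent selections actually show: because many sequence
contexts tolerate the warhead chemistry, no single sequence sweeps the
pool; winners climb round over round yet remain individually
low-abundance. A much larger advantage would saturate the pool within
five rounds, at which point slower winners' *relative* frequencies
start falling even as selection proceeds — a regime inconsistent with
the observed round-by-round rise.

The generators do not model PCR or sequencing errors, chimeras,
per-base quality, bead-capture chemistry, or round-to-round changes in
stringency (the wash effect is collapsed into a single survival
factor). Passing tests therefore demonstrate the correctness of the
decoding, counting and fitting machinery under the stated statistical
model, not robustness to real-library artefacts such as indels or
quality-correlated errors. FASTQ qualities are emitted as a constant
`I` since nothing downstream reads them.

## Numerical conventions and problem sizes

All fits are deterministic given their inputs: multistart grids are
fixed, optimizers are seeded by data-driven heuristics, and ranked
outputs use explicit tie-breaks, so identical inputs give byte-identical
reports (workflow outputs embed a config hash and the seed). Simulation
sizes are chosen at desk scale — 100,000 reads for library composition
checks, 50,000 reads per selection round, 2 s sampling over a ~1 h
sensorgram, 200 replicate fits for noise studies — which keeps every
analysis in seconds-to-minutes while leaving Monte-Carlo error well
below the tolerances asserted.

Degenerate inputs are handled explicitly rather than numerically:
all-identical activities are a degeneracy error; a 4PL that cannot
converge is a flagged result; an IC50 series with fewer than two usable
points is unfittable; an empty sequencing round warns and yields an
empty table; zero input copies is a domain error for recovery
arithmetic.

## Reproducing the analyses

The numbered scripts under `analysis/` run the three studies end to
end (simulate, kinetics, SPR, selection), writing tables under
`results/`; `scripts/acceptance.R --seed 1 --out results/acceptance.json`
recomputes the headline quantities from scratch.
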