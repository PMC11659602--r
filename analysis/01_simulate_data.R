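#!/usr/bin/env Rscript
# Stage 1: generate every synthetic input the downstream analyses
# consume — quench-time activity plates for the lead covalent peptide,
# a single-cycle SPR sensorgram at its SPR constants, and a five-round
# covalent selection run — and write them under results/simulated/.

suppressPackageStartupMessages(library(covrapid))
seed <- 1L
out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## Quench-time plates: three replicates at the lead peptide's
## quench-time parameters (K_I = 0.78 uM, k_inact = 0.17 min^-1) under
## the PADI4/BAEE substrate context (S = 10 mM, K_M = 1.36 mM), with
## 2% plate noise.
ctx <- substrate_context(S = 10, K_M = 1.36)
truth <- krippendorff_model(covalent_params(0.78, 0.17), ctx)
for (r in 1:3) {
  plate <- simulate_colder_plate(truth,
                                 noise = noise_model(plate_sigma = 0.02,
                                                     seed = seed + r),
                                 replicate = paste0("r", r))
  write_plate_csv(plate, file.path(out, sprintf("plate_cP4_15_r%d.csv", r)))
}
message("wrote 3 replicate plates (9 concentrations x 5 quench times)")

## SPR sensorgram: two-state covalent model at K_i = 0.16 uM,
## k_inact = 0.25 min^-1 (k+1 = 1e5 M^-1 s^-1), 1 RU read noise.
spr_truth <- two_state_params(k_plus1 = 1e5, k_minus1 = 0.016,
                              k_plus2 = 0.25 / 60, Rmax = 100)
sch <- default_scheme(0.16e-6)
gram <- simulate_sensorgram_noisy(spr_truth, sch,
                                  noise_model(spr_sigma = 1, seed = seed),
                                  times = seq(0, 3600, 2))
write_sensorgram_csv(gram, file.path(out, "sensorgram_cP4_15.csv"))
write_scheme_yaml(sch, file.path(out, "scheme_cP4_15.yaml"))
message("wrote single-cycle sensorgram (5 injections + final dissociation)")

## Covalent selection: strong-selection preset (5 rounds, 50k reads
## per round, denaturing washes, six moderately advantaged winners).
sim <- evolve_selection(strong_selection_config(seed = seed),
                        out_dir = file.path(out, "selection"))
message("wrote ", length(sim$fastq_paths),
        " per-round FASTQ files + truth ledger")
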