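#!/usr/bin/env Rscript
# Stage 4: selection NGS deconvolution. Decodes the per-round FASTQ
# files under the reprogrammed genetic code, ranks peptides by read
# count, tracks warhead content and the enrichment of the top
# sequences, and clusters the final-round top sequences into families.

suppressPackageStartupMessages(library(covrapid))
sel_dir <- "results/simulated/selection"
out <- "results/selection"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
fastqs <- file.path(sel_dir, paste0("round", 0:5, ".fastq"))
stopifnot(all(file.exists(fastqs)))

res <- run_selection_workflow(fastqs, out_dir = out, track_top = 20)
s <- res$summary
message("per-round decoded reads: ", paste(s$reads_valid, collapse = ", "))
message("warhead-free read %:     ",
        paste(sprintf("%.2f", s$warhead_missing_pct), collapse = ", "))
message(s$n_families_top, " families among the final-round top 20")
final <- res$counts$rounds[[length(res$counts$rounds)]]
message("top 5 peptides of the final round:")
for (i in 1:5)
  message(sprintf("  %-22s %6d reads (%.2f%%)", final$peptide[i],
                  final$count[i], 100 * final$frequency[i]))
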