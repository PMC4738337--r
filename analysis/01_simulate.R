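#!/usr/bin/env Rscript
# Step 1: generate the two-species study dataset.
#
# Draws the default simulated cohort — a mouse-like species with five tumour
# groups (Mb, Nb, lymph, mEIC, mIC) and a human-like species with six (MB,
# NB, hIC1, hIC3, hEC, hIC2), four linked group pairs sharing programs over
# a 1:1 ortholog core at agreement rho = 0.8, plus cortex-like reference and
# per-group progenitor samples — and writes every artifact as TSV/JSON under
# results/data/.

library(crossdex)

seed <- 1
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sim <- simulate_two_species(sim_params(), seed = seed)

write_expression_matrix(sim$a, file.path(out, "expr_mouse.tsv"))
write_expression_matrix(sim$b, file.path(out, "expr_human.tsv"))
write_ortholog_map(sim$map, file.path(out, "orthologs.tsv"))
write.table(sim$annotation, file.path(out, "annotation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(seed = seed,
       labels = lapply(sim$truth$labels, as.list),
       linked = sim$truth$linked,
       programs = sim$truth$programs),
  file.path(out, "truth.json"), auto_unbox = TRUE, pretty = TRUE)

cat(sprintf("mouse: %d genes x %d samples; human: %d genes x %d samples\n",
            nrow(sim$a), ncol(sim$a), nrow(sim$b), ncol(sim$b)))
cat(sprintf("ortholog core: %d 1:1 pairs; linked group pairs: %s\n",
            nrow(sim$map),
            paste(sim$truth$linked$a, sim$truth$linked$b, sep = "~",
                  collapse = ", ")))
cat("wrote", out, "\n")
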