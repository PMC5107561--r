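#!/usr/bin/env Rscript

# Step 1 — simulate the F2 pooled-sequencing experiment.
#
# Generates the default study design: 410 F2 plants from a biparental
# cross segregating 1:2:1 at a recessive resistance locus with
# penetrance 26/95, pooled into all resistant plants (br pool) versus
# 297 randomly chosen bolting plants (b pool), with pooled allele
# depths of 60x/30x and a 0.005 per-base error rate over two 5 Mb
# scaffolds at one polymorphic site per kb. Exports the variant table
# (VCF), phenotypes, a 10-marker genotype table spanning the causal
# locus, and the seeded configuration.

suppressMessages(library(bsascan))

out_dir <- "results/dataset"
cfg <- cross_sim_config(seed = 1L)
ds <- simulate_dataset(cfg)

# codominant markers every 100 kb across the locus, one exactly at the
# causal position (2.50 Mb on sca1)
markers <- data.frame(scaffold = "sca1",
                      pos = as.integer(seq(2.0e6, 3.0e6, by = 1e5)))
paths <- export_dataset(ds, out_dir, markers)

pl <- ds$population$plants
cat("simulated", nrow(pl), "F2 plants:",
    sum(pl$phenotype == "resistant"), "resistant,",
    sum(pl$phenotype == "bolting"), "bolting\n")
cat("genotype counts:",
    paste(names(table(pl$causal_genotype)),
          table(pl$causal_genotype), collapse = ", "), "\n")
cat("site catalog:", nrow(ds$sites), "sites (",
    sum(ds$catalog$kind == "ref_divergent"), "reference-divergent )\n")
cat("pools: br =", length(ds$pools$br_ids),
    "plants, b =", length(ds$pools$b_ids), "plants\n")
cat("exported:", paste(basename(paths), collapse = ", "), "->", out_dir, "\n")
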