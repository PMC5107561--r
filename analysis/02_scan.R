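#!/usr/bin/env Rscript

# Step 2 — call pooled genotypes, scan, and delimit the locus.
#
# Reads the exported dataset back from files, classifies each site in
# both pools, applies the heterozygous-in-b / homozygous-in-br candidate
# filter, scores 200 kb windows at a 100 kb step, and extracts the
# contiguous monomorphic region around the peak together with the
# br-pool allele-frequency track.

suppressMessages(library(bsascan))

in_dir <- "results/dataset"
cfg <- read_sim_config(file.path(in_dir, "config.yaml"))
sites <- read_variants(file.path(in_dir, "variants.vcf"))

called <- filter_candidates(sites, call_config())
cat("called", nrow(called), "sites;",
    sum(called$b_call == "HET"), "b-pool heterozygous;",
    sum(called$candidate), "candidates\n")

scores <- score_windows(called, cfg$scaffolds, scan_config())
write.table(scores, "results/windows.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

pk <- find_peak(scores)
cat(sprintf("peak window: %s:%d-%d with %d/%d monomorphic sites\n",
            pk$peak$scaffold, pk$peak$start, pk$peak$end,
            pk$peak$n_monomorphic_br, pk$peak$n_polymorphic_b))

track <- allele_frequency_track(called)
write.table(track, "results/allele_frequency_track.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

regions <- find_monomorphic_regions(called, scan_config())
write_regions(regions, "results/regions.tsv", dialect = "tsv")
write_regions(regions, "results/regions.bed", dialect = "bed")

top <- regions[1, ]
cat(sprintf("top region: %s:%d-%d (%d bp, %d sites)\n",
            top$scaffold, top$start, top$end, top$length_bp, top$n_sites))
hit <- top$scaffold == cfg$causal$scaffold &&
  top$start <= cfg$causal$pos && top$end >= cfg$causal$pos
cat("causal position", cfg$causal$pos, "contained in top region:", hit, "\n")
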