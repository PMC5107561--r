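#!/usr/bin/env Rscript

# Step 5 — coding-sequence consequences of candidate-gene variants.
#
# Demonstrates the consequence caller on engineered coding sequences
# that reproduce, structurally, the three truncating lesions found in
# the locus interval: a frameshifting 2-bp deletion (203 instead of
# 633 aa) and two premature-stop substitutions (226 instead of 237 aa;
# 190 instead of 204 aa).

suppressMessages(library(bsascan))
dir.create("results", showWarnings = FALSE)

# a CDS of n codons + stop from a stop-free repeat, with a premature
# stop introduced by a single substitution at codon `at`
stop_snp_case <- function(ref_aa, at) {
  codons <- rep("AAA", ref_aa)          # AAA = Lys, stop-free repeat
  codons[1] <- "ATG"
  cds <- coding_sequence(sprintf("toy_stop_%daa", ref_aa),
                         paste0(paste(codons, collapse = ""), "TAA"))
  list(cds = cds, var = cds_variant(3L * (at - 1L) + 1L, "A", "T"))  # AAA->TAA
}

cases <- list(
  frameshift_2bp_del = build_frameshift_cds(633L, 191L, 204L),
  premature_stop_a = stop_snp_case(237L, 227L),
  premature_stop_b = stop_snp_case(204L, 191L)
)

rows <- lapply(names(cases), function(nm) {
  cs <- cases[[nm]]
  variants <- if (!is.null(cs$deletion)) cs$deletion else cs$var
  cons <- call_consequence(cs$cds, variants)
  cat(sprintf("%s: %s — %s\n", nm, cons$kind,
              ifelse(nzchar(cons$description), cons$description,
                     "no truncation")))
  data.frame(case = nm, kind = cons$kind,
             ref_aa = cons$ref_protein_length,
             alt_aa = cons$alt_protein_length,
             description = cons$description)
})
write.table(do.call(rbind, rows), "results/consequences.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
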