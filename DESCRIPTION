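Package: bsascan
Title: Bulked-Segregant Mapping of a Recessive Bolting-Resistance Locus
    from Pooled F2 Sequencing
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for mapping-by-sequencing of a
    recessive, incompletely penetrant locus in a biparental F2 population.
    Simulates an F2 cross with Poisson crossovers, phenotype-based DNA
    pooling and pooled read sampling; classifies per-pool genotypes from
    allele depths; applies the heterozygous-in-bolting-pool /
    homozygous-in-resistant-pool candidate filter; runs a sliding-window
    monomorphic-site scan and delimits the contiguous homozygous region
    around the causal locus; analyses codominant marker matrices for
    crossover breakpoints; calls coding-sequence variant consequences
    (frameshift, premature stop); and computes Mendelian segregation,
    penetrance, phenotype-prediction and bolting-rate statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
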