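# bsascan

Mapping-by-sequencing (bulked segregant analysis, BSA-seq) of a recessive,
incompletely penetrant locus in a biparental F2 population — built around
the genetics of post-winter bolting resistance in sugar beet (*Beta
vulgaris*), where a recessive resistance allele (*br1*) on chromosome 9
expresses its phenotype in only a minority of homozygotes.

The package is for geneticists who map a qualitative trait by sequencing
two DNA pools of phenotypically extreme F2 plants, and for anyone who
wants to study — by simulation — how pool sizes, depths, penetrance and
recombination shape the mapping resolution of that design.

## The method

An F2 from two inbred parents segregates 1:2:1 at every cross-specific
polymorphism. Pool the plants by phenotype:

- the **resistant pool (br)** contains only plants homozygous for the
  recessive allele, so near the causal locus every haplotype comes from
  the resistant parent and the pooled alt-allele frequency is 0 or 1;
- the **bolting pool (b)** mixes all three genotypes, so it stays
  heterozygous everywhere, including at the locus.

A site is a **candidate** when it is heterozygous in the b pool (which
also removes positions where both parents diverge identically from the
reference) and homozygous in the br pool, with joint coverage ≥ 50×.
Sliding 200 kb windows at a 100 kb step count the br-monomorphic sites
among the b-polymorphic ones; the genome-wide peak marks the locus, and
the maximal run of consecutive br-monomorphic sites delimits the mapped
interval (1-based inclusive; its span is `end − start + 1`).

Around that core the package provides: a fully seeded F2 cross simulator
(Poisson crossovers, binomial pooled read sampling, configurable
penetrance), codominant-marker breakpoint analysis, coding-sequence
consequence calling (frameshift / premature stop, with truncation
descriptions such as "203 instead of 633 aa"), and the segregation,
penetrance, prediction-accuracy and bolting-rate statistics of the
single-plant and family data.

## Worked example

The `analysis/` directory is a numbered workflow. Step 1 simulates the
default design (410 plants, penetrance 26/95, pools of all resistant vs
297 bolting plants, 60×/30× depths, two 5 Mb scaffolds at 1 site/kb) and
exports it as VCF + TSV; step 2 reads the files back and maps the locus:

```
$ Rscript analysis/01_simulate.R
simulated 410 F2 plants: 28 resistant, 382 bolting
genotype counts: brbr 97, BRbr 213, BRBR 100
site catalog: 9958 sites ( 3986 reference-divergent )
pools: br = 28 plants, b = 297 plants

$ Rscript analysis/02_scan.R
called 9958 sites; 5970 b-pool heterozygous; 908 candidates
peak window: sca1:2600001-2800000 with 139/144 monomorphic sites
top region: sca1:2180723-2695606 (514884 bp, 312 sites)
causal position 2500000 contained in top region: TRUE
```

The peak window and the longest monomorphic region land on the causal
scaffold and the region contains the true causal position (2.5 Mb).
Step 3 computes the single-plant statistics from the genotyped F2
counts — the 1:2:1 segregation test, the fraction of phenotypes the
locus genotype predicts, and the penetrance of resistance:

```
$ Rscript analysis/03_segregation_stats.R
Segregation chi-square: X^2 = 1.917, df = 2, p = 0.3835
locus genotype predicts 83.2% of phenotypes (341/410)
penetrance of resistance in homozygotes: 0.274 (95% CI 0.187-0.375); 72.6% of homozygotes bolt
```

Step 4 verifies that every resistant plant is homozygous for the
resistant-parent allele at the locus marker and finds the flanking
crossovers that bound the resolution; step 5 demonstrates the
consequence caller on engineered coding sequences (a frameshifting 2-bp
deletion truncating a 633-aa protein to 203 aa, plus two premature-stop
substitutions).

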