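---
title: "Pooled-sequencing mapping of a recessive, incompletely penetrant locus"
author: "bsascan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled-sequencing mapping of a recessive, incompletely penetrant locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsascan)
```

## The genetic model

`bsascan` models and analyses a bulked-segregant (BSA-seq) experiment on
a biparental F2 population segregating for a monogenic, fully recessive
trait with incomplete penetrance. The motivating system is post-winter
bolting resistance in biennial beet: plants homozygous for the recessive
resistance allele fail to bolt after vernalization, but only a fraction
of homozygotes — about 26/95 ≈ 0.27 — actually express resistance, while
every carrier of the dominant allele bolts. Phenotype selection is
therefore asymmetric: a resistant plant is (almost) certainly homozygous
recessive, whereas a bolting plant can carry any genotype. That
asymmetry is exactly what the two-pool design exploits:

- **br pool** — every resistant plant. At the causal locus all of its
  haplotypes descend from the resistant parent, so the pooled allele
  frequency is 0 or 1 there, and drifts back toward 0.5 with distance
  at a rate set by recombination.
- **b pool** — a random sample of bolting plants. It remains
  polymorphic everywhere, *including* the locus (because non-penetrant
  homozygotes bolt), so heterozygosity in this pool identifies sites
  that truly segregate in the cross and excludes positions where both
  parents share a non-reference allele.

The scan statistic counts, in sliding windows, sites monomorphic in the
br pool among sites polymorphic in the b pool; a single genome-wide peak
is the signature of one major locus.

## What the simulator emulates — and what it does not

`cross_sim_config()` collects the design in one object. Defaults are the
study conditions the analysis is calibrated for:

| parameter | default | meaning |
|---|---|---|
| `scaffolds` | 2 × 5 Mb | a causal and an unlinked scaffold; desk-scale stand-ins for a fragmented reference |
| `snp_density` | 1e-3 /bp | cross-specific polymorphic sites (≈1 per kb) |
| `ref_divergent_fraction` | 0.4 | sites where both parents identically diverge from the reference; chosen to match the observed ratio of parent-identical to cross-specific variant counts in deep resequencing of this cross type (≈1.47M : 2.11M) |
| `causal` | sca1:2,500,000 | the resistance locus |
| `penetrance_resistant` | 26/95 | P(resistant \| homozygous recessive) |
| `n_f2`, `n_b_pool` | 410, 297 | population and bolting-pool sizes |
| `mean_depth_br`, `mean_depth_b` | 60, 30 | Poisson per-site pool depths |
| `error_rate` | 0.005 | per-base miscall probability; large enough that truly homozygous sites show occasional minor-allele reads, which is what the tolerant call band exists for |
| `crossover_lambda_per_bp` | 2e-7 | one expected crossover per 5 Mb scaffold per gamete, consistent with the handful of single crossovers observed among resistant plants near such a locus |

Each gamete draws a Poisson number of crossover points uniformly on the
scaffold and alternates parental origin from a fair random start;
phenotypes are Bernoulli draws given the causal genotype; pooled reads
are `Binomial(Poisson(depth), f(1−e) + (1−f)e)` at the true pooled
frequency `f`. Everything is driven by one seed: identical
configurations export byte-identical files.

Deliberately **not** modelled: read-level artifacts (alignment,
duplicates, InDel realignment), sub-pool library structure (the analysis
operates on combined pools), length polymorphism of InDels (all sites
are biallelic SNPs, as the scan treats short InDels and SNPs
identically), and any polygenic or heritable modifier of penetrance —
the binary phenotype also sidesteps the ambiguity of "incomplete
bolting" individuals, which the field scoring classifies as bolting.
Consequently, passing tests show that the *pipeline logic* recovers a
locus under the stated statistical structure; they say nothing about
alignment-induced artifacts in real data, and the simulated F3 family
bolting rates for homozygous-recessive parents sit near `1 − penetrance`
(≈0.73), higher than the ≈0.27 observed in the field, where penetrance
itself is partly heritable.

## Pooled genotype calls and the candidate filter

Real pipelines of this kind genotyped the pools with a diploid
multi-sample caller; how such a caller behaves on DNA of ~150 pooled
plants is opaque. `classify_pool()` replaces it with a transparent
frequency-band rule: below `min_pool_depth` (default 10) a pool is
`NO_CALL` (and a NO_CALL pool vetoes candidacy); otherwise the alt
frequency `q = alt/(ref+alt)` maps to `HOM_REF` (`q < 0.15`), `HOM_ALT`
(`q > 0.85`) or `HET`. The band default is tolerant by design: at the
default error rate a homozygous site regularly shows a few percent
minor reads. Tightening the band toward `(0.01, 0.99)` approaches the
idealized "frequency exactly 0 or 1" reading — useful with error-free
deep data, and the mode `region_frequency_mode = "exact"` implements
that reading literally. A caveat follows from the band: frequencies
below `low` are indistinguishable from 0, so with `2N` pool haplotypes
the classifier cannot separate "0 recombinants" from "fewer than
`2N·low` recombinants"; the detected region is therefore wider than the
strict identity-by-descent region, and its fringe can fragment into
more than one reported run. The longest run still tracks the locus.

`filter_candidates()` flags — it never drops — sites with joint depth
≥ 50 that are b-HET and br-HOM, so window scores can use all b-HET
sites as denominator.

## Scan, peak, and region conventions

Windows (default 200 kb, step 100 kb) start at 1 and are truncated at
the scaffold end; coordinates are 1-based inclusive throughout, which
is the only convention under which a region printed as
4,991,549–5,094,401 has length 102,853 bp (`end − start + 1`). Peak
ties break to the lexicographically smallest `(scaffold, start)` and
all tied windows are reported. Region boundaries are the outermost
monomorphic *sites* of a run (not the innermost flanking polymorphic
sites); the flanking non-monomorphic positions are reported separately
as the recombination-bounded uncertainty. `min_region_sites` (default
20) suppresses error-driven short runs — the visual screening such
analyses historically used is replaced by this explicit threshold.
Degenerate inputs are defined: a scaffold with no b-HET sites yields no
regions, an empty score table is an error, and a one-bp scaffold is a
single one-bp window.

## Statistics

- `chi_square_ratio()` — Pearson goodness-of-fit against arbitrary
  ratio weights (scaling-invariant), upper-tail p via the chi-square
  distribution function; the tests cross-check the tail against direct
  numerical integration of the density to 1e-6.
- `penetrance_estimate()` — binomial point estimate with an exact
  Clopper–Pearson interval (an artifact choice; the original analyses
  reported no interval).
- `prediction_accuracy()` — the recessive prediction rule
  (homozygous-recessive → resistant, else bolting).
- `family_rates()` — unweighted means and n−1 standard deviations of
  family bolting rates per parental genotype; singleton groups report a
  missing sd, empty groups are omitted with a warning.
- `compare_rates()` — pairwise 2×2 Pearson tests without continuity
  correction (none was specified for the original comparisons; a flag
  restores Yates), adjusted by Holm by default — conservative without
  independence assumptions; Bonferroni and Benjamini–Hochberg are
  available.

## Markers and consequence calling

Codominant marker genotypes use the A/H/B convention (A = homozygous
resistant-parent). Breakpoints are transitions between adjacent
non-missing genotypes; missing genotypes widen the interval to the
nearest informative flank, and double crossovers between adjacent
markers are undetectable by construction. `flank_refinement()` returns
the nearest recombination interval on each side of a focal marker — the
hard resolution bound the recombinants impose.

`call_consequence()` translates reference and edited CDS (standard
nuclear code only, frame fixed at position 1, stop-at-first-stop,
trailing partial codon ignored) and classifies by severity: frameshift
> stop_gained > stop_lost > inframe_indel > missense > synonymous,
with combined flags retained and truncations described as
"x instead of y aa". A frameshift is asserted to coincide exactly with
a net indel length not divisible by 3. Start-codon absence warns rather
than errors, since gene models may be partial. Real reference gene
sequences are not bundled; truncation patterns are reproduced on
engineered toy CDS built from stop-free codon repeats
(`build_frameshift_cds()`), which keeps the demonstration fully
self-contained.

## Problem sizes and reproducibility

The shipped analyses and tests run the full design (410 plants, ~10,000
sites over 2 × 5 Mb) in seconds per replicate; recovery properties are
evaluated over 20 seeded replicates, and oracle-equivalence properties
over hundreds of small random instances — sizes chosen so the whole
suite re-runs quickly on a laptop while keeping Monte-Carlo error well
below the asserted margins. All randomness flows from explicit seeds;
`scripts/acceptance.R --seed N` reproduces every reported number
exactly.

## Known limitations

- The frequency-band classifier is not a likelihood model; with very
  unequal pool sizes a likelihood-ratio caller would use depth more
  efficiently.
- Multiallelic sites are rejected rather than decomposed.
- The simulator's uniform site density and constant crossover rate
  ignore recombination suppression near centromeres, which in real data
  widens mapped intervals.
- Penetrance is a single Bernoulli parameter; heritable or
  environment-dependent penetrance (clearly present in the motivating
  system's family data) is out of scope.
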