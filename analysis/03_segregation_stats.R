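#!/usr/bin/env Rscript

# Step 3 — segregation, penetrance and bolting-rate statistics.
#
# First on the published F2 genotype/phenotype tables (95/201/114
# genotype counts; 26 resistant among the 95 homozygotes), then on
# simulated F3 families derived by selfing, grouped by parental
# genotype, with pairwise chi-square comparisons of bolting rates.

suppressMessages(library(bsascan))
dir.create("results", showWarnings = FALSE)

f2 <- c(hom_recessive = 95L, het = 201L, hom_dominant = 114L)
seg <- chi_square_ratio(unname(f2), c(1, 2, 1))
print(seg)

pheno <- data.frame(genotype = names(f2),
                    n_resistant = c(26L, 0L, 0L),
                    n_bolting = c(69L, 201L, 114L))
acc <- prediction_accuracy(pheno, counts = f2)
cat(sprintf("locus genotype predicts %.1f%% of phenotypes (%d/%d)\n",
            100 * acc, sum(ifelse(pheno$genotype == "hom_recessive",
                                  pheno$n_resistant, pheno$n_bolting)),
            sum(f2)))

pen <- penetrance_estimate(26L, 95L)
cat(sprintf(paste0("penetrance of resistance in homozygotes: %.3f ",
                   "(95%% CI %.3f-%.3f); %.1f%% of homozygotes bolt\n"),
            pen$estimate, pen$ci_low, pen$ci_high, 100 * (1 - pen$estimate)))

stats_tab <- data.frame(
  quantity = c("segregation_chi_square", "segregation_p",
               "prediction_accuracy", "penetrance_resistant",
               "bolting_fraction_hom_recessive"),
  value = c(seg$statistic, seg$p_value, acc, pen$estimate,
            1 - pen$estimate))
write.table(stats_tab, "results/f2_stats.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# F3 families by selfing: 209 families of 6-31 plants, parental
# genotypes drawn at the F2 1:2:1 frequencies among bolting plants
set.seed(3L)
parents <- sample(c("hom_recessive", "het", "hom_dominant"), 209L,
                  replace = TRUE, prob = c(69, 201, 114))
fam <- simulate_f3_families(parents,
                            family_sizes = sample(6:31, 209L, replace = TRUE))
rates <- family_rates(fam)
print(rates)
write.table(rates, "results/f3_family_rates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

groups <- aggregate(cbind(n_bolting, n_total) ~ parent_genotype, fam, sum)
names(groups)[1] <- "group"
cmp <- compare_rates(groups, adjust = "holm")
print(cmp)
write.table(cmp, "results/f3_rate_comparisons.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
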