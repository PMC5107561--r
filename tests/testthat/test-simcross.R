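test_that("catalog site counts follow the configured density and are sorted", {
  cfg <- cross_sim_config(scaffolds = c(s1 = 1e6), snp_density = 1e-3,
                          causal = list(scaffold = "s1", pos = 1000L),
                          seed = 1L)
  set.seed(cfg$seed)
  cat <- simulate_catalog(cfg)
  # Poisson(1000) central 95% interval
  expect_gte(nrow(cat), qpois(0.025, 1e6 * 1e-3))
  expect_lte(nrow(cat), qpois(0.975, 1e6 * 1e-3))
  expect_true(all(diff(cat$pos) > 0))
  expect_true(all(cat$ref != cat$alt))
  expect_true(1000L %in% cat$pos)
  expect_equal(cat$kind[cat$pos == 1000L], "cross_specific")
})

test_that("the causal site is always present, even at negligible density", {
  cfg <- cross_sim_config(scaffolds = c(s1 = 1e5, s2 = 1e7),
                          snp_density = 1e-6,
                          causal = list(scaffold = "s1", pos = 500L),
                          seed = 3L)
  set.seed(cfg$seed)
  cat <- simulate_catalog(cfg)
  expect_true(any(cat$scaffold == "s1" & cat$pos == 500L &
                    cat$kind == "cross_specific"))
})

test_that("ref_divergent_fraction 0 yields a purely cross-specific catalog", {
  cfg <- small_config(ref_divergent_fraction = 0)
  set.seed(cfg$seed)
  cat <- simulate_catalog(cfg)
  expect_true(all(cat$kind == "cross_specific"))
  expect_false(any(cat$alt_parent == "both"))
})

test_that("zero scaffolds is a configuration error", {
  expect_error(cross_sim_config(scaffolds = numeric(0)), "scaffold")
})

test_that("single-site genotype frequencies are Mendelian 1:2:1", {
  cfg <- cross_sim_config(scaffolds = c(s1 = 1e5), snp_density = 1e-4,
                          causal = list(scaffold = "s1", pos = 50000L),
                          n_f2 = 10000L, n_b_pool = 10L,
                          crossover_lambda_per_bp = 0, seed = 7L)
  set.seed(cfg$seed)
  cat <- simulate_catalog(cfg)
  pop <- simulate_f2(cfg, cat)
  counts <- table(factor(pop$plants$causal_genotype,
                         levels = c("BRBR", "BRbr", "brbr")))
  p <- as.vector(counts) / cfg$n_f2
  se3 <- 3 * sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) / cfg$n_f2)
  expect_true(all(abs(p - c(0.25, 0.5, 0.25)) < se3))
  # and the segregation test itself is non-significant
  expect_gt(chi_square_ratio(as.vector(counts), c(1, 2, 1))$p_value, 0.01)
})

test_that("penetrance controls the resistant count", {
  cfg0 <- small_config(penetrance_resistant = 0, n_f2 = 300L, seed = 11L)
  set.seed(cfg0$seed)
  pop0 <- simulate_f2(cfg0, simulate_catalog(cfg0))
  expect_equal(sum(pop0$plants$phenotype == "resistant"), 0L)
  expect_true(all(pop0$plants$phenotype[pop0$plants$causal_genotype !=
                                          "brbr"] == "bolting"))

  # Monte-Carlo mean resistant count at the published design values
  cfg <- cross_sim_config(scaffolds = c(s1 = 1e5), snp_density = 1e-4,
                          causal = list(scaffold = "s1", pos = 50000L),
                          n_f2 = 410L, n_b_pool = 10L,
                          crossover_lambda_per_bp = 0, seed = 1L)
  set.seed(99L)
  cat <- simulate_catalog(cfg)
  n_res <- replicate(200, {
    pop <- simulate_f2(cfg, cat)
    sum(pop$plants$phenotype == "resistant")
  })
  expected <- 410 * 0.25 * 26 / 95          # ~28.05
  mc_se <- sqrt(410 * 0.0684 * (1 - 0.0684) / 200)
  expect_lt(abs(mean(n_res) - expected), 4 * mc_se)
})

test_that("pools are built from phenotypes and are disjoint", {
  cfg <- small_config(seed = 5L)
  set.seed(cfg$seed)
  pop <- simulate_f2(cfg, simulate_catalog(cfg))
  pools <- make_pools(pop, cfg$n_b_pool)
  expect_setequal(pools$br_ids,
                  pop$plants$id[pop$plants$phenotype == "resistant"])
  expect_length(pools$b_ids, cfg$n_b_pool)
  expect_length(intersect(pools$br_ids, pools$b_ids), 0)

  n_bolting <- sum(pop$plants$phenotype == "bolting")
  all_b <- make_pools(pop, n_bolting)
  expect_setequal(all_b$b_ids, pop$plants$id[pop$plants$phenotype == "bolting"])
  expect_error(make_pools(pop, n_bolting + 1L), "bolting")

  pop$plants$phenotype <- "bolting"
  expect_error(make_pools(pop, 10L), "empty br pool")
})

# a hand-built one-plant population with fixed parental origins
# (1 = resistant parent, 0 = bolting parent), no crossovers
fixed_population <- function(parents = c(1L, 0L)) {
  cfg <- small_config()
  structure(list(
    plants = data.frame(id = "p1", causal_genotype = "BRbr",
                        phenotype = "bolting", stringsAsFactors = FALSE),
    haplotypes = list(list(scA = list(
      hap1 = list(start = parents[1], breaks = numeric(0)),
      hap2 = list(start = parents[2], breaks = numeric(0))))),
    config = cfg), class = "f2_population")
}

test_that("pooled read sampling matches the binomial model", {
  pop <- fixed_population()
  n <- 10000L
  catalog <- data.frame(scaffold = "scA", pos = seq_len(n),
                        kind = "cross_specific", ref = "A", alt = "T",
                        alt_parent = "P_br", stringsAsFactors = FALSE)

  # f = 0.5 at every site (one alt haplotype of two), no error
  set.seed(21L)
  reads <- sample_pool_reads(pop, "p1", catalog, mean_depth = 50,
                             error_rate = 0)
  frac <- sum(reads$alt_count) / sum(reads$ref_count + reads$alt_count)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / (n * 50)))

  # f = 0 with no error: never an alt read (both haplotypes from P_b)
  pop_b <- fixed_population(c(0L, 0L))
  catalog$alt_parent <- "P_br"
  set.seed(22L)
  reads0 <- sample_pool_reads(pop_b, "p1", catalog, 50, 0)
  expect_true(all(reads0$alt_count == 0))

  # f = 1 with error 0.01: mean alt fraction ~ 0.99
  catalog$alt_parent <- "both"
  set.seed(23L)
  reads1 <- sample_pool_reads(pop, "p1", catalog, 50, 0.01)
  frac1 <- sum(reads1$alt_count) / sum(reads1$ref_count + reads1$alt_count)
  expect_lt(abs(frac1 - 0.99), 0.005)
})

test_that("br pool is monomorphic and unlinked b-pool frequencies sit at 0.5", {
  cfg <- cross_sim_config(seed = 17L)
  ds <- simulate_dataset(cfg)
  # every resistant plant is homozygous recessive by construction
  res <- ds$population$plants[match(ds$pools$br_ids, ds$population$plants$id), ]
  expect_true(all(res$causal_genotype == "brbr"))
  # true br alt frequency at the causal site is exactly 0 or 1
  alt_haps <- bsascan:::pool_alt_hap_counts(ds$population, ds$pools$br_ids,
                                            ds$catalog)
  i <- which(ds$catalog$scaffold == cfg$causal$scaffold &
               ds$catalog$pos == cfg$causal$pos)
  expect_true(alt_haps[i] %in% c(0L, 2L * length(ds$pools$br_ids)))
  # ref_divergent sites are alt-saturated in both pools (truth level)
  rd <- ds$catalog$kind == "ref_divergent"
  expect_true(all(alt_haps[rd] == 2L * length(ds$pools$br_ids)))
  # unlinked cross-specific sites: mean b-pool alt frequency ~ 0.5
  other <- ds$sites$scaffold != cfg$causal$scaffold & !rd
  bfreq <- ds$sites$b_alt[other] / (ds$sites$b_ref[other] +
                                      ds$sites$b_alt[other])
  expect_lt(abs(mean(bfreq, na.rm = TRUE) - 0.5), 0.02)
})

test_that("identical config and seed give identical datasets and files", {
  cfg <- small_config(seed = 31L)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$sites, d2$sites)
  expect_identical(d1$pools, d2$pools)

  t1 <- file.path(tempdir(), "exp1"); t2 <- file.path(tempdir(), "exp2")
  mk <- data.frame(scaffold = "scA", pos = c(250000L, 750000L))
  export_dataset(d1, t1, mk)
  export_dataset(d2, t2, mk)
  for (f in c("variants.vcf", "phenotypes.tsv", "markers.tsv", "config.yaml"))
    expect_identical(readLines(file.path(t1, f)),
                     readLines(file.path(t2, f)))
  unlink(c(t1, t2), recursive = TRUE)
})

test_that("gamete segments tile the scaffold and alternate parents", {
  set.seed(41L)
  for (k in 1:20) {
    g <- bsascan:::make_gamete(1e5, 3e-5)  # ~3 crossovers
    seg <- gamete_segments(g, 1e5)
    expect_equal(seg$start[1], 1L)
    expect_equal(seg$end[nrow(seg)], 100000L)
    if (nrow(seg) > 1L) {
      expect_true(all(seg$start[-1] == seg$end[-nrow(seg)] + 1L))
      expect_true(all(seg$parent[-1] != seg$parent[-nrow(seg)]))
    }
    # segment parent agrees with hap_origin at segment midpoints
    mid <- floor((seg$start + seg$end) / 2)
    expect_equal(c("P_b", "P_br")[bsascan:::hap_origin(g, mid) + 1L],
                 seg$parent)
  }
})
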