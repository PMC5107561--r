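#' Configuration for simulating an F2 pooled-sequencing experiment
#'
#' Collects every parameter of the cross simulator: the reference scaffolds,
#' polymorphic-site density, the causal locus, penetrance of the recessive
#' resistance allele, population and pool sizes, per-pool sequencing depths,
#' the per-base miscall rate and the meiotic crossover rate.
#'
#' @param scaffolds named numeric vector of scaffold lengths in bp.
#' @param snp_density expected cross-specific polymorphic sites per bp.
#' @param ref_divergent_fraction fraction of catalog sites at which both
#'   parents carry the same non-reference allele (divergence from the
#'   reference genotype rather than between the parents).
#' @param causal list with `scaffold` and `pos` (1-based) of the causal site.
#' @param penetrance_resistant probability that a plant homozygous for the
#'   recessive resistance allele expresses the resistant phenotype.
#'   Default 26/95, the fraction observed among genotyped homozygotes.
#' @param n_f2 number of F2 plants.
#' @param n_b_pool number of bolting plants sampled into the bolting pool.
#' @param mean_depth_br,mean_depth_b mean per-site read depth of the
#'   resistant (br) and bolting (b) pool.
#' @param error_rate per-base miscall probability in `[0, 0.5)`.
#' @param crossover_lambda_per_bp Poisson mean crossovers per gamete per bp.
#'   The default corresponds to one expected crossover per 5 Mb scaffold.
#' @param seed integer seed recorded with the dataset.
#' @return an object of class `cross_sim_config`.
#' @export
cross_sim_config <- function(scaffolds = c(sca1 = 5e6, sca2 = 5e6),
                             snp_density = 1e-3,
                             ref_divergent_fraction = 0.4,
                             causal = list(scaffold = "sca1", pos = 2500000L),
                             penetrance_resistant = 26 / 95,
                             n_f2 = 410L,
                             n_b_pool = 297L,
                             mean_depth_br = 60,
                             mean_depth_b = 30,
                             error_rate = 0.005,
                             crossover_lambda_per_bp = 2e-7,
                             seed = 1L) {
  if (length(scaffolds) == 0L)
    stop("configuration error: at least one scaffold is required")
  if (is.null(names(scaffolds)) || anyNA(names(scaffolds)) ||
      any(names(scaffolds) == ""))
    stop("configuration error: scaffolds must be a named vector of lengths")
  if (any(scaffolds < 1)) stop("scaffold lengths must be positive")
  if (snp_density <= 0) stop("snp_density must be > 0")
  if (ref_divergent_fraction < 0 || ref_divergent_fraction > 1)
    stop("ref_divergent_fraction must be in [0, 1]")
  if (!causal$scaffold %in% names(scaffolds))
    stop("causal scaffold not among the configured scaffolds")
  if (causal$pos < 1 || causal$pos > scaffolds[[causal$scaffold]])
    stop("causal position outside its scaffold")
  if (penetrance_resistant < 0 || penetrance_resistant > 1)
    stop("penetrance_resistant must be in [0, 1]")
  if (n_f2 < 1) stop("n_f2 must be positive")
  if (n_b_pool < 1) stop("n_b_pool must be positive")
  if (mean_depth_br <= 0 || mean_depth_b <= 0)
    stop("mean depths must be > 0")
  if (error_rate < 0 || error_rate >= 0.5)
    stop("error_rate must be in [0, 0.5)")
  if (crossover_lambda_per_bp < 0) stop("crossover rate must be >= 0")
  if (snp_density * sum(scaffolds) < 1)
    stop("expected total site count below 1; increase snp_density or lengths")
  structure(list(
    scaffolds = scaffolds,
    snp_density = snp_density,
    ref_divergent_fraction = ref_divergent_fraction,
    causal = list(scaffold = causal$scaffold, pos = as.integer(causal$pos)),
    penetrance_resistant = penetrance_resistant,
    n_f2 = as.integer(n_f2),
    n_b_pool = as.integer(n_b_pool),
    mean_depth_br = mean_depth_br,
    mean_depth_b = mean_depth_b,
    error_rate = error_rate,
    crossover_lambda_per_bp = crossover_lambda_per_bp,
    seed = as.integer(seed)
  ), class = "cross_sim_config")
}

BASES <- c("A", "C", "G", "T")

#' Simulate the catalog of polymorphic sites
#'
#' Draws site positions per scaffold as a Poisson process at `snp_density`
#' sites per bp. A fraction `ref_divergent_fraction` of sites is flagged
#' `ref_divergent` (both parents homozygous for the same non-reference
#' allele); the rest are `cross_specific` (the two parents differ, so the
#' F2 segregates). The causal position is always included as a
#' cross-specific site. At each cross-specific site the parent carrying the
#' non-reference allele is drawn at random (either parent may match the
#' reference genotype, which is a third accession).
#'
#' @param config a [cross_sim_config()].
#' @return data.frame with columns `scaffold`, `pos`, `kind`, `ref`, `alt`
#'   and `alt_parent` (`P_br`, `P_b`, or `both`), sorted by scaffold then
#'   position; class `site_catalog`.
#' @export
simulate_catalog <- function(config) {
  stopifnot(inherits(config, "cross_sim_config"))
  out <- lapply(names(config$scaffolds), function(sc) {
    len <- config$scaffolds[[sc]]
    n <- stats::rpois(1L, config$snp_density * len)
    pos <- sort(sample.int(len, min(n, len), replace = FALSE))
    if (sc == config$causal$scaffold && !(config$causal$pos %in% pos))
      pos <- sort(c(pos, config$causal$pos))
    if (length(pos) == 0L) return(NULL)
    kind <- ifelse(stats::runif(length(pos)) < config$ref_divergent_fraction,
                   "ref_divergent", "cross_specific")
    ref <- sample(BASES, length(pos), replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1L), "")
    alt_parent <- ifelse(kind == "ref_divergent", "both",
                         ifelse(stats::runif(length(pos)) < 0.5, "P_br", "P_b"))
    data.frame(scaffold = sc, pos = as.integer(pos), kind = kind,
               ref = ref, alt = unname(alt), alt_parent = alt_parent,
               stringsAsFactors = FALSE)
  })
  cat <- do.call(rbind, out)
  rownames(cat) <- NULL
  # the causal site must segregate in the cross
  i <- which(cat$scaffold == config$causal$scaffold &
               cat$pos == config$causal$pos)
  if (cat$kind[i] != "cross_specific") {
    cat$kind[i] <- "cross_specific"
    cat$alt_parent[i] <- sample(c("P_br", "P_b"), 1L)
  }
  class(cat) <- c("site_catalog", "data.frame")
  cat
}

# One gamete for one scaffold: crossover points are continuous uniforms,
# parental origin alternates from a fair random start.  Encoded as the
# starting parent index (0 = P_b, 1 = P_br) plus the sorted break points.
make_gamete <- function(len, lambda_per_bp, parent_start = NULL) {
  k <- stats::rpois(1L, lambda_per_bp * len)
  list(start = if (is.null(parent_start)) sample(0:1, 1L) else parent_start,
       breaks = sort(stats::runif(k, 0, len)))
}

# Parental origin (0 = P_b, 1 = P_br) of one haplotype at given positions.
hap_origin <- function(gamete, pos) {
  (gamete$start + findInterval(pos, gamete$breaks)) %% 2L
}

#' Expand a gamete into explicit origin segments
#'
#' Returns the tiling of `[1, len]` into maximal parental-origin segments,
#' alternating between `P_br` and `P_b`.
#' @param gamete internal gamete representation (start parent + break points).
#' @param len scaffold length in bp.
#' @return data.frame with `start`, `end` (1-based inclusive), `parent`.
#' @export
gamete_segments <- function(gamete, len) {
  cuts <- floor(gamete$breaks)
  cuts <- cuts[cuts >= 1 & cuts < len]
  starts <- c(1L, as.integer(cuts) + 1L)
  ends <- c(as.integer(cuts), as.integer(len))
  parent <- c("P_b", "P_br")[((gamete$start + seq_along(starts) - 1L) %% 2L) + 1L]
  keep <- starts <= ends
  seg <- data.frame(start = starts[keep], end = ends[keep],
                    parent = parent[keep], stringsAsFactors = FALSE)
  # two crossovers within one bp cancel: merge same-parent neighbours
  grp <- cumsum(c(TRUE, seg$parent[-1] != seg$parent[-nrow(seg)]))
  data.frame(start = tapply(seg$start, grp, min)[unique(grp)],
             end = tapply(seg$end, grp, max)[unique(grp)],
             parent = seg$parent[!duplicated(grp)],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulate the F2 population
#'
#' Each plant receives two independent gametes per scaffold; crossover
#' counts are Poisson with mean `crossover_lambda_per_bp * length`.
#' The genotype at the causal site follows from the parental origins of the
#' two haplotypes; the phenotype is resistant with probability
#' `penetrance_resistant` if and only if the plant is homozygous for the
#' resistance allele, and bolting otherwise.
#'
#' @param config a [cross_sim_config()].
#' @param catalog a `site_catalog` (used only to validate the causal site).
#' @return object of class `f2_population`: list with `plants` (data.frame
#'   `id`, `causal_genotype`, `phenotype`) and `haplotypes` (per plant, per
#'   scaffold, a pair of gametes).
#' @export
simulate_f2 <- function(config, catalog) {
  stopifnot(inherits(config, "cross_sim_config"))
  if (nrow(catalog) == 0L) stop("site catalog is empty")
  sc_names <- names(config$scaffolds)
  haplos <- vector("list", config$n_f2)
  geno <- character(config$n_f2)
  for (i in seq_len(config$n_f2)) {
    haps <- lapply(sc_names, function(sc) {
      len <- config$scaffolds[[sc]]
      list(hap1 = make_gamete(len, config$crossover_lambda_per_bp),
           hap2 = make_gamete(len, config$crossover_lambda_per_bp))
    })
    names(haps) <- sc_names
    haplos[[i]] <- haps
    at <- haps[[config$causal$scaffold]]
    n_br <- hap_origin(at$hap1, config$causal$pos) +
      hap_origin(at$hap2, config$causal$pos)
    geno[i] <- c("BRBR", "BRbr", "brbr")[n_br + 1L]
  }
  resistant <- geno == "brbr" &
    stats::runif(config$n_f2) < config$penetrance_resistant
  plants <- data.frame(
    id = sprintf("F2_%03d", seq_len(config$n_f2)),
    causal_genotype = geno,
    phenotype = ifelse(resistant, "resistant", "bolting"),
    stringsAsFactors = FALSE
  )
  structure(list(plants = plants, haplotypes = haplos, config = config),
            class = "f2_population")
}

#' Pool plants by phenotype
#'
#' The resistant (br) pool contains every resistant plant; the bolting (b)
#' pool is a simple random sample, without replacement, of `n_b_pool`
#' bolting plants.
#'
#' @param population an `f2_population`.
#' @param n_b_pool size of the bolting pool.
#' @return list with character vectors `br_ids` and `b_ids`.
#' @export
make_pools <- function(population, n_b_pool) {
  plants <- population$plants
  br_ids <- plants$id[plants$phenotype == "resistant"]
  bolting <- plants$id[plants$phenotype == "bolting"]
  if (length(br_ids) == 0L)
    stop("empty br pool: no resistant plants were generated")
  if (n_b_pool > length(bolting))
    stop("n_b_pool exceeds the number of bolting plants (",
         length(bolting), ")")
  b_ids <- sort(sample(bolting, n_b_pool))
  list(br_ids = br_ids, b_ids = b_ids)
}

# True count of non-reference haplotypes in a set of plants at every
# catalog site.  At a cross-specific site the alt allele rides on one
# parental background; at a ref-divergent site every haplotype is alt.
pool_alt_hap_counts <- function(population, ids, catalog) {
  idx <- match(ids, population$plants$id)
  alt_counts <- integer(nrow(catalog))
  n_hap <- 2L * length(idx)
  for (sc in unique(catalog$scaffold)) {
    rows <- which(catalog$scaffold == sc)
    pos <- catalog$pos[rows]
    want_br <- catalog$alt_parent[rows] == "P_br"
    is_both <- catalog$alt_parent[rows] == "both"
    acc <- integer(length(rows))  # count of P_br-origin haplotypes
    for (i in idx) {
      haps <- population$haplotypes[[i]][[sc]]
      acc <- acc + hap_origin(haps$hap1, pos) + hap_origin(haps$hap2, pos)
    }
    alt <- ifelse(want_br, acc, n_hap - acc)
    alt[is_both] <- n_hap
    alt_counts[rows] <- alt
  }
  alt_counts
}

#' Sample pooled read counts at every catalog site
#'
#' Per site, the true pool alt-allele frequency is the fraction of
#' non-reference haplotypes among the pooled plants. Depth is Poisson with
#' the given mean; the alt read count is binomial with success probability
#' `f (1 - e) + (1 - f) e`, folding the per-base miscall rate into both
#' directions.
#'
#' @param population an `f2_population`.
#' @param ids plant ids in the pool.
#' @param catalog a `site_catalog`.
#' @param mean_depth mean per-site depth.
#' @param error_rate per-base miscall probability.
#' @return data.frame `ref_count`, `alt_count`, one row per catalog site.
#' @export
sample_pool_reads <- function(population, ids, catalog, mean_depth,
                              error_rate) {
  if (length(ids) == 0L) stop("pool is empty")
  alt_haps <- pool_alt_hap_counts(population, ids, catalog)
  f <- alt_haps / (2 * length(ids))
  p <- f * (1 - error_rate) + (1 - f) * error_rate
  depth <- stats::rpois(nrow(catalog), mean_depth)
  alt <- stats::rbinom(nrow(catalog), depth, p)
  data.frame(ref_count = depth - alt, alt_count = alt)
}

#' Run the whole simulator
#'
#' Seeds the RNG from `config$seed`, then generates the site catalog, the
#' F2 population, the phenotype pools and the pooled read counts for both
#' pools. This is the one entry point whose output is fully determined by
#' the configuration.
#'
#' @param config a [cross_sim_config()].
#' @return object of class `bsa_dataset`: list with `config`, `catalog`,
#'   `population`, `pools`, and `sites` (a pooled-site table with columns
#'   `scaffold`, `pos`, `ref`, `alt`, `br_ref`, `br_alt`, `b_ref`, `b_alt`).
#' @export
simulate_dataset <- function(config) {
  set.seed(config$seed)
  catalog <- simulate_catalog(config)
  population <- simulate_f2(config, catalog)
  pools <- make_pools(population, config$n_b_pool)
  br <- sample_pool_reads(population, pools$br_ids, catalog,
                          config$mean_depth_br, config$error_rate)
  b <- sample_pool_reads(population, pools$b_ids, catalog,
                         config$mean_depth_b, config$error_rate)
  sites <- data.frame(
    scaffold = catalog$scaffold, pos = catalog$pos,
    ref = catalog$ref, alt = catalog$alt,
    br_ref = br$ref_count, br_alt = br$alt_count,
    b_ref = b$ref_count, b_alt = b$alt_count,
    stringsAsFactors = FALSE
  )
  structure(list(config = config, catalog = catalog,
                 population = population, pools = pools, sites = sites),
            class = "bsa_dataset")
}

#' Marker genotypes of every plant at chosen positions
#'
#' Codominant encoding: `A` = homozygous for the resistant-parent
#' haplotype, `B` = homozygous for the bolting-parent haplotype,
#' `H` = heterozygous.
#'
#' @param population an `f2_population`.
#' @param markers data.frame with `scaffold` and `pos`.
#' @return character matrix, plants in rows, markers in columns named
#'   `<scaffold>:<pos>`.
#' @export
marker_genotypes <- function(population, markers) {
  sc_len <- population$config$scaffolds
  bad <- !(markers$scaffold %in% names(sc_len)) |
    markers$pos < 1 | markers$pos > sc_len[markers$scaffold]
  if (any(bad))
    stop("marker positions outside any scaffold: ",
         paste(markers$scaffold[bad], markers$pos[bad], sep = ":",
               collapse = ", "))
  n <- nrow(population$plants)
  out <- matrix("", n, nrow(markers),
                dimnames = list(population$plants$id,
                                paste0(markers$scaffold, ":", markers$pos)))
  for (j in seq_len(nrow(markers))) {
    sc <- markers$scaffold[j]; pos <- markers$pos[j]
    for (i in seq_len(n)) {
      haps <- population$haplotypes[[i]][[sc]]
      n_br <- hap_origin(haps$hap1, pos) + hap_origin(haps$hap2, pos)
      out[i, j] <- c("B", "H", "A")[n_br + 1L]
    }
  }
  out
}

#' Simulate F3 family bolting rates by selfing F2 plants
#'
#' Offspring of a selfed F2 plant segregate Mendelianly at the causal
#' locus; each offspring bolts unless it is homozygous recessive and the
#' penetrance draw makes it resistant. Family bolting rate is the fraction
#' of bolting offspring.
#'
#' @param parent_genotypes character vector in
#'   `{hom_recessive, het, hom_dominant}`, one per family.
#' @param family_sizes integer vector (recycled) of plants per family.
#' @param penetrance_resistant penetrance of resistance in homozygotes.
#' @return data.frame `family_id`, `parent_genotype`, `n_bolting`, `n_total`.
#' @export
simulate_f3_families <- function(parent_genotypes, family_sizes = 20L,
                                 penetrance_resistant = 26 / 95) {
  n <- length(parent_genotypes)
  sizes <- rep_len(as.integer(family_sizes), n)
  p_rr <- c(hom_recessive = 1, het = 0.25, hom_dominant = 0)[parent_genotypes]
  if (anyNA(p_rr)) stop("unknown parent genotype class")
  p_resist <- unname(p_rr) * penetrance_resistant
  n_resistant <- stats::rbinom(n, sizes, p_resist)
  data.frame(
    family_id = sprintf("F3_%03d", seq_len(n)),
    parent_genotype = parent_genotypes,
    n_bolting = sizes - n_resistant,
    n_total = sizes,
    stringsAsFactors = FALSE
  )
}
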