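# Shared fixtures and independent oracles, built in code at test time.

# Small, fast simulator configuration for unit tests.
small_config <- function(seed = 1L, ...) {
  args <- list(
    scaffolds = c(scA = 1e6, scB = 1e6),
    snp_density = 2e-4,
    causal = list(scaffold = "scA", pos = 500000L),
    n_f2 = 120L,
    n_b_pool = 60L,
    seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(cross_sim_config, args)
}

# Hand-build a called_sites table for scanner tests.
make_called <- function(scaffold, pos, b_call, br_call,
                        br_freq = ifelse(br_call == "HOM_ALT", 1,
                                         ifelse(br_call == "HOM_REF", 0, 0.5)),
                        candidate = b_call == "HET" &
                          br_call %in% c("HOM_REF", "HOM_ALT")) {
  out <- data.frame(scaffold = scaffold, pos = as.integer(pos),
                    b_call = b_call, br_call = br_call,
                    br_freq = br_freq, candidate = candidate,
                    stringsAsFactors = FALSE)
  out <- out[order(out$scaffold, out$pos), ]
  rownames(out) <- NULL
  class(out) <- c("called_sites", "data.frame")
  out
}

# Brute-force monomorphic-region finder: enumerate all (i, j) site pairs
# per scaffold among the b-HET sites and keep maximal all-monomorphic runs.
regions_bruteforce <- function(called, min_sites,
                               mode = c("by_call", "exact")) {
  mode <- match.arg(mode)
  out <- list()
  for (sc in unique(called$scaffold)) {
    rows <- called[called$scaffold == sc & called$b_call == "HET", ]
    rows <- rows[order(rows$pos), ]
    n <- nrow(rows)
    if (n == 0L) next
    mono <- if (mode == "by_call") rows$br_call %in% c("HOM_REF", "HOM_ALT")
            else !is.na(rows$br_freq) & rows$br_freq %in% c(0, 1)
    for (i in seq_len(n)) for (j in i:n) {
      if (!all(mono[i:j])) next
      maximal <- (i == 1L || !mono[i - 1L]) && (j == n || !mono[j + 1L])
      if (maximal && (j - i + 1L) >= min_sites)
        out[[length(out) + 1L]] <- data.frame(
          scaffold = sc, start = rows$pos[i], end = rows$pos[j],
          n_sites = j - i + 1L, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(scaffold = character(), start = integer(),
                      end = integer(), n_sites = integer()))
  res <- do.call(rbind, out)
  res[order(res$scaffold, res$start), ]
}

# Random called-sites instance for oracle-equivalence checks.
random_called <- function(n_sites, n_scaffolds = 2L) {
  sc <- sort(sample(paste0("s", seq_len(n_scaffolds)), n_sites,
                    replace = TRUE))
  pos <- unlist(lapply(split(seq_len(n_sites), sc), function(ix)
    sort(sample.int(10000L, length(ix)))), use.names = FALSE)
  make_called(
    scaffold = sc, pos = pos,
    b_call = sample(c("HET", "HOM_REF", "HOM_ALT", "NO_CALL"), n_sites,
                    replace = TRUE, prob = c(0.6, 0.15, 0.15, 0.1)),
    br_call = sample(c("HET", "HOM_REF", "HOM_ALT", "NO_CALL"), n_sites,
                     replace = TRUE, prob = c(0.3, 0.3, 0.3, 0.1)))
}

# Independent chi-square upper-tail probability by numerical integration
# of the density written from its formula.
chisq_tail_integral <- function(x, df) {
  if (x <= 0) return(1)
  dens <- function(t) t^(df / 2 - 1) * exp(-t / 2) /
    (2^(df / 2) * gamma(df / 2))
  stats::integrate(dens, lower = x, upper = Inf, rel.tol = 1e-10,
                   abs.tol = 1e-12)$value
}

# Independent Clopper-Pearson bounds by root-finding on direct summation
# of binomial tail probabilities.
clopper_pearson_bruteforce <- function(x, n, level = 0.95) {
  a <- (1 - level) / 2
  upper_tail <- function(p) sum(stats::dbinom(x:n, n, p))   # P(X >= x)
  lower_tail <- function(p) sum(stats::dbinom(0:x, n, p))   # P(X <= x)
  lo <- if (x == 0) 0 else
    stats::uniroot(function(p) upper_tail(p) - a, c(1e-12, 1 - 1e-12),
                   tol = 1e-12)$root
  hi <- if (x == n) 1 else
    stats::uniroot(function(p) lower_tail(p) - a, c(1e-12, 1 - 1e-12),
                   tol = 1e-12)$root
  c(lo, hi)
}

# Edit a sequence through an exploded character list (oracle for
# apply_variants): delete ref characters, splice alt characters.
apply_variants_bruteforce <- function(seq, variants) {
  chars <- strsplit(seq, "")[[1]]
  slots <- as.list(chars)                       # one slot per original base
  ins_before <- character(length(chars) + 1L)   # pure insertions
  for (k in seq_len(nrow(variants))) {
    pos <- variants$pos[k]; ref <- variants$ref[k]; alt <- variants$alt[k]
    if (nchar(ref) == 0L) {
      ins_before[pos] <- paste0(ins_before[pos], alt)
    } else {
      stopifnot(paste(chars[pos:(pos + nchar(ref) - 1L)], collapse = "") == ref)
      for (i in pos:(pos + nchar(ref) - 1L)) slots[[i]] <- ""
      slots[[pos]] <- alt
    }
  }
  parts <- character(0)
  for (i in seq_along(chars))
    parts <- c(parts, ins_before[i], slots[[i]])
  paste0(paste(parts, collapse = ""), ins_before[length(chars) + 1L])
}

# Classify a single edit by diffing the Biostrings-translated proteins.
consequence_bruteforce <- function(ref_seq, variants) {
  alt_seq <- apply_variants_bruteforce(ref_seq, variants)
  if (identical(alt_seq, ref_seq)) return("no_change")
  tr <- function(s) {
    s <- substr(s, 1L, 3L * (nchar(s) %/% 3L))
    p <- as.character(Biostrings::translate(Biostrings::DNAString(s),
                                            no.init.codon = TRUE))
    stop_at <- regexpr("*", p, fixed = TRUE)
    if (stop_at > 0) list(protein = substr(p, 1L, stop_at - 1L),
                          terminated = TRUE)
    else list(protein = p, terminated = FALSE)
  }
  rp <- tr(ref_seq); ap <- tr(alt_seq)
  net <- nchar(alt_seq) - nchar(ref_seq)
  if (net %% 3L != 0L) return("frameshift")
  ref_stop <- if (rp$terminated) nchar(rp$protein) + 1L else Inf
  alt_stop <- if (ap$terminated) nchar(ap$protein) + 1L else Inf
  if (ap$terminated && alt_stop < ref_stop + net / 3) return("stop_gained")
  if (rp$terminated && !ap$terminated) return("stop_lost")
  if (net != 0L) return("inframe_indel")
  if (ap$protein != rp$protein) return("missense")
  "synonymous"
}

# Random stop-free-prefix CDS for effects tests.
random_cds <- function(n_codons) {
  safe <- setdiff(names(bsascan:::CODON_TABLE),
                  c("TAA", "TAG", "TGA"))
  paste0("ATG", paste(sample(safe, n_codons - 2L, replace = TRUE),
                      collapse = ""), "TAA")
}

# One random single-edit variant for a given sequence.
random_variant <- function(seq) {
  n <- nchar(seq)
  type <- sample(c("snp", "ins", "del"), 1L)
  if (type == "snp") {
    pos <- sample.int(n, 1L)
    ref <- substr(seq, pos, pos)
    cds_variant(pos, ref, sample(setdiff(c("A", "C", "G", "T"), ref), 1L))
  } else if (type == "ins") {
    pos <- sample.int(n, 1L)
    cds_variant(pos, "",
                paste(sample(c("A", "C", "G", "T"), sample.int(4L, 1L),
                             replace = TRUE), collapse = ""))
  } else {
    len <- sample.int(4L, 1L)
    pos <- sample.int(n - len - 3L, 1L) + 3L  # keep the start codon
    cds_variant(pos, substr(seq, pos, pos + len - 1L), "")
  }
}
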