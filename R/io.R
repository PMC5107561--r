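#' Read a pooled-variant table (VCF subset or TSV dialect)
#'
#' The VCF subset carries two samples, `br_pool` and `b_pool`, with an
#' `AD` FORMAT field holding "ref,alt" integer depths. Only biallelic
#' records are accepted; multiallelic or AD-missing records are skipped
#' and counted. The TSV dialect has columns `scaffold pos ref alt br_ref
#' br_alt b_ref b_alt` and yields the identical in-memory table.
#'
#' @param path file path; `.vcf` selects the VCF reader, anything else
#'   the TSV reader.
#' @return data.frame of pooled sites sorted as on disk; attribute
#'   `n_skipped` counts rejected records.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sites <- if (grepl("\\.vcf$", path)) read_variants_vcf(path)
           else read_variants_tsv(path)
  ord <- order(sites$scaffold, sites$pos)
  if (!identical(ord, seq_len(nrow(sites))))
    stop("variant records are not sorted by (scaffold, pos)")
  sites
}

read_variants_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- v@gt
  if (!all(c("br_pool", "b_pool") %in% colnames(gt)))
    stop("malformed header: VCF must carry samples br_pool and b_pool")
  ad_idx <- vapply(strsplit(gt[, "FORMAT"], ":"),
                   function(f) match("AD", f), 0L)
  parse_ad <- function(sample) {
    field <- mapply(function(s, i) {
      if (is.na(i)) return(NA_character_)
      strsplit(s, ":")[[1]][i]
    }, gt[, sample], ad_idx, USE.NAMES = FALSE)
    parts <- strsplit(field, ",")
    list(ref = suppressWarnings(as.integer(vapply(parts, `[`, "", 1L))),
         alt = suppressWarnings(as.integer(vapply(parts, function(p)
           if (length(p) >= 2L) p[2L] else NA_character_, ""))))
  }
  br <- parse_ad("br_pool")
  b <- parse_ad("b_pool")
  multi <- grepl(",", fix$ALT)
  bad_ad <- is.na(br$ref) | is.na(br$alt) | is.na(b$ref) | is.na(b$alt)
  keep <- !multi & !bad_ad
  n_skipped <- sum(!keep)
  if (n_skipped > 0L)
    message("skipped ", n_skipped, " record(s): ",
            sum(multi), " multiallelic, ", sum(bad_ad & !multi), " AD-missing")
  out <- data.frame(scaffold = fix$CHROM[keep],
                    pos = as.integer(fix$POS[keep]),
                    ref = fix$REF[keep], alt = fix$ALT[keep],
                    br_ref = br$ref[keep], br_alt = br$alt[keep],
                    b_ref = b$ref[keep], b_alt = b$alt[keep],
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- n_skipped
  out
}

read_variants_tsv <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("scaffold", "pos", "ref", "alt",
           "br_ref", "br_alt", "b_ref", "b_alt")
  if (!all(req %in% names(out)))
    stop("TSV variant table must have columns: ", paste(req, collapse = ", "))
  multi <- grepl(",", out$alt)
  if (any(multi))
    message("skipped ", sum(multi), " multiallelic record(s)")
  res <- out[!multi, req]
  rownames(res) <- NULL
  attr(res, "n_skipped") <- sum(multi)
  res
}

#' Write a pooled-variant table as a two-sample VCF
#'
#' @param sites data.frame with `scaffold`, `pos`, `ref`, `alt`,
#'   `br_ref`, `br_alt`, `b_ref`, `b_alt`.
#' @param path output path.
#' @param contig_lengths optional named vector written as contig headers.
#' @export
write_variants_vcf <- function(sites, path, contig_lengths = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=bsascan",
    if (!is.null(contig_lengths))
      sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
              as.integer(contig_lengths)),
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "br_pool", "b_pool", sep = "\t")
  )
  body <- paste(sites$scaffold, sites$pos, ".", sites$ref, sites$alt,
                ".", ".", ".", "AD",
                paste0(sites$br_ref, ",", sites$br_alt),
                paste0(sites$b_ref, ",", sites$b_alt), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a pooled-variant table in the TSV dialect
#' @inheritParams write_variants_vcf
#' @export
write_variants_tsv <- function(sites, path) {
  utils::write.table(
    sites[c("scaffold", "pos", "ref", "alt",
            "br_ref", "br_alt", "b_ref", "b_alt")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write monomorphic regions as BED or TSV
#'
#' BED converts the 1-based inclusive `[start, end]` to 0-based half-open
#' `[start - 1, end)`; the TSV dialect keeps 1-based inclusive coordinates
#' plus the `length_bp` and `n_sites` columns. The conversion is an exact
#' bijection, see [read_regions()].
#'
#' @param regions data.frame from [find_monomorphic_regions()].
#' @param path output path.
#' @param dialect `"bed"` or `"tsv"`.
#' @export
write_regions <- function(regions, path, dialect = c("tsv", "bed")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") {
    lines <- paste(regions$scaffold, regions$start - 1L, regions$end,
                   sep = "\t")
    writeLines(c("#chrom\tchromStart\tchromEnd", lines), path)
  } else {
    utils::write.table(
      regions[c("scaffold", "start", "end", "length_bp", "n_sites")],
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read monomorphic regions back from BED or TSV
#' @param path file path.
#' @param dialect `"bed"` or `"tsv"` (BED coordinates are converted back
#'   to 1-based inclusive).
#' @return data.frame `scaffold`, `start`, `end`, `length_bp` (and
#'   `n_sites` for TSV).
#' @export
read_regions <- function(path, dialect = c("tsv", "bed")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") {
    tab <- utils::read.delim(path, comment.char = "#", header = FALSE,
                             col.names = c("scaffold", "chromStart",
                                           "chromEnd"))
    data.frame(scaffold = as.character(tab$scaffold),
               start = tab$chromStart + 1L, end = tab$chromEnd,
               length_bp = tab$chromEnd - tab$chromStart,
               stringsAsFactors = FALSE)
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
}

#' Write a phenotype table
#' @param population an `f2_population`.
#' @param path output path.
#' @export
write_phenotypes <- function(population, path) {
  utils::write.table(population$plants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#' @param path TSV with `id`, `causal_genotype`, `phenotype`.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a marker-genotype table
#' @param genotypes matrix from [marker_genotypes()].
#' @param path output path; columns are `plant_id` then one column per
#'   marker named `<scaffold>:<pos>`.
#' @export
write_marker_table <- function(genotypes, path) {
  df <- data.frame(plant_id = rownames(genotypes), genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a marker-genotype table into a marker_matrix
#' @param path TSV written by [write_marker_table()].
#' @return a [marker_matrix()].
#' @export
read_marker_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  geno <- as.matrix(df[, -1, drop = FALSE])
  rownames(geno) <- df$plant_id
  parts <- strsplit(colnames(geno), ":", fixed = TRUE)
  markers <- data.frame(
    name = colnames(geno),
    scaffold = vapply(parts, `[`, "", 1L),
    pos = as.integer(vapply(parts, `[`, "", 2L)),
    stringsAsFactors = FALSE)
  marker_matrix(markers, geno)
}

#' Write the simulator configuration as YAML
#' @param config a [cross_sim_config()].
#' @param path output path.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$scaffolds <- as.list(x$scaffolds)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' Read a simulator configuration from YAML
#' @param path YAML written by [write_sim_config()].
#' @return a [cross_sim_config()].
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  cross_sim_config(
    scaffolds = unlist(x$scaffolds),
    snp_density = x$snp_density,
    ref_divergent_fraction = x$ref_divergent_fraction,
    causal = x$causal,
    penetrance_resistant = x$penetrance_resistant,
    n_f2 = x$n_f2,
    n_b_pool = x$n_b_pool,
    mean_depth_br = x$mean_depth_br,
    mean_depth_b = x$mean_depth_b,
    error_rate = x$error_rate,
    crossover_lambda_per_bp = x$crossover_lambda_per_bp,
    seed = x$seed)
}

#' Export a simulated dataset to disk
#'
#' Writes the variant table (VCF), the phenotype table, a marker-genotype
#' table at the chosen positions (omitted when `marker_positions` is
#' empty) and the configuration with its seed — everything needed to
#' re-run the analysis from files. Deterministic: identical dataset gives
#' byte-identical files.
#'
#' @param dataset a `bsa_dataset` from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @param marker_positions data.frame with `scaffold`, `pos`, or NULL.
#' @return invisible named vector of the written paths.
#' @export
export_dataset <- function(dataset, dir, marker_positions = NULL) {
  stopifnot(inherits(dataset, "bsa_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    variants = file.path(dir, "variants.vcf"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    config = file.path(dir, "config.yaml")
  )
  write_variants_vcf(dataset$sites, paths[["variants"]],
                     contig_lengths = dataset$config$scaffolds)
  write_phenotypes(dataset$population, paths[["phenotypes"]])
  write_sim_config(dataset$config, paths[["config"]])
  if (!is.null(marker_positions) && nrow(marker_positions) > 0L) {
    paths[["markers"]] <- file.path(dir, "markers.tsv")
    geno <- marker_genotypes(dataset$population, marker_positions)
    write_marker_table(geno, paths[["markers"]])
  }
  invisible(paths)
}
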