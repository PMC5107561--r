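#' Thresholds for pooled genotype classification
#'
#' @param min_joint_coverage minimum summed depth over both pools for a
#'   site to be considered at all (candidate filter). Default 50.
#' @param min_pool_depth minimum per-pool depth below which a pool is
#'   NO_CALL. Default 10.
#' @param het_band numeric length-2: alt-frequency band `(low, high)`
#'   classified heterozygous; below is HOM_REF, above HOM_ALT.
#' @return object of class `call_config`.
#' @export
call_config <- function(min_joint_coverage = 50L, min_pool_depth = 10L,
                        het_band = c(0.15, 0.85)) {
  if (min_joint_coverage < 0 || min_pool_depth < 0)
    stop("coverage thresholds must be non-negative")
  if (length(het_band) != 2L || het_band[1] <= 0 || het_band[2] >= 1 ||
      het_band[1] >= het_band[2])
    stop("het_band must satisfy 0 < low < high < 1")
  structure(list(min_joint_coverage = as.integer(min_joint_coverage),
                 min_pool_depth = as.integer(min_pool_depth),
                 het_band = as.numeric(het_band)),
            class = "call_config")
}

#' Classify a pool from its allele depths
#'
#' Frequency-band rule: depth below `min_pool_depth` gives NO_CALL;
#' otherwise with `q = alt / (ref + alt)`, `q < low` is HOM_REF,
#' `q > high` is HOM_ALT, and anything in between is HET. Vectorised over
#' the count arguments.
#'
#' @param ref_count,alt_count non-negative integer vectors.
#' @param config a [call_config()].
#' @return data.frame `state`, `alt_frequency` (NA at depth 0), `depth`.
#' @export
classify_pool <- function(ref_count, alt_count, config = call_config()) {
  if (any(ref_count < 0) || any(alt_count < 0))
    stop("allele counts must be non-negative")
  depth <- ref_count + alt_count
  q <- ifelse(depth > 0, alt_count / depth, NA_real_)
  state <- ifelse(depth < config$min_pool_depth, "NO_CALL",
           ifelse(q < config$het_band[1], "HOM_REF",
           ifelse(q > config$het_band[2], "HOM_ALT", "HET")))
  data.frame(state = state, alt_frequency = q, depth = as.integer(depth),
             stringsAsFactors = FALSE)
}

#' Call both pools and flag candidate sites
#'
#' A site is a candidate when the joint depth over both pools reaches
#' `min_joint_coverage`, the bolting pool is heterozygous, and the
#' resistant pool is homozygous (either allele). Heterozygosity in the b
#' pool excludes positions where both parents diverge identically from the
#' reference; homozygosity in the br pool is the mapping signal. Every
#' input site is returned with its calls — candidacy is a flag, not a
#' subset — so downstream scans can use all b-HET sites as denominator.
#'
#' @param sites data.frame with `scaffold`, `pos`, `br_ref`, `br_alt`,
#'   `b_ref`, `b_alt`, sorted by scaffold then position.
#' @param config a [call_config()].
#' @return the input with added columns `br_call`, `br_freq`, `b_call`,
#'   `b_freq`, `joint_depth`, `candidate`; class `called_sites`.
#' @export
filter_candidates <- function(sites, config = call_config()) {
  req <- c("scaffold", "pos", "br_ref", "br_alt", "b_ref", "b_alt")
  if (!all(req %in% names(sites)))
    stop("sites must have columns: ", paste(req, collapse = ", "))
  ord <- order(sites$scaffold, sites$pos)
  if (!identical(ord, seq_len(nrow(sites))))
    stop("sites must be sorted by (scaffold, pos)")
  if (anyDuplicated(sites[c("scaffold", "pos")]))
    stop("duplicate site positions")
  br <- classify_pool(sites$br_ref, sites$br_alt, config)
  b <- classify_pool(sites$b_ref, sites$b_alt, config)
  out <- sites
  out$br_call <- br$state
  out$br_freq <- br$alt_frequency
  out$b_call <- b$state
  out$b_freq <- b$alt_frequency
  out$joint_depth <- br$depth + b$depth
  out$candidate <- out$joint_depth >= config$min_joint_coverage &
    out$b_call == "HET" & out$br_call %in% c("HOM_REF", "HOM_ALT")
  class(out) <- c("called_sites", "data.frame")
  out
}

#' Subset a called-site table to the candidate sites
#' @param called output of [filter_candidates()].
#' @return the candidate rows.
#' @export
candidates <- function(called) {
  stopifnot(inherits(called, "called_sites"))
  called[called$candidate, , drop = FALSE]
}
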