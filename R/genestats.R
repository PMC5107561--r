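#' Chi-square goodness-of-fit test against a segregation ratio
#'
#' Tests observed genotype class counts against expected proportions given
#' as ratio weights (e.g. `c(1, 2, 1)` for an F2 codominant marker). The
#' statistic is Pearson's sum of squared deviations over expectation;
#' the p-value is the upper chi-square tail on `k - 1` degrees of freedom.
#'
#' @param observed integer vector of class counts.
#' @param ratio_weights positive weights defining the expected ratio;
#'   invariant under rescaling.
#' @return list with `statistic`, `df`, `p_value`, `expected`; class
#'   `seg_test`.
#' @export
chi_square_ratio <- function(observed, ratio_weights) {
  if (length(observed) != length(ratio_weights))
    stop("observed and ratio_weights must have equal length")
  if (any(ratio_weights <= 0)) stop("ratio weights must be positive")
  total <- sum(observed)
  if (total < 1) stop("total observed count must be >= 1")
  expected <- total * ratio_weights / sum(ratio_weights)
  if (any(expected == 0)) stop("expected count of zero")
  statistic <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  structure(list(statistic = statistic, df = df,
                 p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
                 expected = expected),
            class = "seg_test")
}

#' @export
print.seg_test <- function(x, ...) {
  cat(sprintf("Segregation chi-square: X^2 = %.3f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Genotype-based phenotype prediction accuracy
#'
#' Prediction rule of a fully recessive locus: homozygous-recessive plants
#' are predicted resistant, all others bolting. Accuracy is the fraction
#' of plants whose observed phenotype matches.
#'
#' @param pheno data.frame with columns `genotype` (values `hom_recessive`,
#'   `het`, `hom_dominant`), `n_resistant`, `n_bolting`.
#' @param counts optional integer vector of per-genotype totals named by
#'   class; checked for consistency with `pheno` when given.
#' @return accuracy in `[0, 1]`.
#' @export
prediction_accuracy <- function(pheno, counts = NULL) {
  req <- c("genotype", "n_resistant", "n_bolting")
  if (!all(req %in% names(pheno)))
    stop("pheno must have columns: ", paste(req, collapse = ", "))
  classes <- c("hom_recessive", "het", "hom_dominant")
  if (!all(pheno$genotype %in% classes) || anyDuplicated(pheno$genotype))
    stop("genotype must be one row each of: ", paste(classes, collapse = ", "))
  totals <- pheno$n_resistant + pheno$n_bolting
  if (!is.null(counts)) {
    if (!all(pheno$genotype %in% names(counts)) ||
        any(counts[pheno$genotype] != totals))
      stop("genotype totals inconsistent with phenotype table")
  }
  correct <- ifelse(pheno$genotype == "hom_recessive",
                    pheno$n_resistant, pheno$n_bolting)
  sum(correct) / sum(totals)
}

#' Penetrance of resistance among homozygous-recessive plants
#'
#' Point estimate `n_resistant / n_hom_recessive` with an exact
#' Clopper-Pearson binomial confidence interval. The complement
#' `1 - estimate` is the fraction of homozygotes that nevertheless bolt.
#'
#' @param n_resistant resistant homozygotes.
#' @param n_hom_recessive all homozygous-recessive plants.
#' @param ci_level confidence level (default 0.95).
#' @return list `estimate`, `ci_low`, `ci_high`, `ci_level`.
#' @export
penetrance_estimate <- function(n_resistant, n_hom_recessive,
                                ci_level = 0.95) {
  if (n_hom_recessive < 1) stop("n_hom_recessive must be >= 1")
  if (n_resistant < 0 || n_resistant > n_hom_recessive)
    stop("n_resistant must be in [0, n_hom_recessive]")
  ci <- stats::binom.test(n_resistant, n_hom_recessive,
                          conf.level = ci_level)$conf.int
  list(estimate = n_resistant / n_hom_recessive,
       ci_low = ci[1], ci_high = ci[2], ci_level = ci_level)
}

#' Per-group summaries of family bolting rates
#'
#' Each family's bolting rate is `n_bolting / n_total`; families are
#' grouped by the genotype of their selfed parent and summarised by the
#' unweighted mean, sample standard deviation (n - 1 denominator, NA for
#' singleton groups) and family count. Genotype classes with no families
#' are omitted with a warning.
#'
#' @param families data.frame `family_id`, `parent_genotype`, `n_bolting`,
#'   `n_total`.
#' @return data.frame `parent_genotype`, `mean_rate`, `sd_rate`, `n_families`.
#' @export
family_rates <- function(families) {
  if (any(families$n_total < 1)) stop("every family needs n_total >= 1")
  if (any(families$n_bolting < 0 | families$n_bolting > families$n_total))
    stop("n_bolting must be in [0, n_total]")
  classes <- c("hom_recessive", "het", "hom_dominant")
  present <- intersect(classes, unique(families$parent_genotype))
  missing <- setdiff(classes, present)
  if (length(missing))
    warning("no families for group(s): ", paste(missing, collapse = ", "),
            "; omitted")
  rate <- families$n_bolting / families$n_total
  out <- do.call(rbind, lapply(present, function(g) {
    r <- rate[families$parent_genotype == g]
    data.frame(parent_genotype = g, mean_rate = mean(r),
               sd_rate = if (length(r) > 1L) stats::sd(r) else NA_real_,
               n_families = length(r), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Pairwise comparison of bolting rates between groups
#'
#' For every pair of groups a 2x2 Pearson chi-square test (no continuity
#' correction by default) compares bolting versus non-bolting counts;
#' p-values are adjusted for the number of pairs.
#'
#' @param groups data.frame with `group`, `n_bolting`, `n_total`.
#' @param adjust multiple-testing adjustment: `holm` (default),
#'   `bonferroni` or `bh`.
#' @param correct apply Yates continuity correction (default FALSE).
#' @return data.frame `group1`, `group2`, `statistic`, `p_raw`, `p_adj`.
#' @export
compare_rates <- function(groups, adjust = c("holm", "bonferroni", "bh"),
                          correct = FALSE) {
  adjust <- match.arg(adjust)
  if (nrow(groups) < 2L) stop("need at least two groups")
  if (any(groups$n_total < 1)) stop("every group needs n_total >= 1")
  pairs <- utils::combn(nrow(groups), 2L)
  res <- apply(pairs, 2L, function(ij) {
    i <- ij[1]; j <- ij[2]
    tab <- rbind(c(groups$n_bolting[i], groups$n_total[i] - groups$n_bolting[i]),
                 c(groups$n_bolting[j], groups$n_total[j] - groups$n_bolting[j]))
    if (any(colSums(tab) == 0)) {
      # both groups all-bolting (or all-resistant): no association testable
      c(statistic = 0, p = 1)
    } else {
      ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
      c(statistic = unname(ht$statistic), p = ht$p.value)
    }
  })
  out <- data.frame(group1 = groups$group[pairs[1, ]],
                    group2 = groups$group[pairs[2, ]],
                    statistic = res["statistic", ],
                    p_raw = res["p", ],
                    stringsAsFactors = FALSE)
  out$p_adj <- stats::p.adjust(out$p_raw,
                               method = c(holm = "holm",
                                          bonferroni = "bonferroni",
                                          bh = "BH")[[adjust]])
  out
}
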