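#' Build a codominant marker matrix
#'
#' Genotypes use the codominant convention: `A` = homozygous for the
#' resistant-parent allele, `B` = homozygous for the bolting-parent
#' allele, `H` = heterozygous, `NA` = missing.
#'
#' @param markers data.frame with `name`, `scaffold`, `pos`; sorted by
#'   `(scaffold, pos)` on construction.
#' @param genotypes character matrix, plants in rows (rownames = plant
#'   ids), one column per marker in the order of `markers`.
#' @return object of class `marker_matrix`.
#' @export
marker_matrix <- function(markers, genotypes) {
  stopifnot(all(c("name", "scaffold", "pos") %in% names(markers)))
  if (ncol(genotypes) != nrow(markers))
    stop("genotype matrix has ", ncol(genotypes),
         " columns but there are ", nrow(markers), " markers")
  if (is.null(rownames(genotypes))) stop("genotype rows must be named by plant")
  ok <- is.na(genotypes) | genotypes %in% c("A", "H", "B")
  if (!all(ok)) stop("genotypes must be A, H, B or NA")
  ord <- order(markers$scaffold, markers$pos)
  markers <- markers[ord, , drop = FALSE]
  rownames(markers) <- NULL
  genotypes <- genotypes[, ord, drop = FALSE]
  colnames(genotypes) <- markers$name
  structure(list(markers = markers, genotypes = genotypes),
            class = "marker_matrix")
}

#' Check every plant's genotype at a focal marker
#'
#' @param mm a [marker_matrix()].
#' @param focal_marker marker name.
#' @param expected expected genotype class (`A`, `H` or `B`).
#' @return list: `per_plant` named logical (missing = FALSE), `n_match`,
#'   `n_total`, `missing_ids`.
#' @export
verify_locus_genotype <- function(mm, focal_marker, expected = "A") {
  stopifnot(inherits(mm, "marker_matrix"))
  if (!focal_marker %in% mm$markers$name)
    stop("unknown marker: ", focal_marker)
  g <- mm$genotypes[, focal_marker]
  match <- !is.na(g) & g == expected
  list(per_plant = match,
       n_match = sum(match),
       n_total = length(g),
       missing_ids = names(g)[is.na(g)])
}

#' Detect crossover breakpoints from a marker matrix
#'
#' For each plant and scaffold, every adjacent pair of non-missing marker
#' genotypes that differ implies at least one crossover between the two
#' marker positions. Missing genotypes are skipped over, so the transition
#' is assessed between the nearest flanking non-missing markers and the
#' reported interval widens accordingly. Double crossovers between
#' adjacent markers are undetectable by construction.
#'
#' @param mm a [marker_matrix()].
#' @return data.frame `plant_id`, `scaffold`, `left_marker`,
#'   `right_marker`, `pos_left`, `pos_right`, `from`, `to`.
#' @export
detect_breakpoints <- function(mm) {
  stopifnot(inherits(mm, "marker_matrix"))
  if (nrow(mm$markers) < 2L) stop("need at least two markers")
  mk <- mm$markers
  rows <- list()
  for (pid in rownames(mm$genotypes)) {
    g <- mm$genotypes[pid, ]
    for (sc in unique(mk$scaffold)) {
      idx <- which(mk$scaffold == sc & !is.na(g))
      if (length(idx) < 2L) next
      for (k in seq_len(length(idx) - 1L)) {
        i <- idx[k]; j <- idx[k + 1L]
        if (g[i] != g[j]) {
          rows[[length(rows) + 1L]] <- data.frame(
            plant_id = pid, scaffold = sc,
            left_marker = mk$name[i], right_marker = mk$name[j],
            pos_left = mk$pos[i], pos_right = mk$pos[j],
            from = unname(g[i]), to = unname(g[j]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(plant_id = character(), scaffold = character(),
                      left_marker = character(), right_marker = character(),
                      pos_left = integer(), pos_right = integer(),
                      from = character(), to = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Nearest recombination intervals flanking a focal marker
#'
#' Among all detected breakpoints on the focal marker's scaffold, returns
#' the breakpoint interval closest to the focal position on each side —
#' the resolution bound that the recombinant plants impose on the mapped
#' locus. A side with no breakpoint is reported as open (NULL).
#'
#' @param breakpoints output of [detect_breakpoints()].
#' @param mm the [marker_matrix()] the breakpoints came from.
#' @param focal_marker marker name.
#' @return list `nearest_left`, `nearest_right` (each a one-row
#'   data.frame or NULL when that side is open).
#' @export
flank_refinement <- function(breakpoints, mm, focal_marker) {
  stopifnot(inherits(mm, "marker_matrix"))
  i <- match(focal_marker, mm$markers$name)
  if (is.na(i)) stop("unknown marker: ", focal_marker)
  sc <- mm$markers$scaffold[i]
  fpos <- mm$markers$pos[i]
  bp <- breakpoints[breakpoints$scaffold == sc, , drop = FALSE]
  left <- bp[bp$pos_right <= fpos, , drop = FALSE]
  right <- bp[bp$pos_left >= fpos, , drop = FALSE]
  pick <- function(side, dist) {
    if (nrow(side) == 0L) return(NULL)
    side[which.min(dist), , drop = FALSE]
  }
  list(nearest_left = pick(left, fpos - left$pos_right),
       nearest_right = pick(right, right$pos_left - fpos))
}
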