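#' Sliding-window and region-detection parameters
#'
#' @param window_bp window size in bp (default 200 kb).
#' @param step_bp step between window starts in bp (default 100 kb).
#' @param min_region_sites minimum number of supporting sites for a
#'   reported monomorphic region (guards against error-driven short runs).
#' @param region_frequency_mode `"by_call"` treats a site as monomorphic
#'   in the br pool when its call is homozygous (tolerant of sequencing
#'   error); `"exact"` requires an observed alt frequency of exactly 0
#'   or 1.
#' @return object of class `scan_config`.
#' @export
scan_config <- function(window_bp = 200000L, step_bp = 100000L,
                        min_region_sites = 20L,
                        region_frequency_mode = c("by_call", "exact")) {
  if (window_bp < 1 || step_bp < 1) stop("window and step must be positive")
  if (step_bp > window_bp) stop("step_bp must not exceed window_bp")
  if (min_region_sites < 1) stop("min_region_sites must be >= 1")
  structure(list(window_bp = as.integer(window_bp),
                 step_bp = as.integer(step_bp),
                 min_region_sites = as.integer(min_region_sites),
                 region_frequency_mode = match.arg(region_frequency_mode)),
            class = "scan_config")
}

#' Tile a scaffold with sliding windows
#'
#' Windows start at 1, 1 + step, 1 + 2 step, ...; each ends at
#' `min(start + window - 1, scaffold_length)`. No window starts beyond the
#' scaffold. Coordinates are 1-based inclusive.
#'
#' @param scaffold_length scaffold length in bp.
#' @param config a [scan_config()].
#' @return data.frame `start`, `end`.
#' @export
make_windows <- function(scaffold_length, config = scan_config()) {
  stopifnot(scaffold_length >= 1)
  starts <- seq.int(1L, scaffold_length, by = config$step_bp)
  data.frame(start = starts,
             end = pmin(starts + config$window_bp - 1L,
                        as.integer(scaffold_length)))
}

#' Score sliding windows with the monomorphic-site count
#'
#' Per window, `n_polymorphic_b` counts the b-pool-heterozygous sites it
#' contains and `n_monomorphic_br` counts those that are candidates
#' (br pool homozygous). The peak of `n_monomorphic_br` marks the locus.
#'
#' @param called a `called_sites` table from [filter_candidates()].
#' @param scaffold_lengths named vector of scaffold lengths; defaults to
#'   the maximum site position per scaffold.
#' @param config a [scan_config()].
#' @return data.frame `scaffold`, `start`, `end`, `n_monomorphic_br`,
#'   `n_polymorphic_b`.
#' @export
score_windows <- function(called, scaffold_lengths = NULL,
                          config = scan_config()) {
  stopifnot(inherits(called, "called_sites"))
  scs <- unique(called$scaffold)
  if (is.null(scaffold_lengths))
    scaffold_lengths <- tapply(called$pos, called$scaffold, max)[scs]
  out <- lapply(scs, function(sc) {
    win <- make_windows(scaffold_lengths[[sc]], config)
    rows <- called[called$scaffold == sc, ]
    p_het <- sort(rows$pos[rows$b_call == "HET"])
    p_cand <- sort(rows$pos[rows$candidate])
    count_in <- function(p) findInterval(win$end, p) -
      findInterval(win$start - 1L, p)
    data.frame(scaffold = sc, start = win$start, end = win$end,
               n_monomorphic_br = count_in(p_cand),
               n_polymorphic_b = count_in(p_het),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Locate the peak window of the scan
#'
#' Maximal `n_monomorphic_br`; ties are broken by lexicographically
#' smallest `(scaffold, start)`, and all tied windows are reported.
#'
#' @param scores output of [score_windows()].
#' @return list with `peak` (one row) and `ties` (all maximal rows).
#' @export
find_peak <- function(scores) {
  if (is.null(scores) || nrow(scores) == 0L) stop("no window scores")
  m <- max(scores$n_monomorphic_br)
  ties <- scores[scores$n_monomorphic_br == m, , drop = FALSE]
  ties <- ties[order(ties$scaffold, ties$start), , drop = FALSE]
  rownames(ties) <- NULL
  list(peak = ties[1L, , drop = FALSE], ties = ties)
}

#' Resistant-pool allele-frequency track
#'
#' One point per b-pool-heterozygous site: the br-pool alt-read frequency.
#' Values pinned at 0 or 1 indicate positions monomorphic in the resistant
#' pool; unlinked regions fluctuate around 0.5. Sites with zero br depth
#' are dropped.
#'
#' @param called a `called_sites` table.
#' @return data.frame `scaffold`, `pos`, `br_alt_frequency`.
#' @export
allele_frequency_track <- function(called) {
  stopifnot(inherits(called, "called_sites"))
  rows <- called[called$b_call == "HET" & !is.na(called$br_freq), ]
  data.frame(scaffold = rows$scaffold, pos = rows$pos,
             br_alt_frequency = rows$br_freq,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Construct a monomorphic-region record
#'
#' Coordinates are 1-based inclusive; the span is `end - start + 1`.
#'
#' @param scaffold scaffold name.
#' @param start,end positions of the first and last supporting site.
#' @param n_sites number of supporting sites.
#' @param flank_left,flank_right nearest non-monomorphic b-HET position on
#'   each side (NA when none exists on that side).
#' @return one-row data.frame with `length_bp` computed.
#' @export
monomorphic_region <- function(scaffold, start, end, n_sites = NA_integer_,
                               flank_left = NA_integer_,
                               flank_right = NA_integer_) {
  stopifnot(end >= start, start >= 1)
  data.frame(scaffold = scaffold, start = as.integer(start),
             end = as.integer(end),
             length_bp = as.integer(end) - as.integer(start) + 1L,
             n_sites = as.integer(n_sites),
             flank_left = as.integer(flank_left),
             flank_right = as.integer(flank_right),
             stringsAsFactors = FALSE)
}

#' Detect contiguous monomorphic regions in the resistant pool
#'
#' Per scaffold, takes the b-pool-heterozygous sites in positional order
#' and finds every maximal run of consecutive sites that are monomorphic
#' in the br pool (homozygous call, or exact frequency 0/1 in `exact`
#' mode). Runs with at least `min_region_sites` sites are reported; region
#' boundaries are the outermost monomorphic sites of the run, and the
#' nearest flanking non-monomorphic b-HET positions bound the
#' recombination uncertainty.
#'
#' @param called a `called_sites` table from [filter_candidates()].
#' @param config a [scan_config()].
#' @return data.frame of regions (see [monomorphic_region()]), sorted by
#'   decreasing length.
#' @export
find_monomorphic_regions <- function(called, config = scan_config()) {
  stopifnot(inherits(called, "called_sites"))
  out <- lapply(unique(called$scaffold), function(sc) {
    rows <- called[called$scaffold == sc & called$b_call == "HET", ]
    rows <- rows[order(rows$pos), ]
    if (nrow(rows) == 0L) return(NULL)
    mono <- if (config$region_frequency_mode == "by_call") {
      rows$br_call %in% c("HOM_REF", "HOM_ALT")
    } else {
      !is.na(rows$br_freq) & (rows$br_freq == 0 | rows$br_freq == 1)
    }
    r <- rle(mono)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= config$min_region_sites
    if (!any(keep)) return(NULL)
    do.call(rbind, lapply(which(keep), function(k) {
      i <- starts[k]; j <- ends[k]
      monomorphic_region(
        scaffold = sc, start = rows$pos[i], end = rows$pos[j],
        n_sites = j - i + 1L,
        flank_left = if (i > 1L) rows$pos[i - 1L] else NA_integer_,
        flank_right = if (j < nrow(rows)) rows$pos[j + 1L] else NA_integer_
      )
    }))
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    return(monomorphic_region("x", 1, 1)[0, ])
  res <- res[order(-res$length_bp, res$scaffold, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
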