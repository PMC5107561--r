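# Standard nuclear genetic code; "*" marks stop codons.
CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

#' Construct a coding sequence
#'
#' @param id gene/transcript identifier.
#' @param sequence nucleotide string over A/C/G/T; the reading frame
#'   starts at position 1. A non-ATG start triggers a warning only (gene
#'   models may be partial), a non-ACGT character an error.
#' @return object of class `coding_sequence`.
#' @export
coding_sequence <- function(id, sequence) {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 3L) stop("coding sequence must be >= 3 nt")
  if (grepl("[^ACGT]", sequence))
    stop("coding sequence contains non-ACGT characters")
  if (substr(sequence, 1L, 3L) != "ATG")
    warning("coding sequence of ", id, " does not start with ATG")
  structure(list(id = id, sequence = sequence), class = "coding_sequence")
}

#' Describe one variant within a coding sequence
#'
#' `alt` replaces `ref` starting at `pos`; an empty `ref` is a pure
#' insertion before `pos`, an empty `alt` a pure deletion.
#'
#' @param pos 1-based position within the CDS.
#' @param ref,alt reference and alternative strings (not both empty).
#' @return one-row data.frame `pos`, `ref`, `alt`.
#' @export
cds_variant <- function(pos, ref, alt) {
  if (nchar(ref) == 0L && nchar(alt) == 0L)
    stop("ref and alt cannot both be empty")
  data.frame(pos = as.integer(pos), ref = toupper(ref), alt = toupper(alt),
             stringsAsFactors = FALSE)
}

#' Apply variants to a coding sequence
#'
#' Variants must not overlap and every `ref` must match the sequence at
#' its position. They are applied right-to-left so that earlier
#' coordinates stay valid throughout.
#'
#' @param cds a [coding_sequence()].
#' @param variants data.frame of [cds_variant()] rows (may be empty).
#' @return the edited `coding_sequence`.
#' @export
apply_variants <- function(cds, variants) {
  stopifnot(inherits(cds, "coding_sequence"))
  if (is.null(variants) || nrow(variants) == 0L) return(cds)
  v <- variants[order(variants$pos), , drop = FALSE]
  span_end <- v$pos + pmax(nchar(v$ref), 1L) - 1L
  if (nrow(v) > 1L && any(v$pos[-1L] <= span_end[-nrow(v)]))
    stop("overlapping variants")
  seq <- cds$sequence
  for (k in rev(seq_len(nrow(v)))) {
    pos <- v$pos[k]; ref <- v$ref[k]; alt <- v$alt[k]
    if (pos < 1L || pos + max(nchar(ref) - 1L, 0L) > nchar(seq))
      stop("variant at position ", pos, " outside the coding sequence")
    if (nchar(ref) > 0L && substr(seq, pos, pos + nchar(ref) - 1L) != ref)
      stop("reference mismatch at position ", pos, ": expected ", ref,
           ", found ", substr(seq, pos, pos + nchar(ref) - 1L))
    left <- if (pos > 1L) substr(seq, 1L, pos - 1L) else ""
    right <- substr(seq, pos + nchar(ref), nchar(seq))
    seq <- paste0(left, alt, right)
  }
  suppressWarnings(coding_sequence(cds$id, seq))
}

#' Translate a coding sequence
#'
#' Standard genetic code, frame fixed at position 1. Translation stops at
#' the first stop codon (not counted in the protein length); a trailing
#' incomplete codon is ignored; the absence of any stop codon is flagged.
#'
#' @param cds a [coding_sequence()] or nucleotide string.
#' @return list `protein` (amino-acid string), `terminated` (TRUE when a
#'   stop codon was reached).
#' @export
translate_cds <- function(cds) {
  seq <- if (inherits(cds, "coding_sequence")) cds$sequence else toupper(cds)
  if (grepl("[^ACGT]", seq)) stop("non-ACGT character in coding sequence")
  n_codon <- nchar(seq) %/% 3L
  if (n_codon < 1L) stop("coding sequence must be >= 3 nt")
  codons <- substring(seq, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
  aa <- unname(CODON_TABLE[codons])
  stop_at <- match("*", aa)
  if (is.na(stop_at)) {
    list(protein = paste(aa, collapse = ""), terminated = FALSE)
  } else {
    list(protein = paste(aa[seq_len(stop_at - 1L)], collapse = ""),
         terminated = TRUE)
  }
}

SEVERITY <- c("frameshift", "stop_gained", "stop_lost", "inframe_indel",
              "missense", "synonymous", "no_change")

#' Call the consequence of coding-sequence variants
#'
#' Translates the reference and edited CDS and classifies the combined
#' effect. A net indel length not divisible by 3 is a frameshift; a new
#' stop codon upstream of the reference stop is stop_gained; an in-frame
#' net indel is inframe_indel; equal-length proteins differing in residues
#' are missense; an identical protein from a changed nucleotide sequence
#' is synonymous. The primary `kind` is the most severe flag (frameshift >
#' stop_gained > inframe_indel > missense > synonymous); truncating
#' variants get a description of the form `"<alt> instead of <ref> aa"`.
#'
#' @param ref_cds a [coding_sequence()].
#' @param variants data.frame of [cds_variant()] rows.
#' @return list `kind`, `flags`, `ref_protein_length`,
#'   `alt_protein_length`, `ref_protein`, `alt_protein`, `description`;
#'   class `consequence`.
#' @export
call_consequence <- function(ref_cds, variants) {
  stopifnot(inherits(ref_cds, "coding_sequence"))
  alt_cds <- apply_variants(ref_cds, variants)
  ref_tr <- translate_cds(ref_cds)
  alt_tr <- translate_cds(alt_cds)
  net <- if (is.null(variants) || nrow(variants) == 0L) 0L else
    sum(nchar(variants$alt)) - sum(nchar(variants$ref))
  flags <- character()
  if (net %% 3L != 0L) flags <- c(flags, "frameshift")
  ref_len <- nchar(ref_tr$protein)
  alt_len <- nchar(alt_tr$protein)
  # stop position in codons (Inf when never terminated)
  ref_stop <- if (ref_tr$terminated) ref_len + 1L else Inf
  alt_stop <- if (alt_tr$terminated) alt_len + 1L else Inf
  # a stop earlier than length bookkeeping alone would predict
  if (alt_tr$terminated && alt_stop < ref_stop + net / 3)
    flags <- c(flags, "stop_gained")
  if (ref_tr$terminated && !alt_tr$terminated) flags <- c(flags, "stop_lost")
  if (net %% 3L == 0L && net != 0L) flags <- c(flags, "inframe_indel")
  if (net == 0L && alt_len == ref_len && alt_tr$protein != ref_tr$protein)
    flags <- c(flags, "missense")
  if (alt_tr$protein == ref_tr$protein && alt_cds$sequence != ref_cds$sequence)
    flags <- c(flags, "synonymous")
  kind <- if (identical(alt_cds$sequence, ref_cds$sequence)) "no_change"
          else if (length(flags) == 0L) "synonymous"
          else SEVERITY[min(match(flags, SEVERITY))]
  description <- if (alt_len < ref_len) {
    sprintf("%d instead of %d aa", alt_len, ref_len)
  } else {
    ""
  }
  structure(list(kind = kind, flags = flags,
                 ref_protein_length = ref_len,
                 alt_protein_length = alt_len,
                 ref_protein = ref_tr$protein,
                 alt_protein = alt_tr$protein,
                 description = description),
            class = "consequence")
}

#' @export
print.consequence <- function(x, ...) {
  cat(sprintf("consequence: %s (%s)%s\n", x$kind,
              paste(x$flags, collapse = ","),
              if (nzchar(x$description)) paste0(" — ", x$description) else ""))
  invisible(x)
}

#' Engineer a frameshift-demonstration coding sequence
#'
#' Builds a CDS of `ref_aa` codons plus stop from a repeating stop-free
#' codon unit, with the downstream sequence arranged so that a 2-bp
#' deletion inside codon `shift_at` shifts the frame into a premature
#' stop at codon `stop_at` of the shifted frame — the structural pattern
#' of a frameshifting deletion that truncates the protein.
#'
#' @param ref_aa reference protein length in aa.
#' @param shift_at codon at which the 2-bp deletion occurs.
#' @param stop_at codon (in the shifted frame) at which the new stop lands.
#' @return list `cds` (the reference [coding_sequence()]) and `deletion`
#'   (the [cds_variant()] 2-bp deletion).
#' @export
build_frameshift_cds <- function(ref_aa = 633L, shift_at = 191L,
                                 stop_at = 204L) {
  stopifnot(stop_at > shift_at, ref_aa > stop_at)
  # GCT repeats are stop-free in all three frames (GCT/CTG/TGC)
  codons <- rep("GCT", ref_aa)
  codons[1] <- "ATG"
  seq <- paste0(paste(codons, collapse = ""), "TAA")
  del_pos <- 3L * (shift_at - 1L) + 1L
  # after deleting 2 bp at del_pos, shifted codon k (k >= shift_at) reads
  # original positions (3k - 2 + 2) .. (3k + 2); plant TAA there for stop_at
  stop_pos <- 3L * stop_at
  ref2 <- substr(seq, del_pos, del_pos + 1L)
  seq <- paste0(substr(seq, 1L, stop_pos - 1L), "TAA",
                substr(seq, stop_pos + 3L, nchar(seq)))
  list(cds = coding_sequence("toy_frameshift", seq),
       deletion = cds_variant(del_pos, ref2, ""))
}
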