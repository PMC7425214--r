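# piRNA-trigger construct design: pick the phased strand of a donor locus,
# extract flanking sequences from the genome in donor-strand orientation, and
# fuse them around a gene-of-interest (GOI) segment. The guiding rule is that
# the phased strand of a piRNA locus is the superior backbone for a trigger.

#' Select the phased strand of a donor locus
#'
#' Returns the strand with the larger phasing Z-score; ties are broken toward
#' the strand with larger total weight, then plus. A warning is issued when
#' both Z-scores are below `z_sig` (weak donor), but a strand is still
#' returned.
#'
#' @param z_plus,z_minus per-strand phasing Z-scores.
#' @param w_plus,w_minus per-strand total read weights (tie-break).
#' @param z_sig weak-donor warning threshold.
#' @return `"+"` or `"-"`.
#' @export
select_phased_strand <- function(z_plus, z_minus, w_plus = 0, w_minus = 0,
                                 z_sig = 3) {
  if (max(z_plus, z_minus) < z_sig)
    warning(sprintf(
      "weak donor: both phasing Z-scores (%.2f, %.2f) below %.1f", z_plus,
      z_minus, z_sig))
  if (z_plus > z_minus) return("+")
  if (z_minus > z_plus) return("-")
  if (w_plus >= w_minus) "+" else "-"
}

#' Extract donor-locus flanking sequences
#'
#' Both intervals are 1-based inclusive on one chromosome, non-overlapping,
#' with `left` before `right` in genomic order. Sequences are fetched in
#' donor-strand orientation; the reported length is end - start + 1.
#'
#' @param genome a `GenomeStore`.
#' @param chrom chromosome/scaffold id.
#' @param left,right `c(start, end)` intervals.
#' @param strand donor strand.
#' @return list of two flank records (`left`, `right`), each with chrom,
#'   start, end, strand, length, seq.
#' @export
extract_flanks <- function(genome, chrom, left, right, strand = "+") {
  stopifnot(length(left) == 2L, length(right) == 2L,
            left[1] <= left[2], right[1] <= right[2])
  if (left[2] >= right[1])
    stop("flank intervals must be non-overlapping with left before right")
  mk <- function(iv) {
    list(chrom = chrom, start = as.integer(iv[1]), end = as.integer(iv[2]),
         strand = strand, length = as.integer(iv[2] - iv[1] + 1L),
         seq = fetch_seq(genome, chrom, iv[1], iv[2], strand))
  }
  list(left = mk(left), right = mk(right))
}

#' Build a piRNA-trigger fusion construct
#'
#' Concatenates left flank + GOI + right flank in donor-strand orientation.
#' On the plus strand the fused sequence is `left -> goi -> right`; on the
#' minus strand the genomic-right interval is the construct's 5' flank, so
#' the fusion is `rc(right) -> goi -> rc(left)` (flank sequences from
#' [extract_flanks()] are already donor-oriented). In `ds` mode the reverse
#' complement is emitted as a second FASTA record.
#'
#' @param flanks result of [extract_flanks()].
#' @param goi gene-of-interest sequence (character).
#' @param mode `"ss"` or `"ds"`.
#' @param donor_id donor locus identifier for provenance.
#' @param goi_id GOI identifier for provenance.
#' @return object of class `TriggerConstruct`.
#' @export
build_trigger <- function(flanks, goi, mode = c("ss", "ds"),
                          donor_id = "donor", goi_id = "goi") {
  mode <- match.arg(mode)
  stopifnot(nzchar(goi), nzchar(flanks$left$seq), nzchar(flanks$right$seq))
  goi <- normalize_seq(goi)
  if (grepl("[^ACGT]", goi))
    warning("ambiguous base(s) in the gene-of-interest sequence")
  strand <- flanks$left$strand
  fused <- if (strand == "+") {
    paste0(flanks$left$seq, goi, flanks$right$seq)
  } else {
    paste0(flanks$right$seq, goi, flanks$left$seq)
  }
  structure(list(donor_locus_id = donor_id, donor_strand = strand,
                 left_flank = flanks$left, right_flank = flanks$right,
                 goi = goi, goi_id = goi_id, fused_seq = fused, mode = mode),
            class = "TriggerConstruct")
}

#' @export
print.TriggerConstruct <- function(x, ...) {
  cat(sprintf(
    "TriggerConstruct: donor %s (%s strand), flanks %d + %d nt, GOI %s %d nt, mode %s, fused %d nt\n",
    x$donor_locus_id, x$donor_strand, x$left_flank$length,
    x$right_flank$length, x$goi_id, nchar(x$goi), x$mode, nchar(x$fused_seq)))
  invisible(x)
}

.trigger_header <- function(tc, record = c("sense", "antisense")) {
  record <- match.arg(record)
  sprintf(
    "%s_%s_%s donor=%s;strand=%s;left=%s:%d-%d;right=%s:%d-%d;goi=%s;goi_len=%d;mode=%s;record=%s",
    tc$donor_locus_id, tc$goi_id, record,
    tc$donor_locus_id, tc$donor_strand,
    tc$left_flank$chrom, tc$left_flank$start, tc$left_flank$end,
    tc$right_flank$chrom, tc$right_flank$start, tc$right_flank$end,
    tc$goi_id, nchar(tc$goi), tc$mode, record)
}

#' Write a trigger construct to FASTA
#'
#' One record in `ss` mode; in `ds` mode a second record carries the reverse
#' complement of the fused sequence. Headers carry full provenance
#' (donor locus, strand, flank intervals, GOI, mode) as `key=value` pairs and
#' round-trip through [parse_trigger_fasta()].
#'
#' @param tc a `TriggerConstruct`.
#' @param path output FASTA path.
#' @export
write_trigger_fasta <- function(tc, path) {
  stopifnot(is(tc, "TriggerConstruct"))
  seqs <- tc$fused_seq
  headers <- .trigger_header(tc, "sense")
  if (tc$mode == "ds") {
    seqs <- c(seqs, revcomp(tc$fused_seq))
    headers <- c(headers, .trigger_header(tc, "antisense"))
  }
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- headers
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Parse a trigger FASTA back into its provenance fields
#' @param path FASTA written by [write_trigger_fasta()].
#' @return list with donor_locus_id, donor_strand, left/right intervals,
#'   goi_id, goi length, mode, and the record sequences.
#' @export
parse_trigger_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- names(ss)[1]
  kv_str <- sub("^\\S+\\s+", "", hdr)
  kv <- strsplit(strsplit(kv_str, ";")[[1]], "=")
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  parse_iv <- function(s) {
    m <- regmatches(s, regexec("^(.+):([0-9]+)-([0-9]+)$", s))[[1]]
    list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
  }
  list(donor_locus_id = vals[["donor"]], donor_strand = vals[["strand"]],
       left = parse_iv(vals[["left"]]), right = parse_iv(vals[["right"]]),
       goi_id = vals[["goi"]], goi_len = as.integer(vals[["goi_len"]]),
       mode = vals[["mode"]],
       seqs = stats::setNames(as.character(ss), names(ss)))
}

#' Design a trigger from a donor locus end-to-end
#'
#' Convenience wrapper: choose the donor strand (`auto` uses
#' [select_phased_strand()] on the locus' per-strand phasing Z-scores),
#' extract the flanks, and build the construct.
#'
#' @param genome a `GenomeStore`.
#' @param locus one locus row with `z_phasing_plus`/`z_phasing_minus` (and
#'   optionally per-strand weights) when `strand = "auto"`.
#' @param left,right flank intervals `c(start, end)` on `locus$chrom`.
#' @param goi gene-of-interest sequence.
#' @param mode `"ss"` or `"ds"`.
#' @param strand `"auto"`, `"+"` or `"-"`.
#' @param goi_id GOI identifier.
#' @return a `TriggerConstruct`.
#' @export
design_trigger <- function(genome, locus, left, right, goi,
                           mode = c("ss", "ds"), strand = "auto",
                           goi_id = "goi") {
  mode <- match.arg(mode)
  if (strand == "auto") {
    wp <- if (!is.null(locus$plus_fraction) && !is.null(locus$w_total))
      locus$plus_fraction * locus$w_total else 0
    wm <- if (!is.null(locus$plus_fraction) && !is.null(locus$w_total))
      (1 - locus$plus_fraction) * locus$w_total else 0
    strand <- select_phased_strand(locus$z_phasing_plus, locus$z_phasing_minus,
                                   wp, wm)
  }
  flanks <- extract_flanks(genome, locus$chrom, left, right, strand)
  build_trigger(flanks, goi, mode = mode,
                donor_id = as.character(locus$locus_id), goi_id = goi_id)
}
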