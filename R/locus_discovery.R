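# Locus discovery: merge read pileups into candidate loci (both strands
# pooled), then triage by span, summed read weight, and the short/long
# size-class ratio.

#' Parameters for locus discovery
#'
#' A candidate locus is a maximal run of reads in which consecutive read
#' spans are separated by at most `merge_gap` read-free bases; it is kept iff
#' its span is at least `min_length` and its summed read weight is strictly
#' greater than `min_reads`.
#'
#' @param min_reads weighted read-count threshold (kept iff weight sum > this).
#' @param min_length minimum locus span in bp.
#' @param merge_gap maximum read-free gap joined into one locus, in bp.
#' @return object of class `LocusDiscoveryParams`.
#' @export
locus_discovery_params <- function(min_reads = 40, min_length = 500L,
                                   merge_gap = 200L) {
  stopifnot(min_reads > 0, min_length > 0, merge_gap > 0)
  structure(list(min_reads = min_reads, min_length = as.integer(min_length),
                 merge_gap = as.integer(merge_gap)),
            class = "LocusDiscoveryParams")
}

# per-group triage fields for one locus' reads
.locus_stats <- function(g, scheme) {
  short <- g$len >= scheme$short_range[1] & g$len <= scheme$short_range[2]
  long <- g$len >= scheme$long_range[1] & g$len <= scheme$long_range[2]
  ws <- sum(g$weight[short])
  wl <- sum(g$weight[long])
  wlong_u1 <- sum(g$weight[long & substr(g$seq, 1, 1) == "T"])
  list(w_short = ws, w_long = wl, w_total = sum(g$weight),
       ratio = if (wl == 0) Inf else ws / wl,
       plus_fraction = sum(g$weight[g$strand == "+"]) / sum(g$weight),
       u1_fraction_long = if (wl == 0) NA_real_ else wlong_u1 / wl,
       n_reads = sum(g$copies))
}

#' Discover small-RNA-producing loci from read pileups
#'
#' Reads on both strands are pooled per chromosome; read spans separated by
#' at most `merge_gap` bases are merged into one candidate locus (interval
#' reduction); candidates are kept iff span >= `min_length` and summed weight
#' > `min_reads`. Loci are returned sorted by coordinate with triage fields
#' populated (size-class weights, short/long ratio, strand fraction, 1U
#' fraction of long reads).
#'
#' @param reads a `ReadCollection`.
#' @param params a [locus_discovery_params()].
#' @param scheme a [size_class_scheme()].
#' @return data.table of loci (one row per locus, `locus_id` key).
#' @export
discover_loci <- function(reads, params = locus_discovery_params(),
                          scheme = size_class_scheme()) {
  dt <- data.table::as.data.table(reads)
  empty <- data.table::data.table(
    locus_id = character(), chrom = character(), start = integer(),
    end = integer(), length = integer(), w_short = numeric(),
    w_long = numeric(), w_total = numeric(), ratio = numeric(),
    plus_fraction = numeric(), u1_fraction_long = numeric(),
    n_reads = integer())
  if (nrow(dt) == 0L) return(empty)
  gr <- GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$start, dt$end))
  merged <- GenomicRanges::reduce(gr, min.gapwidth = params$merge_gap + 1L)
  hits <- GenomicRanges::findOverlaps(gr, merged)
  dt2 <- data.table::copy(dt)
  dt2[, locus_idx := S4Vectors::subjectHits(hits)]
  stats <- dt2[, c(list(chrom = chrom[1], start = min(start), end = max(end)),
                   .locus_stats(.SD, scheme)),
               by = locus_idx]
  stats[, length := end - start + 1L]
  keep <- stats[length >= params$min_length & w_total > params$min_reads]
  if (nrow(keep) == 0L) return(empty)
  data.table::setorder(keep, chrom, start, end)
  keep[, locus_id := sprintf("locus_%04d", seq_len(.N))]
  keep[, locus_idx := NULL]
  data.table::setcolorder(keep, c("locus_id", "chrom", "start", "end", "length",
                                  "w_short", "w_long", "w_total", "ratio",
                                  "plus_fraction", "u1_fraction_long", "n_reads"))
  keep[]
}

#' Reads falling inside a locus
#' @param reads a `ReadCollection`.
#' @param locus one locus row (list/data.frame with chrom, start, end).
#' @return `ReadCollection` of reads fully contained in the locus span.
#' @export
locus_reads <- function(reads, locus) {
  dt <- data.table::as.data.table(reads)
  out <- dt[chrom == locus$chrom & start >= locus$start & end <= locus$end]
  data.table::setattr(out, "class", class(reads))
  out
}

#' Short/long size-class ratio and bias label
#'
#' ratio = w_short / w_long; a locus is short-biased iff ratio > 1. A zero
#' long-class weight yields the +Inf sentinel (short-biased).
#'
#' @param loci locus table (or any table with `w_short`, `w_long`).
#' @return data.table with `locus_id` (if present), `ratio` and `bias`.
#' @export
size_ratio <- function(loci) {
  dt <- data.table::as.data.table(loci)
  out <- data.table::data.table(
    ratio = data.table::fifelse(dt$w_long == 0, Inf, dt$w_short / dt$w_long))
  out[, bias := data.table::fifelse(ratio > 1, "short", "long")]
  if ("locus_id" %in% names(dt)) out <- cbind(dt[, .(locus_id)], out)
  out[]
}

#' Top expressed loci of a given size bias
#'
#' Loci with the requested bias (short: ratio > 1; long: ratio <= 1), sorted
#' by total weight descending and truncated to `n`; ties broken by coordinate.
#'
#' @param loci locus table.
#' @param n number of loci to keep (default 50).
#' @param bias `"long"` or `"short"`.
#' @return subset of `loci`, ordered by expression.
#' @export
select_top_biased <- function(loci, n = 50L, bias = c("long", "short")) {
  bias <- match.arg(bias)
  stopifnot(n >= 1L)
  dt <- data.table::as.data.table(loci)
  lab <- size_ratio(dt)$bias
  sel <- dt[lab == bias]
  data.table::setorder(sel, -w_total, chrom, start)
  if (nrow(sel) < n)
    message("only ", nrow(sel), " ", bias, "-biased loci available (asked for ", n, ")")
  utils::head(sel, n)
}

#' Per-strand, per-size, unique/multimapper weight partition of a locus
#'
#' @param reads a `ReadCollection`.
#' @param locus one locus row.
#' @param sizes size window to tabulate (default 15:35).
#' @return data.table with strand, len, mapping (`unique`/`multi`), weight;
#'   attribute `plus_fraction` carries the strand fraction.
#' @export
strand_partition <- function(reads, locus = NULL, sizes = 15:35) {
  dt <- if (is.null(locus)) data.table::as.data.table(reads)
        else data.table::as.data.table(locus_reads(reads, locus))
  grid <- data.table::CJ(strand = c("+", "-"), len = sizes,
                         mapping = c("unique", "multi"))
  if (nrow(dt) == 0L) {
    grid[, weight := 0]
    data.table::setattr(grid, "plus_fraction", NA_real_)
    return(grid[])
  }
  dt[, mapping := data.table::fifelse(n_sites == 1L, "unique", "multi")]
  agg <- dt[, .(weight = sum(weight)), by = .(strand, len, mapping)]
  out <- merge(grid, agg, by = c("strand", "len", "mapping"), all.x = TRUE)
  out[is.na(weight), weight := 0]
  pf <- sum(dt$weight[dt$strand == "+"]) / sum(dt$weight)
  data.table::setattr(out, "plus_fraction", pf)
  out[]
}
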