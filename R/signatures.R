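# Pairwise biogenesis statistics:
#   * ping-pong: 5'-5' overlaps of opposite-strand read pairs (focal 10 nt);
#   * phasing: distance from a read's 3' end to downstream same-strand 1U
#     reads' 5' ends in transcription direction (end-to-end = 1, the focal);
#   * Dicer 2-nt 3'-overhang duplex geometry, tabulated by (query, target)
#     read size.
# Each spectrum is summarized by a Z-score of the focal offset against the
# whole offset range (population sd, focal bin included in the background).
# Pair weight is the product of the two reads' weights.

#' Construct an offset spectrum
#' @param counts numeric vector of weighted pair counts, one per offset.
#' @param offsets integer offsets.
#' @param focal the signature offset.
#' @param kind `"pingpong"` or `"phasing"`.
#' @return object of class `OffsetSpectrum`.
#' @export
offset_spectrum <- function(counts, offsets, focal, kind = "pingpong") {
  stopifnot(length(counts) == length(offsets), focal %in% offsets,
            all(counts >= 0))
  structure(list(kind = kind, offsets = as.integer(offsets),
                 counts = as.numeric(counts), focal = as.integer(focal)),
            class = "OffsetSpectrum")
}

#' @export
print.OffsetSpectrum <- function(x, ...) {
  cat(sprintf("OffsetSpectrum[%s]: offsets %d..%d, focal %d, Z = %.3f\n",
              x$kind, min(x$offsets), max(x$offsets), x$focal,
              spectrum_zscore(x)))
  invisible(x)
}

#' @export
as.data.frame.OffsetSpectrum <- function(x, ...) {
  data.frame(kind = x$kind, offset = x$offsets, count = x$counts)
}

.filter_region <- function(dt, region) {
  if (is.null(region)) return(dt)
  dt[chrom == region$chrom & start >= region$start & end <= region$end]
}

.filter_sizes <- function(dt, size_range) {
  if (is.null(size_range)) return(dt)
  dt[len >= size_range[1] & len <= size_range[2]]
}

#' Ping-pong 5'-5' overlap spectrum
#'
#' For every opposite-strand read pair on a chromosome, the 5'-5' overlap is
#' o = (minus-read 5') - (plus-read 5') + 1. Pairs with o inside `offsets`
#' contribute the product of the two weights to `counts[o]`. Ping-pong
#' amplification puts the focal at o = 10.
#'
#' @param reads a `ReadCollection`.
#' @param offsets overlap range (default 1:20).
#' @param focal signature overlap (default 10).
#' @param region optional list(chrom, start, end) restriction (reads fully
#'   inside).
#' @param size_range optional inclusive `c(lo, hi)` size filter applied to
#'   both reads first (e.g. `c(28, 30)` for piRNA-sized pairs).
#' @return an `OffsetSpectrum`.
#' @export
pingpong_spectrum <- function(reads, offsets = 1:20, focal = 10L,
                              region = NULL, size_range = NULL) {
  dt <- .filter_sizes(.filter_region(data.table::as.data.table(reads), region),
                      size_range)
  plus <- dt[strand == "+", .(w = sum(weight)), by = .(chrom, fp = five_prime)]
  minus <- dt[strand == "-", .(w = sum(weight)), by = .(chrom, fp = five_prime)]
  counts <- numeric(length(offsets))
  if (nrow(plus) && nrow(minus)) {
    data.table::setkey(plus, chrom, fp)
    for (i in seq_along(offsets)) {
      o <- offsets[i]
      m <- plus[minus[, .(chrom, fp = fp - (o - 1L), wm = w)],
                on = c("chrom", "fp"), nomatch = NULL]
      counts[i] <- sum(m$w * m$wm)
    }
  }
  offset_spectrum(counts, offsets, focal, "pingpong")
}

#' Z-score of an offset spectrum at its focal offset
#'
#' Z = (counts[focal] - mean(counts)) / population-sd(counts), with Z = 0
#' when the spectrum is constant (sd = 0). The background includes the focal
#' bin.
#'
#' @param spec an `OffsetSpectrum`.
#' @return numeric Z.
#' @export
spectrum_zscore <- function(spec) {
  stopifnot(is(spec, "OffsetSpectrum"))
  s <- pop_sd(spec$counts)
  if (s == 0) return(0)
  (spec$counts[match(spec$focal, spec$offsets)] - mean(spec$counts)) / s
}

#' Phasing (trailing-1U distance) spectrum for one strand
#'
#' For each read on the given strand, the distance to every downstream
#' same-strand read in transcription direction is
#' d = (downstream read's 5') - (this read's 3'), accumulated for d inside
#' `offsets` with pair weight = product of weights. End-to-end juxtaposition
#' gives d = 1, the focal offset. When `require_trailing_1U` (default), only
#' downstream reads whose first base is U count.
#'
#' @param reads a `ReadCollection`.
#' @param strand `"+"` or `"-"` (the precursor strand being tested).
#' @param offsets distance range (default 0:30).
#' @param focal focal distance (default 1, i.e. end-to-end).
#' @param require_trailing_1U gate downstream reads on a 5' U.
#' @param region optional restriction as in [pingpong_spectrum()].
#' @return an `OffsetSpectrum`.
#' @export
phasing_spectrum <- function(reads, strand = "+", offsets = 0:30, focal = 1L,
                             require_trailing_1U = TRUE, region = NULL) {
  st <- strand
  dt <- .filter_region(data.table::as.data.table(reads), region)
  dt <- dt[dt$strand == st]
  counts <- numeric(length(offsets))
  if (nrow(dt) >= 2L) {
    up <- dt[, .(w = sum(weight)), by = .(chrom, tp = three_prime)]
    dn <- dt
    if (require_trailing_1U) dn <- dn[substr(seq, 1, 1) == "T"]
    if (nrow(dn)) {
      dn <- dn[, .(w = sum(weight)), by = .(chrom, fp = five_prime)]
      data.table::setkey(up, chrom, tp)
      sgn <- if (st == "+") 1L else -1L
      for (i in seq_along(offsets)) {
        d <- offsets[i]
        m <- up[dn[, .(chrom, tp = fp - sgn * d, wm = w)],
                on = c("chrom", "tp"), nomatch = NULL]
        counts[i] <- sum(m$w * m$wm)
      }
    }
  }
  offset_spectrum(counts, offsets, focal, "phasing")
}

#' Dicer 2-nt 3'-overhang duplex matrix
#'
#' Opposite-strand read pairs in Dicer duplex geometry, tabulated by (query
#' size, target size) with the plus-strand read as query; each overlapping
#' pair is counted once. In `loose` mode a pair is counted at (Lq, Lt) iff the
#' shared genomic positions equal Lq - 2 (the literal "overlapped by 2 minus
#' its total length" rule). In `strict` mode (default) the query's 3' end must
#' additionally extend exactly 2 nt past the target's 5' end - the canonical
#' RNase III duplex layout with 2-nt 3' overhangs. Weights multiply.
#'
#' The per-query-size Z-score compares the weight at overlap Lq - 2 with the
#' weight distribution over all overlaps 1..Lq for pairs with that query size.
#'
#' @param reads a `ReadCollection`.
#' @param query_sizes,target_sizes inclusive size ranges (default 15:31).
#' @param geometry `"strict"` or `"loose"`.
#' @param region optional restriction as in [pingpong_spectrum()].
#' @return object of class `OverhangMatrix`: list with `counts` (matrix
#'   query x target), `z` (per-query-size Z), `geometry`.
#' @export
dicer_overhang_matrix <- function(reads, query_sizes = 15:31,
                                  target_sizes = 15:31,
                                  geometry = c("strict", "loose"),
                                  region = NULL) {
  geometry <- match.arg(geometry)
  dt <- .filter_region(data.table::as.data.table(reads), region)
  counts <- matrix(0, nrow = length(query_sizes), ncol = length(target_sizes),
                   dimnames = list(query = as.character(query_sizes),
                                   target = as.character(target_sizes)))
  z <- stats::setNames(numeric(length(query_sizes)), as.character(query_sizes))
  P <- dt[strand == "+"]
  M <- dt[strand == "-"]
  pair <- NULL
  if (nrow(P) && nrow(M)) {
    gp <- GenomicRanges::GRanges(P$chrom, IRanges::IRanges(P$start, P$end))
    gm <- GenomicRanges::GRanges(M$chrom, IRanges::IRanges(M$start, M$end))
    hits <- GenomicRanges::findOverlaps(gp, gm)
    if (length(hits)) {
      qi <- S4Vectors::queryHits(hits)
      ti <- S4Vectors::subjectHits(hits)
      pair <- data.table::data.table(
        Lq = P$len[qi], Lt = M$len[ti],
        ps = P$start[qi], pe = P$end[qi],
        ms = M$start[ti], me = M$end[ti],
        w = P$weight[qi] * M$weight[ti])
      pair[, ovl := pmin(pe, me) - pmax(ps, ms) + 1L]
    }
  }
  if (!is.null(pair) && nrow(pair)) {
    sel <- pair[Lq %in% query_sizes & Lt %in% target_sizes & ovl == Lq - 2L]
    if (geometry == "strict") sel <- sel[pe == me + 2L]
    if (nrow(sel)) {
      agg <- sel[, .(w = sum(w)), by = .(Lq, Lt)]
      counts[cbind(as.character(agg$Lq), as.character(agg$Lt))] <- agg$w
    }
    for (q in query_sizes) {
      sub <- pair[Lq == q & ovl >= 1L & ovl <= q]
      if (nrow(sub)) {
        cnt <- numeric(q)
        agg <- sub[, .(w = sum(w)), by = ovl]
        cnt[agg$ovl] <- agg$w
        z[as.character(q)] <- spectrum_zscore(
          offset_spectrum(cnt, seq_len(q), focal = q - 2L, kind = "pingpong"))
      }
    }
  }
  structure(list(counts = counts, z = z, geometry = geometry,
                 query_sizes = as.integer(query_sizes),
                 target_sizes = as.integer(target_sizes)),
            class = "OverhangMatrix")
}

#' @export
print.OverhangMatrix <- function(x, ...) {
  tot <- sum(x$counts)
  top <- if (tot > 0) {
    ij <- which(x$counts == max(x$counts), arr.ind = TRUE)[1, ]
    sprintf(" argmax (%s,%s)", rownames(x$counts)[ij[1]], colnames(x$counts)[ij[2]])
  } else ""
  cat(sprintf("OverhangMatrix[%s]: %.1f weighted pairs%s\n", x$geometry, tot, top))
  invisible(x)
}

#' Positional nucleotide filter (IUPAC)
#'
#' A mapping from 1-based read positions (counted from the 5' end) to allowed
#' base sets given as IUPAC codes (N = any, H = U/A/C, D = A/U/G, W = A/U,
#' plus the four single bases) or explicit base strings.
#'
#' @param ... named constraints, e.g. `positional_filter("1" = "U", "20" = "A")`,
#'   or a single named list/vector.
#' @return object of class `PositionalFilter`.
#' @export
positional_filter <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)))
    args <- as.list(args[[1]])
  if (is.null(names(args)) || any(!nzchar(names(args))))
    stop("constraints must be named by read position")
  pos <- as.integer(names(args))
  if (anyNA(pos) || any(pos < 1L)) stop("filter positions must be integers >= 1")
  sets <- lapply(args, iupac_bases)
  structure(list(positions = pos, sets = sets), class = "PositionalFilter")
}

#' Subset reads by positional base identity
#'
#' A read is kept iff, for every constrained position p, p <= read length and
#' the base at p (in the read's own orientation) is in the allowed set. Reads
#' shorter than a constrained position, or with an ambiguous base there, are
#' excluded.
#'
#' @param reads a `ReadCollection`.
#' @param filter a [positional_filter()].
#' @return filtered `ReadCollection`.
#' @export
subset_reads <- function(reads, filter) {
  stopifnot(is(filter, "PositionalFilter"))
  dt <- data.table::as.data.table(reads)
  keep <- rep(TRUE, nrow(dt))
  for (i in seq_along(filter$positions)) {
    p <- filter$positions[i]
    allowed <- filter$sets[[i]]
    b <- substr(dt$seq, p, p)
    keep <- keep & dt$len >= p & b %in% allowed
  }
  out <- dt[keep]
  data.table::setattr(out, "class", class(reads))
  out
}

#' Size distribution with optional first-base / tenth-base decomposition
#'
#' Weighted read counts per size, optionally split by sequence identity at
#' positions 1 (5' U) and 10 (A), with the per-size 1U fraction reported.
#'
#' @param reads a `ReadCollection`.
#' @param sizes sizes to tabulate (default 15:35).
#' @param annotate_base also report 1U / 10A decompositions (default TRUE).
#' @return data.table with len, weight and (optionally) w_1u, w_10a,
#'   u1_fraction.
#' @export
size_distribution <- function(reads, sizes = 15:35, annotate_base = TRUE) {
  dt <- data.table::as.data.table(reads)
  base <- data.table::data.table(len = as.integer(sizes))
  if (nrow(dt) == 0L) {
    base[, weight := 0]
    if (annotate_base) base[, `:=`(w_1u = 0, w_10a = 0, u1_fraction = NA_real_)]
    return(base[])
  }
  agg <- dt[, .(weight = sum(weight),
                w_1u = sum(weight[substr(seq, 1, 1) == "T"]),
                w_10a = sum(weight[len >= 10L & substr(seq, 10, 10) == "A"])),
            by = len]
  out <- merge(base, agg, by = "len", all.x = TRUE)
  for (cc in c("weight", "w_1u", "w_10a")) out[is.na(get(cc)), (cc) := 0]
  out[, u1_fraction := data.table::fifelse(weight > 0, w_1u / weight, NA_real_)]
  if (!annotate_base) out[, c("w_1u", "w_10a", "u1_fraction") := NULL]
  data.table::setorder(out, len)
  out[]
}

#' Position frequency matrix for reads of one size
#'
#' Weighted base frequencies at each position 1..L among reads of length L;
#' every column sums to 1.
#'
#' @param reads a `ReadCollection`.
#' @param size read length L.
#' @return 4 x L numeric matrix with rows A, C, G, T.
#' @export
position_frequency_matrix <- function(reads, size) {
  dt <- data.table::as.data.table(reads)[len == size]
  if (nrow(dt) == 0L) stop("no reads of length ", size)
  bases <- c("A", "C", "G", "T")
  m <- matrix(0, nrow = 4L, ncol = size,
              dimnames = list(base = bases, pos = as.character(seq_len(size))))
  chars <- matrix(unlist(strsplit(dt$seq, "")), nrow = nrow(dt), byrow = TRUE)
  for (p in seq_len(size)) {
    tab <- tapply(dt$weight, factor(chars[, p], levels = bases), sum)
    tab[is.na(tab)] <- 0
    m[, p] <- tab / sum(tab)
  }
  m
}
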