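# Five-way locus categorization (siRNA, cisNAT, no_bias, piRNA,
# piRNA_cluster), per-read identity labeling, and target-feature counting.
# Categories follow a deterministic decision cascade on the short-read
# fraction f = w_short / (w_short + w_long), the signature Z-scores, the
# locus span, and (for cis-NATs) antisense mRNA annotation overlap.

#' Classification thresholds
#'
#' All numeric thresholds are this package's choices (the five categories are
#' qualitative in origin); they are echoed into output headers for
#' provenance.
#'
#' @param z_sig significance threshold for any signature Z (default 3).
#' @param f_short_hi short-fraction bound for the siRNA class (default 0.8).
#' @param no_bias_band short-fraction interval for no_bias (default 0.4--0.6).
#' @param cluster_min_length piRNA-cluster span threshold in bp (default 5000).
#' @return object of class `ClassificationParams`.
#' @export
classification_params <- function(z_sig = 3, f_short_hi = 0.8,
                                  no_bias_band = c(0.4, 0.6),
                                  cluster_min_length = 5000L) {
  stopifnot(f_short_hi > 0, f_short_hi < 1,
            length(no_bias_band) == 2L, no_bias_band[1] < no_bias_band[2],
            all(no_bias_band > 0), all(no_bias_band < 1),
            cluster_min_length > 0)
  structure(list(z_sig = z_sig, f_short_hi = f_short_hi,
                 no_bias_band = no_bias_band,
                 cluster_min_length = as.integer(cluster_min_length)),
            class = "ClassificationParams")
}

#' Classify a single locus
#'
#' Decision cascade: (a) `cisNAT` if the siRNA criteria hold and the locus
#' lies inside the overlap of two opposite-strand mRNA annotations;
#' (b) `siRNA` if f >= `f_short_hi` and z_dicer >= `z_sig`; (c) `no_bias` if
#' f in the no-bias band, z_dicer >= `z_sig` and max(z_pingpong, z_phasing)
#' >= `z_sig`; (d) `piRNA_cluster` if f below the band, max(z_pingpong,
#' z_phasing) >= `z_sig` and span >= `cluster_min_length`; (e) `piRNA` as (d)
#' with a shorter span; otherwise `unclassified`.
#'
#' @param f_short short-read fraction w_short / (w_short + w_long).
#' @param span locus span in bp.
#' @param z_dicer,z_pingpong,z_phasing signature Z-scores (z_phasing should be
#'   the per-strand maximum).
#' @param in_cisnat_overlap does the locus lie within the overlap of two
#'   opposite-strand mRNA annotations?
#' @param params a [classification_params()].
#' @return category string.
#' @export
classify_locus <- function(f_short, span, z_dicer, z_pingpong, z_phasing,
                           in_cisnat_overlap = FALSE,
                           params = classification_params()) {
  if (anyNA(c(z_dicer, z_pingpong, z_phasing)))
    stop("missing signature Z-score(s) for locus")
  if (is.na(f_short)) return("unclassified")
  z_pi <- max(z_pingpong, z_phasing)
  sirna_like <- f_short >= params$f_short_hi && z_dicer >= params$z_sig
  if (sirna_like && isTRUE(in_cisnat_overlap)) return("cisNAT")
  if (sirna_like) return("siRNA")
  if (f_short >= params$no_bias_band[1] && f_short <= params$no_bias_band[2] &&
      z_dicer >= params$z_sig && z_pi >= params$z_sig) return("no_bias")
  if (f_short < params$no_bias_band[1] && z_pi >= params$z_sig) {
    if (span >= params$cluster_min_length) return("piRNA_cluster")
    return("piRNA")
  }
  "unclassified"
}

# loci whose span lies inside the intersection of a plus- and a minus-strand
# mRNA feature
.cisnat_overlap_flags <- function(loci, annotation) {
  flags <- rep(FALSE, nrow(loci))
  if (is.null(annotation) || nrow(annotation) == 0L) return(flags)
  ann <- data.table::as.data.table(annotation)[feature_class == "mRNA"]
  P <- ann[strand == "+"]
  M <- ann[strand == "-"]
  if (nrow(P) == 0L || nrow(M) == 0L) return(flags)
  gp <- GenomicRanges::GRanges(P$chrom, IRanges::IRanges(P$start, P$end))
  gm <- GenomicRanges::GRanges(M$chrom, IRanges::IRanges(M$start, M$end))
  hits <- GenomicRanges::findOverlaps(gp, gm)
  if (length(hits) == 0L) return(flags)
  qi <- S4Vectors::queryHits(hits)
  ti <- S4Vectors::subjectHits(hits)
  ov <- data.table::data.table(
    chrom = P$chrom[qi],
    start = pmax(P$start[qi], M$start[ti]),
    end = pmin(P$end[qi], M$end[ti]))
  for (i in seq_len(nrow(loci))) {
    flags[i] <- ov[chrom == loci$chrom[i] & start <= loci$start[i] &
                     end >= loci$end[i], .N] > 0L
  }
  flags
}

#' Classify a table of loci
#'
#' Expects the per-locus signature Z columns `z_pingpong`,
#' `z_phasing_plus`, `z_phasing_minus`, `z_dicer` (see
#' [locus_signatures()]). Adds a `category` column.
#'
#' @param loci locus table with signature Z columns.
#' @param annotation optional feature table from [read_annotation()] for
#'   cis-NAT calls.
#' @param params a [classification_params()].
#' @return the locus table with `category` added.
#' @export
classify_loci <- function(loci, annotation = NULL,
                          params = classification_params()) {
  dt <- data.table::as.data.table(loci)
  need <- c("z_pingpong", "z_phasing_plus", "z_phasing_minus", "z_dicer")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("loci lack signature column(s): ", paste(miss, collapse = ", "))
  flags <- .cisnat_overlap_flags(dt, annotation)
  dt[, category := vapply(seq_len(.N), function(i) {
    denom <- w_short[i] + w_long[i]
    classify_locus(
      f_short = if (denom == 0) NA_real_ else w_short[i] / denom,
      span = end[i] - start[i] + 1L,
      z_dicer = z_dicer[i], z_pingpong = z_pingpong[i],
      z_phasing = max(z_phasing_plus[i], z_phasing_minus[i]),
      in_cisnat_overlap = flags[i], params = params)
  }, character(1))]
  dt[]
}

#' Label individual reads by biogenesis identity
#'
#' Precedence pingpong_piRNA > phasing_piRNA > siRNA > other:
#' * `pingpong_piRNA`: length in the piRNA window (28--30 nt), 5' U, 10th
#'   base A, and an opposite-strand partner whose 5' end overlaps this read's
#'   5' end by exactly 10 nt exists;
#' * `phasing_piRNA`: piRNA-sized 5' U read without such a partner;
#' * `siRNA`: 22-nt read with first base U/A and 20th base A/U that has a
#'   strict-geometry 2-nt 3'-overhang partner;
#' * `other`: everything else.
#'
#' @param reads a `ReadCollection` (typically one locus' reads).
#' @param scheme a [size_class_scheme()].
#' @return list with `reads` (the collection plus a `label` column) and
#'   `totals` (weighted per-strand totals per label).
#' @export
label_reads <- function(reads, scheme = size_class_scheme()) {
  dt <- data.table::copy(data.table::as.data.table(reads))
  if (nrow(dt) == 0L) {
    dt[, label := character(0)]
    return(list(reads = dt,
                totals = data.table::data.table(strand = character(),
                                                label = character(),
                                                weight = numeric())))
  }
  plus5 <- unique(dt[strand == "+", .(chrom, fp = five_prime)])
  minus5 <- unique(dt[strand == "-", .(chrom, fp = five_prime)])
  # ping-pong partner at 5'-5' overlap 10
  pp_plus <- rep(FALSE, nrow(dt))
  if (nrow(minus5)) {
    key <- paste(dt$chrom, dt$five_prime + 9L)
    pp_plus <- dt$strand == "+" & key %in% paste(minus5$chrom, minus5$fp)
  }
  pp_minus <- rep(FALSE, nrow(dt))
  if (nrow(plus5)) {
    key <- paste(dt$chrom, dt$five_prime - 9L)
    pp_minus <- dt$strand == "-" & key %in% paste(plus5$chrom, plus5$fp)
  }
  has_pp <- pp_plus | pp_minus
  # strict Dicer duplex partner for 22-nt reads:
  # plus query [ps,pe]: minus read with end == pe-2 and length >= 20
  # minus query [ms,me]: plus read with start == ms+2 and end >= ms+21
  minus_ok <- dt[strand == "-" & len >= 20L, .(chrom, end)]
  plus_reads <- dt[strand == "+"]
  sirna_plus <- rep(FALSE, nrow(dt))
  if (nrow(minus_ok)) {
    key <- paste(dt$chrom, dt$end - 2L)
    sirna_plus <- dt$strand == "+" & key %in% paste(minus_ok$chrom, minus_ok$end)
  }
  sirna_minus <- rep(FALSE, nrow(dt))
  if (nrow(plus_reads)) {
    pk <- paste(plus_reads$chrom, plus_reads$start)
    cand <- paste(dt$chrom, dt$start + 2L)
    idx <- match(cand, pk)
    # require the matched plus read to span past the duplex (length >= 20)
    long_enough <- !is.na(idx) & plus_reads$end[idx] >= dt$start + 21L
    # a position may host several plus reads; fall back to an any() check
    need_scan <- !is.na(idx) & !long_enough
    if (any(need_scan)) {
      for (j in which(need_scan)) {
        long_enough[j] <- plus_reads[chrom == dt$chrom[j] &
                                       start == dt$start[j] + 2L &
                                       end >= dt$start[j] + 21L, .N] > 0L
      }
    }
    sirna_minus <- dt$strand == "-" & long_enough
  }
  has_sirna_partner <- sirna_plus | sirna_minus
  pi_lo <- scheme$pirna_range[1]; pi_hi <- scheme$pirna_range[2]
  b1 <- substr(dt$seq, 1, 1)
  b10 <- substr(dt$seq, 10, 10)
  b20 <- substr(dt$seq, 20, 20)
  is_pi_size <- dt$len >= pi_lo & dt$len <= pi_hi
  lab <- rep("other", nrow(dt))
  lab[is_pi_size & b1 == "T" & b10 == "A" & has_pp] <- "pingpong_piRNA"
  lab[lab == "other" & is_pi_size & b1 == "T" & !has_pp] <- "phasing_piRNA"
  lab[lab == "other" & dt$len == scheme$sirna_size & b1 %in% c("T", "A") &
        b20 %in% c("A", "T") & has_sirna_partner] <- "siRNA"
  dt[, label := lab]
  totals <- dt[, .(weight = sum(weight)), by = .(strand, label)]
  data.table::setorder(totals, strand, label)
  list(reads = dt[], totals = totals[])
}

#' Count distinct annotated targets hit by re-mapped locus reads
#'
#' Intersects genome-wide secondary alignments of a locus' reads with the
#' annotation (>= 1 bp overlap, strand-agnostic) and counts distinct mRNA and
#' TE feature ids.
#'
#' @param alignments a `ReadCollection` of the re-mapped reads (mismatch
#'   tolerance is the upstream aligner's concern).
#' @param annotation feature table from [read_annotation()].
#' @return list with `n_mrna` and `n_te`.
#' @export
count_targets <- function(alignments, annotation) {
  if (is.null(annotation) || nrow(annotation) == 0L) {
    warning("empty annotation: zero targets reported")
    return(list(n_mrna = 0L, n_te = 0L))
  }
  aln <- data.table::as.data.table(alignments)
  if (nrow(aln) == 0L) return(list(n_mrna = 0L, n_te = 0L))
  ann <- data.table::as.data.table(annotation)
  ga <- GenomicRanges::GRanges(aln$chrom, IRanges::IRanges(aln$start, aln$end))
  gf <- GenomicRanges::GRanges(ann$chrom, IRanges::IRanges(ann$start, ann$end))
  hits <- GenomicRanges::findOverlaps(ga, gf)
  hit_ids <- unique(S4Vectors::subjectHits(hits))
  list(n_mrna = length(unique(ann$id[hit_ids][ann$feature_class[hit_ids] == "mRNA"])),
       n_te = length(unique(ann$id[hit_ids][ann$feature_class[hit_ids] == "TE"])))
}
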