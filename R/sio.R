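# Data model and readers/writers: aligned small-RNA reads (SAM/BAM or the
# tabular dialect), genome FASTA, GFF3 annotation, and BED6+ locus output.
#
# Internal coordinates are 1-based fully-closed; BED on disk is 0-based
# half-open. A read's 5' coordinate is `start` on the plus strand and `end`
# on the minus strand. Sequences are stored in the read's own 5'->3'
# orientation in the DNA alphabet.

#' Size-class scheme for read triage
#'
#' Inclusive size windows used throughout: short (siRNA-sized) reads default
#' to 19--23 nt, long (piRNA-sized) reads to 25--30 nt, the piRNA window used
#' for read-identity labeling to 28--30 nt, and the canonical Dicer product
#' size to 22 nt.
#'
#' @param short_range,long_range,pirna_range inclusive `c(lo, hi)` windows in nt.
#' @param sirna_size single Dicer-product size in nt.
#' @return object of class `SizeClassScheme`.
#' @export
size_class_scheme <- function(short_range = c(19L, 23L),
                              long_range = c(25L, 30L),
                              pirna_range = c(28L, 30L),
                              sirna_size = 22L) {
  stopifnot(length(short_range) == 2L, length(long_range) == 2L,
            length(pirna_range) == 2L, short_range[1] <= short_range[2],
            long_range[1] <= long_range[2], pirna_range[1] <= pirna_range[2])
  if (max(short_range[1], long_range[1]) <= min(short_range[2], long_range[2]))
    stop("short_range and long_range must be disjoint")
  structure(list(short_range = as.integer(short_range),
                 long_range = as.integer(long_range),
                 pirna_range = as.integer(pirna_range),
                 sirna_size = as.integer(sirna_size)),
            class = "SizeClassScheme")
}

#' Build a read collection from a table of aligned reads
#'
#' The collection is a `data.table` (class `ReadCollection`) with one row per
#' collapsed alignment: `chrom`, `start`, `end` (1-based inclusive), `strand`
#' (`+`/`-`), `seq` (read-orientation DNA), `copies`, `n_sites`, `weight`,
#' plus derived `len`, `five_prime`, `three_prime` and a `read_id`.
#'
#' @param dt data.frame with at least chrom/start/end/strand/seq; optional
#'   copies, n_sites, read_id.
#' @param weighting `"fractional"` (weight = copies / n_sites) or
#'   `"unique"` (every collapsed sequence counts 1).
#' @return a `ReadCollection`.
#' @export
read_collection <- function(dt, weighting = c("fractional", "unique")) {
  weighting <- match.arg(weighting)
  dt <- data.table::as.data.table(dt)
  req <- c("chrom", "start", "end", "strand", "seq")
  miss <- setdiff(req, names(dt))
  if (length(miss)) stop("missing read columns: ", paste(miss, collapse = ", "))
  if (!"copies" %in% names(dt)) dt[, copies := 1L]
  if (!"n_sites" %in% names(dt)) dt[, n_sites := 1L]
  if (!"read_id" %in% names(dt))
    dt[, read_id := sprintf("read_%06d", seq_len(.N))]
  dt[, `:=`(chrom = as.character(chrom), start = as.integer(start),
            end = as.integer(end), strand = as.character(strand),
            seq = normalize_seq(seq), copies = as.integer(copies),
            n_sites = as.integer(n_sites))]
  if (nrow(dt)) {
    stopifnot(all(dt$strand %in% c("+", "-")),
              all(dt$end >= dt$start),
              all(dt$copies >= 1L), all(dt$n_sites >= 1L))
    bad <- dt[nchar(seq) != end - start + 1L]
    if (nrow(bad))
      stop(nrow(bad), " read(s) whose sequence length disagrees with the span")
  }
  dt[, len := end - start + 1L]
  dt[, five_prime := data.table::fifelse(strand == "+", start, end)]
  dt[, three_prime := data.table::fifelse(strand == "+", end, start)]
  dt[, weight := if (weighting == "unique") 1.0 else copies / n_sites]
  data.table::setcolorder(dt, c("read_id", "chrom", "start", "end", "strand",
                                "seq", "len", "copies", "n_sites", "weight",
                                "five_prime", "three_prime"))
  data.table::setkey(dt, chrom, start, end)
  data.table::setattr(dt, "class", c("ReadCollection", class(data.table::data.table())))
  data.table::setattr(dt, "weighting", weighting)
  dt
}

#' @export
print.ReadCollection <- function(x, ...) {
  cat(sprintf("ReadCollection: %d alignments, %.1f total weight, %d chrom(s)\n",
              nrow(x), sum(x$weight), data.table::uniqueN(x$chrom)))
  NextMethod()
}

#' Summed weights of a read collection, overall and per size
#' @param reads a `ReadCollection`.
#' @return list with `total` and a data.table `per_size` (`len`, `weight`).
#' @export
collection_totals <- function(reads) {
  per_size <- data.table::as.data.table(reads)[, .(weight = sum(weight)), by = len]
  data.table::setorder(per_size, len)
  list(total = sum(reads$weight), per_size = per_size[])
}

#' Read genome-aligned small-RNA reads
#'
#' Accepts SAM/BAM (via Rsamtools) or the package's tabular dialect: a TSV
#' with header columns `chrom start end strand seq` and optional
#' `copies n_sites read_id` (1-based inclusive coordinates, strand `+`/`-`).
#'
#' Unmapped records are skipped; records with indels or clipping (CIGAR not a
#' single match run) are skipped with a warning count, since all signature
#' geometry assumes span = sequence length. Reads outside
#' `[min_len, max_len]` or mapping to more than `max_sites` positions are
#' dropped. Identical `(chrom, start, end, strand, seq)` records are collapsed
#' into `copies`. Multimapping multiplicity `n_sites` is taken from the
#' aligner's `NH` tag when present, else computed as the number of alignment
#' records sharing the read sequence.
#'
#' @param path SAM/BAM file or tabular dialect file.
#' @param min_len,max_len inclusive mapping window in nt (default 15--35).
#' @param max_sites drop reads mapping to more genomic sites (default 100).
#' @param weighting see [read_collection()].
#' @param scheme a [size_class_scheme()] (kept on the collection as an attr).
#' @return a `ReadCollection`.
#' @export
read_alignments <- function(path, min_len = 15L, max_len = 35L,
                            max_sites = 100L,
                            weighting = c("fractional", "unique"),
                            scheme = size_class_scheme()) {
  weighting <- match.arg(weighting)
  if (!file.exists(path)) stop("cannot read alignment file: ", path)
  if (grepl("\\.(sam|bam)$", path, ignore.case = TRUE)) {
    dt <- .read_sam_records(path)
  } else {
    dt <- .read_tabular_records(path)
  }
  if (nrow(dt)) {
    if (is.null(dt$n_sites) || all(is.na(dt$n_sites))) {
      dt[, n_sites := .N, by = seq]
    } else if (anyNA(dt$n_sites)) {
      dt[is.na(n_sites), n_sites := NA_integer_]
      dt[, n_sites := {
        ns <- n_sites
        ns[is.na(ns)] <- sum(!duplicated(paste(chrom, start, end, strand)))
        ns
      }, by = seq]
    }
    dt <- dt[len >= min_len & len <= max_len & n_sites <= max_sites]
    dt <- dt[, .(copies = sum(copies), n_sites = max(n_sites)),
             by = .(chrom, start, end, strand, seq)]
  }
  rc <- read_collection(dt[, .(chrom, start, end, strand, seq, copies, n_sites)],
                        weighting = weighting)
  data.table::setattr(rc, "scheme", scheme)
  rc
}

.read_sam_records <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- suppressMessages(
      Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                       indexDestination = FALSE))
  }
  p <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "strand", "seq", "cigar", "flag"),
    tag = "NH",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  r <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(r$pos)
  if (n == 0L) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), strand = character(),
                                  seq = character(), copies = integer(),
                                  n_sites = integer(), len = integer()))
  }
  ok_cigar <- grepl("^[0-9]+M$", r$cigar)
  n_bad <- sum(!ok_cigar)
  if (n_bad > 0L)
    warning(n_bad, " record(s) with indels/clipping skipped (span != sequence length)")
  sq <- r$seq[ok_cigar]
  minus <- as.character(r$strand[ok_cigar]) == "-"
  # BAM stores the reference-orientation sequence; recover read orientation
  sq[minus] <- Biostrings::reverseComplement(sq[minus])
  nh <- if (!is.null(r$tag$NH)) as.integer(r$tag$NH[ok_cigar]) else NA_integer_
  dt <- data.table::data.table(
    chrom = as.character(r$rname[ok_cigar]),
    start = as.integer(r$pos[ok_cigar]),
    strand = data.table::fifelse(minus, "-", "+"),
    seq = normalize_seq(as.character(sq)),
    copies = 1L,
    n_sites = nh)
  dt[, len := nchar(seq)]
  dt[, end := start + len - 1L]
  dt[]
}

.read_tabular_records <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  req <- c("chrom", "start", "end", "strand", "seq")
  miss <- setdiff(req, names(dt))
  if (length(miss))
    stop("tabular alignment file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  if (!"copies" %in% names(dt)) dt[, copies := 1L]
  if (!"n_sites" %in% names(dt)) dt[, n_sites := NA_integer_]
  dt[, seq := normalize_seq(seq)]
  dt[, len := nchar(seq)]
  bad <- dt[len != end - start + 1L]
  if (nrow(bad)) {
    warning(nrow(bad), " record(s) whose sequence length disagrees with the span skipped")
    dt <- dt[len == end - start + 1L]
  }
  dt[, .(chrom = as.character(chrom), start = as.integer(start),
         end = as.integer(end), strand = as.character(strand), seq,
         copies = as.integer(copies), n_sites = as.integer(n_sites), len)]
}

#' Write a read collection in the tabular alignment dialect
#' @param reads a `ReadCollection`.
#' @param path output TSV path.
#' @export
write_alignments <- function(reads, path) {
  dt <- data.table::as.data.table(reads)[
    , .(read_id, chrom, start, end, strand, seq, copies, n_sites)]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

# ---- genome store ----------------------------------------------------------

#' Load a genome FASTA into a random-access store
#' @param path FASTA file with unique record ids.
#' @return object of class `GenomeStore`.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("cannot read genome FASTA: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate FASTA record ids in ", path)
  genome_store(seqs)
}

#' Wrap a DNAStringSet as a genome store
#' @param seqs named `DNAStringSet` (or named character vector).
#' @return object of class `GenomeStore`.
#' @export
genome_store <- function(seqs) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  structure(list(seqs = seqs), class = "GenomeStore")
}

#' @export
print.GenomeStore <- function(x, ...) {
  cat(sprintf("GenomeStore: %d sequence(s), %.0f bp total\n",
              length(x$seqs), sum(Biostrings::width(x$seqs))))
  invisible(x)
}

#' Fetch a genomic subsequence
#'
#' Returns the 1-based inclusive subsequence `chrom:start-end`,
#' reverse-complemented when `strand == "-"`.
#'
#' @param genome a `GenomeStore`.
#' @param chrom sequence id.
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"+"` or `"-"`.
#' @return character scalar (DNA alphabet).
#' @export
fetch_seq <- function(genome, chrom, start, end, strand = "+") {
  stopifnot(is(genome, "GenomeStore"))
  if (!chrom %in% names(genome$seqs)) stop("unknown sequence id: ", chrom)
  L <- length(genome$seqs[[chrom]])
  if (start < 1L || end > L || end < start)
    stop(sprintf("fetch out of range: %s:%d-%d (length %d)", chrom, start, end, L))
  s <- Biostrings::subseq(genome$seqs[[chrom]], start, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Chromosome lengths of a genome store
#' @param genome a `GenomeStore`.
#' @return named integer vector.
#' @export
genome_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome$seqs), names(genome$seqs))
}

# ---- annotation ------------------------------------------------------------

#' Read a GFF3 annotation into feature records
#'
#' Feature types are mapped to classes `mRNA`, `TE` or `other` via the
#' configurable type lists; coordinates stay 1-based inclusive. Lines that do
#' not have nine tab-separated fields are skipped with a warning.
#'
#' @param path GFF3 file.
#' @param mrna_types,te_types GFF `type` values counted as mRNA / TE.
#' @return data.table with chrom, start, end, strand, feature_class, id.
#' @export
read_annotation <- function(path,
                            mrna_types = c("mRNA", "gene", "transcript"),
                            te_types = c("transposable_element", "TE",
                                         "repeat_region", "mobile_genetic_element")) {
  if (!file.exists(path)) stop("cannot read annotation: ", path)
  lines <- readLines(path)
  is_body <- !grepl("^#", lines) & nzchar(lines)
  nfield <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- is_body & nfield != 9L
  if (any(bad)) {
    warning(sum(bad), " malformed GFF3 line(s) skipped")
    lines <- lines[!bad]
  }
  tmp <- tempfile(fileext = ".gff3")
  writeLines(lines, tmp)
  gr <- rtracklayer::import(tmp, format = "gff3")
  if (length(gr) == 0L) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), strand = character(),
                                  feature_class = character(), id = character()))
  }
  ids <- as.character(gr$ID)
  if (is.null(gr$ID) || all(is.na(ids))) ids <- rep(NA_character_, length(gr))
  ids[is.na(ids)] <- sprintf("feature_%05d", which(is.na(ids)))
  typ <- as.character(gr$type)
  data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    feature_class = data.table::fcase(typ %in% mrna_types, "mRNA",
                                      typ %in% te_types, "TE",
                                      default = "other"),
    id = ids)
}

# ---- locus BED I/O ---------------------------------------------------------

.locus_extra_cols <- c("w_short", "w_long", "w_total", "ratio", "plus_fraction",
                       "u1_fraction_long", "n_reads", "category",
                       "z_pingpong", "z_phasing_plus", "z_phasing_minus",
                       "z_dicer")

#' Write loci as BED6+ (0-based half-open on disk)
#'
#' Columns 1--6 are chrom, bedStart, bedEnd, locus_id, score (w_total),
#' strand (`.`: loci pool both strands); extra columns carry the triage and
#' signature fields. Rows are sorted by (chrom, start).
#'
#' @param loci locus table as produced by [discover_loci()].
#' @param path output path.
#' @export
write_loci_bed <- function(loci, path) {
  dt <- data.table::as.data.table(loci)
  data.table::setorder(dt, chrom, start, end)
  bed <- data.table::data.table(
    chrom = dt$chrom,
    start = dt$start - 1L,
    end = dt$end,
    name = dt$locus_id,
    score = round(dt$w_total, 4),
    strand = ".")
  for (cc in .locus_extra_cols) {
    bed[[cc]] <- if (cc %in% names(dt)) dt[[cc]] else NA
  }
  data.table::fwrite(bed, path, sep = "\t")
  invisible(path)
}

#' Read a BED6+ locus file written by [write_loci_bed()]
#' @param path BED path.
#' @return locus data.table with 1-based inclusive coordinates.
#' @export
read_loci_bed <- function(path) {
  bed <- data.table::fread(path, sep = "\t")
  dt <- data.table::data.table(
    locus_id = bed$name,
    chrom = as.character(bed$chrom),
    start = bed$start + 1L,
    end = bed$end)
  dt[, length := end - start + 1L]
  for (cc in .locus_extra_cols) {
    if (cc %in% names(bed)) dt[[cc]] <- bed[[cc]]
  }
  data.table::setorder(dt, chrom, start, end)
  dt[]
}
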