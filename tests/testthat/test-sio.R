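test_that("SAM reading collapses duplicates, filters the size window, and skips bad records", {
  tmp <- tempfile(fileext = ".sam")
  recs <- data.table(
    chrom = "chr1",
    pos = c(100L, 100L, 200L, 300L, 400L, 500L),
    strand = c("+", "+", "+", "-", "+", "+"),
    seq = c(paste0(strrep("ACGT", 5), "AC"),   # 22 nt, duplicated
            paste0(strrep("ACGT", 5), "AC"),
            strrep("AC", 7),               # 14 nt: below window
            "TTTTGGGGCCCCAAAAGGGGTT",      # 22 nt minus strand
            strrep("A", 22),               # soft-clipped below
            strrep("G", 22)),
    cigar = c(NA, NA, NA, NA, "20M2S", NA),
    flag_extra = c(NA, NA, NA, NA, NA, 4L)) # last record unmapped
  write_sam(recs, tmp)
  expect_warning(rc <- read_alignments(tmp), "indels/clipping")
  # duplicate pair collapsed; 14-nt, clipped and unmapped records gone
  expect_equal(nrow(rc), 2L)
  dup <- as.data.table(rc)[start == 100]
  expect_equal(dup$copies, 2L)
  expect_equal(dup$strand, "+")
  # minus-strand read is stored in its own 5'->3' orientation
  minus <- as.data.table(rc)[strand == "-"]
  expect_equal(minus$seq, "TTTTGGGGCCCCAAAAGGGGTT")
  expect_equal(minus$five_prime, minus$end)
})

test_that("collapse conserves copies and totals match a line-by-line count", {
  set.seed(42)
  n <- 300L
  len <- sample(10:40, n, TRUE)
  st <- sample(5000L, n, TRUE)
  tab <- data.table(chrom = sample(c("s1", "s2"), n, TRUE), start = st,
                    end = st + len - 1L,
                    strand = sample(c("+", "-"), n, TRUE),
                    seq = vapply(len, rand_seq, ""))
  tmp <- tempfile(fileext = ".tsv")
  fwrite(tab, tmp, sep = "\t")
  rc <- read_alignments(tmp)
  # independent single-pass count under the same filters
  keep <- len >= 15 & len <= 35
  expect_equal(sum(rc$copies), sum(keep))
  per_size <- collection_totals(rc)$per_size
  # with n_sites recounted from records sharing a sequence, the apportioned
  # weights of one sequence sum to 1, so the per-size total equals the number
  # of distinct surviving sequences of that size
  for (L in unique(len[keep])) {
    expect_equal(per_size[len == L, weight],
                 as.numeric(uniqueN(tab[keep][nchar(seq) == L, seq])),
                 info = paste("size", L))
  }
})

test_that("U and T spellings of the same reads load identically", {
  dt <- data.table(chrom = "c", start = c(10L, 50L), end = c(31L, 71L),
                   strand = c("+", "-"),
                   seq = c("UGGAUCGAUCGAUCGAUCGAAC", "uggaucgaucgaucgaucgaac"))
  t1 <- tempfile(fileext = ".tsv"); t2 <- tempfile(fileext = ".tsv")
  fwrite(dt, t1, sep = "\t")
  dt2 <- copy(dt)[, seq := chartr("Uu", "Tt", seq)]
  fwrite(dt2, t2, sep = "\t")
  a <- read_alignments(t1); b <- read_alignments(t2)
  expect_identical(as.data.table(a), as.data.table(b))
  expect_true(all(grepl("^T", a$seq)))
})

test_that("weights respect the multimap apportionment bound", {
  rc <- random_rc(200, seed = 9)
  expect_true(all(rc$weight <= rc$copies + 1e-12))
  expect_true(all(rc$weight > 0))
  uniq <- as.data.table(rc)[n_sites == 1L]
  expect_equal(uniq$weight, as.numeric(uniq$copies))
  # unique-sequence counting mode: every collapsed row counts 1
  rc2 <- read_collection(as.data.table(rc)[, .(chrom, start, end, strand, seq,
                                               copies, n_sites)],
                         weighting = "unique")
  expect_true(all(rc2$weight == 1))
})

test_that("genome fetch honors coordinates, strand, and bounds", {
  g <- genome_store(c(chr1 = "ACGTACGTACGTACGTACGT"))
  expect_equal(fetch_seq(g, "chr1", 5, 5, "+"), "A")
  fwd <- fetch_seq(g, "chr1", 3, 10, "+")
  rev <- fetch_seq(g, "chr1", 3, 10, "-")
  expect_equal(revcomp(fwd), rev)
  expect_equal(revcomp(rev), fwd)
  expect_error(fetch_seq(g, "chr1", 15, 25, "+"), "out of range")
  expect_error(fetch_seq(g, "nope", 1, 2, "+"), "unknown sequence id")
  dup <- tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "GGGG"), dup)
  expect_error(read_genome(dup), "duplicate")
})

test_that("printed flank coordinates reconcile under 1-based inclusive arithmetic", {
  # a synthetic scaffold long enough to host the published donor intervals
  set.seed(1)
  g <- genome_store(c(Scaffold185 = rand_seq(16500)))
  expect_equal(nchar(fetch_seq(g, "Scaffold185", 15168, 15509, "+")), 342L)
  expect_equal(nchar(fetch_seq(g, "Scaffold185", 15616, 15981, "+")), 366L)
})

test_that("GFF3 reading maps feature classes and skips malformed lines", {
  tmp <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "s1\tsrc\tmRNA\t100\t200\t.\t+\t.\tID=gene1",
    "s1\tsrc\ttransposable_element\t500\t900\t.\t-\t.\tID=te1",
    "s1\tsrc\tlnc_RNA\t1000\t1100\t.\t+\t.\tID=x1",
    "this line is broken"), tmp)
  expect_warning(ann <- read_annotation(tmp), "malformed")
  expect_equal(nrow(ann), 3L)
  expect_equal(ann[id == "gene1", feature_class], "mRNA")
  expect_equal(ann[id == "te1", feature_class], "TE")
  expect_equal(ann[id == "x1", feature_class], "other")
  expect_equal(ann[id == "gene1", .(start, end)], data.table(start = 100L, end = 200L))
  empty <- tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", empty)
  expect_equal(nrow(read_annotation(empty)), 0L)
})

test_that("internal 1-based closed and BED half-open conversion is a bijection", {
  set.seed(7)
  s <- sample.int(1e6, 1e4, replace = TRUE)
  e <- s + sample.int(1e4, 1e4, replace = TRUE)
  bed <- to_bed_coords(s, e)
  back <- from_bed_coords(bed$start, bed$end)
  expect_identical(back$start, as.integer(s))
  expect_identical(back$end, as.integer(e))
  expect_equal(bed$end - bed$start, e - s + 1)
})

test_that("locus BED round-trips coordinates and triage fields", {
  loci <- data.table(
    locus_id = c("locus_0002", "locus_0001"),
    chrom = "s1", start = c(701L, 101L), end = c(1400L, 700L),
    length = c(700L, 600L),
    w_short = c(1.5, 80), w_long = c(60, 2), w_total = c(70, 90),
    ratio = c(0.025, 40), plus_fraction = c(0.5, 0.9),
    u1_fraction_long = c(0.85, 0.2), n_reads = c(70L, 95L),
    category = c("piRNA", "siRNA"),
    z_pingpong = c(5.1, 0.2), z_phasing_plus = c(4.0, -0.5),
    z_phasing_minus = c(0.3, 0.1), z_dicer = c(0.1, 6.2))
  tmp <- tempfile(fileext = ".bed")
  write_loci_bed(loci, tmp)
  raw <- fread(tmp)
  # 1-based [101, 700] must serialize as BED 100/700, sorted by start
  expect_equal(raw$start[1], 100L)
  expect_equal(raw$end[1], 700L)
  expect_equal(raw$name, c("locus_0001", "locus_0002"))
  back <- read_loci_bed(tmp)
  setorder(loci, chrom, start)
  for (cc in names(loci)) expect_equal(back[[cc]], loci[[cc]], info = cc)
})
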