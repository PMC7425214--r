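test_that("ping-pong overlap arithmetic matches the worked geometry", {
  # plus 5' at 100, minus 5' at 109 -> o = 109 - 100 + 1 = 10
  rc <- read_collection(data.table(
    chrom = "c1", start = c(100L, 82L), end = c(127L, 109L),
    strand = c("+", "-"), seq = c(rand_seq(28), rand_seq(28))))
  spec <- pingpong_spectrum(rc)
  expect_equal(spec$counts[spec$offsets == 10], 1)
  expect_equal(sum(spec$counts), 1)
  # single-strand input: all zeros
  solo <- make_reads("c1", c(100L, 130L), 28L, "+")
  expect_equal(sum(pingpong_spectrum(solo)$counts), 0)
})

test_that("spectrum Z follows the population-sd definition", {
  flat <- offset_spectrum(rep(3, 20), 1:20, 10L)
  expect_equal(spectrum_zscore(flat), 0)
  spike <- offset_spectrum(c(rep(0, 9), 20, rep(0, 10)), 1:20, 10L)
  expect_equal(spectrum_zscore(spike), 19 / sqrt(19), tolerance = 1e-12)
  expect_equal(spectrum_zscore(spike), 4.3589, tolerance = 1e-4)
})

test_that("phasing counts end-to-end pairs and gates on trailing 1U", {
  # [100,129] then [130,158]: d = 130 - 129 = 1
  rc <- read_collection(data.table(
    chrom = "c1", start = c(100L, 130L), end = c(129L, 158L), strand = "+",
    seq = c(rand_seq(30), paste0("T", rand_seq(28)))))
  spec <- phasing_spectrum(rc, strand = "+")
  expect_equal(spec$counts[spec$offsets == 1], 1)
  expect_equal(sum(spec$counts), 1)
  # same geometry, trailing read starts G: gated out
  rcG <- read_collection(data.table(
    chrom = "c1", start = c(100L, 130L), end = c(129L, 158L), strand = "+",
    seq = c(rand_seq(30), paste0("G", rand_seq(28)))))
  expect_equal(sum(phasing_spectrum(rcG, strand = "+")$counts), 0)
  expect_equal(sum(phasing_spectrum(rcG, strand = "+",
                                    require_trailing_1U = FALSE)$counts), 1)
  # minus-strand transcription direction: downstream = lower coordinates
  rcM <- read_collection(data.table(
    chrom = "c1", start = c(130L, 100L), end = c(158L, 129L), strand = "-",
    seq = c(rand_seq(29), paste0("T", rand_seq(29)))))
  specM <- phasing_spectrum(rcM, strand = "-")
  expect_equal(specM$counts[specM$offsets == 1], 1)
})

test_that("the canonical siRNA duplex is scored at (22,22) in both geometries", {
  # plus [100,121], minus [98,119]: overlap 20 = 22 - 2, both 3' ends +2
  rc <- read_collection(data.table(
    chrom = "c1", start = c(100L, 98L), end = c(121L, 119L),
    strand = c("+", "-"), seq = c(rand_seq(22), rand_seq(22))))
  for (geo in c("strict", "loose")) {
    om <- dicer_overhang_matrix(rc, geometry = geo)
    expect_equal(om$counts["22", "22"], 1)
    expect_equal(sum(om$counts), 1)
  }
  solo <- make_reads("c1", c(100L, 200L), 22L, "+")
  expect_equal(sum(dicer_overhang_matrix(solo)$counts), 0)
})

test_that("blunt-ended duplexes count in loose but not strict geometry", {
  # plus [100,121] (22 nt) vs minus [102,121] (20 nt): shared = 20 = Lq - 2,
  # but the plus 3' end does not protrude past the minus 5' end
  rc <- read_collection(data.table(
    chrom = "c1", start = c(100L, 102L), end = c(121L, 121L),
    strand = c("+", "-"), seq = c(rand_seq(22), rand_seq(20))))
  expect_equal(sum(dicer_overhang_matrix(rc, geometry = "strict")$counts), 0)
  expect_equal(dicer_overhang_matrix(rc, geometry = "loose")$counts["22", "20"], 1)
})

test_that("all three pair statistics equal exhaustive enumeration on random data", {
  for (sd in 1:25) {
    rc <- random_rc(sample(30:200, 1), seed = sd)
    expect_equal(pingpong_spectrum(rc)$counts, oracle_pingpong(rc),
                 tolerance = 1e-12, info = paste("pp seed", sd))
    for (st in c("+", "-")) {
      expect_equal(phasing_spectrum(rc, strand = st)$counts,
                   oracle_phasing(rc, st), tolerance = 1e-12,
                   info = paste("ph", st, "seed", sd))
    }
    for (geo in c("strict", "loose")) {
      expect_equal(dicer_overhang_matrix(rc, geometry = geo)$counts,
                   oracle_dicer(rc, strict = geo == "strict"),
                   tolerance = 1e-12, info = paste("dicer", geo, "seed", sd))
    }
  }
})

test_that("ping-pong counts are invariant under a genome mirror (strand swap)", {
  G <- 5000L
  for (sd in 1:5) {
    rc <- random_rc(120, seed = 100 + sd, glen = G - 40L)
    dt <- as.data.table(rc)
    mirrored <- read_collection(data.table(
      chrom = dt$chrom, start = G - dt$end + 1L, end = G - dt$start + 1L,
      strand = ifelse(dt$strand == "+", "-", "+"), seq = dt$seq,
      copies = dt$copies, n_sites = dt$n_sites))
    expect_equal(pingpong_spectrum(rc)$counts,
                 pingpong_spectrum(mirrored)$counts, tolerance = 1e-12)
    # plus-strand phasing of the original equals minus-strand of the mirror
    expect_equal(phasing_spectrum(rc, "+")$counts,
                 phasing_spectrum(mirrored, "-")$counts, tolerance = 1e-12)
  }
})

test_that("IUPAC positional subsetting filters and partitions reads", {
  rc22 <- read_collection(data.table(
    chrom = "c1", start = 100L, end = 121L, strand = "+",
    seq = "TGGATCGATCGATCGATCGAAC"))
  expect_equal(nrow(subset_reads(rc22, positional_filter("1" = "U", "20" = "A"))), 1L)
  expect_equal(nrow(subset_reads(rc22, positional_filter("1" = "G"))), 0L)
  # H/D/W expansions
  expect_equal(nrow(subset_reads(rc22, positional_filter("1" = "H"))), 1L)
  expect_equal(nrow(subset_reads(rc22, positional_filter("1" = "W", "20" = "W"))), 1L)
  # reads shorter than a constrained position are excluded
  short <- make_reads("c1", 100L, 16L, "+", seq = paste0("T", rand_seq(15)))
  expect_equal(nrow(subset_reads(short, positional_filter("20" = "N"))), 0L)
  # the four first-base subsets partition unambiguous reads
  rc <- random_rc(300, seed = 77)
  sizes <- vapply(c("U", "A", "C", "G"), function(b) {
    nrow(subset_reads(rc, positional_filter("1" = b)))
  }, 0L)
  expect_equal(sum(sizes), nrow(subset_reads(rc, positional_filter("1" = "N"))))
  expect_equal(sum(sizes), nrow(rc))
})

test_that("size distribution reports per-size weight and 1U fraction", {
  seqs <- c(replicate(6, paste0("T", rand_seq(21))),
            replicate(4, paste0("G", rand_seq(21))))
  rc <- read_collection(data.table(
    chrom = "c1", start = seq(100L, by = 50L, length.out = 10L),
    end = seq(100L, by = 50L, length.out = 10L) + 21L,
    strand = "+", seq = seqs))
  sd_ <- size_distribution(rc)
  expect_equal(sd_[len == 22, weight], 10)
  expect_equal(sd_[len == 22, u1_fraction], 0.6)
  expect_equal(sd_[len != 22, sum(weight)], 0)
  empty <- size_distribution(read_collection(data.table(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), seq = character())))
  expect_equal(sum(empty$weight), 0)
})

test_that("position frequency matrix columns are weighted and normalized", {
  rc <- read_collection(data.table(
    chrom = "c1", start = c(100L, 200L), end = c(121L, 221L), strand = "+",
    seq = c(paste0("TA", rand_seq(20)), paste0("TG", rand_seq(20))),
    copies = c(1L, 1L), n_sites = c(1L, 1L)))
  pfm <- position_frequency_matrix(rc, 22L)
  expect_equal(pfm["T", 1], 1)
  expect_equal(pfm["A", 2], 0.5)
  expect_equal(pfm["G", 2], 0.5)
  expect_equal(colSums(pfm), rep(1, 22), ignore_attr = TRUE)
  expect_error(position_frequency_matrix(rc, 30L), "30")
})

test_that("uniform strand-balanced reads rarely reach the significance threshold", {
  hits <- matrix(FALSE, nrow = 60L, ncol = 4L)
  for (r in seq_len(nrow(hits))) {
    rc <- random_rc(200, seed = 5000 + r)
    hits[r, ] <- abs(c(
      spectrum_zscore(pingpong_spectrum(rc)),
      spectrum_zscore(phasing_spectrum(rc, "+")),
      spectrum_zscore(phasing_spectrum(rc, "-")),
      dicer_overhang_matrix(rc)$z["22"])) < 3
  }
  expect_gte(mean(colMeans(hits)), 0.95)
})
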