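test_that("the category cascade resolves each archetype", {
  p <- classification_params()
  expect_equal(classify_locus(0.95, 800, z_dicer = 6, z_pingpong = 0,
                              z_phasing = 0), "siRNA")
  expect_equal(classify_locus(0.95, 800, z_dicer = 6, z_pingpong = 0,
                              z_phasing = 0, in_cisnat_overlap = TRUE), "cisNAT")
  expect_equal(classify_locus(0.5, 1500, z_dicer = 4, z_pingpong = 5,
                              z_phasing = 0), "no_bias")
  expect_equal(classify_locus(0.1, 20000, z_dicer = 0, z_pingpong = 0,
                              z_phasing = 8), "piRNA_cluster")
  expect_equal(classify_locus(0.1, 2000, z_dicer = 0, z_pingpong = 8,
                              z_phasing = 0), "piRNA")
  expect_equal(classify_locus(0.95, 800, z_dicer = 1, z_pingpong = 0,
                              z_phasing = 0), "unclassified")
  expect_error(classify_locus(0.5, 1000, z_dicer = NA, z_pingpong = 0,
                              z_phasing = 0), "missing")
})

test_that("raising z_sig never rescues a locus into a signature-requiring class", {
  set.seed(3)
  sig_classes <- c("siRNA", "cisNAT", "no_bias", "piRNA", "piRNA_cluster")
  for (i in 1:200) {
    f <- runif(1); span <- sample(500:20000, 1)
    zs <- runif(3, -1, 8)
    lo <- classify_locus(f, span, zs[1], zs[2], zs[3],
                         params = classification_params(z_sig = 2))
    hi <- classify_locus(f, span, zs[1], zs[2], zs[3],
                         params = classification_params(z_sig = 4))
    if (lo == "unclassified") expect_false(hi %in% sig_classes)
  }
})

test_that("cis-NAT calls require containment in an antisense mRNA overlap", {
  loci <- data.table(locus_id = c("a", "b"), chrom = "c1",
                     start = c(1000L, 5000L), end = c(1900L, 5900L),
                     w_short = 90, w_long = 2,
                     z_pingpong = 0, z_phasing_plus = 0, z_phasing_minus = 0,
                     z_dicer = 6)
  ann <- data.table(chrom = "c1",
                    start = c(500L, 700L), end = c(2500L, 2300L),
                    strand = c("+", "-"), feature_class = "mRNA",
                    id = c("m1", "m2"))
  out <- classify_loci(loci, annotation = ann)
  expect_equal(out[locus_id == "a", category], "cisNAT")
  expect_equal(out[locus_id == "b", category], "siRNA")
  # same-strand overlapping genes never produce a cis-NAT call
  ann_same <- copy(ann)[, strand := "+"]
  out2 <- classify_loci(loci, annotation = ann_same)
  expect_equal(out2$category, c("siRNA", "siRNA"))
})

test_that("classification is a pure function of the numeric inputs", {
  rc <- simulate_dataset(sim_config(seed = 4))$reads
  loci <- discover_loci(rc)
  sig <- locus_signatures(rc, loci)
  a <- classify_loci(sig$loci)
  perm <- sig$loci[sample(nrow(sig$loci))]
  b <- classify_loci(perm)
  m <- merge(a[, .(locus_id, category)], b[, .(locus_id, category)],
             by = "locus_id")
  expect_equal(m$category.x, m$category.y)
})

test_that("read labels are exclusive, exhaustive, and weight-conserving", {
  sim <- simulate_dataset(sim_config(seed = 6))
  loci <- discover_loci(sim$reads)
  for (i in seq_len(min(4L, nrow(loci)))) {
    lr <- locus_reads(sim$reads, loci[i])
    out <- label_reads(lr)
    expect_equal(nrow(out$reads), nrow(lr))
    expect_true(all(out$reads$label %in%
                      c("pingpong_piRNA", "phasing_piRNA", "siRNA", "other")))
    expect_equal(sum(out$totals$weight), sum(lr$weight))
    for (st in c("+", "-")) {
      expect_equal(out$totals[strand == st, sum(weight)],
                   sum(lr$weight[lr$strand == st]))
    }
  }
})

test_that("read identity definitions follow the 1U/10A and duplex rules", {
  # 29-nt 1U/10A read with an antisense 10-overlap partner -> ping-pong
  guide <- paste0("T", rand_seq(8), "A", rand_seq(19))
  rc <- read_collection(data.table(
    chrom = "c1", start = c(200L, 181L), end = c(228L, 209L),
    strand = c("+", "-"), seq = c(guide, rand_seq(29))))
  lab <- label_reads(rc)$reads
  expect_equal(lab[strand == "+", label], "pingpong_piRNA")
  # same read without the partner -> phasing
  solo <- read_collection(data.table(chrom = "c1", start = 200L, end = 228L,
                                     strand = "+", seq = guide))
  expect_equal(label_reads(solo)$reads$label, "phasing_piRNA")
  # 22-nt 1U/20A read with a strict-geometry duplex partner -> siRNA
  si <- paste0("T", rand_seq(18), "A", rand_seq(2))
  duo <- read_collection(data.table(
    chrom = "c1", start = c(100L, 98L), end = c(121L, 119L),
    strand = c("+", "-"), seq = c(si, rand_seq(22))))
  expect_equal(label_reads(duo)$reads[strand == "+", label], "siRNA")
  # precedence: a piRNA-sized 1U/10A read in both contexts stays ping-pong
  both <- read_collection(data.table(
    chrom = "c1", start = c(200L, 181L, 229L), end = c(228L, 209L, 257L),
    strand = c("+", "-", "+"),
    seq = c(guide, rand_seq(29), paste0("T", rand_seq(28)))))
  expect_equal(label_reads(both)$reads[start == 200L, label], "pingpong_piRNA")
})

test_that("target counting deduplicates feature ids and matches a scan oracle", {
  ann <- data.table(chrom = "c1",
                    start = c(100L, 1000L), end = c(500L, 1500L),
                    strand = c("+", "-"), feature_class = c("mRNA", "TE"),
                    id = c("m1", "t1"))
  one <- make_reads("c1", 200L, 22L, "+")
  expect_equal(count_targets(one, ann), list(n_mrna = 1L, n_te = 0L))
  # two alignments in the same TE count one distinct id
  two <- make_reads("c1", c(1100L, 1200L), 22L, c("+", "-"))
  expect_equal(count_targets(two, ann), list(n_mrna = 0L, n_te = 1L))
  expect_warning(out <- count_targets(one, ann[0]), "empty annotation")
  expect_equal(out, list(n_mrna = 0L, n_te = 0L))
  # random fixture vs brute-force interval scan
  set.seed(8)
  feats <- data.table(chrom = sample(c("cA", "cB"), 20, TRUE),
                      start = sample.int(5000, 20))
  feats[, end := start + sample(100:800, 20, TRUE)]
  feats[, `:=`(strand = sample(c("+", "-"), 20, TRUE),
               feature_class = sample(c("mRNA", "TE"), 20, TRUE),
               id = sprintf("f%02d", 1:20))]
  aln <- random_rc(50, seed = 8, glen = 6000L)
  got <- count_targets(aln, feats)
  hit <- vapply(seq_len(nrow(feats)), function(j) {
    any(aln$chrom == feats$chrom[j] & aln$start <= feats$end[j] &
          aln$end >= feats$start[j])
  }, TRUE)
  expect_equal(got$n_mrna, sum(hit & feats$feature_class == "mRNA"))
  expect_equal(got$n_te, sum(hit & feats$feature_class == "TE"))
})
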