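# Seeded simulator: a synthetic genome plus small-RNA reads with planted
# biogenesis signatures (ping-pong pairs, phased 1U trails, Dicer duplexes,
# cis-NAT siRNAs, mixed no-bias loci) over a degradation background, with a
# truth manifest naming every read. Signatures are planted by construction
# (the pair geometry is forced); sequence biases (1U, 10A, 20A) emerge from
# the genome itself: the simulator forces the genome base at planted 5'
# positions, then derives every read sequence by fetching from the genome,
# so complementarity produces partner biases exactly as in real data.

#' Specification of one planted locus
#'
#' @param class one of `pingpong`, `phased`, `dicer_siRNA`, `cisnat`,
#'   `no_bias`.
#' @param span locus span in bp.
#' @param n_reads number of planted reads (pre-collapse).
#' @param strand precursor strand.
#' @return a `sim_locus_spec` list.
#' @export
sim_locus_spec <- function(class = c("pingpong", "phased", "dicer_siRNA",
                                     "cisnat", "no_bias"),
                           span = 2000L, n_reads = 300L, strand = "+") {
  class <- match.arg(class)
  stopifnot(span >= 100L, n_reads >= 1L, strand %in% c("+", "-"))
  structure(list(class = class, span = as.integer(span),
                 n_reads = as.integer(n_reads), strand = strand),
            class = "sim_locus_spec")
}

.default_sim_loci <- function() {
  list(
    sim_locus_spec("pingpong", span = 2000L, n_reads = 300L),
    sim_locus_spec("pingpong", span = 2500L, n_reads = 350L),
    sim_locus_spec("phased", span = 8000L, n_reads = 500L),
    sim_locus_spec("phased", span = 2500L, n_reads = 300L),
    sim_locus_spec("dicer_siRNA", span = 800L, n_reads = 240L),
    sim_locus_spec("dicer_siRNA", span = 1200L, n_reads = 280L),
    sim_locus_spec("cisnat", span = 900L, n_reads = 240L),
    sim_locus_spec("no_bias", span = 1600L, n_reads = 300L))
}

#' Simulator configuration
#'
#' Defaults emulate the endogenous read landscape the package targets: a
#' bimodal size mixture (Dicer products at 22 nt, piRNAs peaking at
#' 29--30 nt), strong 1U bias on piRNAs, planted ping-pong pairs (10-nt 5'
#' overlaps), end-to-end phased 1U trails with ~20:1 strand asymmetry, 22-nt
#' Dicer duplexes with 2-nt 3' overhangs, and an abundant 15--35-nt
#' degradation background decaying from 15 nt.
#'
#' @param seed RNG seed; every output is deterministic given (config, seed).
#' @param n_chrom,chrom_length synthetic genome shape.
#' @param gc genome GC fraction.
#' @param loci list of [sim_locus_spec()]s.
#' @param background_reads number of degradation reads.
#' @param background_decay exponential decay rate of background sizes from
#'   15 nt.
#' @param u1_bias probability a planted piRNA 5' base is forced to U.
#' @param pp_partner_frac fraction of ping-pong guides given an antisense
#'   partner at 10-nt 5' overlap.
#' @param phased_jitter probability of a small gap between consecutive
#'   phased reads.
#' @param phased_antisense_frac minor antisense read fraction at phased loci.
#' @param pirna_len_prob sampling weights for piRNA lengths 28/29/30 nt.
#' @param multimap_frac fraction of reads marked as multimappers.
#' @param cluster_min_length span at/above which a planted piRNA locus is
#'   expected to classify as a piRNA cluster.
#' @return object of class `SimConfig`.
#' @export
sim_config <- function(seed = 1L, n_chrom = 2L, chrom_length = 100000L,
                       gc = 0.35, loci = .default_sim_loci(),
                       background_reads = 600L, background_decay = 0.18,
                       u1_bias = 0.9, pp_partner_frac = 0.8,
                       phased_jitter = 0.2, phased_antisense_frac = 0.05,
                       pirna_len_prob = c(0.2, 0.4, 0.4),
                       multimap_frac = 0, cluster_min_length = 5000L) {
  stopifnot(u1_bias >= 0, u1_bias <= 1, pp_partner_frac >= 0,
            pp_partner_frac <= 1, phased_jitter >= 0, phased_jitter <= 1,
            phased_antisense_frac >= 0, phased_antisense_frac < 1,
            gc > 0, gc < 1, length(pirna_len_prob) == 3L,
            multimap_frac >= 0, multimap_frac < 1)
  for (sp in loci) {
    if (!is(sp, "sim_locus_spec"))
      stop("config error at loci[[...]]: each entry must be a sim_locus_spec")
  }
  structure(list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
                 chrom_length = as.integer(chrom_length), gc = gc,
                 loci = loci, background_reads = as.integer(background_reads),
                 background_decay = background_decay, u1_bias = u1_bias,
                 pp_partner_frac = pp_partner_frac,
                 phased_jitter = phased_jitter,
                 phased_antisense_frac = phased_antisense_frac,
                 pirna_len_prob = pirna_len_prob,
                 multimap_frac = multimap_frac,
                 cluster_min_length = as.integer(cluster_min_length)),
            class = "SimConfig")
}

.comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

.sample_pirna_len <- function(n, prob) sample(28:30, n, TRUE, prob = prob)

.sim_copies <- function(n) 1L + stats::rgeom(n, 0.6)

#' Plant a ping-pong locus
#'
#' Guide piRNAs (28--30 nt) on the precursor strand with a forced 5' U
#' (probability `u1_bias`) and forced 10A; a configured fraction acquires an
#' antisense responder whose 5' end overlaps the guide's by exactly 10 nt.
#' Responder 1U/10A identities follow from genome complementarity.
#'
#' @param chrom,start locus placement (1-based).
#' @param span,n_reads,strand locus geometry.
#' @param u1_bias,partner_frac,pirna_len_prob see [sim_config()].
#' @return list with `reads` (chrom/start/end/strand/copies/label) and
#'   `forced` (plus-strand genome bases to force).
#' @export
plant_pingpong_locus <- function(chrom, start, span, n_reads, strand = "+",
                                 u1_bias = 0.9, partner_frac = 0.8,
                                 pirna_len_prob = c(0.2, 0.4, 0.4)) {
  margin <- 40L
  lo <- start + margin
  hi <- start + span - margin
  n_guides <- max(1L, round(n_reads / (1 + partner_frac)))
  g5 <- sample(lo:hi, n_guides, replace = TRUE)
  Lg <- .sample_pirna_len(n_guides, pirna_len_prob)
  partner <- stats::runif(n_guides) < partner_frac
  Lr <- .sample_pirna_len(n_guides, pirna_len_prob)
  force_u1 <- stats::runif(n_guides) < u1_bias
  if (strand == "+") {
    guides <- data.table::data.table(chrom = chrom, start = g5,
                                     end = g5 + Lg - 1L, strand = "+")
    resp <- data.table::data.table(chrom = chrom,
                                   start = g5[partner] + 9L - Lr[partner] + 1L,
                                   end = g5[partner] + 9L, strand = "-")
    forced <- data.table::data.table(
      chrom = chrom,
      pos = c(g5[force_u1], g5 + 9L),
      base = c(rep("T", sum(force_u1)), rep("A", n_guides)))
  } else {
    guides <- data.table::data.table(chrom = chrom, start = g5 - Lg + 1L,
                                     end = g5, strand = "-")
    resp <- data.table::data.table(chrom = chrom, start = g5[partner] - 9L,
                                   end = g5[partner] - 9L + Lr[partner] - 1L,
                                   strand = "+")
    forced <- data.table::data.table(
      chrom = chrom,
      pos = c(g5[force_u1], g5 - 9L),
      base = c(rep("A", sum(force_u1)), rep("T", n_guides)))
  }
  # a guide without a responder shows no 10-nt overlap partner: its planted
  # identity is that of a phased (non-ping-pong) piRNA
  guides[, label := data.table::fifelse(partner, "pingpong_piRNA",
                                        "phasing_piRNA")]
  resp[, label := "pingpong_piRNA"]
  reads <- rbind(guides, resp)
  reads[, copies := .sim_copies(.N)]
  list(reads = reads[], forced = forced[])
}

#' Plant a phased piRNA locus
#'
#' Single-strand 28--30-nt reads tiled end-to-end (distance 1) from the
#' locus edge, with occasional small gaps (`jitter`), 5' U forced with
#' probability `u1_bias`; several overlapping walks model precursor
#' abundance. A minor antisense read population (`antisense_frac`) emulates
#' the ~20:1 strand asymmetry of phased piRNA clusters.
#'
#' @inheritParams plant_pingpong_locus
#' @param jitter,antisense_frac see [sim_config()].
#' @return list with `reads` and `forced` as in [plant_pingpong_locus()].
#' @export
plant_phased_locus <- function(chrom, start, span, n_reads, strand = "+",
                               u1_bias = 0.9, jitter = 0.2,
                               antisense_frac = 0.05,
                               pirna_len_prob = c(0.2, 0.4, 0.4)) {
  n_anti <- round(antisense_frac * n_reads)
  n_sense <- n_reads - n_anti
  s_list <- vector("list", 64L)
  wi <- 0L
  emitted <- 0L
  last <- start + span - 1L
  while (emitted < n_sense) {
    # one walk along the precursor in transcription direction
    k_max <- ceiling(span / 28) + 2L
    Ls <- .sample_pirna_len(k_max, pirna_len_prob)
    gaps <- data.table::fifelse(stats::runif(k_max) < jitter,
                                sample(0:4, k_max, TRUE), 0L)
    if (strand == "+") {
      starts <- start + cumsum(c(0L, (Ls + gaps)[-k_max]))
      ends <- starts + Ls - 1L
      keep <- ends <= last
    } else {
      ends <- last - cumsum(c(0L, (Ls + gaps)[-k_max]))
      starts <- ends - Ls + 1L
      keep <- starts >= start
    }
    k <- min(sum(keep), n_sense - emitted)
    if (k <= 0L) break
    idx <- which(keep)[seq_len(k)]
    wi <- wi + 1L
    s_list[[wi]] <- data.table::data.table(chrom = chrom, start = starts[idx],
                                           end = ends[idx], strand = strand)
    emitted <- emitted + k
  }
  sense <- data.table::rbindlist(s_list[seq_len(wi)])
  fp <- if (strand == "+") sense$start else sense$end
  force_u1 <- stats::runif(nrow(sense)) < u1_bias
  forced <- data.table::data.table(
    chrom = chrom, pos = fp[force_u1],
    base = if (strand == "+") "T" else "A")
  anti <- NULL
  if (n_anti > 0L) {
    La <- .sample_pirna_len(n_anti, pirna_len_prob)
    a5 <- sample((start + 40L):(start + span - 40L), n_anti, replace = TRUE)
    anti <- if (strand == "+") {
      data.table::data.table(chrom = chrom, start = a5 - La + 1L, end = a5,
                             strand = "-")
    } else {
      data.table::data.table(chrom = chrom, start = a5, end = a5 + La - 1L,
                             strand = "+")
    }
  }
  sense[, label := "phasing_piRNA"]
  if (!is.null(anti)) anti[, label := "other"]
  reads <- rbind(sense, anti)
  reads[, copies := .sim_copies(.N)]
  data.table::setcolorder(reads, c("chrom", "start", "end", "strand",
                                   "copies", "label"))
  list(reads = reads[], forced = forced[])
}

#' Plant a Dicer siRNA locus
#'
#' 22-nt duplexes with canonical 2-nt 3' overhangs on both ends, placed at
#' random registers along the locus (duplex abundance varies by position, as
#' when multiple precursor molecules are diced independently). The genome
#' base under each duplex 5' end is forced to U/A with the 20th base
#' complementarity-matched, giving the 1U/1A + 20A/20U bias of Dicer
#' products.
#'
#' @inheritParams plant_pingpong_locus
#' @return list with `reads` and `forced` as in [plant_pingpong_locus()].
#' @export
plant_dicer_locus <- function(chrom, start, span, n_reads, strand = "+") {
  n_dup <- max(1L, ceiling(n_reads / 2))
  s <- sample((start + 2L):(start + span - 24L), n_dup, replace = TRUE)
  b1 <- sample(c("T", "A"), n_dup, replace = TRUE)
  plus <- data.table::data.table(chrom = chrom, start = s, end = s + 21L,
                                 strand = "+")
  minus <- data.table::data.table(chrom = chrom, start = s - 2L,
                                  end = s + 19L, strand = "-")
  forced <- data.table::data.table(
    chrom = chrom, pos = c(s, s + 19L),
    base = c(b1, unname(.comp_base(b1))))
  reads <- rbind(plus, minus)
  reads[, copies := .sim_copies(.N)]
  reads[, label := "siRNA"]
  list(reads = reads[], forced = forced[])
}

.plant_cisnat_locus <- function(chrom, start, span, n_reads) {
  out <- plant_dicer_locus(chrom, start, span, n_reads)
  out$ann <- data.table::data.table(
    chrom = chrom,
    start = c(start - 1000L, start - 800L),
    end = c(start + span + 1000L, start + span + 800L),
    strand = c("+", "-"),
    feature_class = "mRNA",
    id = sprintf("%s_nat_%d_%s", chrom, start, c("fwd", "rev")))
  out
}

.plant_no_bias_locus <- function(chrom, start, span, n_reads, cfg) {
  half <- floor(n_reads / 2)
  di <- plant_dicer_locus(chrom, start, span, half)
  ph <- plant_phased_locus(chrom, start, span, n_reads - half, strand = "+",
                           u1_bias = cfg$u1_bias, jitter = cfg$phased_jitter,
                           antisense_frac = 0,
                           pirna_len_prob = cfg$pirna_len_prob)
  list(reads = rbind(di$reads, ph$reads),
       forced = rbind(di$forced, ph$forced))
}

# place loci round-robin over chromosomes with randomized inter-locus gaps;
# returns per-locus chrom/start and the full read/forced/annotation plan
.sim_plan <- function(config) {
  set.seed(config$seed)
  chroms <- sprintf("sim_chr%02d", seq_len(config$n_chrom))
  cursor <- stats::setNames(rep(2000L, config$n_chrom), chroms)
  loci <- vector("list", length(config$loci))
  reads_l <- vector("list", length(config$loci) + 1L)
  forced_l <- vector("list", length(config$loci))
  ann_l <- list()
  for (i in seq_along(config$loci)) {
    sp <- config$loci[[i]]
    ch <- chroms[((i - 1L) %% config$n_chrom) + 1L]
    s0 <- cursor[[ch]]
    if (s0 + sp$span + 1000L > config$chrom_length)
      stop("config error at loci[[", i, "]]: genome too short for planted loci")
    cursor[[ch]] <- s0 + sp$span + sample(3000:8000, 1L)
    pl <- switch(sp$class,
      pingpong = plant_pingpong_locus(ch, s0, sp$span, sp$n_reads, sp$strand,
                                      config$u1_bias, config$pp_partner_frac,
                                      config$pirna_len_prob),
      phased = plant_phased_locus(ch, s0, sp$span, sp$n_reads, sp$strand,
                                  config$u1_bias, config$phased_jitter,
                                  config$phased_antisense_frac,
                                  config$pirna_len_prob),
      dicer_siRNA = plant_dicer_locus(ch, s0, sp$span, sp$n_reads, sp$strand),
      cisnat = .plant_cisnat_locus(ch, s0, sp$span, sp$n_reads),
      no_bias = .plant_no_bias_locus(ch, s0, sp$span, sp$n_reads, config))
    pl$reads[, locus_idx := i]
    reads_l[[i]] <- pl$reads
    forced_l[[i]] <- pl$forced
    if (!is.null(pl$ann)) ann_l[[length(ann_l) + 1L]] <- pl$ann
    expected <- switch(sp$class,
      pingpong = , phased = if (sp$span >= config$cluster_min_length)
        "piRNA_cluster" else "piRNA",
      dicer_siRNA = "siRNA", cisnat = "cisNAT", no_bias = "no_bias")
    loci[[i]] <- list(locus_id = sprintf("sim_locus_%02d", i),
                      class = sp$class, expected_category = expected,
                      chrom = ch, start = s0, end = s0 + sp$span - 1L,
                      precursor_strand = sp$strand)
  }
  # degradation background: sizes decay from 15 nt, uniform placement
  nb <- config$background_reads
  if (nb > 0L) {
    Lb <- sample(15:35, nb, replace = TRUE,
                 prob = exp(-config$background_decay * (0:20)))
    bch <- sample(chroms, nb, replace = TRUE)
    bst <- floor(stats::runif(nb, 1, config$chrom_length - 35L)) + 0L
    reads_l[[length(config$loci) + 1L]] <- data.table::data.table(
      chrom = bch, start = as.integer(bst), end = as.integer(bst) + Lb - 1L,
      strand = sample(c("+", "-"), nb, replace = TRUE),
      copies = 1L + stats::rgeom(nb, 0.8),
      label = "background", locus_idx = NA_integer_)
  }
  reads <- data.table::rbindlist(reads_l, use.names = TRUE, fill = TRUE)
  forced <- data.table::rbindlist(forced_l)
  if (nrow(forced) == 0L)
    forced <- data.table::data.table(chrom = character(), pos = integer(),
                                     base = character())
  forced <- unique(forced, by = c("chrom", "pos"))
  list(chroms = chroms, loci = loci, reads = reads, forced = forced,
       ann = if (length(ann_l)) data.table::rbindlist(ann_l) else NULL)
}

.sim_build_genome <- function(config, plan) {
  probs <- c(A = (1 - config$gc) / 2, C = config$gc / 2, G = config$gc / 2,
             T = (1 - config$gc) / 2)
  seqs <- lapply(plan$chroms, function(ch) {
    s <- sample(names(probs), config$chrom_length, replace = TRUE, prob = probs)
    f <- plan$forced[chrom == ch]
    if (nrow(f)) s[f$pos] <- f$base
    paste(s, collapse = "")
  })
  genome_store(stats::setNames(unlist(seqs), plan$chroms))
}

#' Simulate only the genome of a configuration
#'
#' The genome depends on the planted-read plan (bases under planted 5' ends
#' are forced), so this runs the same seeded plan as [simulate_dataset()] and
#' returns just the genome; given an equal config it is identical to the
#' genome that `simulate_dataset` emits.
#'
#' @param config a [sim_config()].
#' @return a `GenomeStore`.
#' @export
simulate_genome <- function(config = sim_config()) {
  plan <- .sim_plan(config)
  .sim_build_genome(config, plan)
}

#' Generate a full synthetic dataset
#'
#' Deterministic for a fixed config (the config carries the seed): a genome
#' FASTA, reads in the tabular alignment dialect, a GFF3 with cis-NAT mRNA
#' pairs (when planted), and a JSON truth manifest in which every emitted
#' read id appears exactly once (background included).
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, writes `genome.fa`,
#'   `reads.tsv`, `annotation.gff3` (if any) and `truth.json`.
#' @return list with `genome` (GenomeStore), `reads` (ReadCollection with
#'   planted labels retained in the truth), `annotation` (or NULL), `truth`
#'   (manifest list), and `paths` when `out_dir` is used.
#' @export
simulate_dataset <- function(config = sim_config(), out_dir = NULL) {
  plan <- .sim_plan(config)
  genome <- .sim_build_genome(config, plan)
  reads <- plan$reads
  # collapse identical planted/background molecules into copies
  reads <- reads[, .(copies = sum(copies)),
                 by = .(chrom, start, end, strand, label, locus_idx)]
  data.table::setorder(reads, chrom, start, end, strand, label)
  reads[, n_sites := 1L]
  if (config$multimap_frac > 0) {
    nm <- floor(config$multimap_frac * nrow(reads))
    if (nm > 0L) {
      idx <- sample(nrow(reads), nm)
      reads[idx, n_sites := sample(2:4, nm, replace = TRUE)]
    }
  }
  reads[, read_id := sprintf("read_%06d", seq_len(.N))]
  # derive every read sequence from the genome (minus-strand reads are
  # reverse-complemented into their own 5'->3' orientation)
  reads[, seq := {
    cs <- as.character(genome$seqs[[chrom[1]]])
    substring(cs, start, end)
  }, by = chrom]
  reads[strand == "-", seq := revcomp(seq)]
  truth_loci <- plan$loci
  for (i in seq_along(truth_loci)) {
    sub <- reads[locus_idx == i]
    truth_loci[[i]]$reads <- split(sub$read_id, sub$label)
  }
  truth <- list(
    seed = config$seed,
    genome = list(n_chrom = config$n_chrom,
                  chrom_length = config$chrom_length, gc = config$gc),
    u1_bias = config$u1_bias,
    loci = truth_loci,
    background_read_ids = reads[is.na(locus_idx), read_id])
  rc <- read_collection(
    reads[, .(read_id, chrom, start, end, strand, seq, copies, n_sites)])
  # carry planted truth labels alongside (same row order as rc)
  lab <- reads[, .(read_id, label, locus_idx)]
  data.table::setattr(rc, "truth_labels", lab)
  ann <- plan$ann
  out <- list(genome = genome, reads = rc, annotation = ann, truth = truth)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths <- list(
      genome = file.path(out_dir, "genome.fa"),
      reads = file.path(out_dir, "reads.tsv"),
      truth = file.path(out_dir, "truth.json"))
    gs <- Biostrings::DNAStringSet(vapply(genome$seqs, as.character, ""))
    names(gs) <- names(genome$seqs)
    Biostrings::writeXStringSet(gs, paths$genome, width = 80L)
    write_alignments(rc, paths$reads)
    if (!is.null(ann)) {
      paths$annotation <- file.path(out_dir, "annotation.gff3")
      gr <- GenomicRanges::GRanges(ann$chrom,
                                   IRanges::IRanges(ann$start, ann$end),
                                   strand = ann$strand)
      gr$type <- "mRNA"
      gr$ID <- ann$id
      rtracklayer::export(gr, paths$annotation, format = "gff3")
    }
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    out$paths <- paths
  }
  out
}
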