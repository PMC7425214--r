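# Fixture builders and independent brute-force oracles used across tests.
# The oracles enumerate all read pairs explicitly and never share code with
# the package's indexed implementations.

library(data.table)

rand_seq <- function(L) paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")

# random strand-balanced read collection over two chromosomes
random_rc <- function(n, seed, glen = 3000L, sizes = 15:31) {
  set.seed(seed)
  len <- sample(sizes, n, TRUE)
  st <- sample(glen, n, TRUE)
  read_collection(data.table(
    chrom = sample(c("cA", "cB"), n, TRUE),
    start = st, end = st + len - 1L,
    strand = sample(c("+", "-"), n, TRUE),
    seq = vapply(len, rand_seq, ""),
    copies = sample(1:4, n, TRUE),
    n_sites = sample(1:3, n, TRUE)))
}

# simple read table builder (unit weights unless stated)
make_reads <- function(chrom, start, len, strand, seq = NULL, copies = 1L,
                       n_sites = 1L) {
  k <- max(length(chrom), length(start), length(len), length(strand))
  dt <- data.table(chrom = rep_len(chrom, k), start = rep_len(start, k),
                   len = rep_len(len, k), strand = rep_len(strand, k),
                   copies = rep_len(copies, k), n_sites = rep_len(n_sites, k))
  dt[, end := start + len - 1L]
  if (is.null(seq)) dt[, seq := vapply(len, rand_seq, "")]
  else dt[, seq := rep_len(seq, k)]
  read_collection(dt[, .(chrom, start, end, strand, seq, copies, n_sites)])
}

# ---- exhaustive all-pairs oracles -----------------------------------------

oracle_pingpong <- function(rc, offsets = 1:20) {
  dt <- as.data.table(rc)
  P <- dt[dt$strand == "+"]
  M <- dt[dt$strand == "-"]
  cnt <- numeric(length(offsets))
  if (nrow(P) == 0L || nrow(M) == 0L) return(cnt)
  ii <- rep(seq_len(nrow(P)), each = nrow(M))
  jj <- rep(seq_len(nrow(M)), times = nrow(P))
  same <- P$chrom[ii] == M$chrom[jj]
  o <- M$five_prime[jj] - P$five_prime[ii] + 1L
  w <- P$weight[ii] * M$weight[jj]
  for (k in seq_along(offsets)) {
    cnt[k] <- sum(w[same & o == offsets[k]])
  }
  cnt
}

oracle_phasing <- function(rc, which_strand, offsets = 0:30, gate = TRUE) {
  dt <- as.data.table(rc)
  S <- dt[dt$strand == which_strand]
  cnt <- numeric(length(offsets))
  if (nrow(S) < 2L) return(cnt)
  ii <- rep(seq_len(nrow(S)), each = nrow(S))
  jj <- rep(seq_len(nrow(S)), times = nrow(S))
  keep <- S$chrom[ii] == S$chrom[jj]
  if (gate) keep <- keep & substr(S$seq[jj], 1, 1) == "T"
  d <- if (which_strand == "+") S$five_prime[jj] - S$three_prime[ii]
       else S$three_prime[ii] - S$five_prime[jj]
  w <- S$weight[ii] * S$weight[jj]
  for (k in seq_along(offsets)) {
    cnt[k] <- sum(w[keep & d == offsets[k]])
  }
  cnt
}

oracle_dicer <- function(rc, qs = 15:31, ts = 15:31, strict = TRUE) {
  dt <- as.data.table(rc)
  P <- dt[dt$strand == "+"]
  M <- dt[dt$strand == "-"]
  cnt <- matrix(0, length(qs), length(ts),
                dimnames = list(query = as.character(qs),
                                target = as.character(ts)))
  if (nrow(P) == 0L || nrow(M) == 0L) return(cnt)
  for (i in seq_len(nrow(P))) for (j in seq_len(nrow(M))) {
    if (P$chrom[i] != M$chrom[j]) next
    ovl <- min(P$end[i], M$end[j]) - max(P$start[i], M$start[j]) + 1L
    if (ovl < 1L || ovl != P$len[i] - 2L) next
    if (strict && P$end[i] != M$end[j] + 2L) next
    if (!(P$len[i] %in% qs) || !(M$len[j] %in% ts)) next
    q <- as.character(P$len[i]); t <- as.character(M$len[j])
    cnt[q, t] <- cnt[q, t] + P$weight[i] * M$weight[j]
  }
  cnt
}

# ---- SAM fixture writer ----------------------------------------------------

# records: data.table with chrom, pos, strand, seq (read orientation),
# optional nh, cigar, flag_extra
write_sam <- function(records, path, sq = c(chr1 = 100000L)) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sq), sq))
  body <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i]
    flag <- if (r$strand == "-") 16L else 0L
    if (!is.null(records$flag_extra) && !is.na(r$flag_extra))
      flag <- flag + r$flag_extra
    sq_field <- if (r$strand == "-") pingphase::revcomp(r$seq) else r$seq
    cigar <- if (!is.null(records$cigar) && !is.na(r$cigar)) r$cigar
             else sprintf("%dM", nchar(r$seq))
    fields <- c(sprintf("q%04d", i), flag, r$chrom, r$pos, 255L, cigar, "*",
                0L, 0L, sq_field, "*")
    if (!is.null(records$nh) && !is.na(r$nh))
      fields <- c(fields, sprintf("NH:i:%d", r$nh))
    paste(fields, collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  path
}

# reciprocal-overlap matcher: TRUE when intervals overlap by >= frac of both
reciprocal_overlap <- function(s1, e1, s2, e2, frac = 0.5) {
  ov <- pmin(e1, e2) - pmax(s1, s2) + 1
  ov >= frac * (e1 - s1 + 1) & ov >= frac * (e2 - s2 + 1)
}
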