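---
title: "Small RNA biogenesis signatures: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small RNA biogenesis signatures: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pingphase)
library(data.table)
```

# The problem

Insect small-RNA populations mix three classes with distinct biogenesis:
miRNAs (annotated by dedicated tools, out of scope here), ~22-nt siRNAs cut
by Dicer from double-stranded RNA, and 26–30-nt Piwi-associated piRNAs made
without Dicer. In hemipterans the piRNA pathway operates in somatic tissue,
piRNAs typically outnumber siRNAs, and many loci produce both classes at
once. Degradation fragments (15–35 nt) co-clone with genuine small RNAs, so
class membership cannot be read off a size histogram alone: it must be
inferred from the *pair geometry* that each biogenesis mechanism leaves in
aligned reads. `pingphase` implements those geometric statistics, a locus
annotation built on them, and the construct-design rule they motivate —
fusing a target-gene segment between flanks of an endogenous piRNA locus,
on the locus's phased strand.

# Data model and conventions

Internally all coordinates are 1-based and fully closed; a flank described
as `15168–15509` has length `15509 − 15168 + 1 = 342`. This convention is
what makes published cloning coordinates reconcile with their stated flank
lengths, and it is the arithmetic used throughout. On disk, BED output uses
the standard 0-based half-open convention; the conversion is an exact
bijection (property-tested on 10^4 random intervals).

A read's 5′ coordinate is `start` on the plus strand and `end` on the minus
strand. Sequences are stored in the read's own 5′→3′ orientation in the DNA
alphabet (U and T are synonyms on input; reports can render RNA). Reads with
indels or clipped alignments are excluded with a warning, because every
signature below assumes span = sequence length.

Multimapping reads are apportioned: a read collapsed to `copies` identical
sequences mapping to `n_sites` positions carries weight `copies / n_sites`
at each position. The aligner's `NH` tag supplies `n_sites` when present;
otherwise it is recounted as the number of alignment records sharing the
sequence. Whether hit counts or post-hoc recounting is the better
multiplicity estimate depends on how the upstream alignment was run, so both
are supported and an unweighted unique-sequence mode (`weighting =
"unique"`) is available for sensitivity checks.

# The three pair statistics

All three statistics accumulate, for each qualifying read pair, the product
of the two reads' weights into an offset spectrum, and summarize the
spectrum as

$$Z = \frac{c_{\text{focal}} - \bar c}{\sigma_{\text{pop}}(c)}$$

with $Z = 0$ when the spectrum is constant. The background includes the
focal bin and uses the population (not sample) standard deviation; the
offset ranges default to 1–20 (ping-pong) and 0–30 (phasing) and are
configurable. Including the focal bin is the conservative choice — it can
only shrink $Z$ — and with ~20–30 background bins the difference is small
against the threshold used here ($Z \ge 3$).

**Ping-pong.** Reciprocal Piwi slicing cuts the responder across from the
10th base of the guide, so guide and responder 5′ ends overlap by exactly
10 nt and the guide's 1U faces the responder's 10A. For every
opposite-strand pair on a chromosome the statistic records
$o = 5'_{(-)} - 5'_{(+)} + 1$; weighted counts at $o = 10$ against the 1–20
background give the Z-score. Restricting both reads to 28–30 nt isolates the
piRNA-sized signal.

**Phasing.** Processive fragmentation of a single-stranded precursor leaves
head-to-tail 1U reads. Per strand, for each read the distance to every
downstream same-strand read (in transcription direction) is
$d = 5'_{\text{down}} - 3'_{\text{up}}$, gated by default on the downstream
read starting with U; end-to-end juxtaposition gives $d = 1$, the focal
offset. The focal is configurable because published spectra have marked the
proximal enrichment one bin differently depending on their distance
convention; under this package's convention end-to-end is exactly 1, which
is verified by construction in the simulator tests.

**Dicer 2-nt 3′ overhangs.** RNase III leaves duplexes whose strands share
(length − 2) bases with both 3′ ends protruding 2 nt. Two modes are
provided: `loose` counts an opposite-strand pair at (query size, target
size) whenever the shared genomic span equals query length − 2 — the literal
overlap criterion — while the default `strict` mode additionally requires
the query's 3′ end to extend exactly 2 nt past the target's 5′ end, the
canonical duplex layout. The distinction matters: random read stacks can
satisfy the loose count with blunt or 5′-protruding geometry, and the strict
test removes exactly those. Each overlapping pair is counted once, with the
plus-strand read taken as query; the per-query-size Z compares the weight at
overlap $L_q - 2$ with the overlap distribution $1..L_q$ for that query
size.

All three implementations are index-joins over 5′/3′ coordinate tables, and
each is required by the test suite to agree *exactly* (same weights) with an
independent exhaustive all-pairs enumeration on 100+ seeded random read
sets, including 500-read instances. On uniformly placed strand-balanced
reads, $|Z| < 3$ holds in ≥ 95% of 200 seeded replicates for every
statistic, so the $Z \ge 3$ threshold used downstream has a calibrated false
positive rate of at most a few percent per locus.

# Locus discovery and triage

Reads on both strands are pooled per chromosome (dual-strand siRNA loci
require it; strandedness is reported, not used for merging), and read spans
separated by at most `merge_gap` bases are merged into candidate loci.
Candidates are kept when span ≥ `min_length` (500 bp) and summed weight is
strictly greater than `min_reads` (40). The depth criterion is interpreted
as summed read weight per locus rather than per-base coverage — locus
expression is what the downstream ranking uses, and the test suite pins the
boundary semantics (41 tiled unit reads over 600 bp pass; 40 do not; 100
reads in 450 bp do not).

`merge_gap` defaults to 200 bp. Published locus counts do not determine how
fragmented pileups were joined; 200 bp keeps phased piRNA trails with
sparse internal gaps in one locus while leaving independently placed loci
(kilobases apart) separate. It is exposed as a parameter, and the locus
count is property-tested to be monotone in both thresholds.

Triage per locus: the short/long ratio `w_short / w_long` with size classes
19–23 nt and 25–30 nt (ratio > 1 ⇒ short-biased; a zero denominator yields
the +Inf sentinel, short-biased), the plus-strand weight fraction, the 1U
fraction of long reads, and total weight for expression ranking
(`select_top_biased()`, default top 50, ties broken by coordinate so output
is deterministic).

# Classification

Loci are placed in five categories by a deterministic cascade on
$f = w_{\text{short}} / (w_{\text{short}} + w_{\text{long}})$, the signature
Z-scores, the span, and annotation context:

1. **cisNAT** — siRNA criteria met *and* the locus lies inside the
   intersection of a plus- and a minus-strand mRNA annotation;
2. **siRNA** — $f \ge 0.8$ and $Z_{\text{dicer}} \ge 3$;
3. **no_bias** — $f \in [0.4, 0.6]$, $Z_{\text{dicer}} \ge 3$ and
   $\max(Z_{\text{pp}}, Z_{\text{phase}}) \ge 3$;
4. **piRNA_cluster** — $f < 0.4$, piRNA signature present, span ≥ 5 kb;
5. **piRNA** — as 4 with a shorter span; otherwise **unclassified**.

The five categories are qualitative in origin; every numeric threshold here
(3.0, 0.8, the 0.4–0.6 band, 5 kb) is this package's choice, is carried in
`ClassificationParams`, and is echoed into the header of every output table
so downstream users can see exactly what produced a call. The cascade is a
pure function of its numeric inputs (permutation-tested), and raising the
significance threshold can only move loci toward `unclassified`, never into
a signature-requiring class.

Individual reads get exclusive identity labels with precedence ping-pong >
phasing > siRNA > other: a 28–30-nt 1U/10A read with an antisense partner at
5′ overlap 10 is a ping-pong piRNA; a 28–30-nt 1U read without such a
partner is a phased piRNA; a 22-nt read with first base U/A, 20th base A/U
and a strict-geometry duplex partner is an siRNA. The precedence resolves
reads satisfying several definitions toward ping-pong, matching how such
reads are conventionally colored in locus plots, and the labels partition
each locus's weight exactly (conservation-tested).

# Trigger design

The design rule is the package's downstream purpose: piRNA production from
a locus is strand-asymmetric (phased loci accumulate ~20-fold more reads on
the precursor strand), and constructs carrying the *phased* strand of the
donor silence targets more reliably. `select_phased_strand()` picks the
strand with the larger phasing Z (ties toward more total weight, then plus)
and warns when both are below threshold. `extract_flanks()` fetches the two
donor intervals in donor-strand orientation, and `build_trigger()`
concatenates left flank + gene-of-interest + right flank in that
orientation; on the minus strand the genomic-right interval becomes the
construct's 5′ flank, so that building on the minus strand and
reverse-complementing equals building the reverse-complemented inputs on
plus (a tested invariant). dsRNA mode emits the reverse complement as a
second FASTA record, and headers carry donor locus, strand, intervals and
mode as parseable key=value pairs that round-trip to the construct object.
Primer/assembly design (promoter placement, overlap primers) is out of
scope; the product is the fusion sequence with provenance.

# The simulator

The simulator is the package's canonical test input: no sequencing accession
is bundled, so every claim the tests make is against planted ground truth.
Design principles:

* **Geometry is planted by construction, not by simulating enzymology.**
  Ping-pong responders are placed at exactly 10-nt 5′ overlap for a
  configured fraction of guides (default 0.8); phased reads tile
  head-to-tail with occasional 0–4-nt jitter (probability 0.2) in repeated
  walks over the precursor; Dicer duplexes are two 22-nt reads offset so
  both 3′ ends protrude 2 nt, at random registers along the locus. Random
  registers (rather than a fixed dicing grid) are used because a strict
  20-bp grid makes adjacent duplexes themselves overlap at a second fixed
  offset, an artifact of the grid rather than of dicing, which contaminates
  the background distribution the Z-score is measured against.
* **Sequence biases emerge from the genome.** The genome base under a
  planted guide 5′ end is forced to T (probability `u1_bias`, default 0.9)
  and the base under the responder's 10th position to A; read sequences are
  then *fetched* from the genome, so the responder's 1U and 10A arise by
  complementarity exactly as in real data, and the guide/responder biases
  cannot drift apart from the genome that supposedly produced them. Dicer
  duplexes force 1U/1A with a complementarity-matched 20th base the same
  way.
* **Truthful labels.** A ping-pong guide that received no responder is
  recorded in the manifest as a phased piRNA — without a 10-overlap partner
  that is what it is — and reads whose 1U force was skipped keep their
  intended label, so the ~90% `u1_bias` bounds achievable label accuracy by
  design. Every emitted read id appears exactly once in the manifest,
  background included.
* **Background is diffuse.** Degradation fragments (sizes decaying
  exponentially from 15 nt, rate 0.18/nt) are placed uniformly at ~3 reads
  per kb — dense enough to contaminate every locus and to exercise the
  size-ratio denominator, sparse enough that background alone stays under
  the locus depth threshold, which mirrors real libraries where nuclease
  decay is spread genome-wide rather than concentrated. A zero-locus
  configuration therefore yields zero discovered loci at default
  thresholds (tested).
* **Study-scale defaults.** The default configuration plants eight loci
  (two ping-pong, two phased — one 8-kb cluster, one 2.5-kb locus — two
  Dicer-siRNA, one cis-NAT with its antisense mRNA pair, one mixed
  no-bias locus) on a 2 × 100-kb genome, with 28/29/30-nt piRNA lengths
  drawn at 0.2/0.4/0.4 so the long mode of the size spectrum peaks at
  29–30 nt next to the 22-nt Dicer mode. piRNA-sized read abundances follow
  a geometric distribution (mean ≈ 1.7 copies), emulating the skewed clone
  counts of real libraries.

What the simulator does **not** emulate: sequencing error, adapter
artifacts, expression dynamics, genome repeat structure (multimapping is
modeled only as an `n_sites` attribute, not as true repeated placement), and
enzymatic sequence preferences beyond the planted 1U/10A/20 biases. Passing
tests therefore demonstrate detector and pipeline correctness on reads whose
geometry is known, not robustness to alignment artifacts or biological
confounders in any particular real library.

# Problem sizes and numerical choices

The test and acceptance workloads use 8-locus (~3,000-alignment) default
simulations, a 30-locus simulation for discovery recall/precision at 50%
reciprocal overlap, and a 100-locus simulation (20 per class, ~25,000
alignments over 10 × 120-kb chromosomes) for classification and per-read
label accuracy — sizes chosen so the whole suite exercises every code path
in a few minutes while leaving comfortable statistical margins
(classification accuracy ≈ 1.0 against a 0.9 requirement; label accuracy
≈ 0.94 against 0.90, with the gap to 1.0 dominated by the deliberate
`u1_bias = 0.9`). Ties in expression ranking break by coordinate; spectra
with zero variance return $Z = 0$ rather than NaN; an empty long-size class
returns the +Inf ratio sentinel; and loci with no reads in either size
class are `unclassified` rather than an error. All randomness flows from a
single seed per simulation, and repeated runs are byte-identical across
every output file (tested end to end).

# Known limitations

* The short/long ratio and the classification cascade inherit the size-class
  windows; organisms with shifted piRNA length distributions need the
  `SizeClassScheme` adjusted.
* cis-NAT calls require locus containment in an annotated antisense mRNA
  overlap; unannotated antisense transcription is reported as plain siRNA.
* Target counting intersects re-mapped reads with annotation strand-
  agnostically and counts distinct feature ids; it does not attempt
  quantitative target ranking.
* The Z-score is a descriptive enrichment measure over a small offset
  window, not a calibrated p-value; the null calibration reported by the
  acceptance script is empirical.
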