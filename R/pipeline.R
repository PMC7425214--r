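# Pipeline assembly: discover -> per-locus signatures -> classify
# (-> trigger design on request), with every stage writing standard-format
# files (BED/TSV/FASTA/JSON) so any stage is independently re-runnable. All
# thresholds are echoed into '#' header lines of each table.

#' Per-locus signature Z-scores and spectra
#'
#' For each locus computes the ping-pong Z (10-nt 5' overlaps), per-strand
#' phasing Z (trailing-1U distance 1), and the Dicer 2-nt-overhang Z at the
#' scheme's siRNA size, from the reads falling inside the locus.
#'
#' @param reads a `ReadCollection`.
#' @param loci locus table from [discover_loci()].
#' @param scheme a [size_class_scheme()].
#' @param geometry Dicer geometry mode.
#' @return list with `loci` (input plus z columns) and `spectra` (long table:
#'   locus_id, kind, offset, count).
#' @export
locus_signatures <- function(reads, loci, scheme = size_class_scheme(),
                             geometry = c("strict", "loose")) {
  geometry <- match.arg(geometry)
  dt <- data.table::as.data.table(loci)
  zs <- data.table::data.table(locus_id = dt$locus_id,
                               z_pingpong = 0, z_phasing_plus = 0,
                               z_phasing_minus = 0, z_dicer = 0)
  spectra <- vector("list", nrow(dt))
  for (i in seq_len(nrow(dt))) {
    region <- list(chrom = dt$chrom[i], start = dt$start[i], end = dt$end[i])
    lr <- locus_reads(reads, region)
    pp <- pingpong_spectrum(lr)
    php <- phasing_spectrum(lr, strand = "+")
    phm <- phasing_spectrum(lr, strand = "-")
    om <- dicer_overhang_matrix(lr, geometry = geometry)
    zs[i, `:=`(z_pingpong = spectrum_zscore(pp),
               z_phasing_plus = spectrum_zscore(php),
               z_phasing_minus = spectrum_zscore(phm),
               z_dicer = om$z[as.character(scheme$sirna_size)])]
    spectra[[i]] <- data.table::rbindlist(list(
      data.table::data.table(locus_id = dt$locus_id[i], kind = "pingpong",
                             offset = pp$offsets, count = pp$counts),
      data.table::data.table(locus_id = dt$locus_id[i], kind = "phasing_plus",
                             offset = php$offsets, count = php$counts),
      data.table::data.table(locus_id = dt$locus_id[i], kind = "phasing_minus",
                             offset = phm$offsets, count = phm$counts)))
  }
  list(loci = merge(dt, zs, by = "locus_id", sort = FALSE),
       spectra = data.table::rbindlist(spectra))
}

# balloon-style subset table: per IUPAC constraint set, per-size abundance
# and strict 2-nt-overhang pair weight
.subset_balloon_table <- function(reads, scheme, sizes = 15:31) {
  filters <- list(
    "1N" = positional_filter("1" = "N"),
    "1U" = positional_filter("1" = "U"),
    "1A" = positional_filter("1" = "A"),
    "1C" = positional_filter("1" = "C"),
    "1G" = positional_filter("1" = "G"),
    "1H-20D" = positional_filter("1" = "H", "20" = "D"),
    "1W-20W" = positional_filter("1" = "W", "20" = "W"),
    "1U-20A" = positional_filter("1" = "U", "20" = "A"),
    "1A-20U" = positional_filter("1" = "A", "20" = "U"),
    "1C-20G" = positional_filter("1" = "C", "20" = "G"),
    "1G-20C" = positional_filter("1" = "G", "20" = "C"))
  out <- vector("list", length(filters))
  for (i in seq_along(filters)) {
    sub <- subset_reads(reads, filters[[i]])
    sd <- size_distribution(sub, sizes = sizes, annotate_base = FALSE)
    om <- dicer_overhang_matrix(sub, query_sizes = sizes, target_sizes = sizes)
    out[[i]] <- data.table::data.table(
      subset = names(filters)[i], len = sd$len, weight = sd$weight,
      overhang_pairs = rowSums(om$counts), overhang_z = om$z)
  }
  data.table::rbindlist(out)
}

.refuse_overwrite <- function(paths, force) {
  existing <- paths[file.exists(unlist(paths))]
  if (length(existing) && !force)
    stop("output file(s) already exist (use force = TRUE to overwrite): ",
         paste(unlist(existing), collapse = ", "))
}

#' Run the discovery -> signatures -> classification pipeline
#'
#' Executes locus discovery, per-locus signature statistics, five-way
#' classification and per-read identity labeling, writing one table per
#' figure-style summary: `loci.bed`, `loci_triage.tsv` (span/expression/
#' ratio), `locus_signatures.tsv` (long locus x offset spectra),
#' `overhang_matrix.tsv` (query x target Dicer pairs), `subset_balloons.tsv`
#' (IUPAC positional subsets), `read_identity_totals.tsv` (per-strand label
#' weights per locus) and `classified.tsv`. Every table carries the
#' thresholds in `#` header lines.
#'
#' @param reads path to an alignment file, or a `ReadCollection`.
#' @param out_dir output directory (created if missing).
#' @param annotation optional GFF3 path or feature table.
#' @param params a [locus_discovery_params()].
#' @param class_params a [classification_params()].
#' @param scheme a [size_class_scheme()].
#' @param geometry Dicer geometry mode.
#' @param min_len,max_len,max_sites,weighting reader options (used when
#'   `reads` is a path), see [read_alignments()].
#' @param force overwrite existing outputs.
#' @return invisibly, a list of the tables plus output paths.
#' @export
run_pipeline <- function(reads, out_dir, annotation = NULL,
                         params = locus_discovery_params(),
                         class_params = classification_params(),
                         scheme = size_class_scheme(),
                         geometry = "strict",
                         min_len = 15L, max_len = 35L, max_sites = 100L,
                         weighting = "fractional", force = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- list(
    loci_bed = file.path(out_dir, "loci.bed"),
    triage = file.path(out_dir, "loci_triage.tsv"),
    signatures = file.path(out_dir, "locus_signatures.tsv"),
    overhang = file.path(out_dir, "overhang_matrix.tsv"),
    balloons = file.path(out_dir, "subset_balloons.tsv"),
    identities = file.path(out_dir, "read_identity_totals.tsv"),
    classified = file.path(out_dir, "classified.tsv"))
  .refuse_overwrite(paths, force)
  stamp <- c(params, class_params,
             list(geometry = geometry, min_len = min_len, max_len = max_len,
                  max_sites = max_sites, weighting = weighting,
                  short_range = scheme$short_range,
                  long_range = scheme$long_range,
                  pirna_range = scheme$pirna_range,
                  sirna_size = scheme$sirna_size))
  stage <- "read input"
  tables <- list()
  tryCatch({
    if (is.character(reads))
      reads <- read_alignments(reads, min_len = min_len, max_len = max_len,
                               max_sites = max_sites, weighting = weighting,
                               scheme = scheme)
    if (is.character(annotation)) annotation <- read_annotation(annotation)
    stage <- "discover"
    loci <- discover_loci(reads, params = params, scheme = scheme)
    triage <- loci[, .(locus_id, chrom, start, end, length, w_total, w_short,
                       w_long, ratio, plus_fraction, u1_fraction_long, n_reads)]
    write_table_stamped(triage, paths$triage, stamp)
    stage <- "signatures"
    sig <- locus_signatures(reads, loci, scheme = scheme, geometry = geometry)
    write_table_stamped(sig$spectra, paths$signatures, stamp)
    om <- dicer_overhang_matrix(reads, geometry = geometry)
    om_long <- data.table::as.data.table(as.table(om$counts))
    data.table::setnames(om_long, c("query", "target", "weight"))
    write_table_stamped(om_long, paths$overhang, stamp)
    balloons <- .subset_balloon_table(reads, scheme)
    write_table_stamped(balloons, paths$balloons, stamp)
    stage <- "classify"
    classified <- classify_loci(sig$loci, annotation = annotation,
                                params = class_params)
    write_table_stamped(
      classified[, !c("chrom", "start", "end", "length", "w_short", "w_long",
                      "w_total", "ratio", "plus_fraction", "u1_fraction_long",
                      "n_reads"), with = FALSE],
      paths$classified, stamp)
    write_loci_bed(classified, paths$loci_bed)
    stage <- "label reads"
    idt <- vector("list", nrow(classified))
    for (i in seq_len(nrow(classified))) {
      lr <- locus_reads(reads, classified[i])
      tot <- label_reads(lr, scheme = scheme)$totals
      if (nrow(tot)) tot[, locus_id := classified$locus_id[i]]
      idt[[i]] <- tot
    }
    identities <- data.table::rbindlist(idt, fill = TRUE)
    write_table_stamped(identities, paths$identities, stamp)
    tables <- list(loci = classified, triage = triage, spectra = sig$spectra,
                   overhang = om, balloons = balloons,
                   identities = identities)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(c(tables, list(paths = paths)))
}

#' Merge per-locus stage outputs into one summary table
#'
#' Joins the triage and classification tables of a pipeline run on
#' `locus_id`; mismatched locus ids are an error (listed). Writes
#' `summary.tsv` alongside the stage outputs.
#'
#' @param out_dir directory holding a [run_pipeline()] result.
#' @return the merged data.table (invisibly written to `summary.tsv`).
#' @export
make_report <- function(out_dir) {
  need <- c(triage = "loci_triage.tsv", classified = "classified.tsv")
  paths <- file.path(out_dir, need)
  missing <- !file.exists(paths)
  if (any(missing))
    stop("missing stage table(s): ", paste(need[missing], collapse = ", "))
  triage <- read_table_stamped(paths[1])
  classified <- read_table_stamped(paths[2])
  only_t <- setdiff(triage$locus_id, classified$locus_id)
  only_c <- setdiff(classified$locus_id, triage$locus_id)
  if (length(only_t) || length(only_c))
    stop("locus id mismatch between stage tables: ",
         paste(c(only_t, only_c), collapse = ", "))
  merged <- merge(triage, classified, by = "locus_id", sort = TRUE)
  data.table::fwrite(merged, file.path(out_dir, "summary.tsv"), sep = "\t")
  merged[]
}
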