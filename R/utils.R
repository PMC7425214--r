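# Small shared helpers: sequence normalization, reverse complement,
# coordinate-convention conversion (internal 1-based closed <-> BED 0-based
# half-open).

#' Normalize a nucleotide string to the internal DNA alphabet
#'
#' Sequences are stored internally in the DNA alphabet (T); U and T are
#' treated as synonyms on input. Case is folded to upper.
#'
#' @param x character vector of nucleotide sequences (RNA or DNA).
#' @return character vector in upper-case DNA alphabet.
#' @export
normalize_seq <- function(x) {
  chartr("U", "T", toupper(x))
}

#' Render an internal DNA sequence as RNA for reports
#' @param x character vector of DNA sequences.
#' @return character vector with T replaced by U.
#' @export
as_rna <- function(x) chartr("T", "U", toupper(x))

#' Reverse complement of character sequences
#' @param x character vector of DNA sequences (IUPAC codes allowed).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Convert 1-based closed intervals to BED (0-based half-open)
#'
#' @param start,end integer vectors, 1-based inclusive.
#' @return data.frame with columns `start` and `end` in BED convention.
#' @export
to_bed_coords <- function(start, end) {
  data.frame(start = as.integer(start) - 1L, end = as.integer(end))
}

#' Convert BED (0-based half-open) intervals to 1-based closed
#' @param start,end integer vectors in BED convention.
#' @return data.frame with 1-based inclusive `start` and `end`.
#' @export
from_bed_coords <- function(start, end) {
  data.frame(start = as.integer(start) + 1L, end = as.integer(end))
}

# expand an IUPAC code (or an explicit base string) to DNA base set
iupac_bases <- function(code) {
  code <- normalize_seq(code)
  map <- Biostrings::IUPAC_CODE_MAP
  out <- unique(unlist(lapply(strsplit(code, "")[[1]], function(ch) {
    if (ch %in% names(map)) strsplit(map[[ch]], "")[[1]] else ch
  })))
  bad <- setdiff(out, c("A", "C", "G", "T"))
  if (length(bad)) stop("unknown base code(s): ", paste(bad, collapse = ","))
  out
}

# population standard deviation
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

# write a TSV with '#'-prefixed provenance header lines (thresholds etc.)
write_table_stamped <- function(dt, path, params = list()) {
  hdr <- c(
    sprintf("# pingphase=%s", as.character(utils::packageVersion("pingphase"))),
    if (length(params)) {
      sprintf("# %s=%s", names(params),
              vapply(params, function(p) paste(format(p), collapse = ","), ""))
    }
  )
  writeLines(hdr, path)
  data.table::fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

# read back a stamped TSV, returning the table (header lines in attr "header")
read_table_stamped <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  dt <- data.table::fread(text = paste(body, collapse = "\n"), sep = "\t")
  data.table::setattr(dt, "header", hdr)
  dt
}
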