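#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased on read; record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) abort(sprintf("empty FASTA file: %s", path))
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) {
    abort(sprintf("duplicate FASTA record names in %s", path))
  }
  setNames(toupper(as.character(ss)), nm)
}

#' Write sequences to FASTA
#'
#' Writes uppercase sequences wrapped at 80 columns.
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    abort("`seqs` must be a fully named character vector")
  }
  ss <- Biostrings::DNAStringSet(toupper(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Read a BED4 file of labelled segments
#'
#' Coordinates are 0-based half-open. Rows are sorted by (chrom, start) on
#' read; a warning is raised if the input was unsorted.
#'
#' @param path Path to a 4-column tab-separated BED file
#'   (chrom, start, end, label), no header.
#' @return Tibble with columns `chrom`, `start`, `end`, `label`.
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path,
    col_names = c("chrom", "start", "end", "label"),
    col_types = "ciic", progress = FALSE
  )
  if (nrow(x) == 0) abort(sprintf("empty BED file: %s", path))
  if (any(x$start < 0)) abort("negative coordinate in BED input")
  if (any(x$end <= x$start)) abort("BED interval with end <= start")
  sorted <- arrange(x, .data$chrom, .data$start)
  if (!identical(sorted$start, x$start) || !identical(sorted$chrom, x$chrom)) {
    warn("BED input was not sorted; sorting by (chrom, start)")
  }
  sorted
}

#' Write labelled segments as BED4
#'
#' @param segments Tibble with columns `chrom`, `start`, `end`, `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(segments, path) {
  stopifnot(all(c("chrom", "start", "end", "label") %in% names(segments)))
  if (any(segments$end <= segments$start)) abort("BED interval with end <= start")
  out <- arrange(segments, .data$chrom, .data$start)
  readr::write_tsv(out[, c("chrom", "start", "end", "label")], path,
    col_names = FALSE, progress = FALSE
  )
  invisible(path)
}
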