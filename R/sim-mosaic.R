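#' Specification of a mosaic chromosome
#'
#' An ordered list of segments, each taken from one donor group's panel
#' sequence at the homologous (cumulative) coordinates, emulating a hybrid
#' chromosome assembled from several ancestral origins.
#'
#' @param chrom Chromosome name of the mosaic.
#' @param lengths Integer vector of segment lengths in bp (> 0).
#' @param groups Character vector of donor group names, one per segment.
#' @param haps Integer vector of donor haplotype (panel sequence) indices,
#'   one per segment; recycled if length 1.
#' @return An object of class `mosaic_spec`.
#' @export
#' @examples
#' mosaic_spec("chr1", c(10000, 5000, 10000), c("A", "B", "A"))
mosaic_spec <- function(chrom, lengths, groups, haps = 1L) {
  if (length(lengths) == 0) abort("at least one segment is required")
  if (any(lengths <= 0)) abort("segment lengths must be > 0")
  if (length(groups) != length(lengths)) {
    abort("`groups` must have one entry per segment")
  }
  haps <- rep_len(as.integer(haps), length(lengths))
  structure(
    list(
      chrom = as.character(chrom), lengths = as.integer(lengths),
      groups = as.character(groups), haps = haps
    ),
    class = "mosaic_spec"
  )
}

as_panel_list <- function(panels) {
  if (inherits(panels, "ancestry_panel_sim")) panels <- panels$panels
  if (!is.list(panels) || is.null(names(panels))) {
    abort("`panels` must be a named list of group sequence sets")
  }
  panels
}

#' Build a mosaic chromosome with known ancestry truth
#'
#' Concatenates donor slices taken at the cumulative mosaic coordinates from
#' each segment's donor group, and returns the sequence together with a
#' truth table (BED-like, 0-based half-open) that tiles the chromosome.
#'
#' @param panels A named list (group -> character vector of panel sequences)
#'   or an `ancestry_panel_sim` from [simulate_ancestral_groups()].
#' @param spec A [mosaic_spec()].
#' @return A list of class `mosaic_genome` with `seq` (named character
#'   vector of length 1) and `truth` (tibble: chrom, start, end, label).
#' @export
build_mosaic_genome <- function(panels, spec) {
  stopifnot(inherits(spec, "mosaic_spec"))
  panels <- as_panel_list(panels)
  missing <- setdiff(unique(spec$groups), names(panels))
  if (length(missing) > 0) {
    abort(sprintf("unknown donor group(s): %s", paste(missing, collapse = ", ")))
  }
  ends <- cumsum(spec$lengths)
  starts <- c(0L, ends[-length(ends)])
  pieces <- character(length(spec$lengths))
  for (i in seq_along(spec$lengths)) {
    donor <- panels[[spec$groups[i]]]
    if (spec$haps[i] > length(donor)) {
      abort(sprintf(
        "group %s has no haplotype %d", spec$groups[i], spec$haps[i]
      ))
    }
    dseq <- donor[[spec$haps[i]]]
    if (nchar(dseq) < ends[i]) {
      abort(sprintf(
        "segment %d extends past donor %s length (%d < %d)",
        i, spec$groups[i], nchar(dseq), ends[i]
      ))
    }
    pieces[i] <- substr(dseq, starts[i] + 1L, ends[i])
  }
  truth <- tibble(
    chrom = spec$chrom, start = starts, end = ends, label = spec$groups
  )
  # collapse adjacent same-donor segments so truth rows are maximal runs
  runs <- cumsum(c(TRUE, truth$label[-1] != truth$label[-nrow(truth)]))
  truth <- truth |>
    mutate(run = runs) |>
    group_by(.data$run) |>
    summarise(
      chrom = .data$chrom[1], start = min(.data$start), end = max(.data$end),
      label = .data$label[1], .groups = "drop"
    ) |>
    select("chrom", "start", "end", "label")
  structure(
    list(
      seq = setNames(paste(pieces, collapse = ""), spec$chrom),
      truth = truth, spec = spec
    ),
    class = "mosaic_genome"
  )
}
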