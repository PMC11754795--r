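#' Chromosome rearrangement events
#'
#' Constructors for the two rearrangement event types observed between
#' Musa assemblies: intrachromosomal inversions and reciprocal
#' translocations (mutual exchange of distal segments between two
#' chromosomes), optionally combined (e.g. an inversion within one
#' chromosome followed by a reciprocal translocation). All coordinates are
#' 0-based half-open and refer to the chromosome state at the time the
#' event is applied (events are applied in listed order).
#'
#' @param chrom,chrom_a,chrom_b Chromosome names.
#' @param start,end Inversion interval `[start, end)`.
#' @param break_a,break_b Translocation breakpoints; the exchanged parts are
#'   `[break, chrom_end)`.
#' @return An event object for [rearrangement_spec()].
#' @export
rearr_inversion <- function(chrom, start, end) {
  if (end <= start || start < 0) abort("inversion requires 0 <= start < end")
  structure(
    list(type = "inversion", chrom = chrom, start = as.double(start),
         end = as.double(end)),
    class = "rearr_event"
  )
}

#' @rdname rearr_inversion
#' @export
rearr_translocation <- function(chrom_a, break_a, chrom_b, break_b) {
  if (break_a < 0 || break_b < 0) abort("breakpoints must be >= 0")
  if (identical(chrom_a, chrom_b)) abort("translocation needs two chromosomes")
  structure(
    list(type = "translocation", chrom_a = chrom_a, break_a = as.double(break_a),
         chrom_b = chrom_b, break_b = as.double(break_b)),
    class = "rearr_event"
  )
}

#' Ordered list of rearrangement events
#'
#' @param ... `rearr_event` objects from [rearr_inversion()] /
#'   [rearr_translocation()], applied in order.
#' @return An object of class `rearrangement_spec`.
#' @export
rearrangement_spec <- function(...) {
  events <- list(...)
  if (!all(vapply(events, inherits, logical(1), "rearr_event"))) {
    abort("all arguments must be rearrangement events")
  }
  structure(list(events = events), class = "rearrangement_spec")
}

# --- internal block algebra ------------------------------------------------
# A chromosome under rearrangement is an ordered list of blocks, each a row
# (src_chrom, src_start, src_end, strand) pointing into the ORIGINAL
# assembly. Current coordinates are implied by cumulative block lengths.

block_lengths <- function(b) b$src_end - b$src_start

# ensure a block boundary exists at current coordinate x
split_blocks_at <- function(b, x) {
  lens <- block_lengths(b)
  cum <- cumsum(lens)
  total <- if (length(cum)) cum[length(cum)] else 0
  if (x < 0 || x > total) abort(sprintf("breakpoint %s outside chromosome bounds", x))
  if (x == 0 || x == total || x %in% cum) return(b)
  i <- findInterval(x, c(0, cum), rightmost.closed = FALSE)
  off <- x - c(0, cum)[i]
  row <- b[i, ]
  if (row$strand == "+") {
    left <- row; left$src_end <- row$src_start + off
    right <- row; right$src_start <- row$src_start + off
  } else {
    left <- row; left$src_start <- row$src_end - off
    right <- row; right$src_end <- row$src_end - off
  }
  bind_rows(b[seq_len(i - 1), ], left, right, b[setdiff(seq_len(nrow(b)), seq_len(i)), ])
}

blocks_in_range <- function(b, start, end) {
  cum <- cumsum(block_lengths(b))
  begin <- c(0, cum[-length(cum)])
  which(begin >= start & cum <= end)
}

apply_event <- function(chrom_blocks, ev) {
  if (ev$type == "inversion") {
    if (!ev$chrom %in% names(chrom_blocks)) abort(sprintf("unknown chromosome %s", ev$chrom))
    b <- chrom_blocks[[ev$chrom]]
    b <- split_blocks_at(b, ev$start)
    b <- split_blocks_at(b, ev$end)
    idx <- blocks_in_range(b, ev$start, ev$end)
    if (length(idx) > 0) {
      mid <- b[rev(idx), ]
      mid$strand <- ifelse(mid$strand == "+", "-", "+")
      b <- bind_rows(b[seq_len(min(idx) - 1), ], mid,
                     b[setdiff(seq_len(nrow(b)), seq_len(max(idx))), ])
    }
    chrom_blocks[[ev$chrom]] <- b
  } else {
    for (cn in c(ev$chrom_a, ev$chrom_b)) {
      if (!cn %in% names(chrom_blocks)) abort(sprintf("unknown chromosome %s", cn))
    }
    ba <- split_blocks_at(chrom_blocks[[ev$chrom_a]], ev$break_a)
    bb <- split_blocks_at(chrom_blocks[[ev$chrom_b]], ev$break_b)
    cuma <- cumsum(block_lengths(ba))
    cumb <- cumsum(block_lengths(bb))
    ia <- sum(cuma <= ev$break_a)
    ib <- sum(cumb <= ev$break_b)
    heada <- ba[seq_len(ia), , drop = FALSE]
    taila <- ba[setdiff(seq_len(nrow(ba)), seq_len(ia)), , drop = FALSE]
    headb <- bb[seq_len(ib), , drop = FALSE]
    tailb <- bb[setdiff(seq_len(nrow(bb)), seq_len(ib)), , drop = FALSE]
    chrom_blocks[[ev$chrom_a]] <- bind_rows(heada, tailb)
    chrom_blocks[[ev$chrom_b]] <- bind_rows(headb, taila)
  }
  chrom_blocks
}

#' Apply chromosome rearrangements to an assembly
#'
#' Applies inversions and reciprocal translocations in order, tracking the
#' provenance of every base. The total base count is conserved; inverted
#' intervals are reverse-complemented; a reciprocal translocation exchanges
#' the distal parts of two chromosomes. The returned block map relates
#' original (`src`) and rearranged (`dst`) coordinates and is a bijection
#' over all bases.
#'
#' @param assembly Named character vector of chromosome sequences.
#' @param spec A [rearrangement_spec()]. An empty spec returns the assembly
#'   unchanged with an identity map.
#' @return A list of class `rearranged_assembly` with `seq` (named character
#'   vector) and `blocks`, a tibble with columns `dst_chrom`, `dst_start`,
#'   `dst_end`, `src_chrom`, `src_start`, `src_end`, `strand`.
#' @seealso [map_coords()] to project positions through the block map.
#' @export
apply_rearrangement <- function(assembly, spec = rearrangement_spec()) {
  stopifnot(inherits(spec, "rearrangement_spec"))
  if (is.null(names(assembly))) abort("`assembly` must be named")
  chrom_blocks <- lapply(names(assembly), function(cn) {
    tibble(src_chrom = cn, src_start = 0, src_end = nchar(assembly[[cn]]),
           strand = "+")
  })
  names(chrom_blocks) <- names(assembly)
  for (ev in spec$events) chrom_blocks <- apply_event(chrom_blocks, ev)

  blocks <- purrr::imap(chrom_blocks, function(b, cn) {
    lens <- block_lengths(b)
    ends <- cumsum(lens)
    b |>
      mutate(dst_chrom = cn, dst_start = c(0, ends[-length(ends)]),
             dst_end = ends) |>
      select("dst_chrom", "dst_start", "dst_end",
             "src_chrom", "src_start", "src_end", "strand")
  }) |> bind_rows()

  newseq <- vapply(names(chrom_blocks), function(cn) {
    b <- chrom_blocks[[cn]]
    pieces <- vapply(seq_len(nrow(b)), function(i) {
      s <- substr(assembly[[b$src_chrom[i]]], b$src_start[i] + 1, b$src_end[i])
      if (b$strand[i] == "-") revcomp(s) else s
    }, character(1))
    paste(pieces, collapse = "")
  }, character(1))

  structure(
    list(seq = newseq, blocks = blocks, spec = spec),
    class = "rearranged_assembly"
  )
}

#' Project positions through a rearrangement block map
#'
#' Maps 0-based positions between the original (`src`) and rearranged
#' (`dst`) coordinate systems. The forward map composed with the inverse map
#' is the identity on every base.
#'
#' @param blocks Block map tibble from [apply_rearrangement()].
#' @param chrom,pos Vectors of chromosome names and 0-based positions.
#' @param direction `"forward"` (src -> dst) or `"inverse"` (dst -> src).
#' @return Tibble with columns `chrom`, `pos`, `strand` (the mapped
#'   position; strand `-` means the base is reverse-complemented there).
#' @export
map_coords <- function(blocks, chrom, pos, direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  if (direction == "forward") {
    from <- c("src_chrom", "src_start", "src_end")
    to <- c("dst_chrom", "dst_start", "dst_end")
  } else {
    from <- c("dst_chrom", "dst_start", "dst_end")
    to <- c("src_chrom", "src_start", "src_end")
  }
  n <- length(pos)
  out_chrom <- character(n)
  out_pos <- rep(NA_real_, n)
  out_strand <- character(n)
  for (i in seq_len(n)) {
    hit <- blocks[blocks[[from[1]]] == chrom[i] &
                    blocks[[from[2]]] <= pos[i] &
                    blocks[[from[3]]] > pos[i], ]
    if (nrow(hit) != 1) abort(sprintf("position %s:%s not covered by map", chrom[i], pos[i]))
    off <- pos[i] - hit[[from[2]]]
    out_chrom[i] <- hit[[to[1]]]
    out_pos[i] <- if (hit$strand == "+") hit[[to[2]]] + off else hit[[to[3]]] - 1 - off
    out_strand[i] <- hit$strand
  }
  tibble(chrom = out_chrom, pos = out_pos, strand = out_strand)
}
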