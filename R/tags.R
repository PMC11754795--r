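#' Tag discovery configuration
#'
#' @param k Tag length in bases; must be odd (odd k rules out palindromic
#'   k-mers, so every tag has a well-defined strand). Default 31.
#' @param min_group_freq Minimum fraction of a group's panel sequences that
#'   must contain a k-mer for it to be a candidate tag of that group
#'   (0 < min_group_freq <= 1). Default 1 (present in every panel
#'   sequence).
#' @param max_hits Maximum number of assembly loci a tag may hit before it
#'   is discarded entirely by [match_tags()]; `Inf` keeps all.
#' @return An object of class `tag_config`.
#' @export
tag_config <- function(k = 31L, min_group_freq = 1, max_hits = Inf) {
  stopifnot_scalar_count(k, "k", 3)
  if (k %% 2 == 0) abort("`k` must be odd")
  if (min_group_freq <= 0 || min_group_freq > 1) {
    abort("`min_group_freq` must be in (0, 1]")
  }
  structure(
    list(k = as.integer(k), min_group_freq = min_group_freq,
         max_hits = max_hits),
    class = "tag_config"
  )
}

# all canonical k-mers of one sequence (unique), skipping windows with
# characters outside ACGT
canonical_kmers <- function(seq, k) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < k) return(character(0))
  fwd <- substring(seq, 1:(n - k + 1), k:n)
  ok <- !grepl("[^ACGT]", fwd)
  fwd <- fwd[ok]
  if (length(fwd) == 0) return(character(0))
  unique(pmin(fwd, revcomp(fwd)))
}

#' Discover group-diagnostic sequence tags
#'
#' Finds k-mers specific to each ancestral group: present (exact match,
#' either strand) in at least `min_group_freq` of the group's own panel
#' sequences and absent from every sequence of every other group's panel.
#' Tags are reported in canonical form (the lexicographically smaller of a
#' k-mer and its reverse complement).
#'
#' @param panels Named list (group -> character vector of panel sequences),
#'   or an `ancestry_panel_sim`.
#' @param cfg A [tag_config()].
#' @return Tibble with columns `tag`, `group`, `freq`, sorted by
#'   (group, tag).
#' @export
#' @examples
#' panels <- list(A = "ACGTACGTACGT", B = "ACGTAGGTACGT")
#' discover_tags(panels, tag_config(k = 5))
discover_tags <- function(panels, cfg = tag_config()) {
  stopifnot(inherits(cfg, "tag_config"))
  panels <- as_panel_list(panels)
  if (length(panels) < 2) abort("at least 2 groups are required for specificity")
  if (any(vapply(panels, length, integer(1)) == 0)) abort("empty panel")
  per_seq <- lapply(panels, function(seqs) lapply(seqs, canonical_kmers, k = cfg$k))
  group_union <- lapply(per_seq, function(x) unique(unlist(x, use.names = FALSE)))
  rows <- lapply(names(panels), function(g) {
    nseq <- length(per_seq[[g]])
    counts <- table(unlist(per_seq[[g]], use.names = FALSE))
    freq <- as.numeric(counts) / nseq
    cand <- names(counts)[freq >= cfg$min_group_freq]
    other <- unique(unlist(group_union[setdiff(names(panels), g)], use.names = FALSE))
    keep <- setdiff(cand, other)
    tibble(tag = keep, group = g,
           freq = as.numeric(counts[keep]) / nseq)
  })
  bind_rows(rows) |> arrange(.data$group, .data$tag)
}

#' Locate diagnostic tags on an assembly
#'
#' Reports every exact occurrence of each tag on either strand of each
#' chromosome, once per locus, with 0-based start coordinates. Strand `+`
#' means the assembly substring equals the (canonical) tag sequence, `-`
#' that it equals its reverse complement. Windows containing characters
#' outside ACGT produce no hits. Tags hitting more than `cfg$max_hits`
#' loci across the assembly are dropped entirely.
#'
#' @param assembly Named character vector of chromosome/contig sequences.
#' @param tags Tibble from [discover_tags()] (columns `tag`, `group`), or a
#'   named list group -> character vector of tag sequences.
#' @param cfg A [tag_config()]; `cfg$k` must match the tag length.
#' @return Tibble with columns `tag`, `group`, `chrom`, `start`, `strand`,
#'   sorted by (chrom, start).
#' @export
match_tags <- function(assembly, tags, cfg = tag_config()) {
  if (is.list(tags) && !is.data.frame(tags)) {
    tags <- bind_rows(purrr::imap(tags, function(tg, g) tibble(tag = tg, group = g)))
  }
  if (length(assembly) == 0 || any(nchar(assembly) == 0)) {
    abort("`assembly` must contain non-empty sequences")
  }
  if (is.null(names(assembly))) abort("`assembly` must be named")
  if (nrow(tags) == 0) {
    return(tibble(tag = character(0), group = character(0),
                  chrom = character(0), start = integer(0),
                  strand = character(0)))
  }
  if (any(nchar(tags$tag) != cfg$k)) {
    abort("tag lengths do not match `cfg$k`")
  }
  if (any(grepl("[^ACGT]", tags$tag))) {
    abort("tags must be over {A,C,G,T}")
  }
  fwd <- Biostrings::PDict(Biostrings::DNAStringSet(tags$tag))
  rev <- Biostrings::PDict(Biostrings::DNAStringSet(revcomp(tags$tag)))
  hits <- lapply(names(assembly), function(cn) {
    subj <- Biostrings::DNAString(toupper(assembly[[cn]]))
    sp <- Biostrings::startIndex(Biostrings::matchPDict(fwd, subj))
    sm <- Biostrings::startIndex(Biostrings::matchPDict(rev, subj))
    np <- lengths(sp)
    nm <- lengths(sm)
    tibble(
      idx = c(rep(seq_along(np), np), rep(seq_along(nm), nm)),
      start = c(unlist(sp, use.names = FALSE),
                unlist(sm, use.names = FALSE)) - 1L,
      strand = c(rep("+", sum(np)), rep("-", sum(nm))),
      chrom = cn
    )
  }) |> bind_rows()
  if (nrow(hits) == 0) {
    return(tibble(tag = character(0), group = character(0),
                  chrom = character(0), start = integer(0),
                  strand = character(0)))
  }
  if (is.finite(cfg$max_hits)) {
    per_tag <- table(hits$idx)
    drop <- as.integer(names(per_tag)[per_tag > cfg$max_hits])
    hits <- hits[!hits$idx %in% drop, ]
  }
  hits |>
    mutate(tag = tags$tag[.data$idx], group = tags$group[.data$idx]) |>
    select("tag", "group", "chrom", "start", "strand") |>
    arrange(.data$chrom, .data$start, .data$tag)
}
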