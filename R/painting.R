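#' Ancestry painting configuration
#'
#' Controls the windowed majority rule that turns tag hits into ancestry
#' labels. A window is labelled with the group holding the plurality of its
#' tag hits only when there is enough evidence (`min_hits`) and the top
#' group is dominant enough (`ratio`); otherwise the window is `NA`,
#' meaning no origin could be attributed.
#'
#' @param window Window size in bp (default 10 kb, suited to synthetic
#'   chromosomes; use ~100 kb at whole-genome scale).
#' @param min_hits Minimum total tag hits in a window for a call (default 5).
#' @param ratio Dominance ratio: the top group's share of the window's hits
#'   must reach this value (0.5 < ratio <= 1; default 0.75).
#' @param normalize If `TRUE`, each group's window counts are divided by
#'   the group's total tag count before the rule is applied (useful when
#'   panel tag sets are unbalanced). Default `FALSE` (raw counts).
#' @return An object of class `painting_config`.
#' @export
painting_config <- function(window = 10000L, min_hits = 5L, ratio = 0.75,
                            normalize = FALSE) {
  stopifnot_scalar_count(window, "window", 1)
  stopifnot_scalar_count(min_hits, "min_hits", 0)
  if (ratio <= 0.5 || ratio > 1) abort("`ratio` must be in (0.5, 1]")
  structure(
    list(window = as.integer(window), min_hits = min_hits, ratio = ratio,
         normalize = isTRUE(normalize)),
    class = "painting_config"
  )
}

#' Count tag hits in fixed windows along chromosomes
#'
#' Tiles each chromosome with `cfg$window`-sized windows (the last window
#' of a chromosome may be shorter) and counts each hit in exactly one
#' window by its start coordinate. All groups present in `hits` (plus any
#' in `groups`) get a count column in every window, zero-filled.
#'
#' @param hits Tag hit tibble from [match_tags()].
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param cfg A [painting_config()].
#' @param groups Optional character vector of group labels to force columns
#'   for, even when unhit.
#' @return Tibble with columns `chrom`, `start`, `end`, one count column
#'   per group, and `total`.
#' @export
count_window_hits <- function(hits, chrom_lengths, cfg = painting_config(),
                              groups = NULL) {
  if (is.null(names(chrom_lengths))) abort("`chrom_lengths` must be named")
  groups <- sort(union(groups, unique(hits$group)))
  if (length(groups) == 0) abort("no group labels available")
  bad <- hits$start >= chrom_lengths[hits$chrom]
  if (any(is.na(bad)) || any(bad)) abort("hit beyond chromosome end (or unknown chromosome)")
  wins <- purrr::imap(chrom_lengths, function(L, cn) {
    s <- seq(0, L - 1, by = cfg$window)
    tibble(chrom = cn, start = s, end = pmin(s + cfg$window, L))
  }) |> bind_rows()
  counted <- hits |>
    mutate(start = (.data$start %/% cfg$window) * cfg$window) |>
    count(.data$chrom, .data$start, .data$group)
  wide <- counted |>
    tidyr::pivot_wider(names_from = "group", values_from = "n", values_fill = 0)
  for (g in setdiff(groups, names(wide))) wide[[g]] <- 0L
  out <- wins |>
    left_join(wide, by = c("chrom", "start")) |>
    mutate(dplyr::across(dplyr::all_of(groups), ~ tidyr::replace_na(.x, 0L)))
  out$total <- rowSums(out[, groups, drop = FALSE])
  out
}

#' Assign an ancestry label to window counts
#'
#' The dominance rule: a window is labelled with the group of maximal count
#' when the total evidence reaches `min_hits` and the maximal count is at
#' least `ratio` of the total; ties and everything below threshold give
#' `NA` (no origin attributable). With `cfg$normalize`, counts are first
#' divided by each group's total tag count (`tag_totals`).
#'
#' @param windows Window tibble from [count_window_hits()].
#' @param cfg A [painting_config()].
#' @param groups Character vector of the group count columns; defaults to
#'   every column that is not `chrom`/`start`/`end`/`total`.
#' @param tag_totals Named vector of per-group tag counts, required when
#'   `cfg$normalize`.
#' @return The window tibble with an added `label` column (`NA` where no
#'   call is made).
#' @export
assign_ancestry <- function(windows, cfg = painting_config(), groups = NULL,
                            tag_totals = NULL) {
  groups <- groups %||% setdiff(names(windows), c("chrom", "start", "end", "total"))
  counts <- as.matrix(windows[, groups, drop = FALSE])
  total_raw <- rowSums(counts)
  score <- counts
  if (cfg$normalize) {
    if (is.null(tag_totals)) abort("`tag_totals` needed when cfg$normalize")
    score <- sweep(counts, 2, as.numeric(tag_totals[groups]), "/")
  }
  stot <- rowSums(score)
  smax <- apply(score, 1, max)
  n_at_max <- rowSums(score == smax & score > 0)
  top <- groups[max.col(score, ties.method = "first")]
  label <- ifelse(
    total_raw >= cfg$min_hits & stot > 0 & smax / stot >= cfg$ratio &
      n_at_max == 1,
    top, NA_character_
  )
  mutate(windows, label = label)
}

#' Merge labelled windows into maximal ancestry segments
#'
#' Collapses runs of consecutive same-label windows (per chromosome) into
#' segments; the output tiles exactly the windowed extent and adjacent
#' segments always differ in label. `NA` labels form segments of their own
#' (label `NA`).
#'
#' @param windows Labelled window tibble from [assign_ancestry()]; must be
#'   sorted by (chrom, start).
#' @return Tibble with columns `chrom`, `start`, `end`, `label`,
#'   `n_windows`.
#' @export
merge_segments <- function(windows) {
  if (nrow(windows) == 0) {
    return(tibble(chrom = character(0), start = numeric(0), end = numeric(0),
                  label = character(0), n_windows = integer(0)))
  }
  ord <- order(windows$chrom, windows$start)
  if (!identical(ord, seq_len(nrow(windows)))) abort("windows must be sorted by (chrom, start)")
  lab <- ifelse(is.na(windows$label), "\r\rNA", windows$label)
  new_run <- c(TRUE, lab[-1] != lab[-length(lab)] |
                 windows$chrom[-1] != windows$chrom[-nrow(windows)])
  run <- cumsum(new_run)
  windows |>
    mutate(.run = run) |>
    group_by(.data$.run) |>
    summarise(
      chrom = .data$chrom[1], start = min(.data$start), end = max(.data$end),
      label = .data$label[1], n_windows = dplyr::n(), .groups = "drop"
    ) |>
    select("chrom", "start", "end", "label", "n_windows") |>
    arrange(.data$chrom, .data$start)
}

#' Paint an assembly with ancestral origins
#'
#' The full painting pipeline: locate the diagnostic tags on the assembly,
#' count hits in windows, apply the dominance rule, and merge windows into
#' labelled segments. Also reports the fraction of painted bases per label
#' (including `NA`, the unattributable fraction); fractions sum to 1.
#'
#' @param assembly Named character vector of chromosome sequences.
#' @param tags Tag tibble from [discover_tags()].
#' @param tag_cfg A [tag_config()] matching `tags`.
#' @param cfg A [painting_config()].
#' @return A list of class `ancestry_painting` with elements `segments`
#'   (tibble: chrom, start, end, label, n_windows), `windows` (labelled
#'   window tibble), `fractions` (tibble: label, bases, fraction) and
#'   `config`.
#' @export
paint_assembly <- function(assembly, tags, tag_cfg = tag_config(),
                           cfg = painting_config()) {
  hits <- match_tags(assembly, tags, tag_cfg)
  lens <- setNames(nchar(assembly), names(assembly))
  groups <- sort(unique(tags$group))
  windows <- count_window_hits(hits, lens, cfg, groups = groups)
  tag_totals <- table(factor(tags$group, levels = groups))
  windows <- assign_ancestry(windows, cfg, groups = groups,
                             tag_totals = c(tag_totals))
  segments <- merge_segments(windows)
  fractions <- segments |>
    mutate(label = ifelse(is.na(.data$label), "NA", .data$label)) |>
    group_by(.data$label) |>
    summarise(bases = sum(.data$end - .data$start), .groups = "drop") |>
    mutate(fraction = .data$bases / sum(.data$bases)) |>
    arrange(dplyr::desc(.data$fraction))
  structure(
    list(segments = segments, windows = windows, fractions = fractions,
         config = cfg),
    class = "ancestry_painting"
  )
}

#' Compare a painting against a truth tiling
#'
#' Base-level agreement between painted segments and a truth table
#' (both 0-based half-open tilings of the same chromosomes). `NA`-labelled
#' painted bases count as disagreement.
#'
#' @param painting An `ancestry_painting` (or its `segments` tibble).
#' @param truth Truth tibble (chrom, start, end, label).
#' @return One-row tibble: `bases`, `correct`, `accuracy`.
#' @export
painting_accuracy <- function(painting, truth) {
  seg <- if (inherits(painting, "ancestry_painting")) painting$segments else painting
  per_chrom <- lapply(unique(truth$chrom), function(cn) {
    tb <- filter(truth, .data$chrom == cn)
    sb <- filter(seg, .data$chrom == cn)
    cuts <- sort(unique(c(tb$start, tb$end, sb$start, sb$end)))
    s <- cuts[-length(cuts)]
    e <- cuts[-1]
    mid <- (s + e) / 2
    tlab <- tb$label[findInterval(mid, tb$start)]
    slab <- sb$label[findInterval(mid, sb$start)]
    tibble(len = e - s, agree = !is.na(slab) & tlab == slab)
  }) |> bind_rows()
  tibble(
    bases = sum(per_chrom$len),
    correct = sum(per_chrom$len[per_chrom$agree]),
    accuracy = sum(per_chrom$len[per_chrom$agree]) / sum(per_chrom$len)
  )
}
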