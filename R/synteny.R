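#' Pair gene anchors of two assemblies into a hit table
#'
#' Joins two anchor tables on the gene identifier, producing the one
#' best-hit-per-gene table that synteny chaining consumes. With real data
#' the hit table usually comes from an aligner's best hits instead; any
#' tibble with the same columns works.
#'
#' @param anchors_a,anchors_b Anchor tibbles with columns `gene`, `chrom`,
#'   `rank` (order index along the chromosome) and optionally `mid`
#'   (midpoint bp). Side `a` is conventionally the reference.
#' @return Tibble with columns `gene_a`, `chrom_a`, `rank_a`, (`mid_a`),
#'   `gene_b`, `chrom_b`, `rank_b`, (`mid_b`).
#' @export
anchor_hits <- function(anchors_a, anchors_b) {
  for (x in list(anchors_a, anchors_b)) {
    stopifnot(all(c("gene", "chrom", "rank") %in% names(x)))
    if (anyDuplicated(x$gene)) abort("duplicate gene ids within one assembly")
  }
  a <- setNames(anchors_a, paste0(names(anchors_a), "_a"))
  b <- setNames(anchors_b, paste0(names(anchors_b), "_b"))
  inner_join(a, b, by = c(gene_a = "gene_b"), keep = TRUE)
}

# longest collinear chain by dynamic programming over hits on one
# (chrom_a, chrom_b) pair and one orientation; returns indices of the best
# chain (max gene count, leftmost tie-break)
best_chain <- function(rank_a, rank_b, orientation, max_gap) {
  n <- length(rank_a)
  ord <- order(rank_a)
  ra <- rank_a[ord]
  rb <- rank_b[ord]
  best <- rep(1L, n)
  prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      da <- ra[i] - ra[j]
      db <- if (orientation == "+") rb[i] - rb[j] else rb[j] - rb[i]
      if (da >= 1 && da <= max_gap && db >= 1 && db <= max_gap &&
            best[j] + 1L > best[i]) {
        best[i] <- best[j] + 1L
        prev[i] <- j
      }
    }
  }
  end <- which.max(best)
  chain <- integer(0)
  while (end != 0L) {
    chain <- c(end, chain)
    end <- prev[end]
  }
  ord[chain]
}

#' Chain gene hits into collinear synteny blocks
#'
#' Finds maximal collinear chains of gene anchors under a rank-gap limit,
#' separately for parallel (`+`) and antiparallel (`-`) orientation, and
#' extracts non-overlapping chains greedily best-first until no chain
#' reaches `min_block` genes. Every anchor belongs to at most one block;
#' the result is deterministic.
#'
#' @param hits Hit tibble from [anchor_hits()].
#' @param max_gap Maximum rank gap between consecutive anchors of a chain,
#'   in both assemblies (default 10).
#' @param min_block Minimum genes per block (default 5).
#' @return Tibble with one row per block: `block_id`, `chrom_a`, `chrom_b`,
#'   `orientation`, `n_genes`, and `anchors`, a list-column of the block's
#'   hit rows ordered along assembly a.
#' @export
chain_blocks <- function(hits, max_gap = 10L, min_block = 5L) {
  need <- c("gene_a", "chrom_a", "rank_a", "gene_b", "chrom_b", "rank_b")
  stopifnot(all(need %in% names(hits)))
  if (anyDuplicated(hits$gene_a) || anyDuplicated(hits$gene_b)) {
    abort("hits must contain one best hit per gene on both sides")
  }
  blocks <- list()
  remaining <- hits
  repeat {
    if (nrow(remaining) == 0) break
    candidates <- remaining |>
      group_by(.data$chrom_a, .data$chrom_b) |>
      dplyr::group_split()
    found <- NULL
    for (cc in candidates) {
      for (orient in c("+", "-")) {
        idx <- best_chain(cc$rank_a, cc$rank_b, orient, max_gap)
        if (length(idx) >= min_block &&
              (is.null(found) || length(idx) > nrow(found$rows))) {
          found <- list(rows = cc[idx, ], orientation = orient)
        }
      }
    }
    if (is.null(found)) break
    blocks[[length(blocks) + 1L]] <- found
    remaining <- anti_join(remaining, found$rows, by = "gene_a")
  }
  if (length(blocks) == 0) {
    return(tibble(block_id = integer(0), chrom_a = character(0),
                  chrom_b = character(0), orientation = character(0),
                  n_genes = integer(0), anchors = list()))
  }
  tibble(
    block_id = seq_along(blocks),
    chrom_a = vapply(blocks, function(b) as.character(b$rows$chrom_a[1]), character(1)),
    chrom_b = vapply(blocks, function(b) as.character(b$rows$chrom_b[1]), character(1)),
    orientation = vapply(blocks, `[[`, character(1), "orientation"),
    n_genes = vapply(blocks, function(b) nrow(b$rows), integer(1)),
    anchors = lapply(blocks, `[[`, "rows")
  )
}

#' Associate synteny blocks of two assemblies through the reference
#'
#' Two blocks (each computed against the same reference, side `a`) are
#' associated when strictly more than `min_shared` reference genes occur in
#' both. With the default 20 this is the "more than 20 shared genes" rule;
#' block pairs sharing exactly 20 genes are not associated. Orientation is
#' ignored; only the shared-gene count matters. Association is reported
#' per block pair, never closed transitively.
#'
#' @param blocks_x,blocks_y Block tibbles from [chain_blocks()], both with
#'   the reference on side `a`.
#' @param min_shared Association threshold; shared count must exceed it.
#' @return Tibble: `block_x`, `block_y`, `shared`.
#' @export
associate_blocks <- function(blocks_x, blocks_y, min_shared = 20L) {
  gx <- lapply(blocks_x$anchors, function(a) a$gene_a)
  gy <- lapply(blocks_y$anchors, function(a) a$gene_a)
  out <- list()
  for (i in seq_along(gx)) {
    for (j in seq_along(gy)) {
      shared <- length(intersect(gx[[i]], gy[[j]]))
      if (shared > min_shared) {
        out[[length(out) + 1L]] <- tibble(
          block_x = blocks_x$block_id[i], block_y = blocks_y$block_id[j],
          shared = shared
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(block_x = integer(0), block_y = integer(0), shared = integer(0)))
  }
  bind_rows(out)
}

#' Build ortholog groups across assemblies from associated blocks
#'
#' One candidate group per reference gene found in a synteny block of at
#' least one assembly: the group's members are the genes paired with the
#' reference gene in each assembly's block, and the group is kept only when
#' the blocks of all its member assemblies are mutually associated (the
#' more-than-`min_shared`-shared-genes rule for every pair). With
#' `complete = TRUE`, groups must have a member in every assembly.
#'
#' @param block_sets Named list: assembly -> block tibble from
#'   [chain_blocks()] (reference on side `a` in every table).
#' @param min_shared Association threshold passed to [associate_blocks()].
#' @param complete Require a member in every assembly (default `FALSE`).
#' @return Tibble with `ref_gene` and one member-gene column per assembly
#'   (`NA` where absent).
#' @export
build_ortholog_groups <- function(block_sets, min_shared = 20L,
                                  complete = FALSE) {
  stopifnot(is.list(block_sets), !is.null(names(block_sets)))
  asms <- names(block_sets)
  # per assembly: reference gene -> (member gene, block id)
  maps <- lapply(block_sets, function(blocks) {
    if (nrow(blocks) == 0) {
      return(tibble(ref_gene = character(0), member = character(0),
                    block_id = integer(0)))
    }
    purrr::map2(blocks$anchors, blocks$block_id, function(a, id) {
      tibble(ref_gene = a$gene_a, member = a$gene_b, block_id = id)
    }) |> bind_rows()
  })
  dup_dropped <- character(0)
  for (i in seq_along(maps)) {
    dup <- unique(maps[[i]]$ref_gene[duplicated(maps[[i]]$ref_gene)])
    if (length(dup) > 0) {
      dup_dropped <- union(dup_dropped, dup)
      maps[[i]] <- filter(maps[[i]], !.data$ref_gene %in% dup)
    }
  }
  if (length(dup_dropped) > 0) {
    warn(sprintf("%d reference gene(s) with conflicting members dropped",
                 length(dup_dropped)))
  }
  assoc <- list()
  for (i in seq_along(asms)) {
    for (j in seq_along(asms)) {
      if (i < j) {
        assoc[[paste(asms[i], asms[j])]] <-
          associate_blocks(block_sets[[asms[i]]], block_sets[[asms[j]]],
                           min_shared = min_shared)
      }
    }
  }
  ref_genes <- sort(unique(unlist(lapply(maps, `[[`, "ref_gene"))))
  ref_genes <- setdiff(ref_genes, dup_dropped)
  rows <- lapply(ref_genes, function(g) {
    present <- purrr::map(maps, ~ filter(.x, .data$ref_gene == g))
    has <- vapply(present, nrow, integer(1)) == 1
    if (complete && !all(has)) return(NULL)
    if (!any(has)) return(NULL)
    idx <- which(has)
    for (i in idx) {
      for (j in idx) {
        if (i < j) {
          a <- assoc[[paste(asms[i], asms[j])]]
          ok <- any(a$block_x == present[[i]]$block_id &
                      a$block_y == present[[j]]$block_id)
          if (!ok) return(NULL)
        }
      }
    }
    members <- setNames(rep(NA_character_, length(asms)), asms)
    members[idx] <- vapply(present[idx], function(x) as.character(x$member), character(1))
    c(list(ref_gene = g), as.list(members))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    out <- tibble(ref_gene = character(0))
    for (a in asms) out[[a]] <- character(0)
    return(out)
  }
  bind_rows(lapply(rows, as_tibble))
}

#' Filter ortholog groups by the ancestry of the focal member
#'
#' Keeps only groups whose member in the focal assembly lies (by gene
#' midpoint, half-open interval membership) in an ancestry segment carrying
#' the target label — e.g. restricting to genes in regions assigned to an
#' unknown ancestor. Groups without a focal member are dropped.
#'
#' @param groups Group tibble from [build_ortholog_groups()].
#' @param focal Name of the focal assembly (a member column of `groups`).
#' @param anchors Anchor tibble of the focal assembly: `gene`, `chrom`,
#'   `mid`.
#' @param segments Ancestry segments tiling the focal assembly: `chrom`,
#'   `start`, `end`, `label`.
#' @param label Target ancestry label.
#' @return The retained subset of `groups`.
#' @export
filter_groups_by_ancestry <- function(groups, focal, anchors, segments, label) {
  if (!focal %in% names(groups)) abort(sprintf("no member column `%s`", focal))
  stopifnot(all(c("gene", "chrom", "mid") %in% names(anchors)))
  target <- filter(segments, !is.na(.data$label) & .data$label == !!label)
  g <- filter(groups, !is.na(.data[[focal]]))
  if (nrow(target) == 0 || nrow(g) == 0) return(g[0, ])
  pos <- anchors[match(g[[focal]], anchors$gene), ]
  keep <- vapply(seq_len(nrow(g)), function(i) {
    if (is.na(pos$gene[i])) return(FALSE)
    any(target$chrom == pos$chrom[i] & target$start <= pos$mid[i] &
          pos$mid[i] < target$end)
  }, logical(1))
  g[keep, ]
}

#' Dot-plot points from a best-hit table
#'
#' One point per best hit at (reference position, target position), grouped
#' by chromosome pair; identical assemblies give diagonal runs, inverted
#' segments anti-diagonal runs.
#'
#' @param hits Hit tibble from [anchor_hits()] with `mid_a` and `mid_b`.
#' @return Tibble of class `dotplot_data`: `chrom_a`, `chrom_b`, `x`, `y`,
#'   `gene_a`, `gene_b`.
#' @export
dotplot_data <- function(hits) {
  stopifnot(all(c("mid_a", "mid_b") %in% names(hits)))
  out <- hits |>
    dplyr::transmute(
      chrom_a = .data$chrom_a, chrom_b = .data$chrom_b,
      x = .data$mid_a, y = .data$mid_b,
      gene_a = .data$gene_a, gene_b = .data$gene_b
    ) |>
    arrange(.data$chrom_a, .data$x)
  class(out) <- c("dotplot_data", class(out))
  out
}
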