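#' Jukes-Cantor distance matrix from aligned sequences
#'
#' Pairwise JC69 distances `d = -(3/4) log(1 - 4p/3)` on a single
#' alignment, or on the concatenation of several gene alignments sharing a
#' taxon set. Pairs whose raw mismatch proportion reaches 3/4 are
#' saturated: their entry is `NA` with a warning.
#'
#' @param alignments Named character vector (taxon -> aligned sequence), or
#'   a list of such vectors (one per gene, equal taxon sets).
#' @param concatenate When `alignments` is a list: concatenate genes before
#'   computing (default `TRUE`); otherwise a list of per-gene matrices is
#'   returned.
#' @return Symmetric numeric matrix with zero diagonal (or a list of
#'   matrices).
#' @export
jc_distance_matrix <- function(alignments, concatenate = TRUE) {
  if (is.list(alignments) && !concatenate) {
    return(lapply(alignments, jc_distance_matrix))
  }
  if (is.list(alignments)) {
    taxa <- names(alignments[[1]])
    alignments <- vapply(taxa, function(tx) {
      paste(vapply(alignments, `[[`, character(1), tx), collapse = "")
    }, character(1))
  }
  taxa <- names(alignments)
  if (length(taxa) < 2) abort("need at least 2 taxa")
  if (length(unique(nchar(alignments))) != 1) abort("sequences must be aligned (equal length)")
  mat <- do.call(rbind, strsplit(toupper(alignments), ""))
  n <- length(taxa)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  sat <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- mat[i, ] %in% DNA_BASES & mat[j, ] %in% DNA_BASES
      p <- mean(mat[i, ok] != mat[j, ok])
      if (p >= 3 / 4) {
        d[i, j] <- d[j, i] <- NA_real_
        sat <- TRUE
      } else {
        d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 * p / 3)
      }
    }
  }
  if (sat) warn("saturated pair(s): distance undefined (p >= 3/4)")
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining (Saitou & Nei 1987) on a symmetric distance
#' matrix; on additive matrices the generating topology and branch lengths
#' are recovered exactly. Internal branches of length ~0 are collapsed
#' into polytomies, so an all-zero matrix yields a star tree.
#'
#' @param d Symmetric numeric matrix with taxon dimnames, >= 3 taxa.
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) abort("need at least 3 taxa")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) abort("matrix must be symmetric")
  if (anyNA(d)) abort("distance matrix contains NA (saturated pairs?)")
  tr <- ape::nj(as.dist(d))
  tr$edge.length[tr$edge.length < 0 & tr$edge.length > -1e-12] <- 0
  ape::di2multi(tr, tol = 1e-10)
}

# --- bipartition machinery -------------------------------------------------

# tip-label sets below each edge of a tree, by postorder accumulation
edge_tip_sets <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  sets <- vector("list", max(tree$edge))
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  for (i in seq_len(nrow(tree$edge))) {
    par <- tree$edge[i, 1]
    chi <- tree$edge[i, 2]
    sets[[par]] <- c(sets[[par]], sets[[chi]])
  }
  list(tree = tree, sets = sets)
}

# canonical key of a bipartition side over taxon set `taxa`: the sorted
# side that does not contain the smallest taxon (empty key = trivial/full)
split_key <- function(side, taxa) {
  ref <- min(taxa)
  if (ref %in% side) side <- setdiff(taxa, side)
  paste(sort(side), collapse = ",")
}

#' Bipartitions (splits) of a tree
#'
#' Returns the non-trivial bipartitions of the (unrooted) tree: for each
#' internal branch, the two tip sets it separates.
#'
#' @param tree An [ape::phylo] object (rooted trees are unrooted first).
#' @param trivial Include trivial splits (single-tip sides)? Default
#'   `FALSE`.
#' @return Tibble with columns `key` (canonical split id), `side` (list
#'   column: tips of the side not containing the alphabetically first
#'   taxon), `size` (tips on that side).
#' @export
tree_bipartitions <- function(tree, trivial = FALSE) {
  taxa <- tree$tip.label
  tree <- ape::unroot(tree)
  ets <- edge_tip_sets(tree)
  ntip <- length(taxa)
  sides <- list()
  for (i in seq_len(nrow(ets$tree$edge))) {
    chi <- ets$tree$edge[i, 2]
    side <- ets$sets[[chi]]
    if (!trivial && (length(side) <= 1 || length(side) >= ntip - 1)) next
    if (trivial && length(side) >= ntip) next
    canon <- setdiff(taxa, side)
    if (min(taxa) %in% side) side <- canon
    sides[[split_key(side, taxa)]] <- sort(side)
  }
  if (length(sides) == 0) {
    return(tibble(key = character(0), side = list(), size = integer(0)))
  }
  tibble(
    key = names(sides),
    side = unname(sides),
    size = lengths(sides)
  ) |> distinct(.data$key, .keep_all = TRUE)
}

#' Gene-tree support for the branches of a global tree
#'
#' For each internal branch (bipartition) of the global tree, the
#' proportion of gene trees that contain that bipartition, among the gene
#' trees in which it is evaluable. Comparison is unrooted. A gene tree
#' covering only a subset of the taxa is used after restricting the
#' bipartition to its taxa; it is evaluable only when both restricted
#' sides keep at least two taxa (a restricted bipartition with a
#' single-taxon side is trivial — present in every tree — so such gene
#' trees carry no signal and are excluded from the denominator).
#' Polytomies in a gene tree support none of the resolved bipartitions
#' they collapse.
#'
#' @param global_tree The species tree ([ape::phylo]).
#' @param gene_trees A list of gene trees (or an `ape::multiPhylo`), taxa
#'   equal to or subsets of the global tree's.
#' @return A tibble of class `support_table`: `key`, `side` (list column),
#'   `n_support`, `n_evaluable`, `support`.
#' @export
branch_support <- function(global_tree, gene_trees) {
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  if (length(gene_trees) == 0) abort("zero gene trees")
  taxa <- sort(global_tree$tip.label)
  glob <- tree_bipartitions(global_tree)
  gene_splits <- lapply(gene_trees, function(gt) {
    gtaxa <- sort(gt$tip.label)
    bp <- tree_bipartitions(gt)
    keys <- vapply(bp$side, split_key, character(1), taxa = gtaxa)
    list(taxa = gtaxa, keys = keys)
  })
  n_sup <- integer(nrow(glob))
  n_eval <- integer(nrow(glob))
  for (g in gene_splits) {
    for (i in seq_len(nrow(glob))) {
      a <- intersect(glob$side[[i]], g$taxa)
      b <- intersect(setdiff(taxa, glob$side[[i]]), g$taxa)
      if (length(a) < 2 || length(b) < 2) next # trivial after restriction
      n_eval[i] <- n_eval[i] + 1L
      if (split_key(a, g$taxa) %in% g$keys) n_sup[i] <- n_sup[i] + 1L
    }
  }
  out <- glob |>
    mutate(n_support = n_sup, n_evaluable = n_eval,
           support = ifelse(n_eval > 0, n_sup / n_eval, NA_real_)) |>
    select("key", "side", "n_support", "n_evaluable", "support")
  class(out) <- c("support_table", class(out))
  out
}

#' Annotate a tree's internal nodes with gene-tree support
#'
#' @param global_tree The species tree given to [branch_support()].
#' @param support The resulting support table.
#' @param digits Rounding for node labels.
#' @return The tree with `node.label` set to support proportions (empty
#'   where no internal branch / not evaluated).
#' @export
annotate_support <- function(global_tree, support, digits = 2) {
  ets <- edge_tip_sets(ape::unroot(global_tree))
  tree <- ets$tree
  ntip <- length(tree$tip.label)
  taxa <- sort(tree$tip.label)
  labels <- rep("", tree$Nnode)
  for (i in seq_len(nrow(tree$edge))) {
    chi <- tree$edge[i, 2]
    if (chi <= ntip) next
    key <- split_key(ets$sets[[chi]], taxa)
    m <- match(key, support$key)
    if (!is.na(m)) labels[chi - ntip] <- as.character(round(support$support[m], digits))
  }
  tree$node.label <- labels
  tree
}

#' Gene-tree support for alternative placements of one taxon
#'
#' Tests where a focal taxon attaches: candidates are the branches of the
#' global tree with the focal taxon removed. For each gene tree, the focal
#' taxon's attachment — the bipartition of the remaining taxa induced by
#' its attachment edge (its smallest non-trivial split) — is matched
#' against the candidate branches restricted to the gene tree's taxa.
#' Attachments matching no candidate (or several, after restriction) are
#' counted as `other`; proportions over evaluable gene trees sum to 1.
#'
#' @param global_tree The species tree containing the focal taxon.
#' @param focal The focal taxon label.
#' @param gene_trees List of gene trees.
#' @return Tibble: `candidate` (canonical split of the pruned global tree;
#'   `other` for unmatched), `is_global` (the focal taxon's placement in
#'   the global tree), `n_support`, `n_evaluable`, `proportion`.
#' @export
placement_support <- function(global_tree, focal, gene_trees) {
  if (!focal %in% global_tree$tip.label) abort("focal taxon absent from global tree")
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  pruned <- ape::drop.tip(ape::unroot(global_tree), focal)
  ptaxa <- sort(pruned$tip.label)
  cand <- tree_bipartitions(pruned, trivial = TRUE)

  attachment_side <- function(tree, focal_taxon) {
    # smallest non-trivial split side containing the focal taxon
    taxa <- sort(tree$tip.label)
    bp <- tree_bipartitions(ape::unroot(tree), trivial = TRUE)
    sides <- lapply(bp$side, function(s) {
      if (focal_taxon %in% s) s else setdiff(taxa, s)
    })
    sizes <- lengths(sides)
    sides <- sides[sizes >= 2 & sizes < length(taxa)]
    if (length(sides) == 0) return(NULL)
    sides[[which.min(lengths(sides))]]
  }

  glob_att <- attachment_side(global_tree, focal)
  glob_key <- split_key(setdiff(glob_att, focal), ptaxa)

  n_eval <- 0L
  counts <- setNames(rep(0L, nrow(cand) + 1L), c(cand$key, "other"))
  for (gt in gene_trees) {
    if (!focal %in% gt$tip.label) next
    shared <- intersect(gt$tip.label, ptaxa)
    if (length(shared) < 2) next
    gt_res <- ape::keep.tip(gt, c(focal, shared))
    att <- attachment_side(gt_res, focal)
    if (is.null(att)) next
    n_eval <- n_eval + 1L
    a <- setdiff(att, focal)
    att_key <- split_key(a, shared)
    matches <- vapply(cand$side, function(s) {
      sa <- intersect(s, shared)
      sb <- intersect(setdiff(ptaxa, s), shared)
      if (length(sa) == 0 || length(sb) == 0) return(FALSE)
      split_key(sa, shared) == att_key
    }, logical(1))
    if (sum(matches) == 1) {
      counts[cand$key[matches]] <- counts[cand$key[matches]] + 1L
    } else {
      counts["other"] <- counts["other"] + 1L
    }
  }
  if (n_eval == 0) abort("no evaluable gene tree for the focal taxon")
  tibble(
    candidate = names(counts),
    is_global = names(counts) == glob_key,
    n_support = as.integer(counts),
    n_evaluable = n_eval,
    proportion = as.integer(counts) / n_eval
  )
}
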