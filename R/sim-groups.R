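#' Specification of an ancestral group phylogeny
#'
#' Describes the clock-like divergence of several ancestral groups:
#' a rooted tree whose branch lengths are in years, a per-year per-site
#' substitution rate, and the length of the simulated sequence. The default
#' rate, 4.5e-9 substitutions per synonymous site per year, is the average
#' synonymous substitution rate estimated in Musaceae.
#'
#' @param tree A rooted tree: either an [ape::phylo] object or a newick
#'   string. Tip labels are the group names; branch lengths are years.
#' @param rate Substitution rate per site per year (> 0).
#' @param length Sequence length in bases (> 0; multiple of 3 when
#'   `codon_structured`).
#' @param n_per_group Number of panel sequences simulated per group.
#' @param within_group_years Additional within-group divergence time (years)
#'   separating the panel sequences of one group from the group's common
#'   sequence.
#' @param codon_structured If `TRUE`, the root sequence is built from sense
#'   codons and mutations creating stop codons are rejected.
#' @param seed Integer seed; the simulation is a pure function of
#'   (spec, seed).
#' @return An object of class `group_phylogeny_spec`.
#' @export
#' @examples
#' sp <- group_phylogeny_spec("((A:1e6,B:1e6):1e6,C:2e6);", length = 1000)
group_phylogeny_spec <- function(tree, rate = 4.5e-9, length = 100000,
                                 n_per_group = 2, within_group_years = 1e5,
                                 codon_structured = FALSE, seed = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!inherits(tree, "phylo")) abort("`tree` must be a phylo object or newick string")
  if (is.null(tree$edge.length)) abort("`tree` must have branch lengths (years)")
  if (any(tree$edge.length < 0)) abort("branch lengths must be >= 0")
  if (length(tree$tip.label) < 2) abort("at least 2 groups are required")
  if (!ape::is.rooted(tree)) abort("`tree` must be rooted")
  if (rate <= 0) abort("`rate` must be > 0")
  stopifnot_scalar_count(length, "length", 1)
  if (codon_structured && length %% 3 != 0) {
    abort("`length` must be a multiple of 3 when codon_structured")
  }
  stopifnot_scalar_count(n_per_group, "n_per_group", 1)
  if (within_group_years < 0) abort("`within_group_years` must be >= 0")
  structure(
    list(
      tree = tree, groups = tree$tip.label, rate = rate,
      length = as.integer(length), n_per_group = as.integer(n_per_group),
      within_group_years = within_group_years,
      codon_structured = isTRUE(codon_structured), seed = as.integer(seed)
    ),
    class = "group_phylogeny_spec"
  )
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_root_bases <- function(length, codon_structured) {
  if (!codon_structured) {
    return(sample(DNA_BASES, length, replace = TRUE))
  }
  codons <- all_codons()
  sense <- codons[!codons %in% STOP_CODONS]
  picked <- sample(sense, length / 3, replace = TRUE)
  unlist(strsplit(picked, ""), use.names = FALSE)
}

all_codons <- function() {
  g <- expand.grid(p3 = DNA_BASES, p2 = DNA_BASES, p1 = DNA_BASES,
    stringsAsFactors = FALSE
  )
  sort(paste0(g$p1, g$p2, g$p3))
}

# Jukes-Cantor mutation process on a base vector: `nmut` substitution events
# at uniform positions, each replacing the current base by one of the other
# three. Multiple hits at one position are applied sequentially, so back
# mutation happens at the JC rate. When codon_structured, events that would
# create a stop codon pick among the non-stop alternatives, or are dropped
# when none exists (selection removes them).
mutate_jc <- function(bases, nmut, codon_structured = FALSE) {
  if (nmut == 0) return(bases)
  L <- length(bases)
  pos <- sample.int(L, nmut, replace = TRUE)
  for (i in seq_len(nmut)) {
    p <- pos[i]
    alts <- DNA_BASES[DNA_BASES != bases[p]]
    if (codon_structured) {
      c0 <- p - (p - 1L) %% 3L
      cod <- bases[c0:(c0 + 2L)]
      off <- p - c0 + 1L
      ok <- vapply(alts, function(a) {
        cod2 <- cod
        cod2[off] <- a
        !(paste(cod2, collapse = "") %in% STOP_CODONS)
      }, logical(1))
      alts <- alts[ok]
      if (length(alts) == 0) next
    }
    bases[p] <- alts[sample.int(length(alts), 1L)]
  }
  bases
}

#' Simulate diverged ancestral group panels
#'
#' Evolves a random root sequence along a rooted, clock-like tree under a
#' Jukes-Cantor single-nucleotide process, then derives `n_per_group` panel
#' sequences per group by adding a small amount of within-group divergence.
#' The expected number of substitutions separating two sister tips whose
#' branches are `b` years long is `2 * b * rate` per site.
#'
#' @param spec A [group_phylogeny_spec()].
#' @return A list of class `ancestry_panel_sim` with elements `panels`
#'   (named list: group -> named character vector of panel sequences),
#'   `group_seqs` (one sequence per group, the group's common ancestor of
#'   the panel), `root` (root sequence), `tree` (the input tree) and `spec`.
#' @export
#' @examples
#' sp <- group_phylogeny_spec("(A:1e6,B:1e6);", length = 3000, seed = 7)
#' sim <- simulate_ancestral_groups(sp)
#' names(sim$panels)
simulate_ancestral_groups <- function(spec) {
  stopifnot(inherits(spec, "group_phylogeny_spec"))
  with_seed(spec$seed, {
    tree <- ape::reorder.phylo(spec$tree, "cladewise")
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    node_seq <- vector("list", max(tree$edge))
    node_seq[[root]] <- random_root_bases(spec$length, spec$codon_structured)
    for (i in seq_len(nrow(tree$edge))) {
      par <- tree$edge[i, 1]
      chi <- tree$edge[i, 2]
      d <- tree$edge.length[i] * spec$rate
      nmut <- rpois(1, d * spec$length)
      node_seq[[chi]] <- mutate_jc(node_seq[[par]], nmut, spec$codon_structured)
    }
    group_bases <- node_seq[seq_len(ntip)]
    names(group_bases) <- tree$tip.label
    d_within <- spec$within_group_years * spec$rate
    panels <- lapply(tree$tip.label, function(g) {
      seqs <- vapply(seq_len(spec$n_per_group), function(j) {
        nmut <- rpois(1, d_within * spec$length)
        paste(mutate_jc(group_bases[[g]], nmut, spec$codon_structured),
          collapse = ""
        )
      }, character(1))
      setNames(seqs, paste0(g, "_", seq_len(spec$n_per_group)))
    })
    names(panels) <- tree$tip.label
    structure(
      list(
        panels = panels,
        group_seqs = vapply(group_bases, paste, character(1), collapse = ""),
        root = paste(node_seq[[root]], collapse = ""),
        tree = spec$tree, spec = spec
      ),
      class = "ancestry_panel_sim"
    )
  })
}
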