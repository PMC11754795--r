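#' Simulate a diploid child from two diploid parents
#'
#' Each child haplotype is a gamete of one parent: a mosaic of the parent's
#' two haplotypes with crossovers placed uniformly at random (Poisson number
#' per chromosome) or at explicitly given positions. The phase truth records
#' the parental haplotype of origin of every base, 0-based half-open.
#'
#' @param parent1,parent2 Each a list of two named character vectors (the
#'   parent's haplotypes); both parents must carry the same chromosome
#'   names with equal lengths per haplotype.
#' @param crossovers Either a single number, the expected crossover count
#'   per chromosome per gamete (Poisson), or a named list
#'   chromosome -> numeric vector of crossover positions used for both
#'   gametes.
#' @param seed Integer seed.
#' @return A list of class `trio_sim` with `child` (list `h1`, `h2` of
#'   named character vectors; `h1` comes from parent1) and `phase`, a
#'   tibble with columns `haplotype`, `chrom`, `start`, `end`,
#'   `parent`, `parent_hap`.
#' @export
simulate_trio <- function(parent1, parent2, crossovers = 1, seed = 1L) {
  check_diploid <- function(p, who) {
    if (!is.list(p) || length(p) != 2) abort(sprintf("%s must be a list of 2 haplotypes", who))
    if (!identical(sort(names(p[[1]])), sort(names(p[[2]])))) {
      abort(sprintf("%s haplotypes carry different chromosome sets", who))
    }
  }
  check_diploid(parent1, "parent1")
  check_diploid(parent2, "parent2")
  if (!identical(sort(names(parent1[[1]])), sort(names(parent2[[1]])))) {
    abort("parents carry different chromosome sets")
  }
  chroms <- names(parent1[[1]])

  make_gamete <- function(parent, parent_name) {
    seqs <- character(length(chroms))
    names(seqs) <- chroms
    phase <- list()
    for (cn in chroms) {
      L <- nchar(parent[[1]][[cn]])
      xo <- if (is.list(crossovers)) {
        sort(crossovers[[cn]] %||% numeric(0))
      } else {
        sort(runif(rpois(1, crossovers), min = 1, max = L - 1))
      }
      xo <- unique(floor(xo))
      bounds <- c(0, xo, L)
      hap <- sample(1:2, 1)
      pieces <- character(length(bounds) - 1)
      for (j in seq_len(length(bounds) - 1)) {
        h <- if (j %% 2 == 1) hap else 3 - hap
        pieces[j] <- substr(parent[[h]][[cn]], bounds[j] + 1, bounds[j + 1])
        phase[[length(phase) + 1]] <- tibble(
          chrom = cn, start = bounds[j], end = bounds[j + 1],
          parent = parent_name, parent_hap = h
        )
      }
      seqs[[cn]] <- paste(pieces, collapse = "")
    }
    list(seq = seqs, phase = bind_rows(phase))
  }

  with_seed(seed, {
    g1 <- make_gamete(parent1, "parent1")
    g2 <- make_gamete(parent2, "parent2")
    phase <- bind_rows(
      mutate(g1$phase, haplotype = "h1"),
      mutate(g2$phase, haplotype = "h2")
    ) |>
      select("haplotype", "chrom", "start", "end", "parent", "parent_hap")
    structure(
      list(child = list(h1 = g1$seq, h2 = g2$seq), phase = phase),
      class = "trio_sim"
    )
  })
}

#' Split chromosomes into consecutive contigs
#'
#' Utility for emulating a fragmented (contig-level) assembly from
#' chromosome sequences, with a truth table of contig origins.
#'
#' @param seqs Named character vector of chromosome sequences.
#' @param size Target contig size in bp; the last contig of a chromosome
#'   may be shorter.
#' @param prefix Contig name prefix.
#' @return List with `contigs` (named character vector) and `origin`
#'   (tibble: contig, chrom, start, end).
#' @export
fragment_contigs <- function(seqs, size, prefix = "ctg") {
  stopifnot_scalar_count(size, "size", 1)
  out <- list()
  k <- 0L
  for (cn in names(seqs)) {
    L <- nchar(seqs[[cn]])
    starts <- seq(0L, L - 1L, by = size)
    for (s in starts) {
      k <- k + 1L
      e <- min(s + size, L)
      out[[k]] <- tibble(
        contig = sprintf("%s%04d", prefix, k), chrom = cn,
        start = s, end = e, seq = substr(seqs[[cn]], s + 1, e)
      )
    }
  }
  tab <- bind_rows(out)
  list(
    contigs = setNames(tab$seq, tab$contig),
    origin = select(tab, "contig", "chrom", "start", "end")
  )
}
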