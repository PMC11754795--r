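#' Simulate diverged ortholog codon-alignment pairs
#'
#' For each gene, draws a random ancestral coding sequence from sense
#' codons and evolves two descendant copies independently for `t_years`
#' each, so the pair's synonymous sites diverge with expectation
#' `2 * t_years * rate` substitutions per synonymous site. Mutation events
#' hit uniform positions; events creating stop codons are rejected;
#' nonsynonymous events are accepted with probability
#' `nonsyn_rate / rate` (0 by default, i.e. substitutions are placed only
#' at synonymous positions). The output pairs are gapless codon alignments
#' ready for [ng86()].
#'
#' @param t_years Divergence time of the pair's common ancestor, in years
#'   (>= 0). The two lineages each evolve for `t_years`.
#' @param rate Synonymous substitution rate per site per year (> 0);
#'   default the Musaceae estimate 4.5e-9.
#' @param n_genes Number of gene pairs (>= 1).
#' @param codons_per_gene Codons per gene (>= 1).
#' @param nonsyn_rate Nonsynonymous substitution rate per site per year
#'   (0 <= nonsyn_rate <= rate).
#' @param seed Integer seed; output is a pure function of the arguments.
#' @return Tibble with columns `gene`, `seq1`, `seq2`.
#' @export
#' @examples
#' pairs <- sample_gene_pairs(7.8e6, n_genes = 5, codons_per_gene = 50)
#' ng86(pairs$seq1, pairs$seq2, pairs$gene)
sample_gene_pairs <- function(t_years, rate = 4.5e-9, n_genes = 500,
                              codons_per_gene = 300, nonsyn_rate = 0,
                              seed = 1L) {
  if (t_years < 0) abort("`t_years` must be >= 0")
  if (rate <= 0) abort("`rate` must be > 0")
  if (nonsyn_rate < 0 || nonsyn_rate > rate) {
    abort("`nonsyn_rate` must be in [0, rate]")
  }
  stopifnot_scalar_count(n_genes, "n_genes", 1)
  stopifnot_scalar_count(codons_per_gene, "codons_per_gene", 1)
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  L <- 3L * as.integer(codons_per_gene)
  d <- t_years * rate # expected syn substitutions per syn site per lineage
  p_nonsyn <- nonsyn_rate / rate

  # Candidate mutations arrive at rate `rate` per specific single-nucleotide
  # change (3 per position, hence 3*d*L candidates in expectation). A
  # candidate is accepted with probability 1/(3 - n_stop) for a synonymous
  # change -- where n_stop is the number of stop-codon neighbours at that
  # position -- so the realised synonymous substitution rate per
  # Nei-Gojobori-counted synonymous site (which uses the stop-reduced
  # denominator) is exactly `rate`. Stop-creating candidates are rejected;
  # nonsynonymous candidates are scaled by nonsyn_rate/rate on top.
  evolve <- function(bases) {
    nmut <- rpois(1, 3 * d * L)
    if (nmut == 0) return(bases)
    pos <- sample.int(L, nmut, replace = TRUE)
    for (i in seq_len(nmut)) {
      p <- pos[i]
      alts <- DNA_BASES[DNA_BASES != bases[p]]
      newb <- alts[sample.int(3L, 1L)]
      c0 <- p - (p - 1L) %% 3L
      cod <- bases[c0:(c0 + 2L)]
      off <- p - c0 + 1L
      cod2 <- cod
      cod2[off] <- newb
      aa2 <- code[[paste(cod2, collapse = "")]]
      if (aa2 == "*") next
      n_stop <- sum(vapply(alts, function(a) {
        cx <- cod
        cx[off] <- a
        code[[paste(cx, collapse = "")]] == "*"
      }, logical(1)))
      aa1 <- code[[paste(cod, collapse = "")]]
      p_accept <- if (aa1 == aa2) 1 / (3 - n_stop) else p_nonsyn / (3 - n_stop)
      if (runif(1) < p_accept) bases[p] <- newb
    }
    bases
  }

  with_seed(seed, {
    rows <- lapply(seq_len(n_genes), function(g) {
      anc <- unlist(strsplit(sample(sense, codons_per_gene, replace = TRUE), ""),
        use.names = FALSE
      )
      tibble(
        gene = sprintf("g%04d", g),
        seq1 = paste(evolve(anc), collapse = ""),
        seq2 = paste(evolve(anc), collapse = "")
      )
    })
    bind_rows(rows)
  })
}
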