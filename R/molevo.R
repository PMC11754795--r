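#' Synonymous site count of a codon (Nei-Gojobori 1986)
#'
#' For each codon position, the fraction of single-nucleotide changes that
#' are synonymous, with changes to stop codons excluded from both numerator
#' and denominator (the denominator is reduced accordingly). The codon's
#' synonymous site count is the sum over its three positions; synonymous
#' plus nonsynonymous sites always total 3.
#'
#' @param codon Character vector of codons over {A,C,G,T}; stop codons are
#'   an error.
#' @param code Genetic code: named character vector codon -> amino acid,
#'   default the standard nuclear code.
#' @return Numeric vector of synonymous site counts in `[0, 3]`.
#' @export
#' @examples
#' codon_sites(c("GGG", "AAA", "ATG")) # 1, 1/3, 0
codon_sites <- function(codon, code = Biostrings::GENETIC_CODE) {
  tab <- syn_sites_table(code)
  bad <- !codon %in% names(tab)
  if (any(bad)) {
    abort(sprintf("invalid or stop codon: %s", paste(unique(codon[bad]), collapse = ", ")))
  }
  unname(tab[codon])
}

# memoised per-code lookup of synonymous site counts for all sense codons
syn_sites_env <- new.env(parent = emptyenv())

syn_sites_table <- function(code = Biostrings::GENETIC_CODE) {
  key <- paste(code, collapse = "")
  if (!is.null(syn_sites_env[[key]])) return(syn_sites_env[[key]])
  codons <- names(code)[code != "*"]
  tab <- vapply(codons, function(cod) {
    bases <- strsplit(cod, "")[[1]]
    aa <- code[[cod]]
    s <- 0
    for (p in 1:3) {
      nb <- vapply(DNA_BASES[DNA_BASES != bases[p]], function(b) {
        x <- bases
        x[p] <- b
        paste(x, collapse = "")
      }, character(1))
      nb_aa <- code[nb]
      keep <- nb_aa != "*"
      if (any(keep)) s <- s + sum(nb_aa[keep] == aa) / sum(keep)
    }
    s
  }, numeric(1))
  syn_sites_env[[key]] <- tab
  tab
}

# Average synonymous/nonsynonymous difference counts between two codons,
# over all orderings of the single-nucleotide steps, excluding pathways
# whose intermediate codons are stops. If every pathway passes through a
# stop, all pathways are used (endpoints are always sense codons).
# Memoised; returns c(sd, nd).
codon_diff_env <- new.env(parent = emptyenv())

codon_path_diffs <- function(c1, c2, code = Biostrings::GENETIC_CODE) {
  key <- paste(c1, c2, paste(code, collapse = ""), sep = "|")
  if (!is.null(codon_diff_env[[key]])) return(codon_diff_env[[key]])
  b1 <- strsplit(c1, "")[[1]]
  b2 <- strsplit(c2, "")[[1]]
  pos <- which(b1 != b2)
  d <- length(pos)
  if (d == 0) return(c(0, 0))
  orderings <- if (d == 1) list(pos) else {
    perms <- function(v) {
      if (length(v) == 1) return(list(v))
      unlist(lapply(seq_along(v), function(i) {
        lapply(perms(v[-i]), function(p) c(v[i], p))
      }), recursive = FALSE)
    }
    perms(pos)
  }
  paths <- lapply(orderings, function(ord) {
    cur <- b1
    steps <- matrix("", nrow = d, ncol = 2)
    through_stop <- FALSE
    for (j in seq_len(d)) {
      nxt <- cur
      nxt[ord[j]] <- b2[ord[j]]
      from <- paste(cur, collapse = "")
      to <- paste(nxt, collapse = "")
      if (j < d && code[[to]] == "*") through_stop <- TRUE
      steps[j, ] <- c(from, to)
      cur <- nxt
    }
    list(steps = steps, through_stop = through_stop)
  })
  valid <- paths[!vapply(paths, `[[`, logical(1), "through_stop")]
  if (length(valid) == 0) valid <- paths
  per_path <- vapply(valid, function(p) {
    syn <- vapply(seq_len(nrow(p$steps)), function(j) {
      code[[p$steps[j, 1]]] == code[[p$steps[j, 2]]]
    }, logical(1))
    c(sum(syn), sum(!syn))
  }, numeric(2))
  res <- rowMeans(per_path)
  codon_diff_env[[key]] <- res
  res
}

split_codons <- function(seq) {
  L <- nchar(seq)
  substring(seq, seq(1, L, 3), seq(3, L, 3))
}

ng86_one <- function(s1, s2, code) {
  if (nchar(s1) != nchar(s2)) abort("aligned sequences must have equal length")
  if (nchar(s1) %% 3 != 0) abort("alignment length must be a multiple of 3")
  c1 <- split_codons(toupper(s1))
  c2 <- split_codons(toupper(s2))
  sense <- names(code)[code != "*"]
  usable <- c1 %in% sense & c2 %in% sense
  c1 <- c1[usable]
  c2 <- c2[usable]
  ncod <- length(c1)
  if (ncod == 0) {
    return(tibble(
      codons_used = 0L, S = NA_real_, N = NA_real_, Sd = NA_real_,
      Nd = NA_real_, pS = NA_real_, pN = NA_real_, dS = NA_real_,
      dN = NA_real_, saturated_s = NA, saturated_n = NA
    ))
  }
  tab <- syn_sites_table(code)
  S <- (sum(tab[c1]) + sum(tab[c2])) / 2
  N <- 3 * ncod - S
  diff <- which(c1 != c2)
  sd_nd <- c(0, 0)
  for (i in diff) sd_nd <- sd_nd + codon_path_diffs(c1[i], c2[i], code)
  pS <- if (S > 0) sd_nd[1] / S else NA_real_
  pN <- if (N > 0) sd_nd[2] / N else NA_real_
  jc <- function(p) {
    if (is.na(p) || p >= 3 / 4) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  }
  tibble(
    codons_used = ncod, S = S, N = N, Sd = sd_nd[1], Nd = sd_nd[2],
    pS = pS, pN = pN, dS = jc(pS), dN = jc(pN),
    saturated_s = !is.na(pS) && pS >= 3 / 4,
    saturated_n = !is.na(pN) && pN >= 3 / 4
  )
}

#' Nei-Gojobori (1986) synonymous and nonsynonymous divergence
#'
#' Counts synonymous (S) and nonsynonymous (N) sites, averaged over the two
#' sequences, and synonymous/nonsynonymous differences (Sd, Nd) between
#' pairs of gapless codon alignments, then applies the Jukes-Cantor
#' correction `d = -(3/4) log(1 - 4p/3)`. Codons containing gaps,
#' ambiguity codes, or stops in either sequence are skipped pairwise.
#' Codons differing at several positions are resolved by averaging the
#' difference counts over all orderings of the single-nucleotide steps,
#' excluding pathways through stop codons. `dS` (Ks) and `dN` (Ka) are
#' `NA` and flagged saturated when the corrected proportion reaches 3/4.
#' The result is symmetric in the order of the two sequences.
#'
#' @param seq1,seq2 Character vectors of aligned coding sequences (equal
#'   lengths pairwise, multiples of 3).
#' @param gene Optional gene identifiers (defaults to an index).
#' @param code Genetic code, default standard nuclear.
#' @return A tibble with one row per pair: `gene`, `codons_used`, `S`, `N`,
#'   `Sd`, `Nd`, `pS`, `pN`, `dS`, `dN`, `saturated_s`, `saturated_n`.
#' @export
#' @examples
#' ng86("GGGAAAGGGAAAGGGAAA", "GGAAAAGGGAAAGGGAAA") # S=4, Sd=1, pS=0.25
ng86 <- function(seq1, seq2, gene = NULL, code = Biostrings::GENETIC_CODE) {
  if (length(seq1) != length(seq2)) abort("`seq1` and `seq2` must pair up")
  gene <- gene %||% as.character(seq_along(seq1))
  rows <- purrr::map2(seq1, seq2, ng86_one, code = code)
  bind_rows(rows) |> mutate(gene = gene, .before = 1)
}

#' Median Ks over a set of ortholog gene pairs
#'
#' Summarises a per-gene NG86 table into the median synonymous divergence,
#' excluding genes whose Ks is saturated or undefined. Even-length medians
#' use the mean of the central pair.
#'
#' @param ks_tbl Tibble from [ng86()].
#' @return One-row tibble: `median_ks`, `n_genes`, `n_used`, `n_saturated`,
#'   `n_undefined`.
#' @export
median_ks <- function(ks_tbl) {
  stopifnot(all(c("dS", "saturated_s") %in% names(ks_tbl)))
  usable <- !is.na(ks_tbl$dS)
  n_sat <- sum(ks_tbl$saturated_s %in% TRUE)
  if (!any(usable)) abort("no gene with a defined, non-saturated Ks")
  tibble(
    median_ks = median(ks_tbl$dS[usable]),
    n_genes = nrow(ks_tbl),
    n_used = sum(usable),
    n_saturated = n_sat,
    n_undefined = sum(!usable) - n_sat
  )
}

#' Molecular-clock divergence time from median Ks
#'
#' Converts a median synonymous divergence into an absolute divergence time
#' with `T = Ks / (2 * rate)`, where `rate` is the synonymous substitution
#' rate per site per year. The default rate, 4.5e-9/year, is the average
#' synonymous rate estimated in Musaceae.
#'
#' @param median_ks Numeric vector of median Ks values (>= 0).
#' @param rate Substitution rate per synonymous site per year (> 0).
#' @return Divergence time(s) in years.
#' @export
#' @examples
#' divergence_time(0.0702) / 1e6 # 7.8 My
divergence_time <- function(median_ks, rate = 4.5e-9) {
  if (any(rate <= 0)) abort("`rate` must be > 0")
  if (any(median_ks < 0, na.rm = TRUE)) abort("`median_ks` must be >= 0")
  median_ks / (2 * rate)
}
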