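# Independent brute-force oracles used to validate the implementation.
# These are written against the definitions, not against the package code:
# they enumerate neighbours, mutation pathways, k-mer windows and chains
# explicitly and are only run on small instances.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# translate one codon with Biostrings' standard code table
.aa <- function(codon) Biostrings::GENETIC_CODE[[codon]]

# --- brute-force NG86 ------------------------------------------------------

# synonymous site count of one codon: explicit 9-neighbour enumeration
oracle_codon_s <- function(codon) {
  b <- strsplit(codon, "")[[1]]
  total <- 0
  for (p in 1:3) {
    syn <- 0
    nonstop <- 0
    for (nt in c("A", "C", "G", "T")) {
      if (nt == b[p]) next
      nb <- b
      nb[p] <- nt
      nbc <- paste(nb, collapse = "")
      if (.aa(nbc) == "*") next
      nonstop <- nonstop + 1
      if (.aa(nbc) == .aa(codon)) syn <- syn + 1
    }
    if (nonstop > 0) total <- total + syn / nonstop
  }
  total
}

# all mutation pathways between two codons as ordered step lists,
# excluding pathways whose intermediates are stops (recursive formulation)
oracle_paths <- function(c1, c2, allow_stops = FALSE) {
  if (c1 == c2) return(list(list()))
  b1 <- strsplit(c1, "")[[1]]
  b2 <- strsplit(c2, "")[[1]]
  out <- list()
  for (p in which(b1 != b2)) {
    nb <- b1
    nb[p] <- b2[p]
    mid <- paste(nb, collapse = "")
    if (!allow_stops && mid != c2 && .aa(mid) == "*") next
    for (rest in oracle_paths(mid, c2, allow_stops)) {
      out[[length(out) + 1]] <- c(list(c(c1, mid)), rest)
    }
  }
  out
}

oracle_codon_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(0, 0))
  paths <- oracle_paths(c1, c2)
  if (length(paths) == 0) paths <- oracle_paths(c1, c2, allow_stops = TRUE)
  acc <- sapply(paths, function(path) {
    syn <- vapply(path, function(step) .aa(step[1]) == .aa(step[2]), logical(1))
    c(sum(syn), sum(!syn))
  })
  rowMeans(acc)
}

oracle_ng86 <- function(s1, s2) {
  stops <- c("TAA", "TAG", "TGA")
  n <- nchar(s1)
  c1 <- substring(s1, seq(1, n, 3), seq(3, n, 3))
  c2 <- substring(s2, seq(1, n, 3), seq(3, n, 3))
  keep <- !grepl("[^ACGT]", c1) & !grepl("[^ACGT]", c2) &
    !(c1 %in% stops) & !(c2 %in% stops)
  c1 <- c1[keep]
  c2 <- c2[keep]
  S <- mean(c(sum(sapply(c1, oracle_codon_s)), sum(sapply(c2, oracle_codon_s))))
  N <- 3 * length(c1) - S
  sd_nd <- c(0, 0)
  for (i in seq_along(c1)) sd_nd <- sd_nd + oracle_codon_diffs(c1[i], c2[i])
  pS <- sd_nd[1] / S
  pN <- sd_nd[2] / N
  list(
    S = S, N = N, Sd = sd_nd[1], Nd = sd_nd[2], pS = pS, pN = pN,
    dS = if (pS < 0.75) -0.75 * log(1 - 4 * pS / 3) else NA_real_,
    dN = if (pN < 0.75) -0.75 * log(1 - 4 * pN / 3) else NA_real_
  )
}

# random pair of sense-codon sequences with some point differences
rand_codon_pair <- function(n_codons, n_mut) {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  s1 <- paste(sample(sense, n_codons, replace = TRUE), collapse = "")
  b <- strsplit(s1, "")[[1]]
  for (i in seq_len(n_mut)) {
    repeat {
      p <- sample(length(b), 1)
      nt <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
      old <- b[p]
      b[p] <- nt
      cod <- paste(b[(p - (p - 1) %% 3):(p - (p - 1) %% 3 + 2)], collapse = "")
      if (.aa(cod) != "*") break
      b[p] <- old
    }
  }
  c(s1, paste(b, collapse = ""))
}

# --- naive tag scan --------------------------------------------------------

oracle_scan <- function(assembly, tags) {
  out <- list()
  for (cn in names(assembly)) {
    s <- assembly[[cn]]
    n <- nchar(s)
    for (t in seq_len(nrow(tags))) {
      k <- nchar(tags$tag[t])
      rc <- revcomp(tags$tag[t])
      for (i in 0:(n - k)) {
        w <- substr(s, i + 1, i + k)
        if (w == tags$tag[t]) {
          out[[length(out) + 1]] <- data.frame(
            tag = tags$tag[t], group = tags$group[t], chrom = cn,
            start = i, strand = "+"
          )
        } else if (w == rc) {
          out[[length(out) + 1]] <- data.frame(
            tag = tags$tag[t], group = tags$group[t], chrom = cn,
            start = i, strand = "-"
          )
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(tag = character(0), group = character(0),
                      chrom = character(0), start = integer(0),
                      strand = character(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start, res$tag), , drop = FALSE]
}

# brute-force diagnostic k-mers: canonical set difference
oracle_diag_kmers <- function(panels, k, min_freq = 1) {
  canon <- function(seq) {
    n <- nchar(seq)
    if (n < k) return(character(0))
    km <- substring(seq, 1:(n - k + 1), k:n)
    km <- km[!grepl("[^ACGT]", km)]
    unique(pmin(km, revcomp(km)))
  }
  per_group <- lapply(panels, function(ss) lapply(ss, canon))
  res <- list()
  for (g in names(panels)) {
    all_km <- unique(unlist(per_group[[g]]))
    freq <- sapply(all_km, function(x) {
      mean(vapply(per_group[[g]], function(s) x %in% s, logical(1)))
    })
    cand <- all_km[freq >= min_freq]
    others <- unique(unlist(per_group[setdiff(names(panels), g)]))
    res[[g]] <- sort(setdiff(cand, others))
  }
  res
}

# --- exhaustive collinear chain search -------------------------------------

# longest collinear chain by memoised recursion (independent of the
# package's iterative DP); returns the best chain's gene count
oracle_longest_chain <- function(ra, rb, orientation, max_gap) {
  n <- length(ra)
  ord <- order(ra)
  ra <- ra[ord]
  rb <- rb[ord]
  memo <- rep(NA_integer_, n)
  longest_from <- function(i) {
    if (!is.na(memo[i])) return(memo[i])
    best <- 1L
    for (j in seq_len(n)) {
      da <- ra[j] - ra[i]
      db <- if (orientation == "+") rb[j] - rb[i] else rb[i] - rb[j]
      if (da >= 1 && da <= max_gap && db >= 1 && db <= max_gap) {
        best <- max(best, 1L + longest_from(j))
      }
    }
    memo[i] <<- best
    best
  }
  if (n == 0) return(0L)
  max(vapply(seq_len(n), longest_from, integer(1)))
}

# --- exhaustive bipartition support ----------------------------------------

# count gene trees containing each non-trivial split of the global tree,
# using ape's prop.part machinery as an independent split extractor
oracle_branch_support <- function(global_tree, gene_trees) {
  taxa <- sort(global_tree$tip.label)
  splits_of <- function(tr) {
    tr <- ape::unroot(tr)
    pp <- ape::prop.part(tr)
    labs <- attr(pp, "labels")
    sides <- lapply(pp, function(idx) sort(labs[idx]))
    sides <- Filter(function(s) {
      length(s) >= 2 && length(s) <= length(labs) - 2
    }, sides)
    unique(vapply(sides, function(s) {
      if (min(labs) %in% s) s <- setdiff(sort(labs), s)
      paste(s, collapse = ",")
    }, character(1)))
  }
  glob <- splits_of(global_tree)
  res <- lapply(glob, function(key) {
    side <- strsplit(key, ",")[[1]]
    n_sup <- 0L
    n_eval <- 0L
    for (gt in gene_trees) {
      gtaxa <- sort(gt$tip.label)
      a <- intersect(side, gtaxa)
      b <- intersect(setdiff(taxa, side), gtaxa)
      if (length(a) < 2 || length(b) < 2) next
      n_eval <- n_eval + 1L
      if (min(gtaxa) %in% a) a <- sort(setdiff(gtaxa, a))
      if (paste(sort(a), collapse = ",") %in% splits_of(gt)) n_sup <- n_sup + 1L
    }
    data.frame(key = key, n_support = n_sup, n_evaluable = n_eval)
  })
  do.call(rbind, res)
}
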