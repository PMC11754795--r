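#' Phase child markers from a parent-child trio
#'
#' Standard Mendelian trio logic on biallelic calls: a child heterozygote
#' is phased when the parental genotypes force the origin of exactly one
#' allele (an allele absent from one parent must come from the other).
#' Haplotype 1 is the parent-1 side. Sites where neither transmission is
#' compatible with the parents are flagged Mendelian-inconsistent and not
#' phased; sites compatible with both transmissions stay unphased.
#'
#' @param child,parent1,parent2 Tibbles with columns `chrom`, `pos`
#'   (0-based), `a1`, `a2` (the two alleles of the genotype call). A
#'   parent genotype missing at a child position is treated as unknown
#'   (compatible with any transmission); positions absent from both
#'   parents are skipped with a warning.
#' @return Tibble of child heterozygous sites: `chrom`, `pos`, `h1`,
#'   `h2` (alleles assigned to haplotypes 1/2, `NA` when unphased),
#'   `status` (`phased` | `unphased` | `inconsistent`), `source`.
#' @export
phase_markers_from_trio <- function(child, parent1, parent2) {
  need <- c("chrom", "pos", "a1", "a2")
  for (x in list(child, parent1, parent2)) stopifnot(all(need %in% names(x)))
  het <- filter(child, .data$a1 != .data$a2)
  g <- het |>
    left_join(parent1, by = c("chrom", "pos"), suffix = c("", "_p1")) |>
    left_join(parent2, by = c("chrom", "pos"), suffix = c("", "_p2"))
  orphan <- is.na(g$a1_p1) & is.na(g$a1_p2)
  if (any(orphan)) {
    warn(sprintf("%d child position(s) absent from both parents; skipped", sum(orphan)))
    g <- g[!orphan, ]
  }
  in_parent <- function(allele, p1, p2) is.na(p1) | allele == p1 | allele == p2
  # transmission 1: a1 from parent1, a2 from parent2; transmission 2: swapped
  t1 <- in_parent(g$a1, g$a1_p1, g$a2_p1) & in_parent(g$a2, g$a1_p2, g$a2_p2)
  t2 <- in_parent(g$a2, g$a1_p1, g$a2_p1) & in_parent(g$a1, g$a1_p2, g$a2_p2)
  status <- dplyr::case_when(
    t1 & t2 ~ "unphased",
    t1 | t2 ~ "phased",
    TRUE ~ "inconsistent"
  )
  tibble(
    chrom = g$chrom, pos = g$pos,
    h1 = ifelse(status == "phased", ifelse(t1, g$a1, g$a2), NA_character_),
    h2 = ifelse(status == "phased", ifelse(t1, g$a2, g$a1), NA_character_),
    status = status, source = "trio"
  )
}

#' Build haplotype-specific tags from phased markers
#'
#' For every phased marker, substitutes each haplotype's allele into the
#' reference and takes the k-mer centred on the site; nearby phased markers
#' within the same window are substituted too, so overlapping tags carry
#' each haplotype's alleles at all covered sites. Tags occurring in both
#' haplotype sets are removed, making the sets disjoint by construction.
#' Tags are canonical (lexicographically smaller strand).
#'
#' @param markers Phased marker tibble from [phase_markers_from_trio()]
#'   (only `status == "phased"` rows are used); alleles must be single
#'   bases.
#' @param reference Named character vector of reference sequences carrying
#'   the marker coordinates.
#' @param k Tag length (odd). Markers closer than `(k-1)/2` to a sequence
#'   end are skipped with a warning.
#' @return Tibble with columns `tag`, `group` (`H1`/`H2`), compatible with
#'   [match_tags()].
#' @export
build_haplotype_tags <- function(markers, reference, k = 31L) {
  if (k %% 2 == 0) abort("`k` must be odd")
  flank <- (k - 1L) %/% 2L
  ph <- filter(markers, .data$status == "phased")
  if (nrow(ph) == 0) return(tibble(tag = character(0), group = character(0)))
  if (any(nchar(c(ph$h1, ph$h2)) != 1)) abort("alleles must be single bases")
  skipped <- 0L
  sets <- list(H1 = character(0), H2 = character(0))
  for (cn in unique(ph$chrom)) {
    if (!cn %in% names(reference)) abort(sprintf("no reference sequence %s", cn))
    refseq <- toupper(reference[[cn]])
    L <- nchar(refseq)
    m <- filter(ph, .data$chrom == cn) |> arrange(.data$pos)
    refbases <- strsplit(refseq, "")[[1]]
    sub_alleles <- function(alleles) {
      b <- refbases
      b[m$pos + 1L] <- alleles
      paste(b, collapse = "")
    }
    hapseq <- list(H1 = sub_alleles(m$h1), H2 = sub_alleles(m$h2))
    ok <- m$pos - flank >= 0 & m$pos + flank < L
    skipped <- skipped + sum(!ok)
    if (!any(ok)) next
    for (h in c("H1", "H2")) {
      km <- substring(hapseq[[h]], m$pos[ok] + 1L - flank, m$pos[ok] + 1L + flank)
      km <- km[!grepl("[^ACGT]", km)]
      sets[[h]] <- unique(c(sets[[h]], pmin(km, revcomp(km))))
    }
  }
  if (skipped > 0) warn(sprintf("%d marker(s) too close to a sequence end; skipped", skipped))
  shared <- intersect(sets$H1, sets$H2)
  bind_rows(
    tibble(tag = sort(setdiff(sets$H1, shared)), group = "H1"),
    tibble(tag = sort(setdiff(sets$H2, shared)), group = "H2")
  )
}

#' Assign contigs to haplotypes from tag hits
#'
#' Applies the same dominance rule as window painting at whole-contig
#' granularity: a contig is assigned to the haplotype holding at least
#' `ratio` of its tag hits when at least `min_hits` hits are present; ties
#' and low evidence give `unassigned` (such contigs belong in both
#' haplotype assemblies).
#'
#' @param hits Tag-hit tibble from [match_tags()] run on the contigs
#'   (`chrom` = contig name) with haplotype tags.
#' @param contigs Optional character vector of all contig names, so
#'   hit-less contigs are reported as unassigned.
#' @param labels The two haplotype labels. Default `c("H1", "H2")`.
#' @param min_hits,ratio Dominance rule parameters (defaults 5 and 0.75).
#' @return Tibble: `contig`, one count column per label, `total`,
#'   `verdict`.
#' @export
assign_contigs <- function(hits, contigs = NULL, labels = c("H1", "H2"),
                           min_hits = 5, ratio = 0.75) {
  if (ratio <= 0.5 || ratio > 1) abort("`ratio` must be in (0.5, 1]")
  contigs <- contigs %||% sort(unique(hits$chrom))
  counts <- hits |>
    count(contig = .data$chrom, .data$group) |>
    tidyr::pivot_wider(names_from = "group", values_from = "n", values_fill = 0)
  for (l in setdiff(labels, names(counts))) counts[[l]] <- 0L
  out <- tibble(contig = contigs) |>
    left_join(counts, by = "contig") |>
    mutate(dplyr::across(dplyr::all_of(labels), ~ tidyr::replace_na(.x, 0L)))
  cm <- as.matrix(out[, labels, drop = FALSE])
  total <- rowSums(cm)
  cmax <- apply(cm, 1, max)
  n_at_max <- rowSums(cm == cmax & cm > 0)
  top <- labels[max.col(cm, ties.method = "first")]
  out$total <- total
  out$verdict <- ifelse(
    total >= min_hits & cmax / pmax(total, 1) >= ratio & n_at_max == 1,
    top, "unassigned"
  )
  out
}
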