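# ---- ancestral group panels ----------------------------------------------

test_that("zero branch lengths give identical groups; same seed is byte-identical", {
  sp0 <- group_phylogeny_spec("(A:0,B:0);", length = 3000,
                              n_per_group = 1, within_group_years = 0, seed = 3)
  sim0 <- simulate_ancestral_groups(sp0)
  expect_identical(unname(sim0$panels$A[[1]]), sim0$root)
  expect_identical(unname(sim0$panels$B[[1]]), sim0$root)

  sp <- group_phylogeny_spec("(A:1e6,B:1e6);", length = 5000, seed = 11)
  s1 <- simulate_ancestral_groups(sp)
  s2 <- simulate_ancestral_groups(sp)
  expect_identical(s1$panels, s2$panels)
})

test_that("pairwise divergence matches the clock expectation 2*T*rate", {
  sp <- group_phylogeny_spec("(A:7.8e6,B:7.8e6);", rate = 4.5e-9,
                             length = 3e5, n_per_group = 1,
                             within_group_years = 0, seed = 42)
  sim <- simulate_ancestral_groups(sp)
  a <- strsplit(sim$panels$A[[1]], "")[[1]]
  b <- strsplit(sim$panels$B[[1]], "")[[1]]
  p <- mean(a != b)
  d_jc <- -0.75 * log(1 - 4 * p / 3)
  expected <- 2 * 7.8e6 * 4.5e-9 # 0.0702
  # 3 binomial SD on the JC-corrected estimate (delta method)
  se <- sqrt(p * (1 - p) / length(a)) / (1 - 4 * p / 3)
  expect_lt(abs(d_jc - expected), 3 * se)
})

test_that("clock regression of JC divergence on 2*T*rate has slope ~1", {
  depths <- c(1e6, 2e6, 4e6, 6e6, 8e6)
  obs <- vapply(seq_along(depths), function(i) {
    sp <- group_phylogeny_spec(
      sprintf("(A:%g,B:%g);", depths[i], depths[i]),
      rate = 4.5e-9, length = 2e5, n_per_group = 1,
      within_group_years = 0, seed = 100 + i
    )
    sim <- simulate_ancestral_groups(sp)
    p <- mean(strsplit(sim$panels$A[[1]], "")[[1]] !=
                strsplit(sim$panels$B[[1]], "")[[1]])
    -0.75 * log(1 - 4 * p / 3)
  }, numeric(1))
  truth <- 2 * depths * 4.5e-9
  slope <- coef(lm(obs ~ 0 + truth))[[1]]
  expect_lt(abs(slope - 1), 0.05)
})

test_that("spec validation rejects degenerate phylogenies", {
  expect_error(group_phylogeny_spec("(A:1);", length = 100), "2 groups")
  expect_error(group_phylogeny_spec("(A:1,B:1);", rate = 0, length = 100), "rate")
  expect_error(group_phylogeny_spec("(A:1,B:1);", length = 100,
                                    codon_structured = TRUE), "multiple of 3")
})

# ---- mosaic genomes -------------------------------------------------------

test_that("mosaic construction equals donor slices and truth tiles the chromosome", {
  withr::local_seed(5)
  panels <- list(A = c(A_1 = rand_dna(25000)), B = c(B_1 = rand_dna(25000)))
  whole <- build_mosaic_genome(panels, mosaic_spec("c", 25000, "A"))
  expect_identical(unname(whole$seq), unname(panels$A))
  expect_identical(as.data.frame(whole$truth),
                   data.frame(chrom = "c", start = 0L, end = 25000L,
                              label = "A"))

  mos <- build_mosaic_genome(panels,
                             mosaic_spec("c", c(10000, 5000, 10000),
                                         c("A", "B", "A")))
  expect_identical(mos$truth$start, c(0L, 10000L, 15000L))
  expect_identical(mos$truth$end, c(10000L, 15000L, 25000L))
  expect_identical(mos$truth$label, c("A", "B", "A"))
  expect_identical(sum(mos$truth$end - mos$truth$start), nchar(unname(mos$seq)))
  # slices come from homologous (cumulative) donor coordinates
  expect_identical(unname(substr(mos$seq, 10001, 15000)),
                   unname(substr(panels$B, 10001, 15000)))
})

test_that("mosaic construction rejects unknown donors and overruns", {
  panels <- list(A = c(A_1 = strrep("ACGT", 100)))
  expect_error(build_mosaic_genome(panels, mosaic_spec("c", 100, "Z")),
               "unknown donor")
  expect_error(build_mosaic_genome(panels, mosaic_spec("c", 1000, "A")),
               "past donor")
})

# ---- rearrangements -------------------------------------------------------

test_that("empty event list is the identity; inversion reverse-complements in place", {
  withr::local_seed(8)
  asm <- c(c1 = rand_dna(30))
  ra0 <- apply_rearrangement(asm)
  expect_identical(ra0$seq, asm)
  expect_identical(map_coords(ra0$blocks, "c1", 7)$pos, 7)

  ra <- apply_rearrangement(asm, rearrangement_spec(rearr_inversion("c1", 10, 20)))
  expect_identical(nchar(ra$seq), nchar(asm))
  expect_identical(substr(ra$seq, 11, 20), revcomp(substr(asm, 11, 20)))
  expect_identical(substr(ra$seq, 1, 10), substr(asm, 1, 10))
  expect_identical(substr(ra$seq, 21, 30), substr(asm, 21, 30))
})

test_that("inversion + reciprocal translocation recipe conserves bases and round-trips", {
  withr::local_seed(9)
  asm <- c(chr1 = rand_dna(100000), chr7 = rand_dna(100000))
  spec <- rearrangement_spec(
    rearr_inversion("chr7", 30000, 70000),
    rearr_translocation("chr1", 60000, "chr7", 50000),
    rearr_inversion("chr1", 70000, 85000)
  )
  ra <- apply_rearrangement(asm, spec)
  expect_identical(sum(nchar(ra$seq)), sum(nchar(asm)))
  # base multiset conserved up to reverse complement
  count_bases <- function(x) {
    tab <- table(strsplit(paste(x, collapse = ""), "")[[1]])
    c(tab["A"] + tab["T"], tab["C"] + tab["G"])
  }
  expect_equal(unname(count_bases(ra$seq)), unname(count_bases(asm)))

  pos <- sample(0:99999, 1000)
  ch <- sample(names(asm), 1000, replace = TRUE)
  fwd <- map_coords(ra$blocks, ch, pos, "forward")
  back <- map_coords(ra$blocks, fwd$chrom, fwd$pos, "inverse")
  expect_identical(back$chrom, ch)
  expect_identical(back$pos, as.double(pos))
  # each base's provenance: mapped base equals source base (or complement)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in seq_len(50)) {
    src <- substr(asm[[ch[i]]], pos[i] + 1, pos[i] + 1)
    dst <- substr(ra$seq[[fwd$chrom[i]]], fwd$pos[i] + 1, fwd$pos[i] + 1)
    expect_identical(dst, if (fwd$strand[i] == "-") unname(comp[src]) else src)
  }
})

test_that("breakpoints outside chromosome bounds are rejected", {
  asm <- c(c1 = strrep("ACGT", 10), c2 = strrep("ACGT", 10))
  expect_error(
    apply_rearrangement(asm, rearrangement_spec(rearr_inversion("c1", 10, 99))),
    "outside"
  )
  expect_error(
    apply_rearrangement(asm, rearrangement_spec(
      rearr_translocation("c1", 200, "c2", 5))),
    "outside"
  )
})

# ---- trios ----------------------------------------------------------------

test_that("trio children are parental gametes with recorded phase", {
  withr::local_seed(10)
  mk_dip <- function() list(c(chr1 = rand_dna(20000)), c(chr1 = rand_dna(20000)))
  p1 <- mk_dip()
  p2 <- mk_dip()
  # zero recombination: child haplotype 1 is one parent-1 gamete exactly
  tr0 <- simulate_trio(p1, p2, crossovers = 0, seed = 2)
  expect_true(tr0$child$h1[["chr1"]] %in% c(p1[[1]][["chr1"]], p1[[2]][["chr1"]]))
  expect_identical(nrow(dplyr::filter(tr0$phase, haplotype == "h1")), 1L)

  # one crossover at 10 kb: exactly 2 phase blocks per gamete
  tr1 <- simulate_trio(p1, p2, crossovers = list(chr1 = 10000), seed = 2)
  ph <- dplyr::filter(tr1$phase, haplotype == "h1")
  expect_identical(nrow(ph), 2L)
  expect_identical(ph$end[1], 10000)
  h <- ph$parent_hap
  expect_identical(
    tr1$child$h1[["chr1"]],
    paste0(substr(p1[[h[1]]][["chr1"]], 1, 10000),
           substr(p1[[h[2]]][["chr1"]], 10001, 20000))
  )

  expect_identical(simulate_trio(p1, p2, 1, seed = 7),
                   simulate_trio(p1, p2, 1, seed = 7))
  p3 <- list(c(chrX = "ACGT"), c(chrX = "ACGT"))
  expect_error(simulate_trio(p1, p3, 1), "different chromosome sets")
})

# ---- gene pairs -----------------------------------------------------------

test_that("gene pairs at T=0 are identical; same seed reproduces; stops never appear", {
  pairs0 <- sample_gene_pairs(0, n_genes = 5, codons_per_gene = 30, seed = 1)
  expect_identical(pairs0$seq1, pairs0$seq2)
  expect_identical(sample_gene_pairs(1e6, n_genes = 3, codons_per_gene = 20, seed = 9),
                   sample_gene_pairs(1e6, n_genes = 3, codons_per_gene = 20, seed = 9))
  pairs <- sample_gene_pairs(2e7, n_genes = 10, codons_per_gene = 50, seed = 4)
  has_stop <- function(s) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    any(cods %in% c("TAA", "TAG", "TGA"))
  }
  expect_false(any(vapply(c(pairs$seq1, pairs$seq2), has_stop, logical(1))))
  expect_error(sample_gene_pairs(-1), ">= 0")
})

test_that("median NG86 Ks of simulated pairs matches the 2*T*rate expectation", {
  pairs <- sample_gene_pairs(7.8e6, rate = 4.5e-9, n_genes = 120,
                             codons_per_gene = 300, seed = 13)
  ks <- ng86(pairs$seq1, pairs$seq2, pairs$gene)
  m <- median_ks(ks)$median_ks
  # 120 genes: Monte-Carlo SE of the median is ~3%, so bound at 3 SD
  expect_lt(abs(m - 0.0702) / 0.0702, 0.09)
})
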