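mk_anchors <- function(genes, chrom = "c1") {
  tibble::tibble(gene = genes, chrom = chrom, rank = seq_along(genes),
                 mid = seq_along(genes) * 10000)
}

test_that("identical gene orders give a single + block containing every gene", {
  a <- mk_anchors(sprintf("g%02d", 1:30))
  bl <- chain_blocks(anchor_hits(a, a))
  expect_identical(nrow(bl), 1L)
  expect_identical(bl$orientation, "+")
  expect_identical(bl$n_genes, 30L)
  expect_identical(nrow(chain_blocks(anchor_hits(a, a)[0, ])), 0L)
})

test_that("an inverted middle third splits into +/-/+ blocks matching exhaustive search", {
  a <- mk_anchors(sprintf("g%02d", 1:30))
  b <- a
  b$rank[11:20] <- rev(b$rank[11:20])
  b <- dplyr::arrange(b, rank)
  b$mid <- b$rank * 10000
  hits <- anchor_hits(a, b)
  bl <- chain_blocks(hits, max_gap = 5)
  expect_identical(sort(bl$n_genes, decreasing = TRUE), c(10L, 10L, 10L))
  expect_identical(sort(bl$orientation), c("+", "+", "-"))
  # the best chain matches a memoised exhaustive longest-chain search
  best_plus <- oracle_longest_chain(hits$rank_a, hits$rank_b, "+", 5)
  best_minus <- oracle_longest_chain(hits$rank_a, hits$rank_b, "-", 5)
  expect_identical(max(bl$n_genes), max(best_plus, best_minus))
})

test_that("chained blocks always pass a monotonicity audit in both genomes", {
  withr::local_seed(81)
  for (rep in 1:5) {
    perm <- sample(40)
    a <- mk_anchors(sprintf("g%02d", 1:40))
    b <- a
    b$rank <- perm
    hits <- anchor_hits(a, dplyr::arrange(b, rank))
    bl <- chain_blocks(hits, max_gap = 8, min_block = 3)
    for (i in seq_len(nrow(bl))) {
      anc <- bl$anchors[[i]]
      expect_true(all(diff(anc$rank_a) > 0))
      db <- diff(anc$rank_b)
      if (bl$orientation[i] == "+") expect_true(all(db > 0))
      else expect_true(all(db < 0))
    }
    # anchors used at most once
    used <- unlist(lapply(bl$anchors, function(x) x$gene_a))
    expect_identical(anyDuplicated(used), 0L)
  }
})

test_that("chain_blocks(A,B) and chain_blocks(B,A) find the same anchor pairs", {
  withr::local_seed(83)
  a <- mk_anchors(sprintf("g%02d", 1:30))
  b <- a
  b$rank[8:18] <- rev(b$rank[8:18])
  b <- dplyr::arrange(b, rank)
  ab <- chain_blocks(anchor_hits(a, b), max_gap = 5)
  ba <- chain_blocks(anchor_hits(b, a), max_gap = 5)
  pairs_of <- function(bl, flip = FALSE) {
    p <- lapply(bl$anchors, function(x) {
      if (flip) paste(x$gene_b, x$gene_a) else paste(x$gene_a, x$gene_b)
    })
    sort(unlist(p))
  }
  expect_identical(pairs_of(ab), pairs_of(ba, flip = TRUE))
  expect_identical(sort(ab$orientation), sort(ba$orientation))
})

test_that("block association needs strictly more than 20 shared reference genes", {
  a21 <- mk_anchors(sprintf("g%02d", 1:21))
  b21 <- chain_blocks(anchor_hits(a21, a21))
  expect_identical(nrow(associate_blocks(b21, b21)), 1L)
  expect_identical(associate_blocks(b21, b21)$shared, 21L)

  a20 <- mk_anchors(sprintf("g%02d", 1:20))
  b20 <- chain_blocks(anchor_hits(a20, a20))
  expect_identical(nrow(associate_blocks(b20, b20)), 0L) # exactly 20: no
  expect_identical(nrow(associate_blocks(b21, chain_blocks(anchor_hits(
    mk_anchors(sprintf("x%02d", 1:21)), mk_anchors(sprintf("x%02d", 1:21))
  )))), 0L) # zero shared
})

test_that("ortholog groups match a brute-force set-intersection oracle", {
  # reference with 60 genes on two chromosomes; assembly X identical;
  # assembly Y with an inverted run inside chromosome 1
  ref <- dplyr::bind_rows(
    mk_anchors(sprintf("a%02d", 1:30), "c1"),
    mk_anchors(sprintf("b%02d", 1:30), "c2")
  )
  y <- ref
  y$rank[10:17] <- rev(y$rank[10:17])
  y <- dplyr::arrange(y, chrom, rank)
  bx <- chain_blocks(anchor_hits(ref, ref), max_gap = 5)
  by <- chain_blocks(anchor_hits(ref, y), max_gap = 5)
  groups <- build_ortholog_groups(list(X = bx, Y = by))
  # brute force: reference genes in mutually associated block pairs
  assoc <- associate_blocks(bx, by)
  expected <- character(0)
  for (r in seq_len(nrow(assoc))) {
    gx <- bx$anchors[[which(bx$block_id == assoc$block_x[r])]]$gene_a
    gy <- by$anchors[[which(by$block_id == assoc$block_y[r])]]$gene_a
    expected <- union(expected, intersect(gx, gy))
  }
  expect_setequal(groups$ref_gene, expected)
  expect_true(all(groups$X == groups$ref_gene, na.rm = TRUE))

  # complete-occupancy flag with an assembly that has zero associated blocks
  empty_blocks <- chain_blocks(anchor_hits(ref, ref)[0, ])
  g0 <- build_ortholog_groups(list(X = bx, Z = empty_blocks), complete = TRUE)
  expect_identical(nrow(g0), 0L)
})

test_that("ancestry filtering retains exactly the groups inside target segments", {
  groups <- tibble::tibble(
    ref_gene = c("g1", "g2", "g3"), focal = c("f1", "f2", NA)
  )
  anchors <- tibble::tibble(
    gene = c("f1", "f2"), chrom = "c1", mid = c(5000, 15000)
  )
  segments <- tibble::tibble(
    chrom = "c1", start = c(0, 10000), end = c(10000, 20000),
    label = c("U", "A")
  )
  kept <- filter_groups_by_ancestry(groups, "focal", anchors, segments, "U")
  expect_identical(kept$ref_gene, "g1") # f2 outside [0,10000); g3 no member
  none <- filter_groups_by_ancestry(groups, "focal", anchors, segments, "Z")
  expect_identical(nrow(none), 0L)

  # random layout equals a brute-force interval scan
  withr::local_seed(91)
  n <- 200
  g2 <- tibble::tibble(ref_gene = paste0("g", 1:n), focal = paste0("f", 1:n))
  an2 <- tibble::tibble(gene = paste0("f", 1:n), chrom = "c1",
                        mid = sort(sample(0:99999, n)))
  cut <- sort(sample(1000:99000, 9))
  seg2 <- tibble::tibble(
    chrom = "c1", start = c(0, cut), end = c(cut, 100000),
    label = sample(c("U", "A"), 10, replace = TRUE)
  )
  kept2 <- filter_groups_by_ancestry(g2, "focal", an2, seg2, "U")
  brute <- vapply(seq_len(n), function(i) {
    any(seg2$label == "U" & seg2$start <= an2$mid[i] & an2$mid[i] < seg2$end)
  }, logical(1))
  expect_setequal(kept2$ref_gene, g2$ref_gene[brute])
})

test_that("dot-plot points mirror the hit table with diagonals and anti-diagonals", {
  a <- mk_anchors(sprintf("g%02d", 1:20))
  b <- a
  b$rank[6:10] <- rev(b$rank[6:10])
  b <- dplyr::arrange(b, rank)
  b$mid <- b$rank * 10000
  hits <- anchor_hits(a, b)
  pts <- dotplot_data(hits)
  expect_identical(nrow(pts), nrow(hits)) # conservation
  same <- dotplot_data(anchor_hits(a, a))
  expect_true(all(same$x == same$y)) # identical assemblies: diagonal
  inv <- dplyr::filter(pts, gene_a %in% sprintf("g%02d", 6:10))
  expect_true(all(diff(inv$y[order(inv$x)]) < 0)) # anti-diagonal run
})
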