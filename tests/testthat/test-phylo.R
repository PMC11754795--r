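test_that("JC distances match the closed form and matrix structure", {
  s1 <- strrep("A", 100)
  s2 <- paste0(strrep("C", 10), strrep("A", 90))
  d <- jc_distance_matrix(c(x = s1, y = s2))
  expect_equal(d["x", "y"], -0.75 * log(1 - 4 * 0.1 / 3), tolerance = 1e-12)
  expect_equal(d["x", "x"], 0)
  expect_identical(d, t(d))

  ident <- jc_distance_matrix(c(a = "ACGT", b = "ACGT", c = "ACGT"))
  expect_true(all(ident == 0))

  # concatenation of per-gene alignments
  genes <- list(c(a = "AAAA", b = "AAAA"), c(a = "CCCC", b = "GGGG"))
  dc <- jc_distance_matrix(genes, concatenate = TRUE)
  expect_equal(dc["a", "b"], -0.75 * log(1 - 4 * 0.5 / 3), tolerance = 1e-12)
  expect_warning(jc_distance_matrix(c(a = strrep("A", 20), b = strrep("C", 20))),
                 "saturated")
})

test_that("neighbor joining solves the three-taxon closed form", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], 0.5)
  expect_equal(bl[["B"]], 1.5)
  expect_equal(bl[["C"]], 2.5)
})

test_that("neighbor joining recovers additive trees exactly up to 10 taxa", {
  withr::local_seed(111)
  for (ntax in c(5, 8, 10)) {
    gen <- ape::rtree(ntax, br = function(n) runif(n, 0.05, 1))
    dm <- ape::cophenetic.phylo(gen)
    tr <- nj_tree(dm)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(gen), tr)), 0)
    expect_equal(sort(tr$edge.length), sort(ape::unroot(gen)$edge.length),
                 tolerance = 1e-8)
  }
  d0 <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  star <- nj_tree(d0)
  expect_identical(star$Nnode, 1L)
  expect_true(all(star$edge.length == 0))
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))),
               "3 taxa")
})

test_that("branch support counts gene trees containing each bipartition", {
  glob <- ape::read.tree(text = "((A,B),(C,D));")
  trees <- c(
    ape::read.tree(text = "((A,B),(C,D));"),
    ape::read.tree(text = "((A,B),(C,D));"),
    ape::read.tree(text = "((A,C),(B,D));")
  )
  st <- branch_support(glob, trees)
  expect_identical(nrow(st), 1L)
  expect_equal(st$support, 2 / 3)
  expect_identical(st$n_evaluable, 3L)

  # all gene trees identical: every proportion 1
  glob5 <- ape::read.tree(text = "(((A,B),C),(D,E));")
  st5 <- branch_support(glob5, rep(c(glob5), 4))
  expect_true(all(st5$support == 1))
  expect_identical(nrow(st5), 2L)
  expect_error(branch_support(glob, list()), "zero gene trees")
})

test_that("gene trees missing a taxon are excluded from that branch's denominator", {
  glob <- ape::read.tree(text = "((A,B),(C,D));")
  trees <- c(
    ape::read.tree(text = "((A,B),(C,D));"),
    ape::read.tree(text = "(A,B,C);") # AB|CD unresolvable without D
  )
  st <- branch_support(glob, trees)
  expect_identical(st$n_evaluable, 1L)
  expect_equal(st$support, 1)
})

test_that("polytomies support none of the bipartitions they collapse", {
  glob <- ape::read.tree(text = "(((A,B),C),(D,E));")
  poly <- ape::read.tree(text = "((A,B,C),(D,E));") # ABC polytomy
  st <- branch_support(glob, list(poly))
  # AB|CDE collapsed -> not supported but evaluable; DE|ABC intact
  expect_identical(st$n_evaluable, c(1L, 1L))
  expect_identical(sort(st$n_support), c(0L, 1L))
})

test_that("support equals the exhaustive bipartition-count oracle on random instances", {
  withr::local_seed(113)
  for (rep in 1:3) {
    glob <- ape::rtree(8)
    trees <- lapply(1:50, function(i) {
      tr <- ape::rtree(8)
      if (i %% 7 == 0) ape::drop.tip(tr, sample(tr$tip.label, 2)) else tr
    })
    st <- branch_support(glob, trees)
    orc <- oracle_branch_support(glob, trees)
    merged <- merge(as.data.frame(st[, c("key", "n_support", "n_evaluable")]),
                    orc, by = "key", suffixes = c("", "_oracle"))
    expect_identical(nrow(merged), nrow(st))
    expect_identical(merged$n_support, merged$n_support_oracle)
    expect_identical(merged$n_evaluable, merged$n_evaluable_oracle)
  }
})

test_that("support agrees with ape::prop.clades on full-taxon gene trees", {
  withr::local_seed(115)
  glob <- ape::rtree(7)
  trees <- lapply(1:20, function(i) ape::rtree(7))
  st <- branch_support(glob, trees)
  pc <- ape::prop.clades(glob, trees, rooted = FALSE)
  pc[is.na(pc)] <- 0L # prop.clades reports absent bipartitions as NA
  # map each internal node's clade to its canonical split key
  pp <- ape::prop.part(glob)
  labs <- attr(pp, "labels")
  taxa <- sort(labs)
  ntip <- length(labs)
  for (i in seq_along(pp)) {
    side <- sort(labs[pp[[i]]])
    if (length(side) < 2 || length(side) > ntip - 2) next
    if (min(taxa) %in% side) side <- sort(setdiff(taxa, side))
    key <- paste(side, collapse = ",")
    m <- match(key, st$key)
    if (is.na(m)) next
    # root-adjacent nodes can duplicate a split; prop.clades counts the
    # bipartition on at least one of them
    expect_true(pc[i] == st$n_support[m] || pc[i] == 0)
  }
  expect_true(any(pc[-1] > 0) || all(st$n_support == 0))
})

test_that("placement support proportions count gene-tree attachments and sum to 1", {
  glob <- ape::read.tree(text = "(((A,B),C),(D,E));")
  same <- ape::read.tree(text = "(((A,B),C),(D,E));")
  moved <- ape::read.tree(text = "(((A,C),B),(D,E));") # A next to C
  ps <- placement_support(glob, "A", list(same, same, moved))
  expect_equal(sum(ps$proportion), 1)
  expect_equal(ps$proportion[ps$is_global], 2 / 3)
  expect_equal(ps$proportion[ps$candidate == "C"], 1 / 3)

  all_same <- placement_support(glob, "A", list(same, same))
  expect_equal(all_same$proportion[all_same$is_global], 1)
  expect_true(all(all_same$proportion[!all_same$is_global] == 0))
  expect_error(placement_support(glob, "Z", list(same)), "absent")
})

test_that("tree annotation places support values on matching internal nodes", {
  glob <- ape::read.tree(text = "((A,B),(C,D));")
  st <- branch_support(glob, list(glob, glob))
  annotated <- annotate_support(glob, st)
  expect_true("1" %in% annotated$node.label)
})
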