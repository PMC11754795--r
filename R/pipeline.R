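#' Default demo-pipeline configuration
#'
#' A complete, desk-scale parameter set for [run_demo_pipeline()]. All
#' entries are plain values, so a config round-trips through JSON
#' (`jsonlite::write_json(cfg, ..., auto_unbox = TRUE)`).
#'
#' @param seed Global seed; every stage derives its own stream from it.
#' @return Nested list of parameters.
#' @export
demo_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    panel = list(
      tree = "((A:2.2e6,B:2.2e6):2.2e6,C:4.4e6);",
      rate = 4.5e-9, length = 60000, n_per_group = 2,
      within_group_years = 1e5
    ),
    mosaic = list(
      chrom = "chr1",
      lengths = c(20000, 15000, 25000),
      groups = c("A", "B", "A")
    ),
    tags = list(k = 31, min_group_freq = 1),
    painting = list(window = 2000, min_hits = 5, ratio = 0.75),
    genes = list(t_years = 7.8e6, rate = 4.5e-9, n_genes = 100,
                 codons_per_gene = 300),
    synteny = list(n_genes = 90, genes_per_chrom = 45, max_gap = 10,
                   min_block = 5, min_shared = 20),
    support = list(
      tree = "(((A:1.1e6,B:1.1e6):1.1e6,C:2.2e6):2.2e6,(D:2.2e6,E:2.2e6):2.2e6);",
      n_genes = 30, gene_length = 3000, rate = 4.5e-9
    )
  )
}

#' Run the whole pipeline end-to-end on synthetic data
#'
#' Demonstrates and exercises every stage with known truth: simulate
#' ancestral panels, build a two-donor mosaic, discover diagnostic tags and
#' paint the mosaic (scored against the generator's truth), simulate
#' ortholog codon alignments and recover the divergence time from median
#' Ks, chain synthetic gene anchors into synteny blocks and build ortholog
#' groups across an inversion, and compute gene-tree branch support for a
#' five-taxon species tree. Deterministic given `config$seed`.
#'
#' @param config Configuration list from [demo_config()].
#' @param out_dir Optional directory; when given, truth and painting BEDs,
#'   window/Ks/support TSVs and a JSON report are written there.
#' @return A list of class `musaic_demo` with per-stage results and a
#'   `report` tibble of record counts and runtimes.
#' @export
run_demo_pipeline <- function(config = demo_config(), out_dir = NULL) {
  if (is.null(config$seed)) abort("config$seed is required")
  if (length(config$mosaic$groups) < 1) abort("config$mosaic$groups must name donor groups")
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    res
  }

  # 1. ancestral panels
  panel_sim <- stage("panels", {
    spec <- group_phylogeny_spec(
      config$panel$tree, rate = config$panel$rate,
      length = config$panel$length, n_per_group = config$panel$n_per_group,
      within_group_years = config$panel$within_group_years,
      seed = derive_seed(config$seed, 1)
    )
    simulate_ancestral_groups(spec)
  })

  # 2. mosaic + painting
  mosaic <- stage("mosaic", {
    build_mosaic_genome(panel_sim, mosaic_spec(
      config$mosaic$chrom, config$mosaic$lengths, config$mosaic$groups
    ))
  })
  tag_cfg <- tag_config(k = config$tags$k, min_group_freq = config$tags$min_group_freq)
  tags <- stage("tags", discover_tags(panel_sim, tag_cfg))
  paint_cfg <- painting_config(
    window = config$painting$window, min_hits = config$painting$min_hits,
    ratio = config$painting$ratio
  )
  painting <- stage("painting", paint_assembly(mosaic$seq, tags, tag_cfg, paint_cfg))
  accuracy <- painting_accuracy(painting, mosaic$truth)

  # 3. Ks clock
  ks <- stage("ks", {
    pairs <- sample_gene_pairs(
      config$genes$t_years, rate = config$genes$rate,
      n_genes = config$genes$n_genes,
      codons_per_gene = config$genes$codons_per_gene,
      seed = derive_seed(config$seed, 2)
    )
    ng86(pairs$seq1, pairs$seq2, pairs$gene)
  })
  mks <- median_ks(ks)
  t_hat <- divergence_time(mks$median_ks, config$genes$rate)

  # 4. synteny across an inversion
  synteny <- stage("synteny", {
    n <- config$synteny$n_genes
    per <- config$synteny$genes_per_chrom
    ref <- tibble(
      gene = sprintf("g%03d", seq_len(n)),
      chrom = rep(c("r1", "r2"), each = per),
      rank = rep(seq_len(per), 2),
      mid = rep(seq_len(per), 2) * 10000
    )
    inv <- ref
    third <- floor(per / 3)
    idx <- (third + 1):(2 * third) # invert middle third of chromosome 1
    inv$rank[idx] <- rev(inv$rank[idx])
    inv <- arrange(inv, .data$chrom, .data$rank) |>
      mutate(mid = .data$rank * 10000)
    blocks_b <- chain_blocks(anchor_hits(ref, ref),
      max_gap = config$synteny$max_gap, min_block = config$synteny$min_block)
    blocks_c <- chain_blocks(anchor_hits(ref, inv),
      max_gap = config$synteny$max_gap, min_block = config$synteny$min_block)
    groups <- build_ortholog_groups(
      list(asmB = blocks_b, asmC = blocks_c),
      min_shared = config$synteny$min_shared
    )
    list(blocks = list(asmB = blocks_b, asmC = blocks_c), groups = groups,
         dots = dotplot_data(anchor_hits(ref, inv)))
  })

  # 5. gene trees and branch support
  support <- stage("support", {
    sp_tree <- ape::read.tree(text = config$support$tree)
    gene_alns <- lapply(seq_len(config$support$n_genes), function(i) {
      spec <- group_phylogeny_spec(
        config$support$tree, rate = config$support$rate,
        length = config$support$gene_length, n_per_group = 1,
        within_group_years = 0, seed = derive_seed(config$seed, 100 + i)
      )
      sim <- simulate_ancestral_groups(spec)
      setNames(sim$group_seqs, names(sim$group_seqs))
    })
    gene_trees <- lapply(gene_alns, function(a) nj_tree(jc_distance_matrix(a)))
    global <- nj_tree(jc_distance_matrix(gene_alns, concatenate = TRUE))
    tab <- branch_support(global, gene_trees)
    list(global = global, gene_trees = gene_trees, table = tab)
  })

  report <- tibble(
    stage = names(timings),
    seconds = round(unlist(timings), 3),
    records = c(
      panels = sum(lengths(panel_sim$panels)),
      mosaic = nrow(mosaic$truth),
      tags = nrow(tags),
      painting = nrow(painting$segments),
      ks = nrow(ks),
      synteny = nrow(synteny$groups),
      support = nrow(support$table)
    )[names(timings)]
  )

  out <- structure(
    list(
      panel_sim = panel_sim, mosaic = mosaic, tags = tags,
      painting = painting, painting_accuracy = accuracy,
      ks = ks, median_ks = mks, divergence_time_years = t_hat,
      synteny = synteny, support = support, report = report,
      config = config
    ),
    class = "musaic_demo"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_bed(mosaic$truth, file.path(out_dir, "mosaic_truth.bed"))
    seg <- painting$segments |>
      mutate(label = ifelse(is.na(.data$label), "NA", .data$label))
    write_bed(seg, file.path(out_dir, "painting.bed"))
    readr::write_tsv(painting$windows, file.path(out_dir, "windows.tsv"))
    readr::write_tsv(ks, file.path(out_dir, "ks_per_gene.tsv"))
    readr::write_tsv(support$table |> select(-"side"),
                     file.path(out_dir, "branch_support.tsv"))
    ape::write.tree(annotate_support(support$global, support$table),
                    file.path(out_dir, "global_tree.nwk"))
    jsonlite::write_json(
      list(
        painting_accuracy = accuracy$accuracy,
        median_ks = mks$median_ks,
        divergence_time_my = t_hat / 1e6,
        fractions = setNames(as.list(painting$fractions$fraction),
                             painting$fractions$label)
      ),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA
    )
  }
  out
}

#' @export
print.musaic_demo <- function(x, ...) {
  cat("<musaic_demo>\n")
  cat(sprintf("  painting accuracy: %.4f\n", x$painting_accuracy$accuracy))
  cat(sprintf("  median Ks: %.4f -> divergence %.2f My\n",
              x$median_ks$median_ks, x$divergence_time_years / 1e6))
  cat(sprintf("  ortholog groups: %d\n", nrow(x$synteny$groups)))
  cat(sprintf("  mean branch support: %.3f\n", mean(x$support$table$support)))
  print(x$report)
  invisible(x)
}
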