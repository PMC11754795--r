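#' Tidy an ancestry painting into its segment table
#'
#' @param x An `ancestry_painting` from [paint_assembly()].
#' @param ... Unused.
#' @return Tibble of ancestry segments (chrom, start, end, label,
#'   n_windows).
#' @exportS3Method generics::tidy
tidy.ancestry_painting <- function(x, ...) x$segments

#' One-row summary of an ancestry painting
#'
#' @param x An `ancestry_painting`.
#' @param ... Unused.
#' @return One-row tibble: `n_chroms`, `bases`, `n_segments`,
#'   `na_fraction` (fraction of bases with no attributable origin).
#' @exportS3Method generics::glance
glance.ancestry_painting <- function(x, ...) {
  na_frac <- x$fractions$fraction[x$fractions$label == "NA"]
  tibble(
    n_chroms = length(unique(x$segments$chrom)),
    bases = sum(x$segments$end - x$segments$start),
    n_segments = nrow(x$segments),
    na_fraction = if (length(na_frac)) na_frac else 0
  )
}

#' @exportS3Method generics::tidy
tidy.mosaic_genome <- function(x, ...) x$truth

#' @exportS3Method generics::tidy
tidy.trio_sim <- function(x, ...) x$phase

#' @exportS3Method generics::tidy
tidy.rearranged_assembly <- function(x, ...) x$blocks

#' @export
print.ancestry_painting <- function(x, ...) {
  cat(sprintf(
    "<ancestry_painting> %d chromosome(s), %d segment(s)\n",
    length(unique(x$segments$chrom)), nrow(x$segments)
  ))
  print(x$fractions)
  invisible(x)
}

#' Ideogram plot of an ancestry painting
#'
#' Draws each chromosome as a horizontal bar whose segments are coloured by
#' assigned ancestry; unattributable (`NA`) regions are grey.
#'
#' @param object An `ancestry_painting`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ancestry_painting <- function(object, ...) {
  seg <- object$segments |>
    mutate(label = ifelse(is.na(.data$label), "NA", .data$label))
  ggplot2::ggplot(seg) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start / 1e3, xmax = .data$end / 1e3,
      ymin = 0, ymax = 1, fill = .data$label
    )) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$chrom), switch = "y") +
    ggplot2::scale_fill_brewer(palette = "Set2", na.value = "grey80") +
    ggplot2::labs(x = "position (kb)", y = NULL, fill = "ancestry") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.y = ggplot2::element_blank(),
      panel.grid = ggplot2::element_blank(),
      strip.text.y.left = ggplot2::element_text(angle = 0)
    )
}

#' Dot plot of best gene hits between two assemblies
#'
#' @param object A `dotplot_data` tibble from [dotplot_data()].
#' @param ... Unused.
#' @return A ggplot object; diagonal runs are collinear synteny,
#'   anti-diagonal runs inversions.
#' @exportS3Method ggplot2::autoplot
autoplot.dotplot_data <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x / 1e3, y = .data$y / 1e3)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$chrom_b), cols = ggplot2::vars(.data$chrom_a),
      scales = "free"
    ) +
    ggplot2::labs(x = "reference (kb)", y = "target (kb)") +
    ggplot2::theme_bw()
}

#' Histogram of per-gene Ks with the median marked
#'
#' @param ks_tbl Tibble from [ng86()].
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_ks_distribution <- function(ks_tbl, bins = 40) {
  usable <- filter(ks_tbl, !is.na(.data$dS))
  ggplot2::ggplot(usable, ggplot2::aes(x = .data$dS)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = median(usable$dS), linetype = 2) +
    ggplot2::labs(x = "Ks (synonymous substitutions per synonymous site)",
                  y = "genes") +
    ggplot2::theme_minimal()
}
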