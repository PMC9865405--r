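#' Genome map of clusters and hotspots
#'
#' Draws each chromosome as a grey backbone with cluster intervals colored
#' by trait (QTL clusters above, QTN clusters below the backbone) and
#' hotspot extents as black bars.
#'
#' @param clusters Cluster tibble (`trait`, `kind`, `chrom`, `start`,
#'   `end`).
#' @param hotspots Optional hotspot tibble.
#' @param build Genome build (default [b73_v4_build()]).
#' @return A ggplot object.
#' @export
plot_genome_map <- function(clusters, hotspots = NULL,
                            build = b73_v4_build()) {
  lev <- rev(build$chrom)
  backbone <- dplyr::mutate(build, y = as.numeric(factor(.data$chrom, lev)))
  cl <- clusters |>
    dplyr::mutate(
      y = as.numeric(factor(.data$chrom, lev)) +
        ifelse(.data$kind == "QTL", 0.22, -0.22)
    )
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = backbone,
      ggplot2::aes(x = 0, xend = .data$length / 1e6, y = .data$y,
                   yend = .data$y),
      linewidth = 1.5, colour = "grey80", lineend = "round") +
    ggplot2::geom_segment(
      data = cl,
      ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                   y = .data$y, yend = .data$y, colour = .data$trait),
      linewidth = 3, alpha = 0.8) +
    ggplot2::scale_y_continuous(breaks = seq_along(lev), labels = lev) +
    ggplot2::labs(x = "position (Mb)", y = "chromosome", colour = "trait") +
    ggplot2::theme_minimal()
  if (!is.null(hotspots) && nrow(hotspots)) {
    hs <- dplyr::mutate(hotspots,
                        y = as.numeric(factor(.data$chrom, lev)))
    p <- p + ggplot2::geom_segment(
      data = hs,
      ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                   y = .data$y, yend = .data$y),
      linewidth = 1.2, colour = "black")
  }
  p
}

#' @rdname plot_genome_map
#' @param object A `kernel_run` object.
#' @param ... Unused.
#' @method autoplot kernel_run
#' @export
autoplot.kernel_run <- function(object, ...) {
  plot_genome_map(object$clusters, object$hotspots, object$build)
}

#' Bar chart of enriched GO terms
#'
#' @param object A `go_enrichment` tibble from [enrich_go()].
#' @param top Maximal number of terms shown (by p-value).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot go_enrichment
#' @export
autoplot.go_enrichment <- function(object, top = 15, ...) {
  d <- utils::head(tibble::as_tibble(object), top)
  d$label <- ifelse(is.na(d$term_name), d$term_id, d$term_name)
  ggplot2::ggplot(d, ggplot2::aes(
    x = -log10(.data$fdr),
    y = stats::reorder(.data$label, -.data$fdr),
    fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "-log10 FDR", y = NULL, fill = "significant") +
    ggplot2::theme_minimal()
}

#' Histogram of kernel expression bins
#'
#' @param bins Output of [bin_expression()].
#' @param which `"fpkm"` or `"ratio"`.
#' @return A ggplot object.
#' @export
plot_expression_bins <- function(bins, which = c("fpkm", "ratio")) {
  which <- match.arg(which)
  d <- bins[[which]]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = if (which == "fpkm") "MaxExpKernel (FPKM)"
          else "MaxExp / MaxExpKernel",
      y = "genes") +
    ggplot2::theme_minimal()
}
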