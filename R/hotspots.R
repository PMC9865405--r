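#' Integrate QTL and QTN clusters into consensus hotspots
#'
#' Clusters of all four traits and both kinds are pooled; a consensus
#' hotspot is a connected component of cluster-interval overlap containing
#' at least `min_clusters` clusters (default 3). The hotspot extent is the
#' union span of its member clusters, and hotspots are numbered `HS01`,
#' `HS02`, ... genome-wide in (chromosome, start) order.
#'
#' @param clusters Tibble of named clusters (rows from
#'   [find_qtl_clusters()] and/or [find_qtn_clusters()], row-bound).
#' @param min_clusters Minimum co-localized clusters per hotspot.
#' @param build Optional genome build (also fixes chromosome order for
#'   numbering).
#' @return Tibble of hotspots: `hotspot`, `chrom`, `start`, `end`,
#'   `n_clusters`, and a `clusters` list-column of member cluster names.
#' @export
integrate_hotspots <- function(clusters, min_clusters = 3, build = NULL) {
  stopifnot(min_clusters >= 1)
  need <- c("name", "chrom", "start", "end")
  if (!all(need %in% names(clusters))) {
    stop("clusters need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  empty <- tibble::tibble(hotspot = character(), chrom = character(),
                          start = double(), end = double(),
                          n_clusters = integer(), clusters = list())
  if (nrow(clusters) == 0) return(empty)
  validate_intervals(clusters, build)
  check_unique(clusters$name, "cluster name")

  comp <- merge_overlapping(clusters)$components
  hs <- dplyr::filter(comp, .data$n_members >= min_clusters)
  if (nrow(hs) == 0) return(empty)
  hs$clusters <- lapply(hs$members, function(i) clusters$name[i])
  hs <- hs |>
    dplyr::arrange(factor(.data$chrom, chrom_levels(.data$chrom, build)),
                   .data$start)
  tibble::tibble(
    hotspot = sprintf("HS%02d", seq_len(nrow(hs))),
    chrom = hs$chrom, start = hs$start, end = hs$end,
    n_clusters = hs$n_members, clusters = hs$clusters
  )
}

#' Co-locate cloned genes with hotspots
#'
#' A gene is assigned to a hotspot when its span overlaps the hotspot
#' interval by at least 1 nt on the same chromosome. Genes without
#' base-pair coordinates (e.g. entries recording only the chromosome) are
#' skipped with a warning, since containment cannot be decided.
#'
#' @param hotspots Tibble from [integrate_hotspots()].
#' @param genes Tibble of gene records with `name`, `chrom`, `start`,
#'   `end`.
#' @return `hotspots` with added `n_genes` and a `genes` list-column of
#'   co-located gene names.
#' @export
assign_hotspot_genes <- function(hotspots, genes) {
  stopifnot(all(c("hotspot", "chrom", "start", "end") %in% names(hotspots)))
  stopifnot("name" %in% names(genes))
  if (!all(c("chrom", "start", "end") %in% names(genes))) {
    genes$chrom <- genes$chrom %||% NA_character_
    genes$start <- NA_real_
    genes$end <- NA_real_
  }
  usable <- !is.na(genes$start) & !is.na(genes$end) & !is.na(genes$chrom)
  if (any(!usable)) {
    warning(sum(!usable), " gene(s) lack coordinates and were skipped: ",
            paste(utils::head(genes$name[!usable], 3), collapse = ", "),
            if (sum(!usable) > 3) ", ..." else "", call. = FALSE)
  }
  g <- genes[usable, ]
  if (nrow(g)) validate_intervals(g)
  hits <- lapply(seq_len(nrow(hotspots)), function(i) {
    sel <- g$chrom == hotspots$chrom[i] &
      g$start <= hotspots$end[i] & g$end >= hotspots$start[i]
    g$name[sel]
  })
  hotspots$n_genes <- lengths(hits)
  hotspots$genes <- hits
  hotspots
}

#' Summarize a hotspot collection
#'
#' Descriptive statistics of a set of consensus hotspots: total count,
#' hotspots per chromosome (including zero-count chromosomes when a build
#' is supplied), the distribution of member-cluster counts, the number of
#' hotspots with at least five member clusters, the min/max member count,
#' and — when gene co-location is available — how many hotspots carry at
#' least one cloned gene.
#'
#' @param hotspots Tibble with at least `hotspot`, `chrom`, `start`, `end`,
#'   `n_clusters`; optionally `n_genes`. Computed hotspots
#'   ([integrate_hotspots()]) and transcribed published tables
#'   ([table2_hotspots()]) both work.
#' @param build Optional genome build fixing the chromosome universe.
#' @return An object of class `hotspot_summary`: a list with elements
#'   `n_hotspots`, `per_chromosome` (tibble `chrom`, `n`),
#'   `member_distribution` (tibble `n_clusters`, `n`), `n_ge5_clusters`,
#'   `min_members`, `max_members`, `n_with_genes`, `n_without_genes`,
#'   `span_mb` (tibble `hotspot`, `span_mb` at one-decimal precision).
#' @examples
#' summarize_hotspots(table2_hotspots(), b73_v4_build())
#' @export
summarize_hotspots <- function(hotspots, build = NULL) {
  stopifnot(all(c("chrom", "n_clusters") %in% names(hotspots)))
  lev <- chrom_levels(hotspots$chrom, build)
  per_chrom <- hotspots |>
    dplyr::count(chrom = factor(.data$chrom, lev), .drop = FALSE,
                 name = "n") |>
    dplyr::mutate(chrom = as.character(.data$chrom))
  member_dist <- dplyr::count(hotspots, .data$n_clusters, name = "n")
  has_genes <- "n_genes" %in% names(hotspots)
  spans <- if (all(c("hotspot", "start", "end") %in% names(hotspots))) {
    tibble::tibble(hotspot = hotspots$hotspot,
                   span_mb = span_mb(hotspots$start, hotspots$end, 1))
  } else {
    tibble::tibble(hotspot = character(), span_mb = double())
  }
  structure(list(
    n_hotspots = nrow(hotspots),
    per_chromosome = per_chrom,
    member_distribution = member_dist,
    n_ge5_clusters = sum(hotspots$n_clusters >= 5),
    min_members = if (nrow(hotspots)) min(hotspots$n_clusters) else NA_integer_,
    max_members = if (nrow(hotspots)) max(hotspots$n_clusters) else NA_integer_,
    n_with_genes = if (has_genes) sum(hotspots$n_genes >= 1) else NA_integer_,
    n_without_genes = if (has_genes) sum(hotspots$n_genes == 0) else NA_integer_,
    span_mb = spans
  ), class = "hotspot_summary")
}

#' @export
print.hotspot_summary <- function(x, ...) {
  cat("Hotspot summary:", x$n_hotspots, "hotspots\n")
  occ <- x$per_chromosome[x$per_chromosome$n > 0, ]
  cat("  per chromosome:",
      paste0(occ$chrom, ":", occ$n, collapse = "  "), "\n")
  cat("  member clusters: min", x$min_members, "/ max", x$max_members,
      "/", x$n_ge5_clusters, "hotspot(s) with >= 5\n")
  if (!is.na(x$n_with_genes)) {
    cat("  cloned genes:", x$n_with_genes, "hotspot(s) with >= 1,",
        x$n_without_genes, "without\n")
  }
  invisible(x)
}

#' Flatten list-columns for TSV output
#'
#' Collapses the `member_ids` / `clusters` / `genes` list-columns of
#' cluster and hotspot tibbles into comma-separated strings so they round-
#' trip through [write_hotspot_table()] and friends.
#'
#' @param x Cluster or hotspot tibble.
#' @return The tibble with list-columns collapsed to character.
#' @export
flatten_members <- function(x) {
  for (col in intersect(c("member_ids", "clusters", "genes"), names(x))) {
    if (is.list(x[[col]])) {
      x[[col]] <- vapply(x[[col]], paste, character(1), collapse = ",")
    }
  }
  x
}
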