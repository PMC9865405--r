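#' Merge overlapping intervals into connected components
#'
#' Computes, per chromosome, the connected components of the pairwise
#' interval-overlap graph (the merge behaviour of `bedtools merge` at
#' distance 0 in 1-based inclusive coordinates): intervals that overlap by
#' at least 1 nt belong to one component, and overlap is chained
#' transitively, so a chain a–b, b–c joins a and c even if a and c are
#' disjoint. Intervals that merely touch (`end + 1 == start`) are NOT
#' merged. A sweep over start-sorted intervals implements this in
#' O(n log n).
#'
#' @param x Data frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive). Extra columns pass through.
#' @return A list with two tibbles: `members` — the input rows (original
#'   order preserved, with `.row` index) annotated with a `component` id —
#'   and `components` — one row per component with the merged span
#'   (`chrom`, `start` = min start, `end` = max end), `n_members`, and a
#'   `members` list-column of input row indices. Components are sorted by
#'   (chrom, start) and pairwise disjoint.
#' @examples
#' x <- tibble::tibble(chrom = "1", start = c(1, 8, 18), end = c(10, 20, 30))
#' merge_overlapping(x)$components
#' @export
merge_overlapping <- function(x) {
  validate_intervals(x)
  x <- tibble::as_tibble(x)
  x$.row <- seq_len(nrow(x))
  if (nrow(x) == 0) {
    comp <- tibble::tibble(component = integer(), chrom = character(),
                           start = double(), end = double(),
                           n_members = integer(), members = list())
    return(list(members = dplyr::mutate(x, component = integer(0)),
                components = comp))
  }
  ord <- order(x$chrom, x$start, x$end)
  xs <- x[ord, ]
  comp_local <- unlist(lapply(split(xs, factor(xs$chrom, unique(xs$chrom))),
                              function(g) {
    # new component whenever the running max end falls short of the next start
    hi <- cummax(g$end)
    cumsum(c(TRUE, g$start[-1] > hi[-length(hi)]))
  }), use.names = FALSE)
  # make ids unique across chromosomes
  key <- paste(xs$chrom, comp_local)
  comp_id <- match(key, unique(key))
  xs$component <- comp_id

  components <- xs |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(
      chrom = .data$chrom[1],
      start = min(.data$start),
      end = max(.data$end),
      n_members = dplyr::n(),
      members = list(.data$.row),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chrom, .data$start)

  members <- xs[order(xs$.row), ]
  list(members = members, components = components)
}

#' Name clusters by trait, kind and chromosome
#'
#' Applies the field naming convention `Trait-qCL<chr>-<i>` for QTL
#' clusters and `Trait-gCL<chr>-<i>` for QTN clusters, where the running
#' index `i` restarts at 1 for each trait on each chromosome, counting
#' clusters in order of start position. Thus the second KW QTL cluster on
#' chromosome 1 is `KW-qCL1-2`.
#'
#' @param clusters Tibble with columns `trait`, `kind` (`"QTL"` or
#'   `"QTN"`), `chrom`, `start`.
#' @return The tibble sorted by (trait, chrom, start) with a `name` column
#'   (first), deterministically.
#' @export
name_clusters <- function(clusters) {
  stopifnot(all(c("trait", "kind", "chrom", "start") %in% names(clusters)))
  stopifnot(all(clusters$kind %in% c("QTL", "QTN")))
  tag <- c(QTL = "qCL", QTN = "gCL")
  clusters |>
    dplyr::arrange(.data$trait, .data$chrom, .data$start) |>
    dplyr::group_by(.data$trait, .data$kind, .data$chrom) |>
    dplyr::mutate(name = paste0(.data$trait, "-", tag[.data$kind],
                                .data$chrom, "-", dplyr::row_number())) |>
    dplyr::ungroup() |>
    dplyr::relocate("name")
}

#' Call trait-specific QTL clusters
#'
#' A QTL cluster is a genomic region where at least `min_members` projected
#' QTLs of one trait co-localize. Co-localization is taken as connected
#' components of pairwise overlap (see [merge_overlapping()]), computed per
#' trait per chromosome; the cluster span is the union extent
#' (min start to max end) of its members.
#'
#' @param projected Tibble of projected QTLs with columns `qtl_id`,
#'   `trait`, `chrom`, `start`, `end` (see [projected_qtls()]).
#' @param min_members Minimum co-localized QTLs per cluster (default 3).
#' @param build Optional genome build for interval validation.
#' @return Tibble of clusters sorted by (chrom, start) with columns `name`,
#'   `trait`, `kind` (`"QTL"`), `chrom`, `start`, `end`, `n_members` and a
#'   `member_ids` list-column of QTL ids.
#' @export
find_qtl_clusters <- function(projected, min_members = 3, build = NULL) {
  stopifnot(min_members >= 1)
  need <- c("qtl_id", "trait", "chrom", "start", "end")
  if (!all(need %in% names(projected))) {
    stop("projected QTLs need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(projected)) validate_intervals(projected, build)
  check_trait(projected$trait, "projected QTL")

  per_trait <- lapply(split(projected, projected$trait), function(g) {
    mg <- merge_overlapping(g)
    comp <- dplyr::filter(mg$components, .data$n_members >= min_members)
    comp$member_ids <- lapply(comp$members, function(i) g$qtl_id[i])
    comp$trait <- if (nrow(comp)) g$trait[1] else character(0)
    comp
  })
  out <- dplyr::bind_rows(per_trait)
  if (nrow(out) == 0) {
    return(tibble::tibble(name = character(), trait = character(),
                          kind = character(), chrom = character(),
                          start = double(), end = double(),
                          n_members = integer(), member_ids = list()))
  }
  out$kind <- "QTL"
  out |>
    name_clusters() |>
    dplyr::arrange(factor(.data$chrom, chrom_levels(.data$chrom, build)),
                   .data$start, .data$trait) |>
    dplyr::select("name", "trait", "kind", "chrom", "start", "end",
                  "n_members", "member_ids")
}
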