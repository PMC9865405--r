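#' Project QTLs onto the physical map via flanking markers
#'
#' Each literature QTL is delimited by two flanking markers; its physical
#' interval is the span between the markers' positions on the reference
#' genome. A QTL is rejected (not projected) when a marker name is absent
#' from the record (`missing-marker`), names a marker that is not in the
#' map (`unmapped-marker`), or when the two markers sit on different
#' chromosomes (`cross-chromosome`). If the left marker lies physically
#' right of the right marker the endpoints are swapped silently —
#' genetic-map orientation frequently disagrees with the physical map.
#' Two identical marker positions give a degenerate 1-nt interval.
#'
#' @param qtl Tibble of QTL records (see [read_qtl_table()]).
#' @param markers Tibble marker map (see [read_marker_map()]).
#' @param build Optional genome build for validating the marker map.
#' @return A projection report: the input tibble, row order preserved, with
#'   added columns `chrom`, `start`, `end` (NA for rejected records) and
#'   `status` (`"projected"` or a rejection reason). Use [projected_qtls()]
#'   and [rejected_qtls()] to split it.
#' @examples
#' qtl <- tibble::tibble(qtl_id = "q1", trait = "KL",
#'                       left_marker = "m1", right_marker = "m2")
#' markers <- tibble::tibble(marker = c("m1", "m2"), chrom = "2",
#'                           position = c(5000, 1000))
#' project_qtls(qtl, markers)
#' @export
project_qtls <- function(qtl, markers, build = NULL) {
  stopifnot(is.data.frame(qtl), is.data.frame(markers))
  need <- c("qtl_id", "trait", "left_marker", "right_marker")
  if (!all(need %in% names(qtl))) {
    stop("QTL table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(build)) {
    validate_intervals(
      tibble::tibble(chrom = markers$chrom, start = markers$position,
                     end = markers$position),
      build
    )
  }
  check_unique(markers$marker, "marker name")

  li <- match(qtl$left_marker, markers$marker)
  ri <- match(qtl$right_marker, markers$marker)
  blank <- function(m) is.na(m) | !nzchar(trimws(m))
  miss <- blank(qtl$left_marker) | blank(qtl$right_marker)
  unmapped <- !miss & (is.na(li) | is.na(ri))
  lchrom <- markers$chrom[li]
  rchrom <- markers$chrom[ri]
  cross <- !miss & !unmapped & lchrom != rchrom

  status <- rep("projected", nrow(qtl))
  status[cross] <- "cross-chromosome"
  status[unmapped] <- "unmapped-marker"
  status[miss] <- "missing-marker"

  ok <- status == "projected"
  lpos <- markers$position[li]
  rpos <- markers$position[ri]
  out <- qtl
  out$chrom <- ifelse(ok, lchrom, NA_character_)
  out$start <- ifelse(ok, pmin(lpos, rpos), NA_real_)
  out$end <- ifelse(ok, pmax(lpos, rpos), NA_real_)
  out$status <- status
  tibble::as_tibble(out)
}

#' Split a projection report
#'
#' @param report Output of [project_qtls()].
#' @return `projected_qtls()`: the successfully projected records with
#'   physical coordinates. `rejected_qtls()`: the rejected records with
#'   their `status` reason.
#' @export
projected_qtls <- function(report) {
  dplyr::filter(report, .data$status == "projected")
}

#' @rdname projected_qtls
#' @export
rejected_qtls <- function(report) {
  dplyr::filter(report, .data$status != "projected")
}

#' Per-trait projection counts
#'
#' @param report Output of [project_qtls()].
#' @return Tibble with one row per trait: `n_input`, `n_projected`,
#'   `n_rejected`.
#' @export
projection_counts <- function(report) {
  report |>
    dplyr::group_by(trait = .data$trait) |>
    dplyr::summarise(
      n_input = dplyr::n(),
      n_projected = sum(.data$status == "projected"),
      n_rejected = sum(.data$status != "projected"),
      .groups = "drop"
    )
}
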