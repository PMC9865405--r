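#' Call trait-specific QTN clusters by sliding-window density
#'
#' A QTN cluster is a region where a sliding window of `window` nt (default
#' 5 Mb) harbors at least `min_count` QTNs (default 5) of one trait.
#' Windows are anchored at the QTN positions themselves — a window boundary
#' only matters at a data point, so anchoring is equivalent to sliding at
#' 1-nt steps without choosing an arbitrary stride. A window anchored at
#' position p covers `[p, p + window]` inclusively, i.e. positions with
#' `p_last - p_first <= window` qualify together. Overlapping qualifying
#' windows are chained into one region, and the reported cluster span is
#' trimmed to the extremal member positions, so chained clusters can exceed
#' one window length.
#'
#' @param qtns Tibble of QTN records with `qtn_id`, `trait`, `chrom`,
#'   `position` (see [read_qtn_table()]).
#' @param window Window length in nt (default 5e6).
#' @param min_count Minimum QTNs within one window (default 5).
#' @param build Optional genome build for validation.
#' @return Tibble of clusters sorted by (chrom, start), columns as in
#'   [find_qtl_clusters()] but `kind = "QTN"`; cluster members are all QTNs
#'   inside the chained region.
#' @export
find_qtn_clusters <- function(qtns, window = 5e6, min_count = 5,
                              build = NULL) {
  stopifnot(window > 0, min_count >= 1)
  need <- c("qtn_id", "trait", "chrom", "position")
  if (!all(need %in% names(qtns))) {
    stop("QTN table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  check_trait(qtns$trait, "QTN")
  if (!is.null(build) && nrow(qtns)) {
    validate_intervals(
      tibble::tibble(chrom = qtns$chrom, start = qtns$position,
                     end = qtns$position),
      build
    )
  }

  groups <- split(qtns, list(qtns$trait, qtns$chrom), drop = TRUE)
  out <- dplyr::bind_rows(lapply(groups, function(g) {
    ord <- order(g$position)
    p <- g$position[ord]
    id <- g$qtn_id[ord]
    n <- length(p)
    # last index reachable from each anchor within one window length
    jmax <- findInterval(p + window, p)
    qual <- (jmax - seq_len(n) + 1) >= min_count
    if (!any(qual)) return(NULL)
    # chain qualifying windows [p_i, p_i + window] that overlap in position
    ws <- p[qual]
    we <- p[qual] + window
    brk <- cumsum(c(TRUE, ws[-1] > cummax(we)[-sum(qual)]))
    dplyr::bind_rows(lapply(split(seq_along(ws), brk), function(ii) {
      lo <- min(ws[ii])
      hi <- max(we[ii])
      inside <- p >= lo & p <= hi
      tibble::tibble(trait = g$trait[1], kind = "QTN", chrom = g$chrom[1],
                     start = min(p[inside]), end = max(p[inside]),
                     n_members = sum(inside), member_ids = list(id[inside]))
    }))
  }))
  if (is.null(out) || nrow(out) == 0) {
    return(tibble::tibble(name = character(), trait = character(),
                          kind = character(), chrom = character(),
                          start = double(), end = double(),
                          n_members = integer(), member_ids = list()))
  }
  out |>
    name_clusters() |>
    dplyr::arrange(factor(.data$chrom, chrom_levels(.data$chrom, build)),
                   .data$start, .data$trait) |>
    dplyr::select("name", "trait", "kind", "chrom", "start", "end",
                  "n_members", "member_ids")
}
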