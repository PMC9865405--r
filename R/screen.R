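#' Summarize expression by overall and kernel maxima
#'
#' For each gene, computes `max_exp` (maximal FPKM over all tissues),
#' `max_exp_kernel` (maximal FPKM over the configured kernel tissues) and
#' their ratio `max_exp / max_exp_kernel` — the kernel-specificity measure:
#' a ratio of exactly 1 means the gene is expressed at its highest level in
#' kernels. The ratio is undefined (NA) when the kernel maximum is 0.
#' Tissues absent from a gene's rows count as 0 FPKM.
#'
#' @param expression Long tibble `gene_id`, `tissue`, `fpkm`
#'   (see [read_expression_table()]).
#' @param kernel_tissues Character vector naming the tissues counted as
#'   kernel; must be non-empty and present in the data.
#' @return Tibble `gene_id`, `max_exp`, `max_exp_kernel`, `ratio`.
#' @export
expression_summary <- function(expression, kernel_tissues) {
  stopifnot(all(c("gene_id", "tissue", "fpkm") %in% names(expression)))
  if (length(kernel_tissues) == 0) {
    stop("kernel tissue set must not be empty", call. = FALSE)
  }
  if (any(expression$fpkm < 0, na.rm = TRUE)) {
    stop("FPKM values must be >= 0", call. = FALSE)
  }
  if (!any(expression$tissue %in% kernel_tissues) && nrow(expression)) {
    stop("none of the kernel tissues (",
         paste(kernel_tissues, collapse = ", "),
         ") occur in the expression table", call. = FALSE)
  }
  expression |>
    dplyr::group_by(gene_id = .data$gene_id) |>
    dplyr::summarise(
      max_exp = max(.data$fpkm, 0),
      max_exp_kernel = max(.data$fpkm[.data$tissue %in% kernel_tissues], 0),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ratio = dplyr::if_else(.data$max_exp_kernel > 0,
                             .data$max_exp / .data$max_exp_kernel, NA_real_)
    )
}

#' Filter candidate genes by kernel-expression criteria
#'
#' A gene passes when `max_exp_kernel >= min_kernel_fpkm` AND its
#' MaxExp/MaxExpKernel ratio is defined and `<= max_ratio`; both bounds are
#' inclusive. Genes listed in `genes` but absent from the summaries are
#' tallied separately as `no_data` rather than silently dropped.
#'
#' @param summaries Tibble from [expression_summary()].
#' @param min_kernel_fpkm Minimum kernel FPKM (default 50).
#' @param max_ratio Maximal allowed ratio (default 3).
#' @param genes Optional character vector of all gene ids under study, used
#'   to surface genes lacking expression data.
#' @return Tibble `gene_id`, `max_exp`, `max_exp_kernel`, `ratio`, `status`
#'   with status one of `"pass"`, `"fail"`, `"no_data"`.
#' @export
filter_candidates <- function(summaries, min_kernel_fpkm = 50, max_ratio = 3,
                              genes = NULL) {
  stopifnot(all(c("gene_id", "max_exp", "max_exp_kernel", "ratio")
                %in% names(summaries)))
  out <- summaries |>
    dplyr::mutate(status = dplyr::if_else(
      .data$max_exp_kernel >= min_kernel_fpkm & !is.na(.data$ratio) &
        .data$ratio <= max_ratio, "pass", "fail"))
  if (!is.null(genes)) {
    missing <- setdiff(genes, summaries$gene_id)
    out <- dplyr::bind_rows(out, tibble::tibble(
      gene_id = missing, max_exp = NA_real_, max_exp_kernel = NA_real_,
      ratio = NA_real_, status = "no_data"))
  }
  out
}

#' Bin expression summaries into the reporting histograms
#'
#' Bins kernel expression maxima into the FPKM classes `>500`, `200-500`,
#' `100-200`, `50-100`, `20-50`, `10-20`, `<10`, and the specificity ratio
#' into `=1`, `1-3`, `3-5`, `>5`. The extreme FPKM classes are strict
#' (`>500`, `<10`), so the internal classes are lower-inclusive —
#' `[200, 500]`, `[100, 200)`, ..., `[10, 20)` — with 500 itself kept in
#' `200-500`. Ratio classes follow `=1`, `(1, 3]`, `(3, 5]`, `>5`;
#' undefined ratios (kernel maximum 0) are counted under `undefined`.
#' Both histograms conserve the input gene count.
#'
#' @param summaries Tibble from [expression_summary()].
#' @return List of two tibbles, `fpkm` and `ratio`, each with `bin`
#'   (ordered factor, high to low) and `n`.
#' @export
bin_expression <- function(summaries) {
  fpkm_labs <- c(">500", "200-500", "100-200", "50-100", "20-50", "10-20",
                 "<10")
  v <- summaries$max_exp_kernel
  fb <- factor(dplyr::case_when(
    v > 500 ~ ">500",
    v >= 200 ~ "200-500",
    v >= 100 ~ "100-200",
    v >= 50 ~ "50-100",
    v >= 20 ~ "20-50",
    v >= 10 ~ "10-20",
    TRUE ~ "<10"
  ), levels = fpkm_labs)
  ratio_labs <- c("=1", "1-3", "3-5", ">5", "undefined")
  r <- summaries$ratio
  rb <- dplyr::case_when(
    is.na(r) ~ "undefined",
    r == 1 ~ "=1",
    r <= 3 ~ "1-3",
    r <= 5 ~ "3-5",
    TRUE ~ ">5"
  )
  rb <- factor(rb, levels = ratio_labs)
  list(
    fpkm = tibble::as_tibble(as.data.frame(table(bin = fb),
                                           responseName = "n")),
    ratio = tibble::as_tibble(as.data.frame(table(bin = rb),
                                            responseName = "n"))
  )
}

#' Detect pentatricopeptide-repeat (PPR) annotations
#'
#' Case-insensitive match of "pentatricopeptide" or the standalone token
#' "PPR" in free annotation text. Token boundaries prevent substring hits
#' such as "su**ppr**essor".
#'
#' @param annotation Character vector of annotation text.
#' @return Logical vector; NA annotations give FALSE.
#' @examples
#' is_ppr_annotation(c("PPR protein, RNA editing", "suppressor protein"))
#' @export
is_ppr_annotation <- function(annotation) {
  !is.na(annotation) & (
    stringr::str_detect(annotation,
                        stringr::regex("pentatricopeptide", ignore_case = TRUE)) |
    stringr::str_detect(annotation,
                        stringr::regex("\\bPPR\\b", ignore_case = TRUE))
  )
}

#' List PPR genes per hotspot
#'
#' Looks up the genes co-located with each hotspot (the `genes` column
#' produced by [assign_hotspot_genes()] or present in a transcribed
#' hotspot table) in an annotation table and keeps those whose annotation
#' matches [is_ppr_annotation()].
#'
#' @param hotspots Hotspot tibble with a `genes` column (list of names or
#'   comma-separated string).
#' @param genes Gene tibble with `name` and `annotation`.
#' @return Tibble `hotspot`, `gene`, `annotation` — one row per PPR gene
#'   per hotspot.
#' @export
find_ppr_genes <- function(hotspots, genes) {
  stopifnot(all(c("hotspot", "genes") %in% names(hotspots)),
            all(c("name", "annotation") %in% names(genes)))
  gl <- hotspots$genes
  if (!is.list(gl)) {
    gl <- lapply(strsplit(ifelse(is.na(gl), "", gl), ","), trimws)
    gl <- lapply(gl, function(v) v[nzchar(v)])
  }
  long <- tibble::tibble(
    hotspot = rep(hotspots$hotspot, lengths(gl)),
    gene = unlist(gl, use.names = FALSE) %||% character(0)
  )
  long |>
    dplyr::left_join(dplyr::select(genes, gene = "name", "annotation"),
                     by = "gene") |>
    dplyr::filter(is_ppr_annotation(.data$annotation))
}
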