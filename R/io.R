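#' @importFrom rlang .data
NULL

# shared reader core: TSV, UTF-8, "." decimal point, strict schema.
# `types` is a named vector of readr shortcodes applied to the columns
# actually present, so optional columns parse correctly without warnings.
read_table_checked <- function(path, required, types) {
  hdr <- names(readr::read_tsv(path, n_max = 0, col_types = readr::cols(),
                               progress = FALSE))
  missing <- setdiff(required, hdr)
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  spec <- do.call(readr::cols, c(as.list(types[names(types) %in% hdr]),
                                 .default = readr::col_guess()))
  x <- readr::read_tsv(path, col_types = spec, progress = FALSE,
                       locale = readr::locale(decimal_mark = "."))
  tibble::as_tibble(x)
}

check_trait <- function(trait, what = "record") {
  bad <- which(!trait %in% kernel_traits())
  if (length(bad)) {
    stop("unknown trait ", paste0("'", unique(trait[bad]), "'", collapse = ", "),
         " (must be one of ", paste(kernel_traits(), collapse = ", "),
         ") at ", what, " row(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  invisible(trait)
}

check_unique <- function(id, what) {
  dup <- id[duplicated(id)]
  if (length(dup)) {
    stop("duplicated ", what, ": ", paste(utils::head(unique(dup), 5), collapse = ", "),
         call. = FALSE)
  }
  invisible(id)
}

#' Read a curated QTL table
#'
#' Reads the tab-separated table of literature QTLs. Required columns:
#' `qtl_id`, `trait`, `left_marker`, `right_marker`; any further columns
#' (`study`, `r_squared`, `lod`, population metadata, ...) are carried along
#' untouched. Traits must belong to the closed vocabulary
#' [kernel_traits()]; unknown traits are an error naming the offending rows,
#' never silently dropped. Flanking markers may be empty (`NA`): such QTLs
#' are later rejected by projection as `missing-marker`.
#'
#' @param path Path to a TSV file with a header row.
#' @param build Optional genome build; unused here (QTLs carry no
#'   coordinates before projection) but accepted for interface symmetry.
#' @return Tibble of QTL records.
#' @seealso [project_qtls()], [write_qtl_table()]
#' @export
read_qtl_table <- function(path, build = NULL) {
  x <- read_table_checked(
    path,
    required = c("qtl_id", "trait", "left_marker", "right_marker"),
    types = c(qtl_id = "c", trait = "c", left_marker = "c",
              right_marker = "c", study = "c")
  )
  check_trait(x$trait, "QTL")
  check_unique(x$qtl_id, "qtl_id")
  x
}

#' @rdname read_qtl_table
#' @param x Tibble of QTL records.
#' @export
write_qtl_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read a physical marker map
#'
#' Positions of genetic markers on the reference genome, used to project
#' QTLs via their flanking markers. Columns: `marker`, `chrom`, `position`.
#'
#' @inheritParams read_qtl_table
#' @return Tibble with one row per marker.
#' @export
read_marker_map <- function(path, build = NULL) {
  x <- read_table_checked(
    path, required = c("marker", "chrom", "position"),
    types = c(marker = "c", chrom = "c", position = "d")
  )
  check_unique(x$marker, "marker name")
  if (any(is.na(x$position) | x$position < 1)) {
    stop("marker positions must be >= 1", call. = FALSE)
  }
  if (!is.null(build)) {
    validate_intervals(
      tibble::tibble(chrom = x$chrom, start = x$position, end = x$position),
      build
    )
  }
  x
}

#' @rdname read_marker_map
#' @param x Tibble of markers.
#' @export
write_marker_map <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read a QTN table
#'
#' Point trait associations (GWAS hits) with physical positions. Columns:
#' `qtn_id`, `trait`, `chrom`, `position`; extra columns pass through.
#'
#' @inheritParams read_qtl_table
#' @return Tibble of QTN records.
#' @export
read_qtn_table <- function(path, build = NULL) {
  x <- read_table_checked(
    path, required = c("qtn_id", "trait", "chrom", "position"),
    types = c(qtn_id = "c", trait = "c", chrom = "c", position = "d",
              study = "c")
  )
  check_trait(x$trait, "QTN")
  check_unique(x$qtn_id, "qtn_id")
  if (!is.null(build)) {
    validate_intervals(
      tibble::tibble(chrom = x$chrom, start = x$position, end = x$position),
      build
    )
  }
  x
}

#' @rdname read_qtn_table
#' @param x Tibble of QTN records.
#' @export
write_qtn_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read a cloned-gene table
#'
#' Cloned genes with IDs, annotation text and kernel-phenotype class.
#' Required: `name`, `gene_id`. Coordinates (`chrom`, `start`, `end`) are
#' optional because published gene summaries often print only the
#' chromosome; operations that need coordinates skip genes lacking them,
#' with a warning.
#'
#' @inheritParams read_qtl_table
#' @return Tibble of gene records.
#' @export
read_gene_table <- function(path, build = NULL) {
  x <- read_table_checked(
    path, required = c("name", "gene_id"),
    types = c(name = "c", gene_id = "c", chrom = "c", start = "d",
              end = "d", annotation = "c", phenotype_class = "c")
  )
  check_unique(x$gene_id, "gene_id")
  if (all(c("chrom", "start", "end") %in% names(x)) && !is.null(build)) {
    has <- !is.na(x$start) & !is.na(x$end)
    if (any(has)) validate_intervals(x[has, ], build)
  }
  x
}

#' @rdname read_gene_table
#' @param x Tibble of gene records.
#' @export
write_gene_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read a long-format expression table
#'
#' Per-gene FPKM values by tissue in long format: columns `gene_id`,
#' `tissue`, `fpkm`. Which tissues count as "kernel" is a separate
#' configuration input (a character vector) passed to
#' [expression_summary()].
#'
#' @inheritParams read_qtl_table
#' @return Tibble with one row per gene x tissue.
#' @export
read_expression_table <- function(path, build = NULL) {
  x <- read_table_checked(
    path, required = c("gene_id", "tissue", "fpkm"),
    types = c(gene_id = "c", tissue = "c", fpkm = "d")
  )
  if (any(is.na(x$fpkm) | x$fpkm < 0)) {
    stop("FPKM values must be >= 0", call. = FALSE)
  }
  x
}

#' @rdname read_expression_table
#' @param x Tibble of expression values.
#' @export
write_expression_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read GO annotations
#'
#' Two-column gene-to-term table: `gene_id`, `term_id`. Term names, if
#' available, live in a separate two-column table (`term_id`, `term_name`).
#'
#' @inheritParams read_qtl_table
#' @return Tibble of gene/term pairs.
#' @export
read_go_annotations <- function(path, build = NULL) {
  read_table_checked(
    path, required = c("gene_id", "term_id"),
    types = c(gene_id = "c", term_id = "c", term_name = "c")
  )
}

#' @rdname read_go_annotations
#' @param x Tibble of annotations.
#' @export
write_go_annotations <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read a hotspot table
#'
#' Reads a hotspot summary table as written by [write_hotspot_table()] or
#' transcribed from a publication: columns `hotspot`, `chrom`, `start`,
#' `end`, `n_clusters`, `clusters` (comma-separated member-cluster names),
#' and optionally `n_genes`, `genes`.
#'
#' @inheritParams read_qtl_table
#' @return Tibble of hotspot rows.
#' @export
read_hotspot_table <- function(path, build = NULL) {
  x <- read_table_checked(
    path, required = c("hotspot", "chrom", "start", "end", "n_clusters"),
    types = c(hotspot = "c", chrom = "c", start = "d", end = "d",
              n_clusters = "i", clusters = "c", n_genes = "i", genes = "c")
  )
  validate_intervals(x, build)
  x
}

#' @rdname read_hotspot_table
#' @param x Tibble of hotspots.
#' @export
write_hotspot_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Write intervals as BED4
#'
#' Converts 1-based inclusive intervals to the 0-based half-open BED
#' convention: a 1-based span `start..end` becomes BED `start-1, end`.
#' Invalid intervals are refused.
#'
#' @param x Data frame with columns `chrom`, `start`, `end` and `name`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @seealso [read_bed()]
#' @export
write_bed <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end", "name") %in% names(x)))
  validate_intervals(x)
  bed <- tibble::tibble(
    chrom = x$chrom,
    start = format(x$start - 1, scientific = FALSE, trim = TRUE),
    end = format(x$end, scientific = FALSE, trim = TRUE),
    name = x$name
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a BED4 file back to 1-based inclusive intervals
#'
#' @param path Path to a BED4 file.
#' @return Tibble with `chrom`, `start`, `end` (1-based inclusive), `name`.
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name"),
                       col_types = "cddc", progress = FALSE)
  tibble::tibble(chrom = x$chrom, start = x$start + 1, end = x$end,
                 name = x$name)
}

#' Bundled cloned-gene and hotspot tables
#'
#' `table1_genes()` returns the curated table of 132 cloned maize genes
#' with kernel-size phenotypes (7 phenotype classes; gene IDs on B73_V4;
#' only the chromosome is recorded, not base-pair coordinates).
#' `table2_hotspots()` returns the 31 published consensus QTL/QTN hotspots
#' with their physical spans, member clusters and co-located cloned genes.
#'
#' @return A tibble (see [read_gene_table()] / [read_hotspot_table()] for
#'   the column layout).
#' @examples
#' nrow(table1_genes())
#' nrow(table2_hotspots())
#' @export
table1_genes <- function() {
  read_gene_table(system.file("extdata", "table1_genes.tsv",
                              package = "kernelhotspots", mustWork = TRUE))
}

#' @rdname table1_genes
#' @export
table2_hotspots <- function() {
  read_hotspot_table(system.file("extdata", "table2_hotspots.tsv",
                                 package = "kernelhotspots", mustWork = TRUE))
}
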