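#' Run the full hotspot meta-analysis
#'
#' Orchestrates the stages end to end: QTL projection via flanking markers,
#' trait-specific QTL clustering (>= `min_qtl_members` overlapping
#' intervals), trait-specific QTN clustering (>= `min_qtn_count` variants
#' per `qtn_window`), integration of all clusters into consensus hotspots
#' (>= `min_hotspot_clusters`), gene co-location, candidate screening of
#' hotspot genes by the kernel-expression filter, PPR annotation search,
#' and GO over-representation of the passing candidates. Any stage whose
#' inputs are not supplied is skipped; record counts reconcile across
#' stages (projected + rejected = input; cluster members come from
#' projected records; hotspot members are cluster names).
#'
#' All thresholds default to the field-standard values: 3 QTLs per
#' cluster, 5 QTNs per 5 Mb window, 3 clusters per hotspot, kernel FPKM
#' >= 50 with MaxExp/MaxExpKernel <= 3, and FDR 0.05.
#'
#' @param qtl,markers QTL table and marker map (see [read_qtl_table()],
#'   [read_marker_map()]); both or neither.
#' @param qtn QTN table (optional).
#' @param genes Gene table with coordinates (optional).
#' @param expression Long expression table (optional; needs `genes` and
#'   `kernel_tissues`).
#' @param kernel_tissues Character vector of kernel tissue names.
#' @param go_annotations,go_term_names GO annotation tables (optional).
#' @param min_qtl_members,qtn_window,min_qtn_count,min_hotspot_clusters,min_kernel_fpkm,max_ratio,fdr_threshold
#'   Stage thresholds (defaults above).
#' @param build Genome build (default [b73_v4_build()]).
#' @param verbose Log each stage and the thresholds used.
#' @return A `kernel_run` object: list with `projection`, `qtl_clusters`,
#'   `qtn_clusters`, `clusters`, `hotspots`, `summary`, `candidates`,
#'   `ppr_genes`, `enrichment` and `params`. Has [tidy()], [glance()] and
#'   `autoplot()` methods.
#' @examples
#' sim <- simulate_kernel_dataset(seed = 1, background_qtls = 0,
#'                                background_qtns = 0,
#'                                missing_marker_rate = 0)
#' run <- run_kernel_analysis(qtl = sim$qtl, markers = sim$markers,
#'                            qtn = sim$qtn, genes = sim$genes)
#' glance(run)
#' @export
run_kernel_analysis <- function(qtl = NULL, markers = NULL, qtn = NULL,
                                genes = NULL, expression = NULL,
                                kernel_tissues = NULL,
                                go_annotations = NULL, go_term_names = NULL,
                                min_qtl_members = 3, qtn_window = 5e6,
                                min_qtn_count = 5, min_hotspot_clusters = 3,
                                min_kernel_fpkm = 50, max_ratio = 3,
                                fdr_threshold = 0.05,
                                build = b73_v4_build(), verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  if (xor(is.null(qtl), is.null(markers))) {
    stop("supply `qtl` and `markers` together", call. = FALSE)
  }

  projection <- NULL
  qtl_clusters <- NULL
  if (!is.null(qtl)) {
    say("projecting ", nrow(qtl), " QTLs via flanking markers")
    projection <- project_qtls(qtl, markers, build)
    proj <- projected_qtls(projection)
    say("  projected ", nrow(proj), ", rejected ",
        nrow(projection) - nrow(proj))
    say("calling QTL clusters (min members ", min_qtl_members, ")")
    qtl_clusters <- find_qtl_clusters(proj, min_qtl_members, build)
  }

  qtn_clusters <- NULL
  if (!is.null(qtn)) {
    say("calling QTN clusters (window ", qtn_window, " nt, min count ",
        min_qtn_count, ")")
    qtn_clusters <- find_qtn_clusters(qtn, qtn_window, min_qtn_count, build)
  }

  clusters <- dplyr::bind_rows(qtl_clusters, qtn_clusters)
  say("integrating ", nrow(clusters), " clusters into hotspots (min ",
      min_hotspot_clusters, ")")
  hotspots <- integrate_hotspots(clusters, min_hotspot_clusters, build)

  if (!is.null(genes) && nrow(hotspots) &&
      all(c("chrom", "start", "end") %in% names(genes))) {
    hotspots <- assign_hotspot_genes(hotspots, genes)
  }

  candidates <- NULL
  ppr <- NULL
  if (!is.null(genes) && "genes" %in% names(hotspots)) {
    hot_names <- unique(unlist(hotspots$genes))
    hot_genes <- dplyr::filter(genes, .data$name %in% hot_names)
    if ("annotation" %in% names(genes)) {
      ppr <- find_ppr_genes(hotspots, genes)
      say("PPR search: ", nrow(ppr), " PPR gene hit(s) across hotspots")
    }
    if (!is.null(expression) && !is.null(kernel_tissues) &&
        nrow(hot_genes)) {
      say("screening ", nrow(hot_genes), " hotspot genes by expression ",
          "(kernel FPKM >= ", min_kernel_fpkm, ", ratio <= ", max_ratio, ")")
      summ <- expression_summary(
        dplyr::filter(expression, .data$gene_id %in% hot_genes$gene_id),
        kernel_tissues)
      candidates <- filter_candidates(summ, min_kernel_fpkm, max_ratio,
                                      genes = hot_genes$gene_id)
    }
  }

  enrichment <- NULL
  if (!is.null(go_annotations) && !is.null(candidates)) {
    pass <- candidates$gene_id[candidates$status == "pass"]
    annotated <- intersect(pass, go_annotations$gene_id)
    if (length(annotated)) {
      say("GO enrichment on ", length(annotated), " candidate gene(s), ",
          "FDR threshold ", fdr_threshold)
      enrichment <- enrich_go(annotated, go_annotations, go_term_names,
                              fdr_threshold = fdr_threshold)
    }
  }

  structure(list(
    projection = projection,
    qtl_clusters = qtl_clusters,
    qtn_clusters = qtn_clusters,
    clusters = clusters,
    hotspots = hotspots,
    summary = summarize_hotspots(hotspots, build),
    candidates = candidates,
    ppr_genes = ppr,
    enrichment = enrichment,
    params = list(min_qtl_members = min_qtl_members, qtn_window = qtn_window,
                  min_qtn_count = min_qtn_count,
                  min_hotspot_clusters = min_hotspot_clusters,
                  min_kernel_fpkm = min_kernel_fpkm, max_ratio = max_ratio,
                  fdr_threshold = fdr_threshold),
    build = build
  ), class = "kernel_run")
}

#' @export
print.kernel_run <- function(x, ...) {
  g <- glance(x)
  cat("<kernel_run>\n")
  cat("  QTLs: ", g$n_qtl_input, " in, ", g$n_projected, " projected, ",
      g$n_qtl_clusters, " cluster(s)\n", sep = "")
  cat("  QTNs: ", g$n_qtn_clustered, " in clusters, ", g$n_qtn_clusters,
      " cluster(s)\n", sep = "")
  cat("  hotspots: ", g$n_hotspots, "\n", sep = "")
  if (!is.na(g$n_candidates)) {
    cat("  candidate genes passing expression filter: ", g$n_candidates,
        "\n", sep = "")
  }
  invisible(x)
}

#' Tidy the hotspot table of a run
#'
#' @param x A `kernel_run` object.
#' @param ... Unused.
#' @return The hotspot tibble with list-columns flattened to
#'   comma-separated strings and a `span_mb` column.
#' @method tidy kernel_run
#' @export
tidy.kernel_run <- function(x, ...) {
  h <- flatten_members(x$hotspots)
  if (nrow(h)) h$span_mb <- span_mb(h$start, h$end, 1)
  h
}

#' One-row summary of a run
#'
#' @param x A `kernel_run` object.
#' @param ... Unused.
#' @return One-row tibble of stage counts.
#' @method glance kernel_run
#' @export
glance.kernel_run <- function(x, ...) {
  nr <- function(d) if (is.null(d)) 0L else nrow(d)
  tibble::tibble(
    n_qtl_input = nr(x$projection),
    n_projected = if (is.null(x$projection)) 0L
                  else sum(x$projection$status == "projected"),
    n_rejected = if (is.null(x$projection)) 0L
                 else sum(x$projection$status != "projected"),
    n_qtn_clustered = if (is.null(x$qtn_clusters)) 0L
                      else sum(x$qtn_clusters$n_members),
    n_qtl_clusters = nr(x$qtl_clusters),
    n_qtn_clusters = nr(x$qtn_clusters),
    n_hotspots = nr(x$hotspots),
    n_candidates = if (is.null(x$candidates)) NA_integer_
                   else sum(x$candidates$status == "pass"),
    n_ppr_hits = if (is.null(x$ppr_genes)) NA_integer_
                 else nrow(x$ppr_genes),
    n_enriched_terms = if (is.null(x$enrichment)) NA_integer_
                       else sum(x$enrichment$significant)
  )
}

#' Summarize a transcribed hotspot table (report-only mode)
#'
#' Applies the same summary computation as [summarize_hotspots()] to a
#' hotspot table read from disk or bundled with the package, bypassing
#' inference — useful for reporting on published hotspot collections.
#'
#' @param hotspots Hotspot tibble (default: the bundled table of 31
#'   published hotspots, [table2_hotspots()]).
#' @param build Genome build (default [b73_v4_build()]).
#' @return A `hotspot_summary` object.
#' @examples
#' report_hotspot_fixture()
#' @export
report_hotspot_fixture <- function(hotspots = table2_hotspots(),
                                   build = b73_v4_build()) {
  summarize_hotspots(hotspots, build)
}

#' Write all stage outputs of a run to a directory
#'
#' Emits TSV tables (clusters, hotspots, projection report, candidates,
#' enrichment) plus BED4 files of cluster and hotspot intervals. Re-running
#' on identical inputs yields byte-identical files.
#'
#' @param run A `kernel_run` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "kernel_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  if (!is.null(run$projection)) {
    readr::write_tsv(projected_qtls(run$projection), p("projected.tsv"),
                     progress = FALSE)
    readr::write_tsv(rejected_qtls(run$projection), p("rejected.tsv"),
                     progress = FALSE)
  }
  if (nrow(run$clusters)) {
    cl <- flatten_members(run$clusters)
    readr::write_tsv(cl, p("clusters.tsv"), progress = FALSE)
    write_bed(cl, p("clusters.bed"))
  }
  h <- flatten_members(run$hotspots)
  if (nrow(h)) {
    write_hotspot_table(h, p("hotspots.tsv"))
    write_bed(dplyr::rename(h, name = "hotspot"), p("hotspots.bed"))
  }
  if (!is.null(run$candidates)) {
    readr::write_tsv(run$candidates, p("candidates.tsv"), progress = FALSE)
  }
  if (!is.null(run$enrichment)) {
    readr::write_tsv(run$enrichment, p("enrichment.tsv"), progress = FALSE)
  }
  invisible(dir)
}
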