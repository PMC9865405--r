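#' Simulate a complete curation dataset with planted structure
#'
#' Generates every input table the pipeline consumes — marker map, QTLs,
#' QTNs, genes, a tissue expression matrix and GO annotations — with known
#' ground truth: hotspot loci where several trait-specific clusters are
#' planted on top of a sparse genome-wide background. The generator
#' emulates the statistical structure the hotspot analysis assumes (dense
#' co-localized loci over scattered singletons), not linkage
#' disequilibrium, allele frequencies or effect sizes, which the
#' co-localization rules never use.
#'
#' At each planted locus, `clusters_per_locus` clusters with distinct
#' (trait, kind) labels are drawn: QTL clusters place `qtls_per_cluster`
#' intervals that all contain the locus center (half-widths log-normal,
#' median 2.5 Mb per side, i.e. ~5 Mb full widths, capped at 8 Mb), so
#' mutual overlap is guaranteed; QTN clusters place `qtns_per_cluster`
#' positions uniformly within one window centered on the locus. Loci are
#' separated by at least `locus_separation_min` plus the maximal cluster
#' reach, so planted clusters can never chain across loci. Background
#' records are placed uniformly and re-drawn if they fall within the
#' exclusion zone of a locus. A fraction `missing_marker_rate` of QTLs has
#' its left flanking marker blanked, making them unprojectable — mirroring
#' the sizeable share of literature QTLs that cannot be placed for lack of
#' marker information.
#'
#' Genes are planted inside hotspot loci (two per locus) and scattered
#' elsewhere; a `kernel_gene_fraction` of them is built to pass the
#' kernel-expression filter (kernel FPKM log-normal around 200 with
#' MaxExp/MaxExpKernel forced <= 2.5) and the rest to fail it, either by
#' low kernel expression (< 50) or by a tissue-bias ratio >= 4, giving
#' exact pass/fail truth labels. One GO term (`GO:KERNEL01`) is planted to
#' be enriched among passing genes; other terms annotate genes at random.
#'
#' A single integer `seed` drives the whole dataset through per-table
#' sub-streams, so e.g. changing `n_genes` does not perturb QTL placement.
#'
#' @param seed Integer seed; identical seed and configuration reproduce
#'   the dataset byte-for-byte.
#' @param n_hotspot_loci Number of planted hotspot loci.
#' @param clusters_per_locus Clusters per locus (>= 3 so each locus is a
#'   hotspot; at most 8, the number of distinct trait x kind labels).
#' @param qtls_per_cluster QTLs per planted QTL cluster (>= 3).
#' @param qtns_per_cluster QTNs per planted QTN cluster (>= 5).
#' @param qtl_halfwidth_meanlog,qtl_halfwidth_sdlog Log-normal law of QTL
#'   interval half-widths in nt.
#' @param locus_separation_min Minimal separation between locus centers
#'   and between background records and loci (nt).
#' @param background_qtls,background_qtns Genome-wide background counts.
#' @param missing_marker_rate Fraction of QTLs with a blanked flanking
#'   marker.
#' @param n_genes Total genes (planted + scattered).
#' @param kernel_gene_fraction Fraction of genes built to pass the
#'   expression filter.
#' @param n_go_terms Number of random GO terms beside the planted one.
#' @param qtn_window QTN cluster window length (nt), used to size planted
#'   QTN clusters.
#' @param cluster_kinds Optional tibble with columns `trait` and `kind`
#'   fixing the exact cluster layout planted at every locus (distinct
#'   rows); overrides the random choice of `clusters_per_locus` labels.
#' @param build Genome build (default [b73_v4_build()]).
#' @return A list with the input tibbles (`qtl`, `markers`, `qtn`, `genes`,
#'   `expression`, `kernel_tissues`, `go_annotations`, `go_terms`), the
#'   ground `truth` (list of tibbles: `loci`, `clusters`, `hotspots`,
#'   `gene_labels`) and the `config` used.
#' @export
simulate_kernel_dataset <- function(
    seed,
    n_hotspot_loci = 3,
    clusters_per_locus = 3,
    qtls_per_cluster = 3,
    qtns_per_cluster = 5,
    qtl_halfwidth_meanlog = log(2.5e6),
    qtl_halfwidth_sdlog = 0.4,
    locus_separation_min = 2e7,
    background_qtls = 20,
    background_qtns = 30,
    missing_marker_rate = 0.25,
    n_genes = 200,
    kernel_gene_fraction = 0.5,
    n_go_terms = 20,
    qtn_window = 5e6,
    cluster_kinds = NULL,
    build = b73_v4_build()) {

  stopifnot(n_hotspot_loci >= 0, clusters_per_locus >= 3,
            clusters_per_locus <= 8, qtls_per_cluster >= 3,
            qtns_per_cluster >= 5, locus_separation_min > 0,
            missing_marker_rate >= 0, missing_marker_rate <= 1,
            kernel_gene_fraction >= 0, kernel_gene_fraction <= 1)
  validate_build(build)
  seed <- as.integer(seed)
  sub_seed <- function(k) (abs(seed) + k * 99991L) %% .Machine$integer.max

  hw_cap <- 8e6               # keeps cluster reach bounded for separation
  reach <- hw_cap + qtn_window # widest possible half-extent of a locus
  config <- list(seed = seed, n_hotspot_loci = n_hotspot_loci,
                 clusters_per_locus = clusters_per_locus,
                 qtls_per_cluster = qtls_per_cluster,
                 qtns_per_cluster = qtns_per_cluster,
                 locus_separation_min = locus_separation_min,
                 background_qtls = background_qtls,
                 background_qtns = background_qtns,
                 missing_marker_rate = missing_marker_rate,
                 n_genes = n_genes,
                 kernel_gene_fraction = kernel_gene_fraction,
                 n_go_terms = n_go_terms, qtn_window = qtn_window)

  combos <- tidyr::expand_grid(trait = kernel_traits(),
                               kind = c("QTL", "QTN"))

  ## --- loci and planted cluster layout ------------------------------------
  loci <- withr::with_seed(sub_seed(1L), {
    placed <- list()
    for (i in seq_len(n_hotspot_loci)) {
      ok <- FALSE
      for (attempt in 1:1000) {
        ch <- sample(build$chrom, 1, prob = build$length)
        len <- build$length[build$chrom == ch]
        if (len < 2 * reach + 2) next
        center <- floor(stats::runif(1, reach + 1, len - reach))
        near <- vapply(placed, function(p) {
          p$chrom == ch &&
            abs(p$center - center) < locus_separation_min + 2 * reach
        }, logical(1))
        if (!any(near)) { ok <- TRUE; break }
      }
      if (!ok) {
        stop("could not place ", n_hotspot_loci, " loci with separation ",
             locus_separation_min, " on this genome", call. = FALSE)
      }
      placed[[i]] <- list(locus = paste0("L", i), chrom = ch, center = center)
    }
    placed
  })

  plan <- withr::with_seed(sub_seed(2L), {
    lapply(loci, function(l) {
      pick <- if (is.null(cluster_kinds)) {
        combos[sample(nrow(combos), clusters_per_locus), ]
      } else {
        stopifnot(all(c("trait", "kind") %in% names(cluster_kinds)),
                  !anyDuplicated(cluster_kinds[c("trait", "kind")]))
        tibble::as_tibble(cluster_kinds[c("trait", "kind")])
      }
      pick$locus <- l$locus
      pick
    })
  })

  ## --- QTLs + markers ------------------------------------------------------
  rhw <- function(n) {
    pmin(stats::rlnorm(n, qtl_halfwidth_meanlog, qtl_halfwidth_sdlog), hw_cap)
  }
  qtl_rows <- withr::with_seed(sub_seed(3L), {
    planted <- dplyr::bind_rows(lapply(seq_along(loci), function(i) {
      l <- loci[[i]]
      p <- dplyr::filter(plan[[i]], .data$kind == "QTL")
      if (nrow(p) == 0) return(NULL)
      dplyr::bind_rows(lapply(seq_len(nrow(p)), function(j) {
        tibble::tibble(
          trait = p$trait[j], locus = l$locus,
          cluster = paste0(l$locus, "-", p$trait[j], "-QTL"),
          chrom = l$chrom,
          start = pmax(1, floor(l$center - rhw(qtls_per_cluster))),
          end = floor(l$center + rhw(qtls_per_cluster))
        )
      }))
    }))
    bg <- NULL
    if (background_qtls > 0) {
      rows <- list()
      while (length(rows) < background_qtls) {
        ch <- sample(build$chrom, 1, prob = build$length)
        len <- build$length[build$chrom == ch]
        c0 <- floor(stats::runif(1, 1, len))
        near <- vapply(loci, function(l) {
          l$chrom == ch && abs(l$center - c0) < locus_separation_min + reach
        }, logical(1))
        if (any(near)) next
        s <- pmax(1, floor(c0 - rhw(1)))
        e <- pmin(len, floor(c0 + rhw(1)))
        rows[[length(rows) + 1]] <- tibble::tibble(
          trait = sample(kernel_traits(), 1), locus = NA_character_,
          cluster = NA_character_, chrom = ch, start = s, end = e)
      }
      bg <- dplyr::bind_rows(rows)
    }
    dplyr::bind_rows(planted, bg)
  })
  n_qtl <- if (is.null(qtl_rows)) 0L else nrow(qtl_rows)

  markers <- qtl <- NULL
  if (n_qtl > 0) {
    qtl_rows$qtl_id <- sprintf("sq%04d", seq_len(n_qtl))
    qtl_rows$left_marker <- sprintf("ML%04d", seq_len(n_qtl))
    qtl_rows$right_marker <- sprintf("MR%04d", seq_len(n_qtl))
    blanked <- withr::with_seed(sub_seed(4L),
      stats::runif(n_qtl) < missing_marker_rate)
    markers <- tibble::tibble(
      marker = c(qtl_rows$left_marker, qtl_rows$right_marker),
      chrom = rep(qtl_rows$chrom, 2),
      position = c(qtl_rows$start, qtl_rows$end)
    )
    qtl <- tibble::tibble(
      qtl_id = qtl_rows$qtl_id, trait = qtl_rows$trait,
      left_marker = ifelse(blanked, NA_character_, qtl_rows$left_marker),
      right_marker = qtl_rows$right_marker,
      study = "synthetic"
    )
    qtl_rows$projectable <- !blanked
  } else {
    markers <- tibble::tibble(marker = character(), chrom = character(),
                              position = double())
    qtl <- tibble::tibble(qtl_id = character(), trait = character(),
                          left_marker = character(),
                          right_marker = character(), study = character())
  }

  ## --- QTNs ----------------------------------------------------------------
  qtn_rows <- withr::with_seed(sub_seed(5L), {
    planted <- dplyr::bind_rows(lapply(seq_along(loci), function(i) {
      l <- loci[[i]]
      p <- dplyr::filter(plan[[i]], .data$kind == "QTN")
      if (nrow(p) == 0) return(NULL)
      dplyr::bind_rows(lapply(seq_len(nrow(p)), function(j) {
        tibble::tibble(
          trait = p$trait[j], locus = l$locus,
          cluster = paste0(l$locus, "-", p$trait[j], "-QTN"),
          chrom = l$chrom,
          position = floor(l$center +
                             stats::runif(qtns_per_cluster,
                                          -qtn_window / 2, qtn_window / 2))
        )
      }))
    }))
    bg <- NULL
    if (background_qtns > 0) {
      rows <- list()
      while (length(rows) < background_qtns) {
        ch <- sample(build$chrom, 1, prob = build$length)
        len <- build$length[build$chrom == ch]
        p0 <- floor(stats::runif(1, 1, len))
        near <- vapply(loci, function(l) {
          l$chrom == ch && abs(l$center - p0) < locus_separation_min + reach
        }, logical(1))
        if (any(near)) next
        rows[[length(rows) + 1]] <- tibble::tibble(
          trait = sample(kernel_traits(), 1), locus = NA_character_,
          cluster = NA_character_, chrom = ch, position = p0)
      }
      bg <- dplyr::bind_rows(rows)
    }
    dplyr::bind_rows(planted, bg)
  })
  if (is.null(qtn_rows) || nrow(qtn_rows) == 0) {
    qtn <- tibble::tibble(qtn_id = character(), trait = character(),
                          chrom = character(), position = double(),
                          study = character())
  } else {
    qtn_rows$qtn_id <- sprintf("sn%04d", seq_len(nrow(qtn_rows)))
    qtn <- tibble::tibble(qtn_id = qtn_rows$qtn_id, trait = qtn_rows$trait,
                          chrom = qtn_rows$chrom,
                          position = qtn_rows$position, study = "synthetic")
  }

  ## --- ground truth --------------------------------------------------------
  planted_qtl <- if (n_qtl > 0) {
    dplyr::filter(qtl_rows, !is.na(.data$cluster), .data$projectable)
  }
  planted_qtn <- if (nrow(qtn) > 0) {
    dplyr::filter(qtn_rows, !is.na(.data$cluster))
  }
  truth_clusters <- dplyr::bind_rows(
    if (!is.null(planted_qtl) && nrow(planted_qtl)) {
      planted_qtl |>
        dplyr::group_by(.data$cluster, .data$locus, .data$trait,
                        .data$chrom) |>
        dplyr::summarise(kind = "QTL", start = min(.data$start),
                         end = max(.data$end), n_members = dplyr::n(),
                         .groups = "drop") |>
        dplyr::filter(.data$n_members >= 3)
    },
    if (!is.null(planted_qtn) && nrow(planted_qtn)) {
      planted_qtn |>
        dplyr::group_by(.data$cluster, .data$locus, .data$trait,
                        .data$chrom) |>
        dplyr::summarise(kind = "QTN", start = min(.data$position),
                         end = max(.data$position),
                         n_members = dplyr::n(), .groups = "drop") |>
        dplyr::filter(.data$n_members >= 5)
    }
  )
  truth_loci <- tibble::tibble(
    locus = vapply(loci, `[[`, character(1), "locus"),
    chrom = vapply(loci, `[[`, character(1), "chrom"),
    center = vapply(loci, `[[`, double(1), "center")
  )
  truth_hotspots <- if (nrow(truth_clusters)) {
    truth_clusters |>
      dplyr::group_by(locus = .data$locus, chrom = .data$chrom) |>
      dplyr::summarise(start = min(.data$start), end = max(.data$end),
                       n_clusters = dplyr::n(), .groups = "drop") |>
      dplyr::filter(.data$n_clusters >= 3)
  } else {
    tibble::tibble(locus = character(), chrom = character(),
                   start = double(), end = double(), n_clusters = integer())
  }

  ## --- genes + expression --------------------------------------------------
  kernel_tissues <- c("kernel_14DAP", "embryo_25DAP", "endosperm_14DAP")
  other_tissues <- c("leaf", "root", "tassel", "silk")
  gene_len <- 3000
  genes_expr <- withr::with_seed(sub_seed(6L), {
    n_planted <- min(n_genes, 2 * n_hotspot_loci)
    placed <- list()
    if (n_planted > 0) {
      for (i in seq_len(n_planted)) {
        l <- loci[[(i - 1) %% n_hotspot_loci + 1]]
        s <- floor(l$center + stats::runif(1, -2e5, 2e5))
        placed[[i]] <- tibble::tibble(chrom = l$chrom, start = s,
                                      end = s + gene_len,
                                      in_hotspot = TRUE)
      }
    }
    n_rest <- n_genes - n_planted
    if (n_rest > 0) {
      for (i in seq_len(n_rest)) {
        ch <- sample(build$chrom, 1, prob = build$length)
        len <- build$length[build$chrom == ch]
        s <- floor(stats::runif(1, 1, len - gene_len))
        placed[[n_planted + i]] <- tibble::tibble(chrom = ch, start = s,
                                                  end = s + gene_len,
                                                  in_hotspot = FALSE)
      }
    }
    g <- dplyr::bind_rows(placed)
    if (is.null(g) || nrow(g) == 0) {
      g <- tibble::tibble(chrom = character(), start = double(),
                          end = double(), in_hotspot = logical())
    }
    ng <- nrow(g)
    g$gene_id <- sprintf("ZmSYN%04d", seq_len(ng))
    g$name <- g$gene_id
    lab <- rep("fail", ng)
    lab[stats::runif(ng) < kernel_gene_fraction] <- "pass"
    ppr_pool <- c("PPR protein, RNA editing", "PPR protein, RNA splicing")
    other_pool <- c("Sucrose synthase, starch biosynthesis",
                    "bZIP transcription factor, endosperm regulator",
                    "Cell wall invertase, sucrose transport",
                    "Expansin protein, kernel expansion",
                    "suppressor protein, unknown pathway")
    is_ppr <- stats::runif(ng) < 0.3
    g$annotation <- ifelse(is_ppr, sample(ppr_pool, ng, replace = TRUE),
                           sample(other_pool, ng, replace = TRUE))
    g$label <- lab

    expr <- if (ng > 0) {
      rows <- lapply(seq_len(ng), function(i) {
        if (lab[i] == "pass") {
          mk <- pmax(stats::rlnorm(1, log(200), 0.5), 60)
          ratio <- stats::runif(1, 1, 2.5)
        } else if (stats::runif(1) < 0.5) {
          mk <- stats::runif(1, 0.5, 40)   # fails on kernel FPKM
          ratio <- stats::runif(1, 0.5, 2.5)
        } else {
          mk <- pmax(stats::rlnorm(1, log(100), 0.5), 60)
          ratio <- stats::runif(1, 4, 8)   # fails on tissue bias
        }
        kf <- mk * stats::runif(length(kernel_tissues), 0.3, 1)
        kf[1] <- mk
        of <- mk * ratio * stats::runif(length(other_tissues), 0.2, 1)
        of[1] <- mk * ratio
        tibble::tibble(gene_id = g$gene_id[i],
                       tissue = c(kernel_tissues, other_tissues),
                       fpkm = round(c(kf, of), 3))
      })
      dplyr::bind_rows(rows)
    } else {
      tibble::tibble(gene_id = character(), tissue = character(),
                     fpkm = double())
    }
    list(genes = g, expression = expr)
  })
  genes <- dplyr::select(genes_expr$genes, "name", "gene_id", "chrom",
                         "start", "end", "annotation", "in_hotspot")
  gene_labels <- dplyr::select(genes_expr$genes, "gene_id", "label")

  ## --- GO annotations ------------------------------------------------------
  go <- withr::with_seed(sub_seed(7L), {
    ids <- genes$gene_id
    terms <- sprintf("GO:%07d", seq_len(n_go_terms))
    rand <- dplyr::bind_rows(lapply(terms, function(t) {
      keep <- ids[stats::runif(length(ids)) < 0.08]
      if (!length(keep)) keep <- sample(ids, min(2, length(ids)))
      tibble::tibble(gene_id = keep, term_id = t)
    }))
    pass_ids <- gene_labels$gene_id[gene_labels$label == "pass"]
    other_ids <- setdiff(ids, pass_ids)
    planted <- tibble::tibble(
      gene_id = c(pass_ids[stats::runif(length(pass_ids)) < 0.8],
                  other_ids[stats::runif(length(other_ids)) < 0.05]),
      term_id = "GO:KERNEL01")
    dplyr::bind_rows(rand, planted)
  })
  go_terms <- tibble::tibble(
    term_id = c(sprintf("GO:%07d", seq_len(n_go_terms)), "GO:KERNEL01"),
    term_name = c(sprintf("random process %d", seq_len(n_go_terms)),
                  "kernel development"))

  list(qtl = qtl, markers = markers, qtn = qtn, genes = genes,
       expression = genes_expr$expression, kernel_tissues = kernel_tissues,
       go_annotations = go, go_terms = go_terms,
       truth = list(loci = truth_loci, clusters = truth_clusters,
                    hotspots = truth_hotspots, gene_labels = gene_labels),
       config = config)
}

#' Precision and recall of recovered intervals against planted truth
#'
#' Matches found intervals to ground-truth intervals by reciprocal overlap
#' of at least `min_reciprocal` (default 0.5): the intersection must cover
#' at least that fraction of BOTH intervals. When both tables carry `trait`
#' and `kind` columns, matches must also agree on them. Precision is the
#' fraction of found intervals with a match; recall the fraction of truth
#' intervals recovered.
#'
#' @param found Tibble with `chrom`, `start`, `end` (e.g. cluster or
#'   hotspot calls).
#' @param truth Tibble with `chrom`, `start`, `end` (planted truth).
#' @param min_reciprocal Reciprocal-overlap threshold in (0, 1].
#' @return One-row tibble: `n_truth`, `n_found`, `n_matched_found`,
#'   `n_matched_truth`, `precision`, `recall`. With no found intervals,
#'   precision is NA and recall 0 (or NA when truth is empty too).
#' @export
recovery_report <- function(found, truth, min_reciprocal = 0.5) {
  stopifnot(min_reciprocal > 0, min_reciprocal <= 1)
  for (x in list(found, truth)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  }
  match_labels <- all(c("trait", "kind") %in% names(found)) &&
    all(c("trait", "kind") %in% names(truth))
  ok <- function(i, j) {
    if (found$chrom[i] != truth$chrom[j]) return(FALSE)
    if (match_labels && (found$trait[i] != truth$trait[j] ||
                         found$kind[i] != truth$kind[j])) return(FALSE)
    ov <- min(found$end[i], truth$end[j]) -
      max(found$start[i], truth$start[j]) + 1
    if (ov <= 0) return(FALSE)
    lf <- found$end[i] - found$start[i] + 1
    lt <- truth$end[j] - truth$start[j] + 1
    ov / lf >= min_reciprocal && ov / lt >= min_reciprocal
  }
  nf <- nrow(found)
  nt <- nrow(truth)
  hit <- matrix(FALSE, nf, nt)
  for (i in seq_len(nf)) for (j in seq_len(nt)) hit[i, j] <- ok(i, j)
  mf <- sum(apply(hit, 1, any))
  mt <- if (nt) sum(apply(hit, 2, any)) else 0L
  tibble::tibble(
    n_truth = nt, n_found = nf,
    n_matched_found = mf, n_matched_truth = mt,
    precision = if (nf) mf / nf else NA_real_,
    recall = if (nt) mt / nt else NA_real_
  )
}
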