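noise_free <- function(seed, ...) {
  simulate_kernel_dataset(seed, background_qtls = 0, background_qtns = 0,
                          missing_marker_rate = 0, ...)
}

test_that("identical seed and configuration reproduce the dataset", {
  a <- simulate_kernel_dataset(seed = 5)
  b <- simulate_kernel_dataset(seed = 5)
  expect_equal(a$qtl, b$qtl)
  expect_equal(a$markers, b$markers)
  expect_equal(a$qtn, b$qtn)
  expect_equal(a$genes, b$genes)
  expect_equal(a$expression, b$expression)
  expect_equal(a$go_annotations, b$go_annotations)
  expect_equal(a$truth$clusters, b$truth$clusters)
  c <- simulate_kernel_dataset(seed = 6)
  expect_false(identical(a$qtl, c$qtl))
})

test_that("zero loci and zero background give empty tables", {
  sim <- noise_free(1, n_hotspot_loci = 0, n_genes = 0)
  expect_equal(nrow(sim$qtl), 0)
  expect_equal(nrow(sim$qtn), 0)
  expect_equal(nrow(sim$truth$clusters), 0)
  expect_equal(nrow(sim$truth$hotspots), 0)
})

test_that("a fixed cluster layout is recovered exactly by the pipeline", {
  layout <- tibble::tibble(trait = c("KL", "KW", "HKW", "KT"),
                           kind = c("QTL", "QTL", "QTL", "QTN"))
  sim <- noise_free(3, n_hotspot_loci = 1, cluster_kinds = layout)
  run <- run_kernel_analysis(qtl = sim$qtl, markers = sim$markers,
                             qtn = sim$qtn)
  expect_equal(nrow(run$hotspots), 1)
  expect_equal(run$hotspots$n_clusters, 4L)
  expect_equal(nrow(run$qtl_clusters), 3)
  expect_equal(nrow(run$qtn_clusters), 1)
  rec <- recovery_report(run$clusters, sim$truth$clusters)
  expect_equal(rec$precision, 1)
  expect_equal(rec$recall, 1)
})

test_that("the unprojectable fraction converges to the configured rate", {
  rate <- 0.3
  sim <- simulate_kernel_dataset(seed = 9, n_hotspot_loci = 0,
                                 background_qtls = 500,
                                 background_qtns = 0, n_genes = 0,
                                 missing_marker_rate = rate)
  rep <- project_qtls(sim$qtl, sim$markers)
  frac <- mean(rep$status == "missing-marker")
  se <- sqrt(rate * (1 - rate) / 500)
  expect_lt(abs(frac - rate), 3 * se)
})

test_that("planted expression labels agree with the filter", {
  sim <- noise_free(13, n_genes = 150)
  s <- expression_summary(sim$expression, sim$kernel_tissues)
  out <- filter_candidates(s)
  got <- out$status[match(sim$truth$gene_labels$gene_id, out$gene_id)]
  expect_equal(got, sim$truth$gene_labels$label)
})

test_that("recovery metrics follow their definitions", {
  truth <- tibble::tibble(chrom = "1", start = c(1, 100, 200, 300) * 1e5,
                          end = c(50, 150, 250, 350) * 1e5)
  # one spurious call on top of four perfect ones: precision 0.8
  found <- dplyr::bind_rows(truth,
                            tibble::tibble(chrom = "2", start = 1e6,
                                           end = 2e6))
  rec <- recovery_report(found, truth)
  expect_equal(rec$precision, 0.8)
  expect_equal(rec$recall, 1)
  # empty output: recall 0
  rec0 <- recovery_report(found[0, ], truth)
  expect_equal(rec0$recall, 0)
  expect_true(is.na(rec0$precision))
  # reciprocal overlap below 0.5 does not match
  off <- tibble::tibble(chrom = "1", start = 1, end = 4e6)
  expect_equal(recovery_report(off, truth[1, ])$recall, 1)
  off2 <- tibble::tibble(chrom = "1", start = 1, end = 2e6)
  expect_equal(recovery_report(off2, truth[1, ])$recall, 0)
})

test_that("background placement respects the exclusion zone", {
  sim <- simulate_kernel_dataset(seed = 2, n_hotspot_loci = 2,
                                 background_qtls = 50,
                                 background_qtns = 50,
                                 missing_marker_rate = 0, n_genes = 0)
  loci <- sim$truth$loci
  rep <- projected_qtls(project_qtls(sim$qtl, sim$markers))
  for (i in seq_len(nrow(loci))) {
    mid <- (rep$start + rep$end) / 2
    near <- rep$chrom == loci$chrom[i] & abs(mid - loci$center[i]) < 2e7
    # every record near a locus center must be a planted one, and planted
    # intervals contain the center by construction
    expect_true(all(rep$start[near] <= loci$center[i] &
                      rep$end[near] >= loci$center[i]))
  }
  qn <- sim$qtn
  for (i in seq_len(nrow(loci))) {
    near <- qn$chrom == loci$chrom[i] &
      abs(qn$position - loci$center[i]) < 2e7
    expect_true(all(abs(qn$position[near] - loci$center[i]) <= 2.5e6))
  }
})
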