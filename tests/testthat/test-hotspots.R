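toy_clusters <- function(starts, ends, chrom = "1",
                         names = sprintf("KW-qCL1-%d", seq_along(starts)),
                         traits = "KW", kinds = "QTL") {
  tibble::tibble(name = names, trait = traits, kind = kinds, chrom = chrom,
                 start = starts, end = ends)
}

test_that("two overlapping clusters do not make a hotspot", {
  cl <- toy_clusters(c(100, 200), c(500, 600),
                     names = c("KW-qCL1-1", "KL-qCL1-1"))
  expect_equal(nrow(integrate_hotspots(cl)), 0)
})

test_that("three overlapping clusters of mixed kinds form one hotspot", {
  cl <- tibble::tibble(
    name = c("KW-gCL1-1", "KW-qCL1-1", "HKW-qCL1-1"),
    trait = c("KW", "KW", "HKW"),
    kind = c("QTN", "QTL", "QTL"),
    chrom = "1",
    start = c(12622245, 13000000, 14000000),
    end = c(15000000, 16000000, 17191112)
  )
  hs <- integrate_hotspots(cl)
  expect_equal(nrow(hs), 1)
  expect_equal(hs$hotspot, "HS01")
  expect_equal(c(hs$start, hs$end), c(12622245, 17191112))
  expect_setequal(hs$clusters[[1]],
                  c("KW-gCL1-1", "KW-qCL1-1", "HKW-qCL1-1"))
})

test_that("hotspot integration equals the pairwise-graph oracle", {
  for (seed in 1:10) {
    withr::local_seed(seed)
    x <- random_intervals(100, chroms = c("1", "5"))
    cl <- dplyr::mutate(x, name = sprintf("KW-qCL-%03d", dplyr::row_number()),
                        trait = "KW", kind = "QTL")
    hs <- integrate_hotspots(cl, min_clusters = 3)
    want <- dplyr::filter(oracle_components(x), n_members >= 3)
    expect_equal(hs[c("chrom", "start", "end", "n_clusters")],
                 want, ignore_attr = TRUE)
  }
})

test_that("hotspots are numbered genome-wide by position and are disjoint", {
  cl <- dplyr::bind_rows(
    toy_clusters(c(5e6, 6e6, 7e6), c(9e6, 9e6, 9e6), chrom = "2",
                 names = sprintf("a%d", 1:3)),
    toy_clusters(c(1e6, 2e6, 3e6), c(4e6, 4e6, 4e6), chrom = "1",
                 names = sprintf("b%d", 1:3)),
    toy_clusters(c(8e7, 8.1e7, 8.2e7), c(9e7, 9e7, 9e7), chrom = "1",
                 names = sprintf("c%d", 1:3))
  )
  hs <- integrate_hotspots(cl, build = b73_v4_build())
  expect_equal(hs$hotspot, c("HS01", "HS02", "HS03"))
  expect_equal(hs$chrom, c("1", "1", "2"))
  expect_true(all(hs$n_clusters >= 3))
  same <- hs$chrom[-1] == hs$chrom[-nrow(hs)]
  expect_true(all(hs$start[-1][same] > hs$end[-nrow(hs)][same]))
})

test_that("gene assignment uses any-overlap including 1-nt boundaries", {
  hs <- tibble::tibble(hotspot = "HS01", chrom = "1", start = 1000,
                       end = 2000, n_clusters = 3L,
                       clusters = list(c("a", "b", "c")))
  genes <- tibble::tibble(
    name = c("inside", "left_touch", "right_touch", "outside", "other_chr"),
    chrom = c("1", "1", "1", "1", "2"),
    start = c(1200, 900, 2000, 2500, 1200),
    end = c(1300, 1000, 2600, 3000, 1300)
  )
  out <- assign_hotspot_genes(hs, genes)
  expect_setequal(out$genes[[1]], c("inside", "left_touch", "right_touch"))
  expect_equal(out$n_genes, 3L)
})

test_that("genes without coordinates are skipped with a warning", {
  hs <- tibble::tibble(hotspot = "HS01", chrom = "1", start = 1000,
                       end = 2000, n_clusters = 3L)
  genes <- tibble::tibble(name = c("ok", "nocoord"), chrom = c("1", "1"),
                          start = c(1500, NA), end = c(1600, NA))
  expect_warning(out <- assign_hotspot_genes(hs, genes), "nocoord")
  expect_equal(out$genes[[1]], "ok")
})

test_that("no genes on the chromosome gives an empty list", {
  hs <- tibble::tibble(hotspot = "HS01", chrom = "3", start = 1000,
                       end = 2000, n_clusters = 3L)
  genes <- tibble::tibble(name = "g", chrom = "1", start = 1, end = 10)
  out <- assign_hotspot_genes(hs, genes)
  expect_equal(out$n_genes, 0L)
  expect_equal(out$genes[[1]], character(0))
})

test_that("span_mb reproduces printed lengths", {
  expect_equal(span_mb(20505000, 52520534, 0), 32)
  expect_equal(span_mb(20505000, 69017291, 1), 48.5)
  expect_equal(span_mb(130739025, 149279019, 1), 18.5)
  expect_equal(span_mb(7, 7, 1), 0)
})

test_that("hotspot summary matches the published collection", {
  s <- summarize_hotspots(table2_hotspots(), b73_v4_build())
  expect_equal(s$n_hotspots, 31)
  pc <- tibble::deframe(s$per_chromosome)
  expect_equal(unname(pc["1"]), 7)
  expect_equal(unname(pc["6"]), 0)
  expect_equal(unname(pc["5"]), 6)
  expect_equal(sum(s$per_chromosome$n), s$n_hotspots)
  expect_equal(s$n_ge5_clusters, 12)
  expect_equal(s$n_with_genes, 10)
  expect_equal(s$n_without_genes, 21)
  expect_equal(s$min_members, 3)
  expect_equal(s$max_members, 14)
})

test_that("empty hotspot collection summarizes to zeros", {
  empty <- integrate_hotspots(
    tibble::tibble(name = character(), chrom = character(),
                   start = double(), end = double()))
  s <- summarize_hotspots(empty, b73_v4_build())
  expect_equal(s$n_hotspots, 0)
  expect_equal(sum(s$per_chromosome$n), 0)
  expect_equal(s$n_ge5_clusters, 0)
})
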