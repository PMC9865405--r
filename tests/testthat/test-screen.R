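expr_toy <- function(...) {
  vals <- list(...)
  dplyr::bind_rows(lapply(names(vals), function(g) {
    tibble::tibble(gene_id = g, tissue = names(vals[[g]]),
                   fpkm = unname(vals[[g]]))
  }))
}
kt <- c("kernel", "embryo")

test_that("expression summary computes maxima over the right tissue sets", {
  e <- expr_toy(
    g1 = c(kernel = 100, embryo = 80, leaf = 250),
    g2 = c(kernel = 300, embryo = 10, leaf = 120),
    g3 = c(kernel = 0, embryo = 0, leaf = 0)
  )
  s <- expression_summary(e, kt)
  s <- s[match(c("g1", "g2", "g3"), s$gene_id), ]
  expect_equal(s$max_exp, c(250, 300, 0))
  expect_equal(s$max_exp_kernel, c(100, 300, 0))
  expect_equal(s$ratio, c(2.5, 1, NA))   # highest-in-kernel case gives 1
  expect_true(all(s$max_exp >= s$max_exp_kernel))
})

test_that("an empty kernel tissue set is a configuration error", {
  e <- expr_toy(g1 = c(kernel = 1))
  expect_error(expression_summary(e, character(0)), "must not be empty")
  expect_error(expression_summary(e, "endosperm"), "none of the kernel")
})

test_that("filter bounds are inclusive exactly as stated", {
  s <- tibble::tibble(
    gene_id = c("edge", "low", "ratio_edge", "ratio_over", "undef"),
    max_exp = c(150, 49.9, 300, 301, 0),
    max_exp_kernel = c(50, 49.9, 100, 100, 0),
    ratio = c(3, 1, 3, 3.01, NA)
  )
  out <- filter_candidates(s)
  expect_equal(out$status[out$gene_id == "edge"], "pass")
  expect_equal(out$status[out$gene_id == "low"], "fail")
  expect_equal(out$status[out$gene_id == "ratio_edge"], "pass")
  expect_equal(out$status[out$gene_id == "ratio_over"], "fail")
  expect_equal(out$status[out$gene_id == "undef"], "fail")
})

test_that("genes without expression data are tallied as no_data", {
  s <- tibble::tibble(gene_id = "g1", max_exp = 100, max_exp_kernel = 100,
                      ratio = 1)
  out <- filter_candidates(s, genes = c("g1", "g2", "g3"))
  expect_equal(sum(out$status == "no_data"), 2)
  expect_equal(nrow(out), 3)  # |pass| + |fail| + |no_data| = input size
})

test_that("raising the FPKM threshold never enlarges the passing set", {
  withr::local_seed(21)
  s <- tibble::tibble(gene_id = sprintf("g%d", 1:100),
                      max_exp_kernel = runif(100, 0, 400))
  s$ratio <- runif(100, 1, 6)
  s$max_exp <- s$max_exp_kernel * s$ratio
  prev <- NULL
  for (thr in c(10, 50, 100, 200)) {
    pass <- filter_candidates(s, min_kernel_fpkm = thr)
    pass <- pass$gene_id[pass$status == "pass"]
    if (!is.null(prev)) expect_true(all(pass %in% prev))
    prev <- pass
  }
})

test_that("expression bins keep the extreme classes strict and conserve counts", {
  s <- tibble::tibble(
    gene_id = sprintf("g%d", 1:9),
    max_exp_kernel = c(501, 500, 200, 150, 100, 55, 20, 10, 0),
    max_exp = c(501, 500, 200, 150, 100, 55, 20, 10, 0),
    ratio = c(1, 1, 1, 2, 3, 3.5, 5, 6, NA)
  )
  b <- bin_expression(s)
  f <- tibble::deframe(b$fpkm)
  expect_equal(unname(f[">500"]), 1)      # ">500" is strict
  expect_equal(unname(f["200-500"]), 2)   # 500 exactly stays here
  expect_equal(unname(f["100-200"]), 2)
  expect_equal(unname(f["50-100"]), 1)
  expect_equal(unname(f["20-50"]), 1)
  expect_equal(unname(f["10-20"]), 1)     # "<10" is strict, 10 sits here
  expect_equal(unname(f["<10"]), 1)
  expect_equal(sum(b$fpkm$n), nrow(s))
  r <- tibble::deframe(b$ratio)
  expect_equal(unname(r["=1"]), 3)
  expect_equal(unname(r["1-3"]), 2)       # ratio 3 exactly falls here
  expect_equal(unname(r["3-5"]), 2)
  expect_equal(unname(r[">5"]), 1)
  expect_equal(unname(r["undefined"]), 1)
  expect_equal(sum(b$ratio$n), nrow(s))
})

test_that("empty input gives all-zero histograms", {
  b <- bin_expression(tibble::tibble(gene_id = character(),
                                     max_exp = double(),
                                     max_exp_kernel = double(),
                                     ratio = double()))
  expect_equal(sum(b$fpkm$n), 0)
  expect_equal(sum(b$ratio$n), 0)
  expect_equal(nrow(b$fpkm), 7)
})

test_that("PPR matching is case-insensitive with token boundaries", {
  expect_true(is_ppr_annotation("PPR protein, RNA editing"))
  expect_true(is_ppr_annotation("Plastid PPR protein, chloroplast"))
  expect_true(is_ppr_annotation("pentatricopeptide repeat protein"))
  expect_false(is_ppr_annotation("Sucrose synthase, starch biosynthesis"))
  expect_false(is_ppr_annotation("suppressor protein"))
  expect_false(is_ppr_annotation(NA))
})

test_that("PPR search over hotspots joins annotations per hotspot", {
  hs <- tibble::tibble(hotspot = c("HS01", "HS02"),
                       genes = c("Dek10,Sh1", "Dek1"))
  genes <- tibble::tibble(
    name = c("Dek10", "Sh1", "Dek1"),
    annotation = c("PPR protein, RNA editing",
                   "Sucrose synthase, starch biosynthesis",
                   "Membrane protein, plant signal transduction")
  )
  out <- find_ppr_genes(hs, genes)
  expect_equal(out$hotspot, "HS01")
  expect_equal(out$gene, "Dek10")
})

test_that("the published gene table contains known PPR members", {
  g <- table1_genes()
  ppr <- g[is_ppr_annotation(g$annotation), ]
  expect_true(all(c("Dek10", "Ppr22", "qKW9") %in% ppr$name))
  expect_false("Sh1" %in% ppr$name)
})
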