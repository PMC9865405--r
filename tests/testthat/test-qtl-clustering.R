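test_that("disjoint intervals form separate components", {
  x <- tibble::tibble(chrom = "1", start = c(1, 20), end = c(10, 30))
  comp <- merge_overlapping(x)$components
  expect_equal(nrow(comp), 2)
})

test_that("overlap chains merge transitively", {
  x <- tibble::tibble(chrom = "1", start = c(1, 8, 18), end = c(10, 20, 30))
  comp <- merge_overlapping(x)$components
  expect_equal(nrow(comp), 1)
  expect_equal(c(comp$start, comp$end), c(1, 30))
  expect_equal(comp$n_members, 3)
})

test_that("touching intervals (end + 1 == start) are not merged", {
  x <- tibble::tibble(chrom = "1", start = c(1, 11), end = c(10, 20))
  expect_equal(nrow(merge_overlapping(x)$components), 2)
})

test_that("sweep-line merge equals the pairwise-graph oracle", {
  for (seed in 1:30) {
    withr::local_seed(seed)
    x <- random_intervals(sample(200, 1))
    got <- merge_overlapping(x)$components
    want <- oracle_components(x)
    expect_equal(got[c("chrom", "start", "end", "n_members")],
                 want, ignore_attr = TRUE)
  }
})

test_that("below-threshold components yield no cluster", {
  p <- toy_projected("KL", "1", c(100, 150), c(300, 500))
  expect_equal(nrow(find_qtl_clusters(p)), 0)
})

test_that("three mutually overlapping QTLs form one cluster", {
  p <- toy_projected("KL", "7", c(100, 150, 120), c(400, 500, 450))
  cl <- find_qtl_clusters(p)
  expect_equal(nrow(cl), 1)
  expect_equal(c(cl$start, cl$end), c(100, 500))
  expect_equal(cl$n_members, 3)
  expect_setequal(cl$member_ids[[1]], p$qtl_id)
  expect_equal(cl$name, "KL-qCL7-1")
})

test_that("separated components of sizes 3 and 4 give two clusters", {
  p <- toy_projected("KW", "2",
                     c(100, 150, 120, 9000, 9100, 9050, 9200),
                     c(400, 500, 450, 9500, 9600, 9550, 9700))
  cl <- find_qtl_clusters(p)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$n_members, c(3, 4))
  expect_equal(cl$name, c("KW-qCL2-1", "KW-qCL2-2"))
})

test_that("cluster numbering restarts per chromosome per trait", {
  p <- dplyr::bind_rows(
    toy_projected("KW", "1", c(1, 2, 3), c(100, 100, 100),
                  ids = sprintf("a%d", 1:3)),
    toy_projected("KW", "1", c(5000, 5001, 5002), c(6000, 6000, 6000),
                  ids = sprintf("b%d", 1:3)),
    toy_projected("KW", "2", c(1, 2, 3), c(100, 100, 100),
                  ids = sprintf("c%d", 1:3)),
    toy_projected("KL", "1", c(1, 2, 3), c(100, 100, 100),
                  ids = sprintf("d%d", 1:3))
  )
  cl <- find_qtl_clusters(p)
  expect_setequal(cl$name,
                  c("KW-qCL1-1", "KW-qCL1-2", "KW-qCL2-1", "KL-qCL1-1"))
  # the second KW cluster on chromosome 1 carries index 2
  expect_equal(cl$name[cl$start == 5000], "KW-qCL1-2")
  # deterministic under re-run
  expect_equal(find_qtl_clusters(p), cl)
})

test_that("clustering cluster spans is idempotent", {
  withr::local_seed(42)
  x <- random_intervals(120, chroms = c("1", "2", "3"))
  p <- dplyr::mutate(x, qtl_id = sprintf("q%03d", dplyr::row_number()),
                     trait = "KT")
  cl <- find_qtl_clusters(p, min_members = 1)
  again <- find_qtl_clusters(
    dplyr::mutate(cl, qtl_id = name), min_members = 1)
  expect_equal(again[c("chrom", "start", "end")],
               cl[c("chrom", "start", "end")])
})

test_that("members all overlap the cluster span and appear at most once", {
  withr::local_seed(3)
  x <- random_intervals(150)
  p <- dplyr::mutate(x, qtl_id = sprintf("q%03d", dplyr::row_number()),
                     trait = "HKW")
  cl <- find_qtl_clusters(p)
  ids <- unlist(cl$member_ids)
  expect_equal(anyDuplicated(ids), 0)
  for (i in seq_len(nrow(cl))) {
    m <- p[p$qtl_id %in% cl$member_ids[[i]], ]
    expect_true(all(m$chrom == cl$chrom[i]))
    expect_true(all(m$start <= cl$end[i] & m$end >= cl$start[i]))
  }
})

test_that("adding a QTL never shrinks its component", {
  withr::local_seed(9)
  for (rep in 1:5) {
    x <- random_intervals(60, chroms = "1")
    comp <- merge_overlapping(x)
    extra <- random_intervals(1, chroms = "1")
    comp2 <- merge_overlapping(dplyr::bind_rows(x, extra))
    # count members of the component containing each original interval
    size_of <- function(m, co) {
      co$n_members[match(m$component, co$component)]
    }
    before <- size_of(comp$members, comp$components)
    after <- size_of(comp2$members[seq_len(nrow(x)), ], comp2$components)
    expect_true(all(after >= before))
  }
})
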