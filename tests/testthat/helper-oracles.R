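# Independent oracles used to cross-check the package's own algorithms.
# They deliberately take a different algorithmic route (pairwise graphs,
# exhaustive enumeration) from the implementations they validate.

# O(n^2) pairwise-overlap graph + connected components (igraph route)
oracle_components <- function(x) {
  if (nrow(x) == 0) {
    return(tibble::tibble(chrom = character(), start = double(),
                          end = double(), n_members = integer()))
  }
  n <- nrow(x)
  adj <- outer(seq_len(n), seq_len(n), function(i, j) {
    x$chrom[i] == x$chrom[j] & x$start[i] <= x$end[j] & x$end[i] >= x$start[j]
  })
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  out <- lapply(split(seq_len(n), comp), function(i) {
    tibble::tibble(chrom = x$chrom[i[1]], start = min(x$start[i]),
                   end = max(x$end[i]), n_members = length(i))
  })
  dplyr::arrange(dplyr::bind_rows(out), chrom, start)
}

# exhaustive anchored-window QTN oracle: every window anchored at a point,
# qualifying windows merged through a window-overlap graph
oracle_qtn_clusters <- function(pos, window, min_count) {
  p <- sort(pos)
  n <- length(p)
  anchors <- which(vapply(seq_len(n), function(i) {
    sum(p >= p[i] & p <= p[i] + window) >= min_count
  }, logical(1)))
  if (!length(anchors)) {
    return(tibble::tibble(start = double(), end = double(),
                          n_members = integer()))
  }
  ws <- p[anchors]
  we <- p[anchors] + window
  k <- length(anchors)
  adj <- outer(seq_len(k), seq_len(k), function(i, j) {
    ws[i] <= we[j] & we[i] >= ws[j]
  })
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  out <- lapply(split(seq_len(k), comp), function(i) {
    lo <- min(ws[i]); hi <- max(we[i])
    inside <- p[p >= lo & p <= hi]
    tibble::tibble(start = min(inside), end = max(inside),
                   n_members = length(inside))
  })
  dplyr::arrange(dplyr::bind_rows(out), start)
}

# exhaustive hypergeometric upper tail: enumerate all n-subsets of N
oracle_hyper_upper <- function(k, K, n, N) {
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K)   # items 1..K are the "annotated" ones
  mean(hits >= k)
}

# hand Benjamini-Hochberg: min over j >= i of p_(j) * m / j, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(adj, 1)[order(o)]
}

random_intervals <- function(n, chroms = c("1", "2"), max_pos = 1e6,
                             max_len = 2e5) {
  s <- floor(runif(n, 1, max_pos))
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = s,
    end = s + floor(runif(n, 0, max_len))
  )
}

toy_projected <- function(trait, chrom, starts, ends,
                          ids = sprintf("q%02d", seq_along(starts))) {
  tibble::tibble(qtl_id = ids, trait = trait, chrom = chrom,
                 start = starts, end = ends)
}
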