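#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing at
#' least `k` annotated genes in a sample of `n` from a background of `N`
#' genes of which `K` carry the annotation. This is the classical one-sided
#' over-representation p-value of GO term enrichment. Evaluated through
#' the distribution function of the hypergeometric family in the stats
#' namespace, which is numerically stable over the full parameter range.
#'
#' @param k Observed count(s) of annotated genes in the study set.
#' @param K Annotated genes in the background.
#' @param n Study-set size.
#' @param N Background size.
#' @return Probability vector; `k = 0` gives exactly 1.
#' @examples
#' hypergeom_upper_tail(4, K = 5, n = 4, N = 10) # 5/210
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(K > N) || any(n > N) || any(k < 0) || any(k > pmin(n, K))) {
    stop("need 0 <= k <= min(n, K), K <= N, n <= N", call. = FALSE)
  }
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' GO term over-representation with BH FDR control
#'
#' Tests each GO term for over-representation of study genes relative to a
#' background using the one-sided hypergeometric test, and adjusts
#' p-values across all tested terms with the Benjamini-Hochberg procedure.
#' Only terms with at least one study gene are tested. The background
#' defaults to every gene in the annotation table; study genes absent from
#' the background are an error (they would silently deflate `N`).
#'
#' @param study Character vector of study gene ids.
#' @param annotations Tibble `gene_id`, `term_id` (see
#'   [read_go_annotations()]).
#' @param term_names Optional tibble `term_id`, `term_name`.
#' @param background Optional character vector overriding the default
#'   background gene universe.
#' @param fdr_threshold Significance cutoff on the adjusted value
#'   (default 0.05).
#' @return A `go_enrichment` tibble ordered by (p_value, term_id):
#'   `term_id`, `term_name`, `k`, `n`, `K`, `N`, `p_value`, `fdr`,
#'   `significant`.
#' @export
enrich_go <- function(study, annotations, term_names = NULL,
                      background = NULL, fdr_threshold = 0.05) {
  stopifnot(all(c("gene_id", "term_id") %in% names(annotations)))
  study <- unique(study)
  background <- unique(background %||% annotations$gene_id)
  missing <- setdiff(study, background)
  if (length(missing)) {
    stop("study gene(s) absent from the background: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  ann <- dplyr::distinct(
    dplyr::filter(annotations, .data$gene_id %in% background),
    .data$gene_id, .data$term_id)
  n <- length(study)
  N <- length(background)
  tab <- ann |>
    dplyr::group_by(term_id = .data$term_id) |>
    dplyr::summarise(k = sum(.data$gene_id %in% study),
                     K = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$k >= 1)
  tab$n <- n
  tab$N <- N
  tab$p_value <- hypergeom_upper_tail(tab$k, tab$K, tab$n, tab$N)
  tab$fdr <- stats::p.adjust(tab$p_value, method = "BH")
  tab$significant <- tab$fdr <= fdr_threshold
  if (!is.null(term_names)) {
    tab <- dplyr::left_join(tab,
                            dplyr::select(term_names, "term_id", "term_name"),
                            by = "term_id")
  } else {
    tab$term_name <- NA_character_
  }
  out <- tab |>
    dplyr::arrange(.data$p_value, .data$term_id) |>
    dplyr::select("term_id", "term_name", "k", "n", "K", "N", "p_value",
                  "fdr", "significant")
  class(out) <- c("go_enrichment", class(out))
  out
}
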