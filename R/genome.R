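#' Maize B73_V4 genome build
#'
#' Chromosome names and lengths of the maize B73 reference genome assembly,
#' version 4 (B73 RefGen_v4), the coordinate system on which all QTLs, QTNs
#' and genes are placed. Chromosomes are named `"1"` to `"10"`.
#'
#' @return A tibble with columns `chrom` (character) and `length`
#'   (nucleotides), one row per chromosome, in genome order.
#' @examples
#' b73_v4_build()
#' @export
b73_v4_build <- function() {
  tibble::tibble(
    chrom = as.character(1:10),
    length = c(
      307041717, 244442276, 235667834, 246994605, 223902240,
      174033170, 182381542, 181122637, 159769782, 150982314
    )
  )
}

#' The four kernel size-related traits
#'
#' The closed trait vocabulary used throughout the package: kernel length
#' (KL), kernel width (KW), kernel thickness (KT) and hundred-kernel weight
#' (HKW). Any other trait code in an input table is a curation error and is
#' rejected by the readers.
#'
#' @return Character vector of the four trait codes.
#' @export
kernel_traits <- function() c("KL", "KW", "KT", "HKW")

validate_build <- function(build) {
  stopifnot(is.data.frame(build))
  if (!all(c("chrom", "length") %in% names(build))) {
    stop("a genome build needs `chrom` and `length` columns", call. = FALSE)
  }
  if (anyDuplicated(build$chrom)) {
    stop("chromosome names in the build must be unique", call. = FALSE)
  }
  if (any(build$length <= 0)) {
    stop("chromosome lengths must be positive", call. = FALSE)
  }
  invisible(build)
}

# order chromosome names: build order when supplied, else numeric-aware
chrom_levels <- function(chroms, build = NULL) {
  if (!is.null(build)) {
    return(build$chrom)
  }
  u <- unique(as.character(chroms))
  num <- suppressWarnings(as.numeric(sub("^chr", "", u)))
  u[order(is.na(num), num, u)]
}

#' Validate genomic intervals against a build
#'
#' Checks that every interval satisfies `1 <= start <= end` and, when a
#' build is supplied, that the chromosome exists and `end` does not exceed
#' its length. Coordinates are 1-based and inclusive at both ends.
#'
#' @param x A data frame with columns `chrom`, `start`, `end`.
#' @param build Optional genome build (see [b73_v4_build()]).
#' @return `x`, invisibly; errors describe the offending rows.
#' @export
validate_intervals <- function(x, build = NULL) {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x))) {
    stop("intervals need columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  bad <- which(is.na(x$start) | is.na(x$end) | x$start < 1 | x$start > x$end)
  if (length(bad)) {
    stop("invalid interval (need 1 <= start <= end) at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (!is.null(build)) {
    validate_build(build)
    len <- build$length[match(as.character(x$chrom), build$chrom)]
    bad <- which(is.na(len) | x$end > len)
    if (length(bad)) {
      stop("interval outside build (unknown chromosome or end > length) at row(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  invisible(x)
}

# round half away from zero, the convention used for printed Mb spans
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Interval span in megabases
#'
#' Physical length of an interval as printed in hotspot summaries:
#' `(end - start) / 1e6`, rounded half-up to the requested precision.
#' For example the span 20,505,000-52,520,534 is 32 Mb at integer
#' precision and the span 20,505,000-69,017,291 is 48.5 Mb at one decimal.
#'
#' @param start,end 1-based inclusive endpoints (vectors recycle).
#' @param digits Reporting precision in decimal digits (default 1).
#' @return Numeric vector of spans in Mb.
#' @export
span_mb <- function(start, end, digits = 1) {
  stopifnot(all(end >= start))
  round_half_up((end - start) / 1e6, digits)
}
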