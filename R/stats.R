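#' Repertoire clonality (1 - Pielou evenness)
#'
#' Clonality is `1 + sum(p_i * ln(p_i)) / ln(n)` for a repertoire of `n`
#' unique clones with frequencies `p_i`: 0 for a perfectly even
#' repertoire, approaching 1 as a few clones dominate. For `n = 1` the
#' formula is 0/0 and the value is defined as 1 (maximally uneven) by
#' convention.
#'
#' @param x A [tcr_repertoire()] or a numeric vector of clone frequencies
#'   summing to 1.
#' @return Clonality in `[0, 1]`.
#' @export
clonality <- function(x) {
  p <- if (inherits(x, "tcr_repertoire")) x$clones$freq else as.double(x)
  n <- length(p)
  if (n == 0L) {
    rlang::abort("clonality is undefined for an empty repertoire",
                 class = "tcrioct_empty_repertoire")
  }
  if (any(p <= 0)) {
    rlang::abort("zero or negative clone frequency: drop zero clones first",
                 class = "tcrioct_domain_error")
  }
  if (n == 1L) return(1)
  1 + sum(p * log(p)) / log(n)
}

#' Repertoire diversity above a frequency threshold
#'
#' The number of clones whose frequency is strictly greater than the
#' threshold (default 0.01%).
#'
#' @param rep A [tcr_repertoire()].
#' @param threshold Frequency cut, as a fraction (default `1e-4`).
#' @return Integer clone count.
#' @export
diversity <- function(rep, threshold = 1e-4) {
  sum(rep$clones$freq > threshold)
}

#' Rank-quantile statistics of a repertoire
#'
#' Clones are ranked by descending frequency and split into five
#' equal-rank bins (top 20%, 20-40%, 40-60%, 60-80%, 80-100%); bin `k`
#' covers ranks `(ceil(n(k-1)/5), ceil(nk/5)]`. Reports each bin's
#' combined frequency plus the individual frequencies of the top 5
#' clones.
#'
#' @param rep A [tcr_repertoire()] with at least 5 clones.
#' @return A list of class `quantile_stats` with elements
#'   `bin_frequencies` (length 5, named), `top_clone_frequencies`
#'   (length 5), and `n` (clone count).
#' @export
quantile_stats <- function(rep) {
  cl <- canonical_sort(rep$clones)
  f <- cl$freq[order(-cl$freq, method = "radix")]
  n <- length(f)
  if (n < 5L) {
    rlang::abort(sprintf("quantile statistics need >= 5 clones, got %d", n),
                 class = "tcrioct_insufficient_clones")
  }
  bounds <- ceiling(n * (0:5) / 5)
  bins <- vapply(1:5, function(k) {
    sum(f[(bounds[k] + 1L):bounds[k + 1L]])
  }, numeric(1))
  names(bins) <- c("top_0_20", "q20_40", "q40_60", "q60_80", "q80_100")
  structure(
    list(bin_frequencies = bins,
         top_clone_frequencies = f[1:5],
         n = n),
    class = "quantile_stats"
  )
}

#' @export
print.quantile_stats <- function(x, ...) {
  cat(sprintf("<quantile_stats> n = %d clones\n", x$n))
  print(round(x$bin_frequencies, 4))
  cat("top 5 clones:", paste(signif(x$top_clone_frequencies, 3),
                             collapse = ", "), "\n")
  invisible(x)
}

#' V/J segment usage
#'
#' Combined clone frequency for every observed (V, J) segment pair; the
#' entries sum to 1 when the repertoire's frequencies do.
#'
#' @param rep A [tcr_repertoire()].
#' @param strip_alleles Strip `*NN` allele suffixes before grouping.
#' @return A tibble with columns `v`, `j`, `freq`, sorted by descending
#'   `freq`.
#' @export
vj_usage <- function(rep, strip_alleles = TRUE) {
  cl <- rep$clones
  v <- if (strip_alleles) strip_allele(cl$v) else cl$v
  j <- if (strip_alleles) strip_allele(cl$j) else cl$j
  tibble::tibble(v = v, j = j, freq = cl$freq) |>
    dplyr::group_by(.data$v, .data$j) |>
    dplyr::summarise(freq = sum(.data$freq), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$freq), .data$v, .data$j)
}

#' Rank-frequency distribution
#'
#' Clone frequencies in descending order (ties broken by the package's
#' deterministic clone order), as plotted in repertoire distribution
#' plots.
#'
#' @param rep A [tcr_repertoire()].
#' @param top_n Number of top clones to return (default: all).
#' @return A tibble with columns `rank` and `freq`.
#' @export
rank_frequency <- function(rep, top_n = Inf) {
  if (top_n < 1) {
    rlang::abort("top_n must be >= 1", class = "tcrioct_config_error")
  }
  cl <- canonical_sort(rep$clones)
  f <- cl$freq[order(-cl$freq, method = "radix")]
  m <- min(top_n, length(f))
  tibble::tibble(rank = seq_len(m), freq = f[seq_len(m)])
}
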