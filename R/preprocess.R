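#' Remove non-functional clones
#'
#' Non-functional clones carry a stop codon (`*`) or a frameshift (`_`)
#' marker in their CDR3 amino-acid sequence. They are removed and the
#' frequencies of the surviving clones are recomputed from surviving read
#' counts so that they sum to 1.
#'
#' @param rep A [tcr_repertoire()] with `cdr3aa` populated.
#' @param markers Characters marking a non-functional receptor.
#' @return The filtered, renormalized [tcr_repertoire()].
#' @export
filter_nonfunctional <- function(rep, markers = c("*", "_")) {
  hit <- logical(n_clones(rep))
  for (m in markers) {
    hit <- hit | grepl(m, rep$clones$cdr3aa, fixed = TRUE)
  }
  keep <- rep$clones[!hit, , drop = FALSE]
  if (nrow(keep) == 0L) {
    rlang::abort("all clones are non-functional; nothing left to analyze",
                 class = "tcrioct_empty_repertoire")
  }
  keep$freq <- keep$count / sum(keep$count)
  set_clones(rep, canonical_sort(keep))
}

#' Chain-specific target sequencing coverage
#'
#' Coverage is the ratio of total reads to the number of sorted starting
#' T cells. Repertoires are normalized to a common coverage by
#' downsampling: x9 for TCRbeta, x5 for TCRalpha.
#'
#' @param chain `"TRB"` or `"TRA"`.
#' @return Target coverage (reads per starting cell).
#' @export
default_coverage <- function(chain) {
  switch(as.character(chain),
         TRB = 9,
         TRA = 5,
         rlang::abort(paste0("no default coverage for chain '", chain,
                             "'; supply `coverage` explicitly"),
                      class = "tcrioct_config_error"))
}

#' Coverage-normalize a repertoire by downsampling reads
#'
#' Draws exactly `round(coverage * cell_count)` reads (ties rounded to
#' even) without replacement from the repertoire's read pool — a
#' multivariate hypergeometric draw in which each clone contributes
#' `count` indistinguishable reads. Clones reduced to zero reads are
#' removed and frequencies are recomputed from the sampled counts. The
#' draw is deterministic given `seed`.
#'
#' @param rep A [tcr_repertoire()].
#' @param coverage Target reads per starting cell; defaults to the
#'   chain-specific standard ([default_coverage()]).
#' @param cell_count Number of sorted starting T cells; defaults to the
#'   repertoire's own `cell_count`.
#' @param seed Integer seed; required for reproducibility.
#' @param insufficient What to do when total reads fall short of the
#'   target: `"error"` (default) aborts with the deficit, `"keep"` returns
#'   the repertoire unchanged (permissive mode).
#' @param replace Sample reads with replacement (multinomial) instead of
#'   without (hypergeometric). Off by default.
#' @return The downsampled [tcr_repertoire()]; its total count equals the
#'   target exactly.
#' @export
downsample_repertoire <- function(rep, coverage = NULL, cell_count = NULL,
                                  seed,
                                  insufficient = c("error", "keep"),
                                  replace = FALSE) {
  insufficient <- match.arg(insufficient)
  if (is.null(coverage)) coverage <- default_coverage(rep$chain)
  if (is.null(cell_count)) cell_count <- rep$cell_count
  if (is.null(cell_count) || is.na(cell_count) || cell_count <= 0) {
    rlang::abort("a positive cell_count is required for downsampling",
                 class = "tcrioct_config_error")
  }
  if (missing(seed)) {
    rlang::abort("downsampling requires an explicit seed",
                 class = "tcrioct_config_error")
  }
  target <- as.integer(round(coverage * cell_count))
  total <- total_reads(rep)
  if (total < target && !replace) {
    if (insufficient == "keep") return(rep)
    rlang::abort(
      sprintf(paste0("insufficient coverage: %d reads available, %d",
                     " required (deficit %d)"), total, target, total - target),
      class = "tcrioct_insufficient_coverage",
      deficit = target - total
    )
  }
  counts <- rep$clones$count
  sampled <- withr::with_seed(seed, {
    if (replace) {
      as.integer(stats::rmultinom(1L, target, counts))
    } else {
      rmvhyper(counts, target)
    }
  })
  keep <- rep$clones
  keep$count <- sampled
  keep <- keep[keep$count > 0L, , drop = FALSE]
  keep$freq <- keep$count / target
  set_clones(rep, canonical_sort(keep))
}

# Multivariate hypergeometric draw: k reads without replacement from urns
# holding `counts` reads each, via sequential conditional univariate
# hypergeometric draws.
rmvhyper <- function(counts, k) {
  n <- length(counts)
  out <- integer(n)
  remaining <- sum(counts)
  for (i in seq_len(n)) {
    if (k == 0L) break
    ni <- counts[i]
    remaining <- remaining - ni
    if (remaining == 0L) {
      out[i] <- k
      k <- 0L
      break
    }
    x <- stats::rhyper(1L, ni, remaining, k)
    out[i] <- x
    k <- k - x
  }
  out
}
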