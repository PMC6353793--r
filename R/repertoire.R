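#' Construct a TCR repertoire
#'
#' A repertoire is one sample's clonotype list plus its metadata: which
#' mouse and tissue compartment it came from, the TCR chain, treatment
#' group, and (optionally) the number of sorted starting T cells used for
#' coverage normalization.
#'
#' @param clones A data frame of clonotypes with columns `count`
#'   (non-negative integer read count), `freq` (clone frequency in
#'   `[0, 1]`), `cdr3nt` (CDR3 nucleotide sequence), `cdr3aa` (CDR3
#'   amino-acid sequence; may contain the stop marker `*` or frameshift
#'   marker `_`), `v`, `d`, `j` (IMGT segment names; `d` may be empty).
#' @param mouse_id Sample's mouse identifier.
#' @param compartment Tissue compartment, one of `"dLN_CD44hi"`,
#'   `"dLN_whole"`, `"PBL"`, `"tumor"`.
#' @param chain TCR chain, `"TRA"` or `"TRB"`.
#' @param group Treatment group, `"control"` or `"aCD4"` (or `NA`).
#' @param cell_count Number of sorted starting T cells, or `NA`.
#'
#' @return An object of class `tcr_repertoire`.
#' @export
tcr_repertoire <- function(clones, mouse_id = NA_character_,
                           compartment = NA_character_,
                           chain = NA_character_,
                           group = NA_character_,
                           cell_count = NA_integer_) {
  clones <- tibble::as_tibble(clones)
  required <- c("count", "freq", "cdr3nt", "cdr3aa", "v", "j")
  missing <- setdiff(required, names(clones))
  if (length(missing) > 0L) {
    rlang::abort(
      paste0("clone table is missing required column(s): ",
             paste(missing, collapse = ", ")),
      class = "tcrioct_format_error"
    )
  }
  if (!"d" %in% names(clones)) clones$d <- ""
  clones$d[is.na(clones$d)] <- ""
  clones <- clones[, c("count", "freq", "cdr3nt", "cdr3aa", "v", "d", "j")]
  clones$count <- as.integer(clones$count)
  clones$freq <- as.double(clones$freq)
  rep <- structure(
    list(
      clones = clones,
      mouse_id = as.character(mouse_id),
      compartment = as.character(compartment),
      chain = as.character(chain),
      group = as.character(group),
      cell_count = if (is.na(cell_count)) NA_integer_ else as.integer(cell_count)
    ),
    class = "tcr_repertoire"
  )
  validate_repertoire(rep)
  rep
}

validate_repertoire <- function(rep) {
  cl <- rep$clones
  if (nrow(cl) > 0L) {
    if (any(is.na(cl$count)) || any(cl$count < 0L)) {
      rlang::abort("clone counts must be non-negative integers",
                   class = "tcrioct_format_error")
    }
    if (any(is.na(cl$freq)) || any(cl$freq < 0) || any(cl$freq > 1)) {
      rlang::abort("clone frequencies must lie in [0, 1]",
                   class = "tcrioct_format_error")
    }
    if (any(!nzchar(cl$cdr3nt)) || any(!nzchar(cl$v)) || any(!nzchar(cl$j))) {
      rlang::abort("cdr3nt, v and j must be non-empty for every clone",
                   class = "tcrioct_format_error")
    }
  }
  invisible(rep)
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  cat(sprintf(
    "<tcr_repertoire> %s | %s | %s | %s\n  %d clones, %s reads, cells: %s\n",
    x$mouse_id, x$compartment, x$chain, x$group,
    nrow(x$clones), format(sum(x$clones$count), big.mark = ","),
    ifelse(is.na(x$cell_count), "unknown", format(x$cell_count))
  ))
  print(utils::head(x$clones, 5L))
  if (nrow(x$clones) > 5L) cat(sprintf("  ... and %d more clones\n", nrow(x$clones) - 5L))
  invisible(x)
}

#' Number of clones in a repertoire
#' @param rep A [tcr_repertoire()].
#' @return Integer clone count.
#' @export
n_clones <- function(rep) nrow(rep$clones)

#' Total read count of a repertoire
#' @param rep A [tcr_repertoire()].
#' @return Integer total reads.
#' @export
total_reads <- function(rep) sum(rep$clones$count)

# Deterministic canonical clone order: descending count, ties broken
# lexicographically by (cdr3nt, v, j).  Keeps every downstream ranking
# reproducible across platforms.
canonical_sort <- function(clones) {
  ord <- order(-clones$count, clones$cdr3nt, clones$v, clones$j,
               method = "radix")
  clones[ord, , drop = FALSE]
}

# Replace clone table, preserving metadata.
set_clones <- function(rep, clones) {
  rep$clones <- tibble::as_tibble(clones)
  validate_repertoire(rep)
  rep
}
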