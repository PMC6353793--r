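#' Define a named clone to track
#'
#' A named clone (e.g. a transgenic melanoma-antigen-specific receptor, or
#' a receptor cloned from tumor-infiltrating lymphocytes) is identified by
#' its V segment, J segment and CDR3 sequence, at nucleotide or
#' amino-acid level.
#'
#' @param label Human-readable clone name.
#' @param mode Identity level: `"nt"` or `"aa"`.
#' @param v,j IMGT segment names.
#' @param cdr3 CDR3 sequence (nucleotide or amino acid, per `mode`).
#' @return A list of class `named_clone`.
#' @export
named_clone <- function(label, mode = c("nt", "aa"), v, j, cdr3) {
  mode <- match.arg(mode)
  if (!nzchar(label) || !nzchar(v) || !nzchar(j) || !nzchar(cdr3)) {
    rlang::abort("label, v, j and cdr3 must all be non-empty",
                 class = "tcrioct_config_error")
  }
  structure(list(label = label, mode = mode, v = v, j = j, cdr3 = cdr3),
            class = "named_clone")
}

#' Read named clones from a TSV file
#'
#' Columns: `label`, `mode` (`nt`/`aa`), `v`, `j`, `cdr3`.
#'
#' @param path Path to the tab-separated file.
#' @return A list of [named_clone()] objects.
#' @export
read_named_clones <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("label", "mode", "v", "j", "cdr3")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0L) {
    rlang::abort(paste0("named-clone file missing column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "tcrioct_format_error")
  }
  purrr::pmap(tbl[required], function(label, mode, v, j, cdr3) {
    named_clone(label, mode = mode, v = v, j = j, cdr3 = cdr3)
  })
}

#' Frequency of a named clone in a repertoire
#'
#' Sums the frequencies of all repertoire clones matching the named
#' clone's (V, J, CDR3) identity under its mode; under amino-acid mode
#' this aggregates synonymous nucleotide variants. Returns 0 when the
#' clone is absent. An allele-suffix mismatch alone (e.g. `TRBV13-3` vs
#' `TRBV13-3*01`) still matches by default.
#'
#' @param rep A [tcr_repertoire()].
#' @param clone A [named_clone()].
#' @param strip_alleles Strip allele suffixes before matching.
#' @return The clone's summed frequency (0 if absent).
#' @export
track_clone <- function(rep, clone, strip_alleles = TRUE) {
  stopifnot(inherits(clone, "named_clone"))
  keys <- clone_key(rep, mode = clone$mode, strip_alleles = strip_alleles)
  v <- clone$v
  j <- clone$j
  if (strip_alleles) {
    v <- strip_allele(v)
    j <- strip_allele(j)
  }
  target <- paste(v, j, clone$cdr3, sep = "|")
  sum(rep$clones$freq[keys == target])
}

#' Compare a tracked clone's frequency between treatment groups
#'
#' Tracks the clone in every repertoire, groups the frequencies by each
#' repertoire's `group` metadata, and reports per-group mean +/- SE
#' (SE = sample SD / sqrt(n)) together with a two-sided unpaired
#' Student's t-test (pooled variance; Welch's correction available behind
#' `welch = TRUE`).
#'
#' @param reps A list of [tcr_repertoire()] objects spanning exactly two
#'   treatment groups, with >= 2 mice per group.
#' @param clone A [named_clone()].
#' @param welch Use Welch's unequal-variance t-test instead of the pooled
#'   Student's test.
#' @param strip_alleles Strip allele suffixes before matching.
#' @return A list with `summary` (tibble: `group`, `n`, `mean`, `se`),
#'   `statistic` (t), and `p_value`.
#' @export
compare_tracked <- function(reps, clone, welch = FALSE,
                            strip_alleles = TRUE) {
  groups <- vapply(reps, function(r) r$group, character(1))
  freqs <- vapply(reps, track_clone, numeric(1), clone = clone,
                  strip_alleles = strip_alleles)
  levels <- unique(groups)
  if (length(levels) != 2L) {
    rlang::abort("compare_tracked needs exactly two treatment groups",
                 class = "tcrioct_input_error")
  }
  split_f <- split(freqs, factor(groups, levels = levels))
  ns <- lengths(split_f)
  if (any(ns < 2L)) {
    rlang::abort("each group needs >= 2 mice for a t-test",
                 class = "tcrioct_insufficient_replicates")
  }
  tt <- stats::t.test(split_f[[1L]], split_f[[2L]], var.equal = !welch)
  list(
    summary = tibble::tibble(
      group = levels,
      n = as.integer(ns),
      mean = unname(vapply(split_f, mean, numeric(1))),
      se = unname(vapply(split_f, function(x) stats::sd(x) / sqrt(length(x)),
                         numeric(1)))
    ),
    statistic = unname(tt$statistic),
    p_value = tt$p.value
  )
}
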