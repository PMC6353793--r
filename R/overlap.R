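#' Build an inter-organ overlap table
#'
#' The core of Inter-Organ Clone Tracking: given 2-3 repertoires from
#' distinct tissue compartments of the same mouse (same chain), finds the
#' clonotypes present in at least `min_compartments` of them and tabulates
#' each clone's frequency in every compartment (0 where absent).
#'
#' @param reps A list of 2-3 [tcr_repertoire()] objects sharing `mouse_id`
#'   and `chain`, from distinct compartments.
#' @param mode Clone identity, `"nt"` (default, within-mouse) or `"aa"`.
#' @param min_compartments Minimum number of compartments a clone must
#'   appear in (2 or 3).
#' @param strip_alleles Strip allele suffixes when matching segments.
#' @return A tibble of class `overlap_table`: columns `key`, `v`, `j`,
#'   `cdr3`, then one frequency column per compartment, plus
#'   `n_compartments`. Rows are ordered by descending maximum frequency,
#'   ties by key. Attributes: `mouse_id`, `chain`, `compartments`, `mode`.
#' @export
build_overlap <- function(reps, mode = c("nt", "aa"), min_compartments = 2L,
                          strip_alleles = TRUE) {
  mode <- match.arg(mode)
  if (!is.list(reps) || length(reps) < 2L || length(reps) > 3L) {
    rlang::abort("build_overlap needs a list of 2 or 3 repertoires",
                 class = "tcrioct_input_error")
  }
  if (!min_compartments %in% c(2L, 3L)) {
    rlang::abort("min_compartments must be 2 or 3",
                 class = "tcrioct_input_error")
  }
  comps <- vapply(reps, function(r) r$compartment, character(1))
  if (anyDuplicated(comps)) {
    rlang::abort("duplicate compartment among input repertoires",
                 class = "tcrioct_input_error")
  }
  mouse <- unique(vapply(reps, function(r) r$mouse_id, character(1)))
  chain <- unique(vapply(reps, function(r) r$chain, character(1)))
  if (length(mouse) != 1L || length(chain) != 1L) {
    rlang::abort("repertoires must share mouse_id and chain",
                 class = "tcrioct_input_error")
  }

  per_comp <- purrr::map2(reps, comps, function(r, comp) {
    r <- collapse_by_key(r, mode = mode, strip_alleles = strip_alleles)
    key <- clone_key(r, mode = mode, strip_alleles = strip_alleles)
    out <- tibble::tibble(
      key = key,
      v = if (strip_alleles) strip_allele(r$clones$v) else r$clones$v,
      j = if (strip_alleles) strip_allele(r$clones$j) else r$clones$j,
      cdr3 = if (mode == "nt") r$clones$cdr3nt else r$clones$cdr3aa
    )
    out[[comp]] <- r$clones$freq
    out
  })
  tbl <- purrr::reduce(per_comp, function(a, b) {
    dplyr::full_join(a, b, by = c("key", "v", "j", "cdr3"))
  })
  for (comp in comps) {
    tbl[[comp]][is.na(tbl[[comp]])] <- 0
  }
  fr <- as.matrix(tbl[, comps, drop = FALSE])
  tbl$n_compartments <- as.integer(rowSums(fr > 0))
  tbl <- tbl[tbl$n_compartments >= min_compartments, , drop = FALSE]
  maxf <- if (nrow(tbl) > 0L) {
    do.call(pmax, as.list(tbl[, comps, drop = FALSE]))
  } else numeric(0)
  tbl <- tbl[order(-maxf, tbl$key, method = "radix"), , drop = FALSE]
  structure(
    tbl,
    class = c("overlap_table", class(tibble::tibble())),
    mouse_id = mouse, chain = chain, compartments = comps, mode = mode
  )
}

overlap_compartments <- function(tbl) attr(tbl, "compartments")

#' Summarise an overlap table
#'
#' @param tbl An [build_overlap()] table.
#' @return A list with `clone_count` (number of overlapping clones) and
#'   `combined_frequency` (named per-compartment sums of the overlapping
#'   clones' frequencies).
#' @export
overlap_summary <- function(tbl) {
  comps <- overlap_compartments(tbl)
  combined <- vapply(comps, function(c) sum(tbl[[c]]), numeric(1))
  list(clone_count = nrow(tbl), combined_frequency = combined)
}

pattern_levels <- c("tumor_major_dLN_major", "tumor_major_dLN_minor",
                    "tumor_minor_dLN_major", "tumor_minor_dLN_minor")

#' Classify dLN-tumor overlapping clones into major/minor patterns
#'
#' Major clones have frequency >= `threshold` (default 0.1%, inclusive) in
#' a compartment, minor clones < `threshold`. Each overlapping clone falls
#' in exactly one of four patterns by its (tumor, dLN) status; percentages
#' are over all overlapping clones and sum to 100.
#'
#' @param tbl An [build_overlap()] table containing the dLN and tumor
#'   compartments.
#' @param threshold Major/minor frequency cut (fraction; default `0.001`).
#' @param tumor,dln Names of the tumor and dLN frequency columns.
#' @return A tibble of class `pattern_summary` with columns `pattern`,
#'   `n_clones`, `percent`; attributes `threshold` and `n_total`.
#' @export
classify_patterns <- function(tbl, threshold = 0.001,
                              tumor = "tumor", dln = "dLN_CD44hi") {
  for (col in c(tumor, dln)) {
    if (!col %in% names(tbl)) {
      rlang::abort(paste0("overlap table lacks compartment column '", col, "'"),
                   class = "tcrioct_input_error")
    }
  }
  if (nrow(tbl) == 0L) {
    rlang::abort("no overlapping clones: pattern percentages are undefined",
                 class = "tcrioct_empty_overlap")
  }
  pat <- paste0(
    ifelse(tbl[[tumor]] >= threshold, "tumor_major", "tumor_minor"), "_",
    ifelse(tbl[[dln]] >= threshold, "dLN_major", "dLN_minor")
  )
  counts <- table(factor(pat, levels = pattern_levels))
  out <- tibble::tibble(
    pattern = pattern_levels,
    n_clones = as.integer(counts),
    percent = 100 * as.integer(counts) / nrow(tbl)
  )
  structure(out,
            class = c("pattern_summary", class(tibble::tibble())),
            threshold = threshold, n_total = nrow(tbl))
}

#' Rank-frequency distribution of overlapping clones
#'
#' As [rank_frequency()], restricted to the overlapping clones and ranked
#' within one chosen compartment. Clones absent from that compartment
#' (possible when `min_compartments = 2` of 3) are dropped.
#'
#' @param tbl An [build_overlap()] table.
#' @param compartment Compartment column to rank by.
#' @param top_n Number of top clones to return (default: all).
#' @return A tibble with columns `rank` and `freq`.
#' @export
overlap_rank_frequency <- function(tbl, compartment, top_n = Inf) {
  if (!compartment %in% names(tbl)) {
    rlang::abort(paste0("unknown compartment '", compartment, "'"),
                 class = "tcrioct_input_error")
  }
  f <- tbl[[compartment]]
  f <- sort(f[f > 0], decreasing = TRUE)
  m <- min(top_n, length(f))
  tibble::tibble(rank = seq_len(m), freq = f[seq_len(m)])
}

#' Public clones across mice
#'
#' Public clones are clonotypes (amino-acid identity by default) shared by
#' at least two mice in the same compartment and chain. For each mouse,
#' reports the combined frequency of its clones found in at least one
#' other mouse, plus the cross-mouse mean.
#'
#' @param reps A list of >= 2 [tcr_repertoire()] objects, one per mouse,
#'   same compartment and chain.
#' @param mode Clone identity for cross-mouse matching (default `"aa"`).
#' @param strip_alleles Strip allele suffixes when matching segments.
#' @return A list with `per_mouse` (tibble: `mouse_id`,
#'   `public_frequency`) and `mean` (cross-mouse mean frequency).
#' @export
public_clones <- function(reps, mode = c("aa", "nt"), strip_alleles = TRUE) {
  mode <- match.arg(mode)
  if (!is.list(reps) || length(reps) < 2L) {
    rlang::abort("public-clone analysis needs repertoires from >= 2 mice",
                 class = "tcrioct_input_error")
  }
  comp <- unique(vapply(reps, function(r) r$compartment, character(1)))
  chain <- unique(vapply(reps, function(r) r$chain, character(1)))
  if (length(comp) != 1L || length(chain) != 1L) {
    rlang::abort("repertoires must share compartment and chain",
                 class = "tcrioct_input_error")
  }
  mice <- vapply(reps, function(r) r$mouse_id, character(1))
  if (anyDuplicated(mice)) {
    rlang::abort("duplicate mouse_id among repertoires",
                 class = "tcrioct_input_error")
  }
  collapsed <- purrr::map(reps, collapse_by_key, mode = mode,
                          strip_alleles = strip_alleles)
  keys <- purrr::map(collapsed, clone_key, mode = mode,
                     strip_alleles = strip_alleles)
  pub <- vapply(seq_along(collapsed), function(i) {
    others <- unique(unlist(keys[-i]))
    sum(collapsed[[i]]$clones$freq[keys[[i]] %in% others])
  }, numeric(1))
  list(
    per_mouse = tibble::tibble(mouse_id = mice, public_frequency = pub),
    mean = mean(pub)
  )
}

#' Top-clone sharing matrix across mice
#'
#' Takes the union of each mouse's top `top_n` clones (amino-acid identity
#' by default) and tabulates every clone's log10 frequency in every mouse,
#' the layout of a cross-mouse top-clone heat map. Absent clones are `NA`.
#'
#' @param reps A list of >= 2 [tcr_repertoire()] objects, one per mouse,
#'   same compartment and chain.
#' @param mode Clone identity (default `"aa"`).
#' @param top_n Number of top clones per mouse (default 10).
#' @param strip_alleles Strip allele suffixes when matching segments.
#' @return A numeric matrix (clones x mice) of log10 frequencies with
#'   `NA` marking absence; rows ordered by descending maximum frequency.
#' @export
top_clone_heatmap_data <- function(reps, mode = c("aa", "nt"), top_n = 10L,
                                   strip_alleles = TRUE) {
  mode <- match.arg(mode)
  if (!is.list(reps) || length(reps) < 2L) {
    rlang::abort("heat-map data needs repertoires from >= 2 mice",
                 class = "tcrioct_input_error")
  }
  mice <- vapply(reps, function(r) r$mouse_id, character(1))
  collapsed <- purrr::map(reps, collapse_by_key, mode = mode,
                          strip_alleles = strip_alleles)
  keys <- purrr::map(collapsed, clone_key, mode = mode,
                     strip_alleles = strip_alleles)
  top_keys <- purrr::map2(collapsed, keys, function(r, k) {
    ord <- order(-r$clones$freq, k, method = "radix")
    k[ord][seq_len(min(top_n, length(k)))]
  })
  rows <- unique(unlist(top_keys))
  mat <- matrix(NA_real_, nrow = length(rows), ncol = length(reps),
                dimnames = list(rows, mice))
  for (i in seq_along(collapsed)) {
    hit <- match(keys[[i]], rows)
    ok <- !is.na(hit)
    mat[hit[ok], i] <- log10(collapsed[[i]]$clones$freq[ok])
  }
  maxrow <- apply(mat, 1L, max, na.rm = TRUE)
  mat[order(-maxrow, rownames(mat), method = "radix"), , drop = FALSE]
}
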