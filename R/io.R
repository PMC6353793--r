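#' Column dialect for clonotype tables
#'
#' Maps the package's canonical clone fields onto the column names used in
#' a particular clonotype table format. The default follows the common
#' convention of clonotype-assembly toolchains: `count`, `freq`, `cdr3nt`,
#' `cdr3aa`, `v`, `d`, `j`.
#'
#' @param count,freq,cdr3nt,cdr3aa,v,d,j Column names in the file.
#' @return A named character vector of class `clonotype_dialect`.
#' @export
clonotype_dialect <- function(count = "count", freq = "freq",
                              cdr3nt = "cdr3nt", cdr3aa = "cdr3aa",
                              v = "v", d = "d", j = "j") {
  structure(
    c(count = count, freq = freq, cdr3nt = cdr3nt, cdr3aa = cdr3aa,
      v = v, d = d, j = j),
    class = "clonotype_dialect"
  )
}

#' Read a tab-delimited clonotype table
#'
#' One row per clone; clones are returned in file order and the frequency
#' column is read as-is, never recomputed. Filtering and renormalization
#' are separate, explicit operations ([filter_nonfunctional()],
#' [downsample_repertoire()]).
#'
#' @param path Path to a tab-separated clonotype table with a header row.
#' @param dialect A [clonotype_dialect()] mapping canonical fields to the
#'   file's column names.
#' @param mouse_id,compartment,chain,group,cell_count Sample metadata,
#'   typically taken from a sample sheet ([read_sample_sheet()]).
#' @return A [tcr_repertoire()].
#' @export
read_clonotype_table <- function(path, dialect = clonotype_dialect(),
                                 mouse_id = NA, compartment = NA,
                                 chain = NA, group = NA, cell_count = NA) {
  if (!file.exists(path)) {
    rlang::abort(paste0("clonotype table not found: ", path),
                 class = "tcrioct_io_error")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("count", "freq", "cdr3nt", "cdr3aa", "v", "j")
  for (field in required) {
    if (!dialect[[field]] %in% names(raw)) {
      rlang::abort(
        sprintf("required column '%s' (field '%s') missing from %s",
                dialect[[field]], field, path),
        class = "tcrioct_format_error"
      )
    }
  }
  count <- suppressWarnings(as.integer(raw[[dialect[["count"]]]]))
  bad <- which(is.na(count) & !is.na(raw[[dialect[["count"]]]]))
  if (length(bad) > 0L) {
    rlang::abort(
      sprintf("non-numeric count '%s' at line %d of %s",
              raw[[dialect[["count"]]]][bad[1L]], bad[1L] + 1L, path),
      class = "tcrioct_parse_error"
    )
  }
  freq <- suppressWarnings(as.double(raw[[dialect[["freq"]]]]))
  bad <- which(is.na(freq) & !is.na(raw[[dialect[["freq"]]]]))
  if (length(bad) > 0L) {
    rlang::abort(
      sprintf("non-numeric frequency '%s' at line %d of %s",
              raw[[dialect[["freq"]]]][bad[1L]], bad[1L] + 1L, path),
      class = "tcrioct_parse_error"
    )
  }
  d <- if (dialect[["d"]] %in% names(raw)) raw[[dialect[["d"]]]] else ""
  d[is.na(d)] <- ""
  clones <- tibble::tibble(
    count = count,
    freq = freq,
    cdr3nt = raw[[dialect[["cdr3nt"]]]],
    cdr3aa = raw[[dialect[["cdr3aa"]]]],
    v = raw[[dialect[["v"]]]],
    d = d,
    j = raw[[dialect[["j"]]]]
  )
  tcr_repertoire(clones, mouse_id = mouse_id, compartment = compartment,
                 chain = chain, group = group, cell_count = cell_count)
}

#' Write a repertoire as a tab-delimited clonotype table
#'
#' Round-trip contract: re-reading the written file reproduces every clone
#' field exactly. An absent D segment is written as an empty field.
#'
#' @param rep A [tcr_repertoire()].
#' @param path Output path.
#' @param dialect A [clonotype_dialect()] giving the output column names.
#' @return `path`, invisibly.
#' @export
write_clonotype_table <- function(rep, path, dialect = clonotype_dialect()) {
  out <- rep$clones
  names(out) <- unname(dialect[c("count", "freq", "cdr3nt", "cdr3aa",
                                 "v", "d", "j")])
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' A sample sheet lists one clonotype table per row with its metadata:
#' columns `path`, `mouse_id`, `compartment`, `chain`, `group`,
#' `cell_count`. Relative `path`s are resolved against the sheet's
#' directory.
#'
#' @param path Path to a tab-separated sample sheet.
#' @return A tibble with one row per sample; `path` resolved to the
#'   sheet's directory.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("path", "mouse_id", "compartment", "chain", "group",
                "cell_count")
  missing <- setdiff(required, names(sheet))
  if (length(missing) > 0L) {
    rlang::abort(paste0("sample sheet missing column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "tcrioct_format_error")
  }
  rel <- !grepl("^(/|[A-Za-z]:)", sheet$path)
  sheet$path[rel] <- file.path(dirname(path), sheet$path[rel])
  sheet
}

#' Load all repertoires listed in a sample sheet
#'
#' @param sheet A sample-sheet tibble ([read_sample_sheet()]) or a path to
#'   one.
#' @param dialect A [clonotype_dialect()].
#' @return A list of [tcr_repertoire()] objects, one per sheet row.
#' @export
read_study_tables <- function(sheet, dialect = clonotype_dialect()) {
  if (is.character(sheet)) sheet <- read_sample_sheet(sheet)
  purrr::pmap(sheet, function(path, mouse_id, compartment, chain, group,
                              cell_count, ...) {
    read_clonotype_table(path, dialect = dialect, mouse_id = mouse_id,
                         compartment = compartment, chain = chain,
                         group = group, cell_count = cell_count)
  })
}

strip_allele <- function(x) sub("\\*.*$", "", x)

#' Clone identity keys
#'
#' A clone's identity is its V segment, J segment, and CDR3 sequence.
#' Nucleotide-level identity (`mode = "nt"`) is the default; amino-acid
#' identity (`mode = "aa"`) is used for cross-mouse and named-clone
#' analyses, where synonymous nucleotide variants of one receptor must
#' match. Allele suffixes (e.g. `*01`) are stripped from segment names by
#' default so that gene-level IMGT nomenclature is compared.
#'
#' @param x A [tcr_repertoire()] or a clone tibble.
#' @param mode `"nt"` or `"aa"`.
#' @param strip_alleles Drop `*NN` allele suffixes before comparing
#'   segment names.
#' @return Character vector of keys, one per clone.
#' @export
clone_key <- function(x, mode = c("nt", "aa"), strip_alleles = TRUE) {
  mode <- match.arg(mode)
  clones <- if (inherits(x, "tcr_repertoire")) x$clones else x
  v <- clones$v
  j <- clones$j
  if (strip_alleles) {
    v <- strip_allele(v)
    j <- strip_allele(j)
  }
  cdr3 <- if (mode == "nt") clones$cdr3nt else clones$cdr3aa
  paste(v, j, cdr3, sep = "|")
}

#' Merge clones sharing the same identity key
#'
#' Counts and frequencies of clones with the same key are summed, so total
#' count and total frequency are conserved. Under amino-acid identity this
#' collapses synonymous nucleotide variants of one receptor; the retained
#' CDR3 nucleotide sequence (and D segment) is that of the most abundant
#' variant. Output clones are sorted by descending count with ties broken
#' lexicographically.
#'
#' @param rep A non-empty [tcr_repertoire()].
#' @inheritParams clone_key
#' @return A [tcr_repertoire()] whose keys are unique under `mode`.
#' @export
collapse_by_key <- function(rep, mode = c("nt", "aa"), strip_alleles = TRUE) {
  mode <- match.arg(mode)
  if (n_clones(rep) == 0L) {
    rlang::abort("cannot collapse an empty repertoire",
                 class = "tcrioct_empty_repertoire")
  }
  cl <- canonical_sort(rep$clones)
  key <- clone_key(cl, mode = mode, strip_alleles = strip_alleles)
  cl$.key <- key
  merged <- cl |>
    dplyr::group_by(.data$.key) |>
    dplyr::summarise(
      count = sum(.data$count),
      freq = sum(.data$freq),
      cdr3nt = .data$cdr3nt[1L],
      cdr3aa = .data$cdr3aa[1L],
      v = .data$v[1L],
      d = .data$d[1L],
      j = .data$j[1L],
      .groups = "drop"
    ) |>
    dplyr::select(!".key")
  set_clones(rep, canonical_sort(merged))
}
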