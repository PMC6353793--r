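#' Pipeline run configuration
#'
#' @param chain TCR chain analyzed (`"TRB"` or `"TRA"`); other chains in
#'   the sample sheet are ignored.
#' @param key_mode Clone identity for within-mouse overlap (default
#'   `"nt"`).
#' @param coverage Target coverage for downsampling; `NULL` uses the
#'   chain-specific default ([default_coverage()]).
#' @param diversity_threshold Frequency cut for [diversity()] (default
#'   0.01%).
#' @param pattern_threshold Major/minor frequency cut for
#'   [classify_patterns()] (default 0.1%).
#' @param seed Integer seed for downsampling (one sub-seed is derived per
#'   sample).
#' @param dln,tumor,pbl Compartment labels used for the overlap analyses.
#' @return A list of class `run_config`.
#' @export
run_config <- function(chain = "TRB", key_mode = "nt", coverage = NULL,
                       diversity_threshold = 1e-4,
                       pattern_threshold = 0.001, seed = 1L,
                       dln = "dLN_CD44hi", tumor = "tumor", pbl = "PBL") {
  if (diversity_threshold <= 0 || diversity_threshold >= 1 ||
      pattern_threshold <= 0 || pattern_threshold >= 1) {
    rlang::abort("thresholds must lie in (0, 1)",
                 class = "tcrioct_config_error")
  }
  structure(as.list(environment()), class = "run_config")
}

sample_metrics <- function(rep, cfg) {
  qs <- if (n_clones(rep) >= 5L) quantile_stats(rep) else NULL
  tibble::tibble(
    mouse_id = rep$mouse_id,
    compartment = rep$compartment,
    chain = rep$chain,
    group = rep$group,
    n_clones = n_clones(rep),
    total_reads = total_reads(rep),
    clonality = clonality(rep),
    diversity = diversity(rep, cfg$diversity_threshold),
    top20pct_freq = if (is.null(qs)) NA_real_ else qs$bin_frequencies[[1L]],
    top1_freq = if (is.null(qs)) NA_real_ else qs$top_clone_frequencies[1L],
    top5_combined_freq = if (is.null(qs)) NA_real_ else
      sum(qs$top_clone_frequencies)
  )
}

mouse_overlap_metrics <- function(reps_by_comp, mouse_id, group, cfg) {
  out <- tibble::tibble(mouse_id = mouse_id, group = group)
  have <- names(reps_by_comp)
  pair <- c(cfg$dln, cfg$tumor)
  if (all(pair %in% have)) {
    tbl <- build_overlap(reps_by_comp[pair], mode = cfg$key_mode)
    s <- overlap_summary(tbl)
    out$dln_tumor_count <- s$clone_count
    out$dln_tumor_freq_dln <- s$combined_frequency[[cfg$dln]]
    out$dln_tumor_freq_tumor <- s$combined_frequency[[cfg$tumor]]
    pat <- classify_patterns(tbl, threshold = cfg$pattern_threshold,
                             tumor = cfg$tumor, dln = cfg$dln)
    for (k in seq_len(nrow(pat))) {
      out[[paste0("pct_", pat$pattern[k])]] <- pat$percent[k]
    }
  }
  triple <- c(cfg$dln, cfg$pbl, cfg$tumor)
  if (all(triple %in% have)) {
    any2 <- build_overlap(reps_by_comp[triple], mode = cfg$key_mode,
                          min_compartments = 2L)
    s2 <- overlap_summary(any2)
    out$any2_count <- s2$clone_count
    out$any2_freq_dln <- s2$combined_frequency[[cfg$dln]]
    out$any2_freq_pbl <- s2$combined_frequency[[cfg$pbl]]
    out$any2_freq_tumor <- s2$combined_frequency[[cfg$tumor]]
    all3 <- build_overlap(reps_by_comp[triple], mode = cfg$key_mode,
                          min_compartments = 3L)
    s3 <- overlap_summary(all3)
    out$threeway_count <- s3$clone_count
    out$threeway_freq_dln <- s3$combined_frequency[[cfg$dln]]
    out$threeway_freq_pbl <- s3$combined_frequency[[cfg$pbl]]
    out$threeway_freq_tumor <- s3$combined_frequency[[cfg$tumor]]
  }
  out
}

group_mean_se <- function(tbl, metrics, by = "group") {
  tbl |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "metric")))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      se = stats::sd(.data$value) / sqrt(dplyr::n()),
      .groups = "drop"
    )
}

group_t_tests <- function(tbl, metrics) {
  groups <- unique(tbl$group)
  if (length(groups) != 2L) return(tibble::tibble())
  purrr::map_dfr(metrics, function(m) {
    x <- tbl[[m]][tbl$group == groups[1L]]
    y <- tbl[[m]][tbl$group == groups[2L]]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L) return(tibble::tibble())
    p <- tryCatch(stats::t.test(x, y, var.equal = TRUE)$p.value,
                  error = function(e) NA_real_)
    tibble::tibble(metric = m, group1 = groups[1L], group2 = groups[2L],
                   n1 = length(x), n2 = length(y),
                   mean1 = mean(x), mean2 = mean(y), p_value = p)
  })
}

#' Run the full repertoire analysis over a study
#'
#' Orchestrates, per sample: non-functional filtering and
#' coverage-normalized downsampling, then repertoire statistics; per
#' mouse: dLN-tumor overlap, pattern classification, any-2 and three-way
#' dLN-PBL-tumor overlap; per compartment and group: public-clone
#' frequencies across mice; and group-level mean +/- SE with two-sided
#' unpaired Student's t-tests for every compared metric. Group statistics
#' are computed across mice, never on pooled repertoires. No
#' multiple-testing correction is applied; p-values are reported as-is,
#' one test per metric.
#'
#' A mouse missing a compartment required by an overlap analysis is
#' excluded from that analysis with a warning, not an error.
#'
#' @param sheet A sample sheet (tibble or path), or the result of
#'   [generate_study()].
#' @param cfg A [run_config()].
#' @param out_dir Optional directory for the report bundle: TSVs of every
#'   table, `summary.json`, per-mouse overlap tables, and a run log.
#' @param dialect A [clonotype_dialect()] for reading the tables.
#' @return A list of class `ioct_report`: `samples` (per-sample
#'   statistics), `mice` (per-mouse overlap metrics), `group_stats`
#'   (mean/SE/n per group and metric), `comparisons` (t-tests),
#'   `public` (per compartment, group and mouse), `config`.
#' @export
run_study <- function(sheet, cfg = run_config(), out_dir = NULL,
                      dialect = clonotype_dialect()) {
  if (is.list(sheet) && !is.data.frame(sheet) && !is.null(sheet$sheet_path)) {
    sheet <- sheet$sheet_path
  }
  if (is.character(sheet)) sheet <- read_sample_sheet(sheet)
  sheet <- sheet[sheet$chain == cfg$chain, , drop = FALSE]
  if (nrow(sheet) == 0L) {
    rlang::abort(paste0("no samples for chain ", cfg$chain),
                 class = "tcrioct_input_error")
  }
  reps <- read_study_tables(sheet, dialect = dialect)

  processed <- purrr::imap(reps, function(r, i) {
    r <- filter_nonfunctional(r)
    downsample_repertoire(r, coverage = cfg$coverage,
                          seed = derive_seed(cfg$seed, 5000L + i))
  })

  samples <- purrr::map_dfr(processed, sample_metrics, cfg = cfg)

  by_mouse <- split(processed,
                    vapply(processed, function(r) r$mouse_id, character(1)))
  mice <- purrr::map_dfr(by_mouse, function(rs) {
    comps <- vapply(rs, function(r) r$compartment, character(1))
    names(rs) <- comps
    miss <- setdiff(c(cfg$dln, cfg$pbl, cfg$tumor), comps)
    if (length(miss) > 0L) {
      rlang::warn(sprintf(
        "mouse %s lacks compartment(s) %s: excluded from affected overlap analyses",
        rs[[1L]]$mouse_id, paste(miss, collapse = ", ")))
    }
    mouse_overlap_metrics(rs, rs[[1L]]$mouse_id, rs[[1L]]$group, cfg)
  })

  # Public clones: within each group, per compartment, across that
  # group's mice (amino-acid identity).
  public <- purrr::map_dfr(
    split(processed, paste(
      vapply(processed, function(r) r$group, character(1)),
      vapply(processed, function(r) r$compartment, character(1)),
      sep = "\r")),
    function(rs) {
      if (length(rs) < 2L) return(tibble::tibble())
      pc <- public_clones(rs, mode = "aa")
      tibble::tibble(
        group = rs[[1L]]$group,
        compartment = rs[[1L]]$compartment,
        mouse_id = pc$per_mouse$mouse_id,
        public_frequency = pc$per_mouse$public_frequency
      )
    })

  sample_metric_cols <- c("n_clones", "clonality", "diversity",
                          "top20pct_freq", "top1_freq",
                          "top5_combined_freq")
  mouse_metric_cols <- setdiff(names(mice), c("mouse_id", "group"))
  sample_long <- samples |>
    tidyr::pivot_longer(dplyr::all_of(sample_metric_cols),
                        names_to = "metric", values_to = "value") |>
    dplyr::mutate(metric = paste(.data$compartment, .data$metric,
                                 sep = ".")) |>
    dplyr::select("mouse_id", "group", "metric", "value") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "value")
  per_mouse <- dplyr::full_join(sample_long, mice,
                                by = c("mouse_id", "group"))
  metric_cols <- setdiff(names(per_mouse), c("mouse_id", "group"))
  group_stats <- group_mean_se(per_mouse, metric_cols)
  comparisons <- group_t_tests(per_mouse, metric_cols)

  report <- structure(
    list(samples = samples, mice = mice, per_mouse = per_mouse,
         group_stats = group_stats, comparisons = comparisons,
         public = public, config = cfg),
    class = "ioct_report"
  )
  if (!is.null(out_dir)) write_report(report, processed, out_dir)
  report
}

write_report <- function(report, processed, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$samples, file.path(out_dir, "sample_stats.tsv"),
                   progress = FALSE)
  readr::write_tsv(report$per_mouse, file.path(out_dir, "mouse_metrics.tsv"),
                   progress = FALSE)
  readr::write_tsv(report$group_stats, file.path(out_dir, "group_stats.tsv"),
                   progress = FALSE)
  readr::write_tsv(report$comparisons, file.path(out_dir, "comparisons.tsv"),
                   progress = FALSE)
  readr::write_tsv(report$public, file.path(out_dir, "public_clones.tsv"),
                   progress = FALSE)
  cfg <- report$config
  by_mouse <- split(processed,
                    vapply(processed, function(r) r$mouse_id, character(1)))
  for (rs in by_mouse) {
    comps <- vapply(rs, function(r) r$compartment, character(1))
    names(rs) <- comps
    pair <- c(cfg$dln, cfg$tumor)
    if (all(pair %in% comps)) {
      tbl <- build_overlap(rs[pair], mode = cfg$key_mode)
      readr::write_tsv(
        tibble::as_tibble(tbl),
        file.path(out_dir, sprintf("overlap_%s.tsv", rs[[1L]]$mouse_id)),
        progress = FALSE)
    }
  }
  jsonlite::write_json(
    list(
      config = list(chain = cfg$chain, key_mode = cfg$key_mode,
                    diversity_threshold = cfg$diversity_threshold,
                    pattern_threshold = cfg$pattern_threshold,
                    seed = cfg$seed),
      group_stats = report$group_stats,
      comparisons = report$comparisons
    ),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  writeLines(
    c(sprintf("tcrioct %s | R %s",
              as.character(utils::packageVersion("tcrioct")),
              paste(R.version$major, R.version$minor, sep = ".")),
      sprintf("chain=%s key_mode=%s seed=%d", cfg$chain, cfg$key_mode,
              as.integer(cfg$seed)),
      sprintf("diversity_threshold=%g pattern_threshold=%g",
              cfg$diversity_threshold, cfg$pattern_threshold),
      sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"))),
    file.path(out_dir, "run_log.txt")
  )
  invisible(out_dir)
}

#' @export
print.ioct_report <- function(x, ...) {
  cat(sprintf("<ioct_report> %d samples, %d mice | chain %s\n",
              nrow(x$samples), nrow(x$mice), x$config$chain))
  cat("group means (selected):\n")
  sel <- x$group_stats[grepl("clonality|dln_tumor_count|threeway_count",
                             x$group_stats$metric), ]
  print(as.data.frame(sel), row.names = FALSE)
  invisible(x)
}
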