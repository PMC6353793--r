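# Synthetic multi-mouse, multi-compartment repertoire generator.
#
# Emulates the statistical structure the analysis assumes: heavy-tailed
# (power-law) private backgrounds per compartment with the tumor more
# skewed than dLN/PBL, a mouse-private clone pool shared across that
# mouse's compartments with compartment-specific total weight, a
# compartment-specific public pool shared across mice, nonfunctional
# contamination, named spike-in clones, and a treatment effect that
# enlarges the shared pool and its dLN weight.

trb_v_segments <- c("TRBV1", "TRBV2", "TRBV3", "TRBV4", "TRBV5",
                    "TRBV12-1", "TRBV12-2", "TRBV13-1", "TRBV13-2",
                    "TRBV13-3", "TRBV14", "TRBV15", "TRBV16", "TRBV17",
                    "TRBV19", "TRBV20", "TRBV23", "TRBV26", "TRBV29",
                    "TRBV31")
trb_j_segments <- c("TRBJ1-1", "TRBJ1-2", "TRBJ1-3", "TRBJ1-4", "TRBJ1-5",
                    "TRBJ2-1", "TRBJ2-2", "TRBJ2-3", "TRBJ2-4", "TRBJ2-5",
                    "TRBJ2-7")
trb_d_segments <- c("TRBD1", "TRBD2", "")
tra_v_segments <- c("TRAV1", "TRAV3-3", "TRAV4-3", "TRAV6-5", "TRAV7-2",
                    "TRAV9-4", "TRAV10", "TRAV12-1", "TRAV13-1",
                    "TRAV14-1", "TRAV16", "TRAV19", "TRAV21")
tra_j_segments <- c("TRAJ2", "TRAJ5", "TRAJ9", "TRAJ12", "TRAJ15",
                    "TRAJ21", "TRAJ23", "TRAJ26", "TRAJ27", "TRAJ31",
                    "TRAJ33", "TRAJ37", "TRAJ40", "TRAJ49", "TRAJ56")

segment_pools <- function(chain) {
  if (chain == "TRA") {
    list(v = tra_v_segments, d = "", j = tra_j_segments)
  } else {
    list(v = trb_v_segments, d = trb_d_segments, j = trb_j_segments)
  }
}

all_codons <- as.vector(t(outer(
  as.vector(t(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0))),
  c("A", "C", "G", "T"), paste0)))
stop_codons <- c("TAA", "TAG", "TGA")
sense_codons <- setdiff(all_codons, stop_codons)

translate_cdr3 <- function(nt) {
  code <- Biostrings::GENETIC_CODE
  vapply(nt, function(s) {
    n <- nchar(s)
    cod <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
    paste(code[cod], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# One synonymous nucleotide recoding of an in-frame CDR3 (same amino-acid
# sequence, different nucleotides); NA if no codon has a synonym.
synonymous_variant <- function(nt) {
  code <- Biostrings::GENETIC_CODE
  n <- nchar(nt)
  cod <- substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
  for (i in sample(seq_along(cod))) {
    alt <- names(code)[code == code[[cod[i]]] & names(code) != cod[i] &
                         !names(code) %in% stop_codons]
    if (length(alt) > 0L) {
      cod[i] <- alt[1L]
      return(paste(cod, collapse = ""))
    }
  }
  NA_character_
}

# Random in-frame CDR3s: canonical C...F/W framing, 8-16 codons.
random_cdr3_nt <- function(n) {
  lens <- sample(6:14, n, replace = TRUE)
  first <- sample(c("TGT", "TGC"), n, replace = TRUE)
  last <- sample(c("TTT", "TTC", "TGG"), n, replace = TRUE)
  vapply(seq_len(n), function(i) {
    paste0(first[i],
           paste(sample(sense_codons, lens[i], replace = TRUE),
                 collapse = ""),
           last[i])
  }, character(1))
}

unique_cdr3_nt <- function(n, exclude = character(0)) {
  out <- character(0)
  while (length(out) < n) {
    cand <- random_cdr3_nt(ceiling((n - length(out)) * 1.1) + 10L)
    cand <- setdiff(unique(cand), c(exclude, out))
    out <- c(out, cand)
  }
  out[seq_len(n)]
}

# Clone sequence pool with mildly skewed segment usage.
make_clone_pool <- function(n, chain, exclude = character(0)) {
  segs <- segment_pools(chain)
  pv <- (seq_along(segs$v))^-0.5
  pj <- (seq_along(segs$j))^-0.5
  nt <- unique_cdr3_nt(n, exclude = exclude)
  tibble::tibble(
    cdr3nt = nt,
    cdr3aa = translate_cdr3(nt),
    v = sample(segs$v, n, replace = TRUE, prob = pv / sum(pv)),
    d = if (length(segs$d) > 1L) {
      sample(segs$d, n, replace = TRUE)
    } else "",
    j = sample(segs$j, n, replace = TRUE, prob = pj / sum(pj))
  )
}

zipf_weights <- function(n, alpha) {
  w <- (seq_len(n))^(-alpha)
  w / sum(w)
}

derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 9973) %% 2147483629)
}

#' Spike-in clone specification for the generator
#'
#' @param label Clone name.
#' @param v,j Segment names.
#' @param cdr3nt In-frame CDR3 nucleotide sequence (length divisible
#'   by 3).
#' @param freq Named per-compartment target frequencies (control group).
#' @param freq_treated Named per-compartment target frequencies in the
#'   treated group; defaults to `freq`.
#' @return A list of class `spike_in`.
#' @export
spike_in <- function(label, v, j, cdr3nt, freq, freq_treated = freq) {
  if (nchar(cdr3nt) %% 3L != 0L) {
    rlang::abort("spike-in cdr3nt length must be divisible by 3",
                 class = "tcrioct_config_error")
  }
  structure(list(label = label, v = v, j = j, cdr3nt = cdr3nt,
                 cdr3aa = translate_cdr3(cdr3nt),
                 freq = freq, freq_treated = freq_treated),
            class = "spike_in")
}

#' Default spike-in clones
#'
#' Two tumor-reactive named clones: a transgenic melanoma-antigen-specific
#' receptor planted mainly in the dLN and expanded there by treatment, and
#' a tumor-derived reactive clone planted mainly in the tumor and strongly
#' expanded there by treatment. Sequences are fixed synthetic constructs.
#'
#' @return A list of [spike_in()] objects.
#' @export
default_spike_ins <- function() {
  list(
    spike_in(
      "pmel1_like", v = "TRBV13-3", j = "TRBJ2-7",
      cdr3nt = "TGTGCCAGCAGTGATGCAGGGGGCAGAGATACGCAGTATTTT",
      freq = c(dLN_CD44hi = 0.006, PBL = 0.002, tumor = 0.0007),
      freq_treated = c(dLN_CD44hi = 0.030, PBL = 0.004, tumor = 0.0012)
    ),
    spike_in(
      "b16rc1_like", v = "TRBV5", j = "TRBJ2-5",
      cdr3nt = "TGTGCCAGCAGCTTGGGGGGCAATGAACAGTACTTC",
      freq = c(dLN_CD44hi = 0.0005, PBL = 0.0003, tumor = 0.0049),
      freq_treated = c(dLN_CD44hi = 0.0019, PBL = 0.0006, tumor = 0.045)
    )
  )
}

#' Scenario configuration for the synthetic study
#'
#' Defaults describe the emulated study: 5 control + 5 treated mice, three
#' compartments per mouse, power-law clone-size backgrounds (tumor more
#' oligoclonal), a mouse-private pool shared across compartments whose
#' per-compartment weights mirror the reported combined overlap
#' frequencies, compartment-specific public pools shared across mice,
#' 5% nonfunctional contamination, two named spike-ins, and a 5x
#' treatment effect on shared-pool size and dLN shared weight.
#'
#' @param n_mice Named integer vector: mice per group.
#' @param compartments Compartments generated per mouse.
#' @param chain TCR chain.
#' @param n_clones Named: private background clones per compartment.
#' @param cell_count Named: sorted starting cells per compartment.
#' @param raw_coverage Reads sequenced per starting cell (before coverage
#'   normalization).
#' @param power_exponent Named: power-law exponent of the background
#'   rank-frequency law per compartment.
#' @param shared_pool_size Clones in the within-mouse shared pool.
#' @param shared_pool_weight Named: total frequency of the shared pool per
#'   compartment.
#' @param public_pool_size Clones per compartment-specific cross-mouse
#'   public pool.
#' @param public_pool_weight Named: total frequency of the public pool per
#'   compartment.
#' @param nonfunctional_rate Probability a background clone is
#'   nonfunctional (stop codon or frameshift).
#' @param treatment_effect Multiplier applied, in treated mice, to the
#'   shared-pool size and to the shared pool's dLN weight.
#' @param synonymous_rate Probability a shared-pool clone is emitted as
#'   two synonymous nucleotide variants.
#' @param spike_ins List of [spike_in()] clones.
#' @param seed Integer master seed.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(
    n_mice = c(control = 5L, aCD4 = 5L),
    compartments = c("dLN_CD44hi", "PBL", "tumor"),
    chain = "TRB",
    n_clones = c(dLN_CD44hi = 4000L, PBL = 3000L, tumor = 1500L),
    cell_count = c(dLN_CD44hi = 10000L, PBL = 8000L, tumor = 4000L),
    raw_coverage = 12,
    power_exponent = c(dLN_CD44hi = 1.0, PBL = 1.0, tumor = 1.5),
    shared_pool_size = 150L,
    shared_pool_weight = c(dLN_CD44hi = 0.036, PBL = 0.108, tumor = 0.419),
    public_pool_size = 100L,
    public_pool_weight = c(dLN_CD44hi = 0.231, PBL = 0.033, tumor = 0.482),
    nonfunctional_rate = 0.05,
    treatment_effect = 5,
    synonymous_rate = 0.02,
    spike_ins = default_spike_ins(),
    seed = 1L) {
  cfg <- structure(as.list(environment()), class = "scenario_config")
  frac <- c(cfg$shared_pool_weight, cfg$public_pool_weight,
            cfg$nonfunctional_rate, cfg$synonymous_rate)
  if (any(frac < 0) || any(frac > 1)) {
    rlang::abort("all weights and rates must lie in [0, 1]",
                 class = "tcrioct_config_error")
  }
  if (any(cfg$n_mice <= 0) || any(cfg$n_clones <= 0) ||
      any(cfg$cell_count <= 0) || cfg$shared_pool_size <= 0 ||
      cfg$public_pool_size <= 0 || cfg$raw_coverage <= 0 ||
      cfg$treatment_effect <= 0) {
    rlang::abort("all counts, depths and effects must be positive",
                 class = "tcrioct_config_error")
  }
  cfg
}

spike_freq <- function(spike, compartment, treated) {
  f <- if (treated) spike$freq_treated else spike$freq
  val <- f[[compartment]]
  if (is.null(val) || is.na(val)) 0 else val
}

# Pools that must be identical across mice: per-compartment public pools
# (with their relative weights) -- deterministic in cfg$seed alone.
make_global_pools <- function(cfg) {
  withr::with_seed(derive_seed(cfg$seed, 1L), {
    used <- c(vapply(cfg$spike_ins, function(s) s$cdr3nt, character(1)))
    pools <- list()
    for (comp in cfg$compartments) {
      pool <- make_clone_pool(cfg$public_pool_size, cfg$chain,
                              exclude = used)
      pool$relw <- zipf_weights(nrow(pool), 1)
      used <- c(used, pool$cdr3nt)
      pools[[comp]] <- pool
    }
    pools
  })
}

#' Generate one mouse's repertoires
#'
#' @param cfg A [scenario_config()].
#' @param mouse_index Index of the mouse within its group.
#' @param group `"control"` or `"aCD4"`.
#' @param sample_reads Sample read counts multinomially at the configured
#'   depth (default). With `FALSE`, frequencies are the exact planted
#'   weights (counts rounded), so planted quantities are recoverable
#'   exactly.
#' @return A named list of [tcr_repertoire()] objects (one per
#'   compartment) with attribute `truth`: the planted quantities
#'   (shared-pool keys and per-compartment weights, overlap key set,
#'   public keys and weights, spike-in target frequencies, nonfunctional
#'   weight and the post-filter renormalization factor per compartment).
#' @export
generate_mouse <- function(cfg, mouse_index, group = c("control", "aCD4"),
                           sample_reads = TRUE) {
  group <- match.arg(group)
  treated <- group == "aCD4"
  globals <- make_global_pools(cfg)
  mouse_id <- sprintf("%s_m%02d", group, mouse_index)
  mseed <- derive_seed(cfg$seed, 1000L + mouse_index + 500L * treated)

  withr::with_seed(mseed, {
    used <- c(unlist(lapply(globals, function(p) p$cdr3nt)),
              vapply(cfg$spike_ins, function(s) s$cdr3nt, character(1)))

    # Mouse-private pool shared across this mouse's compartments.
    m <- as.integer(round(cfg$shared_pool_size *
                            if (treated) cfg$treatment_effect else 1))
    shared <- make_clone_pool(m, cfg$chain, exclude = used)
    shared$relw <- zipf_weights(m, 1)
    used <- c(used, shared$cdr3nt)

    # Synonymous nucleotide variants of some shared clones (same
    # receptor at amino-acid level, split 60/40 at nucleotide level).
    split_flag <- stats::runif(m) < cfg$synonymous_rate
    if (any(split_flag)) {
      extra <- shared[split_flag, , drop = FALSE]
      extra$cdr3nt <- vapply(extra$cdr3nt, synonymous_variant, character(1),
                             USE.NAMES = FALSE)
      ok <- !is.na(extra$cdr3nt) & !extra$cdr3nt %in% used
      extra <- extra[ok, , drop = FALSE]
      idx <- which(split_flag)[ok]
      extra$relw <- shared$relw[idx] * 0.4
      shared$relw[idx] <- shared$relw[idx] * 0.6
      shared <- dplyr::bind_rows(shared, extra)
      used <- c(used, extra$cdr3nt)
    }
    shared$relw <- shared$relw / sum(shared$relw)

    # Private backgrounds, generated jointly so compartments never share
    # a background clone, then marked nonfunctional at the configured
    # rate.
    total_bg <- sum(cfg$n_clones[cfg$compartments])
    bg_all <- make_clone_pool(total_bg, cfg$chain, exclude = used)
    nonfun <- stats::runif(total_bg) < cfg$nonfunctional_rate
    mark <- sample(c("*", "_"), total_bg, replace = TRUE)
    bg_all$cdr3aa[nonfun] <- vapply(which(nonfun), function(i) {
      aa <- bg_all$cdr3aa[i]
      pos <- sample(nchar(aa), 1L)
      paste0(substr(aa, 1L, pos - 1L), mark[i],
             substr(aa, pos + 1L, nchar(aa)))
    }, character(1))
    bg_all$nonfunctional <- nonfun
    bg_split <- split(
      bg_all,
      base::rep(cfg$compartments, times = cfg$n_clones[cfg$compartments])
    )

    # Spikes planted in >= 2 compartments join the within-mouse overlap.
    spike_multi <- vapply(cfg$spike_ins, function(s) {
      sum(vapply(cfg$compartments, spike_freq, numeric(1), spike = s,
                 treated = treated) > 0) >= 2L
    }, logical(1))

    reps <- list()
    truth_comp <- list()
    for (comp in cfg$compartments) {
      w_shared <- cfg$shared_pool_weight[[comp]] *
        if (treated && comp == "dLN_CD44hi") cfg$treatment_effect else 1
      w_public <- cfg$public_pool_weight[[comp]]
      f_spikes <- vapply(cfg$spike_ins, spike_freq, numeric(1),
                         compartment = comp, treated = treated)
      w_bg <- 1 - w_shared - w_public - sum(f_spikes)
      if (w_bg < 0.01) {
        rlang::abort(sprintf(
          "planted weights for compartment %s exceed 1 (background %.3f)",
          comp, w_bg), class = "tcrioct_config_error")
      }
      bg <- bg_split[[comp]]
      pub <- globals[[comp]]
      parts <- dplyr::bind_rows(
        dplyr::mutate(shared[, c("cdr3nt", "cdr3aa", "v", "d", "j")],
                      w = shared$relw * w_shared),
        dplyr::mutate(pub[, c("cdr3nt", "cdr3aa", "v", "d", "j")],
                      w = pub$relw * w_public),
        if (length(cfg$spike_ins) > 0L) tibble::tibble(
          cdr3nt = vapply(cfg$spike_ins, `[[`, character(1), "cdr3nt"),
          cdr3aa = vapply(cfg$spike_ins, `[[`, character(1), "cdr3aa"),
          v = vapply(cfg$spike_ins, `[[`, character(1), "v"),
          d = "",
          j = vapply(cfg$spike_ins, `[[`, character(1), "j"),
          w = f_spikes
        ),
        dplyr::mutate(bg[, c("cdr3nt", "cdr3aa", "v", "d", "j")],
                      w = zipf_weights(nrow(bg),
                                       cfg$power_exponent[[comp]]) * w_bg)
      )
      parts <- parts[parts$w > 0, , drop = FALSE]
      depth <- as.integer(round(cfg$cell_count[[comp]] * cfg$raw_coverage))
      if (sample_reads) {
        counts <- as.integer(stats::rmultinom(1L, depth, parts$w))
        keep <- counts > 0L
        clones <- tibble::tibble(
          count = counts[keep], freq = counts[keep] / depth,
          cdr3nt = parts$cdr3nt[keep], cdr3aa = parts$cdr3aa[keep],
          v = parts$v[keep], d = parts$d[keep], j = parts$j[keep]
        )
      } else {
        clones <- tibble::tibble(
          count = as.integer(round(parts$w * depth)), freq = parts$w,
          cdr3nt = parts$cdr3nt, cdr3aa = parts$cdr3aa,
          v = parts$v, d = parts$d, j = parts$j
        )
      }
      reps[[comp]] <- tcr_repertoire(
        canonical_sort(clones), mouse_id = mouse_id, compartment = comp,
        chain = cfg$chain, group = group,
        cell_count = cfg$cell_count[[comp]]
      )
      nf_weight <- sum(bg$nonfunctional *
                         zipf_weights(nrow(bg),
                                      cfg$power_exponent[[comp]])) * w_bg
      truth_comp[[comp]] <- list(
        shared_weight = unname(w_shared),
        overlap_weight = unname(w_shared) +
          sum(f_spikes[spike_multi]),
        public_weight = unname(w_public),
        # spike-ins are planted in every mouse, so they are public too
        public_weight_measured = unname(w_public) + sum(f_spikes),
        spike_freq = stats::setNames(
          f_spikes, vapply(cfg$spike_ins, `[[`, character(1), "label")),
        nonfunctional_weight = nf_weight,
        functional_renorm = 1 / (1 - nf_weight),
        depth = depth
      )
    }

    spike_nt <- vapply(cfg$spike_ins, `[[`, character(1), "cdr3nt")
    spike_keys <- paste(
      strip_allele(vapply(cfg$spike_ins, `[[`, character(1), "v")),
      strip_allele(vapply(cfg$spike_ins, `[[`, character(1), "j")),
      spike_nt, sep = "|")
    truth <- list(
      mouse_id = mouse_id,
      group = group,
      shared_keys_nt = paste(strip_allele(shared$v),
                             strip_allele(shared$j),
                             shared$cdr3nt, sep = "|"),
      overlap_keys_nt = c(
        paste(strip_allele(shared$v), strip_allele(shared$j),
              shared$cdr3nt, sep = "|"),
        spike_keys[spike_multi]
      ),
      public_keys_aa = lapply(globals, function(p) {
        paste(strip_allele(p$v), strip_allele(p$j), p$cdr3aa, sep = "|")
      }),
      compartments = truth_comp
    )
    attr(reps, "truth") <- truth
    reps
  })
}

#' Generate and write a complete synthetic study
#'
#' Writes one clonotype table per (mouse, compartment) and a sample sheet,
#' producing an on-disk layout consumable end-to-end by [run_study()].
#' Byte-identical output for the same configuration and seed.
#'
#' @param cfg A [scenario_config()].
#' @param out_dir Output directory.
#' @param sample_reads Passed to [generate_mouse()].
#' @param overwrite Allow writing into a non-empty directory.
#' @return Invisibly, a list with `sheet_path`, `sheet` (tibble), `truth`
#'   (per-mouse planted quantities, named by mouse id), and `config`.
#' @export
generate_study <- function(cfg, out_dir, sample_reads = TRUE,
                           overwrite = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0L && !overwrite) {
    rlang::abort(paste0("output directory not empty: ", out_dir,
                        " (use overwrite = TRUE)"),
                 class = "tcrioct_io_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  truths <- list()
  for (group in names(cfg$n_mice)) {
    for (i in seq_len(cfg$n_mice[[group]])) {
      reps <- generate_mouse(cfg, i, group, sample_reads = sample_reads)
      truth <- attr(reps, "truth")
      truths[[truth$mouse_id]] <- truth
      for (comp in names(reps)) {
        fname <- sprintf("%s_%s_%s.tsv", truth$mouse_id, comp, cfg$chain)
        write_clonotype_table(reps[[comp]], file.path(out_dir, fname))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          path = fname,
          mouse_id = truth$mouse_id,
          compartment = comp,
          chain = cfg$chain,
          group = group,
          cell_count = cfg$cell_count[[comp]]
        )
      }
    }
  }
  sheet <- dplyr::bind_rows(rows)
  sheet_path <- file.path(out_dir, "sample_sheet.tsv")
  readr::write_tsv(sheet, sheet_path, progress = FALSE)
  # the on-disk sheet stays relative (relocatable); the returned one is
  # resolved so it can be used directly
  sheet$path <- file.path(out_dir, sheet$path)
  invisible(list(sheet_path = sheet_path, sheet = sheet, truth = truths,
                 config = cfg))
}
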