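# Fixture builders and independent naive oracles used across the suite.

nt_alphabet <- c("A", "C", "G", "T")

# A clone table from counts (frequencies proportional to counts unless
# given). CDR3s are deterministic unique dummies.
make_clones <- function(counts, freqs = counts / sum(counts),
                        cdr3nt = NULL, cdr3aa = NULL, v = NULL, j = NULL,
                        d = "") {
  n <- length(counts)
  if (is.null(cdr3nt)) {
    int2nt <- function(i) {
      out <- character(0)
      while (i > 0) {
        out <- c(nt_alphabet[i %% 4 + 1], out)
        i <- i %/% 4
      }
      paste(out, collapse = "")
    }
    cdr3nt <- paste0("TGTGCA", vapply(seq_len(n) + 4L, int2nt,
                                      character(1)), "TTT")
  }
  if (is.null(cdr3aa)) cdr3aa <- paste0("CASS", seq_len(n), "F")
  if (is.null(v)) v <- paste0("TRBV", 1 + (seq_len(n) - 1) %% 7)
  if (is.null(j)) j <- paste0("TRBJ1-", 1 + (seq_len(n) - 1) %% 5)
  tibble::tibble(count = as.integer(counts), freq = freqs,
                 cdr3nt = cdr3nt, cdr3aa = cdr3aa,
                 v = v, d = d, j = j)
}

make_rep <- function(counts, freqs = counts / sum(counts),
                     mouse_id = "m01", compartment = "dLN_CD44hi",
                     chain = "TRB", group = "control", cell_count = NA,
                     ...) {
  tcr_repertoire(make_clones(counts, freqs, ...), mouse_id = mouse_id,
                 compartment = compartment, chain = chain, group = group,
                 cell_count = cell_count)
}

# Random repertoire with unique random CDR3s; counts from a log-normal.
random_rep <- function(n, seed, compartment = "dLN_CD44hi",
                       mouse_id = "m01") {
  withr::with_seed(seed, {
    counts <- pmax(1L, as.integer(round(stats::rlnorm(n, 3, 1.5))))
    cdr3nt <- vapply(seq_len(n), function(i) {
      paste(sample(nt_alphabet, 24, replace = TRUE), collapse = "")
    }, character(1))
    while (anyDuplicated(cdr3nt)) {
      dup <- duplicated(cdr3nt)
      cdr3nt[dup] <- vapply(seq_len(sum(dup)), function(i) {
        paste(sample(nt_alphabet, 24, replace = TRUE), collapse = "")
      }, character(1))
    }
    cdr3aa <- vapply(seq_len(n), function(i) {
      paste0("C", paste(sample(LETTERS[1:20], 8, replace = TRUE),
                        collapse = ""), "F")
    }, character(1))
    make_rep(counts, compartment = compartment, mouse_id = mouse_id,
             cdr3nt = cdr3nt, cdr3aa = cdr3aa)
  })
}

# ---- independent naive oracles (plain loops, no package internals) ----

naive_clonality <- function(p) {
  n <- length(p)
  if (n == 1) return(1)
  s <- 0
  for (x in p) s <- s + x * log(x)
  1 + s / log(n)
}

naive_diversity <- function(p, threshold = 1e-4) {
  k <- 0L
  for (x in p) if (x > threshold) k <- k + 1L
  k
}

naive_quantile_bins <- function(p) {
  f <- sort(p, decreasing = TRUE)
  n <- length(f)
  bins <- numeric(5)
  for (k in 1:5) {
    lo <- ceiling(n * (k - 1) / 5) + 1
    hi <- ceiling(n * k / 5)
    for (i in lo:hi) bins[k] <- bins[k] + f[i]
  }
  bins
}

# Naive two-repertoire overlap summary on (key, freq) pairs.
naive_overlap_summary <- function(keys1, freq1, keys2, freq2) {
  shared <- intersect(keys1, keys2)
  s1 <- 0
  s2 <- 0
  for (k in shared) {
    s1 <- s1 + sum(freq1[keys1 == k])
    s2 <- s2 + sum(freq2[keys2 == k])
  }
  list(count = length(shared), f1 = s1, f2 = s2)
}

# Small scenario used where many replicates are needed.
small_scenario <- function(seed, treatment_effect = 5) {
  scenario_config(
    n_mice = c(control = 5L, aCD4 = 5L),
    n_clones = c(dLN_CD44hi = 400L, PBL = 300L, tumor = 200L),
    cell_count = c(dLN_CD44hi = 700L, PBL = 600L, tumor = 400L),
    shared_pool_size = 40L,
    public_pool_size = 25L,
    treatment_effect = treatment_effect,
    seed = seed
  )
}
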