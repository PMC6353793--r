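toy_pair <- function() {
  dln <- make_rep(c(6L, 4L), freqs = c(0.6, 0.4),
                  cdr3nt = c("TGTGCAAAATTT", "TGTGCACCCTTT"),
                  cdr3aa = c("CAKF", "CAPF"), v = "TRBV1", j = "TRBJ1-1",
                  compartment = "dLN_CD44hi")
  tum <- make_rep(c(7L, 3L), freqs = c(0.7, 0.3),
                  cdr3nt = c("TGTGCACCCTTT", "TGTGCAGGGTTT"),
                  cdr3aa = c("CAPF", "CAGF"), v = "TRBV1", j = "TRBJ1-1",
                  compartment = "tumor")
  list(dln, tum)
}

test_that("build_overlap finds clones shared between compartments", {
  tbl <- build_overlap(toy_pair())
  expect_s3_class(tbl, "overlap_table")
  expect_equal(nrow(tbl), 1L)
  expect_equal(tbl$dLN_CD44hi, 0.4)
  expect_equal(tbl$tumor, 0.7)
  s <- overlap_summary(tbl)
  expect_equal(s$clone_count, 1L)
  expect_equal(unname(s$combined_frequency),
               c(0.4, 0.7))

  # disjoint repertoires -> empty table, zero summary
  a <- make_rep(c(1L), cdr3nt = "TGTAAATTT", compartment = "dLN_CD44hi")
  b <- make_rep(c(1L), cdr3nt = "TGTCCCTTT", compartment = "tumor")
  c <- make_rep(c(1L), cdr3nt = "TGTGGGTTT", compartment = "PBL")
  empty <- build_overlap(list(a, b, c))
  expect_equal(nrow(empty), 0L)
  se <- overlap_summary(empty)
  expect_equal(se$clone_count, 0L)
  expect_true(all(se$combined_frequency == 0))
})

test_that("build_overlap validates its inputs", {
  pair <- toy_pair()
  dup <- pair
  dup[[2]]$compartment <- "dLN_CD44hi"
  expect_error(build_overlap(dup), class = "tcrioct_input_error")
  other_mouse <- pair
  other_mouse[[2]]$mouse_id <- "m99"
  expect_error(build_overlap(other_mouse), class = "tcrioct_input_error")
  expect_error(build_overlap(pair[1]), class = "tcrioct_input_error")
})

test_that("overlap construction is symmetric in its input order", {
  reps <- list(random_rep(40, 31, compartment = "dLN_CD44hi"),
               random_rep(40, 32, compartment = "tumor"),
               random_rep(40, 33, compartment = "PBL"))
  # plant 12 shared clones
  shared_nt <- reps[[1]]$clones$cdr3nt[1:12]
  for (i in 2:3) {
    reps[[i]]$clones$cdr3nt[1:12] <- shared_nt
    reps[[i]]$clones$v[1:12] <- reps[[1]]$clones$v[1:12]
    reps[[i]]$clones$j[1:12] <- reps[[1]]$clones$j[1:12]
  }
  t123 <- build_overlap(reps)
  t321 <- build_overlap(rev(reps))
  expect_equal(nrow(t123), 12L)
  expect_equal(
    tibble::as_tibble(t123)[, c("key", "dLN_CD44hi", "tumor", "PBL")],
    tibble::as_tibble(t321)[, c("key", "dLN_CD44hi", "tumor", "PBL")],
    ignore_attr = TRUE)

  # three-way overlap is a subset of every pairwise overlap
  t3 <- build_overlap(reps, min_compartments = 3L)
  expect_true(all(t3$key %in% t123$key))
  for (pair in list(1:2, c(1, 3), 2:3)) {
    tp <- build_overlap(reps[pair])
    expect_true(all(t3$key %in% tp$key))
  }

  # combined frequency never exceeds the compartment total
  s <- overlap_summary(t123)
  for (comp in names(s$combined_frequency)) {
    expect_lte(s$combined_frequency[[comp]], 1)
  }
})

test_that("classify_patterns uses an inclusive major threshold", {
  mk_tbl <- function(tumor_f, dln_f) {
    n <- length(tumor_f)
    dln <- make_rep(rep(1L, n + 1), freqs = c(dln_f, 1 - sum(dln_f)),
                    compartment = "dLN_CD44hi")
    tum <- make_rep(rep(1L, n + 1), freqs = c(tumor_f, 1 - sum(tumor_f)),
                    compartment = "tumor")
    tum$clones$cdr3nt[n + 1] <- "TGTTTTTTTTTTTTT"  # private tail clone
    build_overlap(list(dln, tum))
  }
  # exactly at 0.1% in both -> major/major (inclusive >=)
  tbl <- mk_tbl(0.001, 0.001)
  pat <- classify_patterns(tbl)
  expect_equal(pat$percent[pat$pattern == "tumor_major_dLN_major"], 100)

  # one clone major in tumor only, one major in dLN only
  tbl2 <- mk_tbl(c(0.01, 0.00001), c(0.00001, 0.01))
  pat2 <- classify_patterns(tbl2)
  expect_equal(pat2$percent[pat2$pattern == "tumor_major_dLN_minor"], 50)
  expect_equal(pat2$percent[pat2$pattern == "tumor_minor_dLN_major"], 50)

  # planted 10/20/30/40 split recovered as percentages
  tf <- c(rep(0.002, 10), rep(0.002, 20), rep(1e-5, 30), rep(1e-5, 40))
  df <- c(rep(0.002, 10), rep(1e-5, 20), rep(0.002, 30), rep(1e-5, 40))
  pat3 <- classify_patterns(mk_tbl(tf, df))
  expect_equal(pat3$percent, c(10, 20, 30, 40))
  expect_equal(pat3$n_clones, c(10L, 20L, 30L, 40L))

  expect_error(classify_patterns(build_overlap(list(
    make_rep(1L, cdr3nt = "TGTAAATTT", compartment = "dLN_CD44hi"),
    make_rep(1L, cdr3nt = "TGTCCCTTT", compartment = "tumor")))),
    class = "tcrioct_empty_overlap")
})

test_that("overlap_rank_frequency ranks within the chosen compartment", {
  tbl <- build_overlap(toy_pair())
  expect_equal(overlap_rank_frequency(tbl, "tumor"),
               tibble::tibble(rank = 1L, freq = 0.7))
  reps <- list(random_rep(30, 41, compartment = "dLN_CD44hi"),
               random_rep(30, 42, compartment = "tumor"))
  reps[[2]]$clones$cdr3nt[1:8] <- reps[[1]]$clones$cdr3nt[1:8]
  reps[[2]]$clones$v[1:8] <- reps[[1]]$clones$v[1:8]
  reps[[2]]$clones$j[1:8] <- reps[[1]]$clones$j[1:8]
  t <- build_overlap(reps)
  for (comp in c("dLN_CD44hi", "tumor")) {
    expect_true(all(diff(overlap_rank_frequency(t, comp)$freq) <= 0))
  }
})

test_that("public clones are those shared by at least two mice", {
  # identical single-clone repertoires -> fully public
  m1 <- make_rep(10L, mouse_id = "m01")
  m2 <- make_rep(10L, mouse_id = "m02")
  pc <- public_clones(list(m1, m2))
  expect_equal(pc$per_mouse$public_frequency, c(1, 1))
  expect_equal(pc$mean, 1)

  # fully private repertoires -> zero everywhere
  r1 <- random_rep(20, 51, mouse_id = "m01")
  r2 <- random_rep(20, 52, mouse_id = "m02")
  r3 <- random_rep(20, 53, mouse_id = "m03")
  pc0 <- public_clones(list(r1, r2, r3))
  expect_equal(pc0$per_mouse$public_frequency, c(0, 0, 0))

  # planted public pool worth 0.3 of each mouse
  pool_nt <- r1$clones$cdr3nt[1:5]
  plant <- function(r) {
    r$clones$cdr3nt[1:5] <- pool_nt
    r$clones$cdr3aa[1:5] <- paste0("CPUB", 1:5, "F")
    r$clones$v[1:5] <- "TRBV7"
    r$clones$j[1:5] <- "TRBJ2-1"
    r$clones$freq <- c(rep(0.06, 5), rep(0.7 / 15, 15))
    r
  }
  pp <- public_clones(list(plant(r1), plant(r2), plant(r3)))
  expect_equal(pp$per_mouse$public_frequency, rep(0.3, 3),
               tolerance = 1e-12)
  expect_equal(pp$mean, 0.3, tolerance = 1e-12)

  expect_error(public_clones(list(m1)), class = "tcrioct_input_error")
})

test_that("top-clone heat-map data marks sharing and absence", {
  m1 <- random_rep(30, 61, mouse_id = "m01")
  m2 <- random_rep(30, 62, mouse_id = "m02")
  # make clone 1 the top clone of each mouse, shared at AA level
  for (nm in c("m1", "m2")) {
    r <- get(nm)
    r$clones$count[1] <- max(r$clones$count) + 1000L
    r$clones$freq <- r$clones$count / sum(r$clones$count)
    assign(nm, r)
  }
  m2$clones$cdr3aa[1] <- m1$clones$cdr3aa[1]
  m2$clones$v[1] <- m1$clones$v[1]
  m2$clones$j[1] <- m1$clones$j[1]
  mat <- top_clone_heatmap_data(list(m1, m2), top_n = 10L)
  expect_equal(ncol(mat), 2L)
  expect_equal(nrow(mat), 19L)  # 10 + 10 - 1 shared
  shared_key <- paste(m1$clones$v[1], m1$clones$j[1], m1$clones$cdr3aa[1],
                      sep = "|")
  expect_true(all(is.finite(mat[shared_key, ])))
  # each mouse has finite entries exactly at its own 10 top clones
  expect_equal(sum(is.finite(mat)), 20L)
  expect_equal(sum(is.na(mat)), 18L)
  # entries are log10 frequencies
  expect_equal(mat[shared_key, "m01"], log10(m1$clones$freq[1]))
})

test_that("pattern percentages partition fuzzed tables", {
  withr::with_seed(71L, {
    for (i in 1:50) {
      n <- sample(1:80, 1)
      tumor_f <- stats::runif(n, 0, 0.01)
      dln_f <- stats::runif(n, 0, 0.01)
      dln <- make_rep(rep(1L, n), freqs = dln_f / sum(dln_f) * 0.5,
                      compartment = "dLN_CD44hi")
      tum <- make_rep(rep(1L, n), freqs = tumor_f / sum(tumor_f) * 0.5,
                      compartment = "tumor")
      pat <- classify_patterns(build_overlap(list(dln, tum)))
      expect_equal(sum(pat$percent), 100, tolerance = 1e-9)
      expect_equal(sum(pat$n_clones), n)
    }
  })
})
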