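test_that("generated tables have coherent frequencies and structure", {
  cfg <- small_scenario(101L)
  reps <- generate_mouse(cfg, 1, "control")
  expect_named(reps, c("dLN_CD44hi", "PBL", "tumor"), ignore.order = TRUE)
  for (r in reps) {
    expect_equal(sum(r$clones$freq), 1, tolerance = 1e-9)
    expect_equal(sum(r$clones$count), attr(reps, "truth")$
                   compartments[[r$compartment]]$depth)
    expect_false(anyDuplicated(clone_key(r)) > 0)
    expect_equal(r$group, "control")
  }
  # exact-weight mode also sums to 1
  repsE <- generate_mouse(cfg, 1, "control", sample_reads = FALSE)
  for (r in repsE) expect_equal(sum(r$clones$freq), 1, tolerance = 1e-9)
})

test_that("generation is deterministic in the seed and varies across mice", {
  cfg <- small_scenario(102L)
  a <- generate_mouse(cfg, 2, "control")
  b <- generate_mouse(cfg, 2, "control")
  expect_identical(a$tumor$clones, b$tumor$clones)
  c <- generate_mouse(cfg, 3, "control")
  expect_false(identical(a$tumor$clones$cdr3nt, c$tumor$clones$cdr3nt))
})

test_that("planted pool structure is exactly recoverable pre-sampling", {
  cfg <- small_scenario(103L)
  reps <- generate_mouse(cfg, 1, "control", sample_reads = FALSE)
  truth <- attr(reps, "truth")
  tbl <- build_overlap(reps[c("dLN_CD44hi", "PBL", "tumor")],
                       min_compartments = 2L)
  expect_setequal(tbl$key, unique(truth$overlap_keys_nt))
  s <- overlap_summary(tbl)
  for (comp in names(reps)) {
    expect_equal(s$combined_frequency[[comp]],
                 truth$compartments[[comp]]$overlap_weight,
                 tolerance = 1e-12)
  }
  # spike-ins sit at their planted frequencies
  for (sp in cfg$spike_ins) {
    clone <- named_clone(sp$label, "nt", v = sp$v, j = sp$j,
                         cdr3 = sp$cdr3nt)
    for (comp in names(reps)) {
      expect_equal(track_clone(reps[[comp]], clone),
                   truth$compartments[[comp]]$spike_freq[[sp$label]],
                   tolerance = 1e-12)
    }
  }
})

test_that("cross-mouse public pools are shared, mouse pools are private", {
  cfg <- small_scenario(104L)
  m1 <- generate_mouse(cfg, 1, "control", sample_reads = FALSE)
  m2 <- generate_mouse(cfg, 2, "control", sample_reads = FALSE)
  t1 <- attr(m1, "truth")
  t2 <- attr(m2, "truth")
  # public keys identical across mice; shared-pool keys disjoint
  expect_identical(t1$public_keys_aa, t2$public_keys_aa)
  expect_length(intersect(t1$shared_keys_nt, t2$shared_keys_nt), 0L)
  # measured public frequency equals the planted public weight (public
  # pool plus the spike-ins, which every mouse carries)
  for (comp in c("dLN_CD44hi", "tumor")) {
    pc <- public_clones(list(m1[[comp]], m2[[comp]]), mode = "aa")
    expect_equal(pc$per_mouse$public_frequency,
                 rep(t1$compartments[[comp]]$public_weight_measured, 2),
                 tolerance = 1e-9)
  }
})

test_that("shared-pool weight is recovered within sampling error", {
  # binomial SE oracle: combined pool frequency at depth d has
  # SE ~ sqrt(w (1 - w) / d)
  cfg <- small_scenario(105L)
  reps <- generate_mouse(cfg, 1, "control")
  truth <- attr(reps, "truth")
  for (comp in c("tumor", "PBL")) {
    w <- truth$compartments[[comp]]$overlap_weight
    d <- truth$compartments[[comp]]$depth
    keys <- clone_key(reps[[comp]])
    got <- sum(reps[[comp]]$clones$freq[keys %in% truth$overlap_keys_nt])
    expect_lt(abs(got - w), 3 * sqrt(w * (1 - w) / d))
  }
})

test_that("nonfunctional contamination appears at the configured rate", {
  cfg <- scenario_config(
    n_mice = c(control = 1L, aCD4 = 1L),
    n_clones = c(dLN_CD44hi = 10000L, PBL = 50L, tumor = 50L),
    cell_count = c(dLN_CD44hi = 5000L, PBL = 300L, tumor = 300L),
    shared_pool_size = 1L,
    shared_pool_weight = c(dLN_CD44hi = 1e-4, PBL = 1e-4, tumor = 1e-4),
    public_pool_size = 1L,
    public_pool_weight = c(dLN_CD44hi = 1e-4, PBL = 1e-4, tumor = 1e-4),
    spike_ins = list(),
    nonfunctional_rate = 0.05,
    seed = 106L
  )
  reps <- generate_mouse(cfg, 1, "control", sample_reads = FALSE)
  r <- reps$dLN_CD44hi
  n_bad <- sum(grepl("[*_]", r$clones$cdr3aa))
  # binomial oracle on 10,000 background clones
  expect_lt(abs(n_bad - 500), 3 * sqrt(10000 * 0.05 * 0.95))
  filtered <- filter_nonfunctional(r)
  expect_equal(n_clones(filtered), n_clones(r) - n_bad)
  expect_equal(sum(filtered$clones$freq), 1, tolerance = 1e-9)
})

test_that("a null treatment effect leaves the groups indistinguishable", {
  clon <- function(group) {
    vapply(1:20, function(i) {
      cfgi <- small_scenario(200L + i, treatment_effect = 1)
      clonality(generate_mouse(cfgi, 1, group)$dLN_CD44hi)
    }, numeric(1))
  }
  ks <- stats::ks.test(clon("control"), clon("aCD4"))
  expect_gt(ks$p.value, 0.01)
})

test_that("generate_study writes a complete, reproducible layout", {
  cfg <- small_scenario(108L)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  st1 <- generate_study(cfg, file.path(dir1, "study"))
  st2 <- generate_study(cfg, file.path(dir2, "study"))
  # 2 groups x 5 mice x 3 compartments + sheet
  expect_equal(nrow(st1$sheet), 30L)
  expect_length(dir(file.path(dir1, "study")), 31L)
  # same seed twice -> byte-identical outputs
  for (f in dir(file.path(dir1, "study"))) {
    expect_identical(readLines(file.path(dir1, "study", f)),
                     readLines(file.path(dir2, "study", f)))
  }
  # collision protection
  expect_error(generate_study(cfg, file.path(dir1, "study")),
               class = "tcrioct_io_error")
  expect_no_error(generate_study(cfg, file.path(dir1, "study"),
                                 overwrite = TRUE))
  # tables are readable through the standard reader
  reps <- read_study_tables(st1$sheet_path)
  expect_length(reps, 30L)
  expect_equal(sum(reps[[1]]$clones$freq), 1, tolerance = 1e-9)
})

test_that("invalid scenario configurations are rejected", {
  expect_error(scenario_config(nonfunctional_rate = 1.2),
               class = "tcrioct_config_error")
  expect_error(scenario_config(shared_pool_size = 0L),
               class = "tcrioct_config_error")
  # per-compartment planted weights exceeding 1 fail at generation
  cfg <- scenario_config(
    shared_pool_weight = c(dLN_CD44hi = 0.6, PBL = 0.1, tumor = 0.4),
    public_pool_weight = c(dLN_CD44hi = 0.5, PBL = 0.1, tumor = 0.4))
  expect_error(generate_mouse(cfg, 1, "control"),
               class = "tcrioct_config_error")
})
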