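# Synthetic cohort generator: schedule, trials, BOLD covariance planting,
# latent coupling, and on-disk round trip.

test_that("block schedule permutes six blocks per load and is deterministic", {
  cfg <- cohort_config(seed = 4)
  s1 <- make_block_schedule(cfg, seed = 11)
  s2 <- make_block_schedule(cfg, seed = 11)
  s3 <- make_block_schedule(cfg, seed = 12)
  expect_identical(s1, s2)
  expect_false(identical(s1$load, s3$load))
  expect_equal(nrow(s1), 18L)
  expect_equal(as.vector(table(s1$load)), rep(6L, 3))
  expect_equal(sum(s1$duration), 18 * 20)
  # non-overlapping with rest gaps
  expect_true(all(diff(s1$onset) == 30))
  # reduced design fits a 120 s session
  cfg_small <- cohort_config(blocks_per_load = 1, n_volumes = 60, seed = 1)
  s <- make_block_schedule(cfg_small, seed = 1)
  expect_equal(nrow(s), 3L)
  expect_lte(max(s$onset + s$duration), 120)
  # infeasible schedule is a configuration error
  expect_error(cohort_config(n_volumes = 100, seed = 1), "exceeds session")
})

test_that("volume labels cover the session at TR resolution", {
  cfg <- cohort_config(seed = 4)
  sched <- make_block_schedule(cfg, seed = 2)
  lab <- volume_labels(sched, cfg)
  expect_length(lab, 275)
  expect_equal(sum(lab != "rest"), 18 * 10)
  for (L in 0:2) expect_equal(sum(lab == as.character(L)), 60)
})

test_that("trials are deterministic, well-formed, and degrade with load", {
  cfg <- cohort_config(seed = 4)
  sched <- make_block_schedule(cfg, seed = 2)
  lat <- list(subject_id = "s1", ability = 0)
  t1 <- simulate_trials(lat, sched, cfg, seed = 5)
  t2 <- simulate_trials(lat, sched, cfg, seed = 5)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 180L)
  expect_true(all(t1$response %in% c("target", "non-target", "omitted")))
  expect_true(all(is.na(t1$rt) == (t1$response == "omitted")))
  expect_true(all(t1$rt[!is.na(t1$rt)] > 0 & t1$rt[!is.na(t1$rt)] <= 2))
  # group-mean pRT monotone increasing in load over >= 20 subjects
  cohort <- default_cohort()
  trials <- do.call(rbind, lapply(cohort$subjects[1:25], `[[`, "trials"))
  prt <- penalized_rt(trials, 2.5)
  m <- tapply(prt$prt, prt$load, mean)
  expect_true(all(diff(m) > 0))
})

test_that("BOLD draws plant the condition-dependent correlation structure", {
  # long-session calibration: within-DMN mean correlation per condition
  # within +/-0.05 of target at >= 500 volumes per condition
  # 67 blocks of 60 s per load -> 2010 volumes per condition at TR 2 s
  cfg <- cohort_config(n_nodes = 24, n_dmn_nodes = 12, n_volumes = 7100,
                       block_len = 60, rest_len = 10, blocks_per_load = 67,
                       base_corr_dmn = 0.3, base_z_sd = 0,
                       hrf_delay_volumes = 0, seed = 9)
  lat <- list(subject_id = "s1", dmn_slope_true = -0.1,
              tpn_slope_true = 0.05, base_z_dmn = 0, base_z_tpn = 0)
  sched <- make_block_schedule(cfg, seed = 3)
  ts <- simulate_bold(lat, sched, cfg, seed = 7)
  expect_equal(dim(ts$data), c(24L, 7100L))
  dmn <- seq_len(12)
  for (L in 0:2) {
    idx <- which(ts$labels == as.character(L))
    r <- cor(t(ts$data[dmn, idx]))
    target <- tanh(atanh(0.3) - 0.1 * (L - 1))
    expect_lt(abs(mean(r[upper.tri(r)]) - target), 0.05)
  }
  # per-edge w1 recovery within +/-0.01 of the planted slope, long session
  zs <- lapply(c("0", "1", "2"), function(cd) {
    condition_connectivity(ts, cd, lag_volumes = 0L)
  })
  lr <- edge_load_regression(zs, rep(c("DMN", "TPN"), each = 12))
  expect_lt(abs(lr$dmn_w1 - (-0.1)), 0.01)
  expect_lt(abs(lr$tpn_w1 - 0.05), 0.01)
  # null case: all slopes zero -> network-mean w1 centred on zero. Edge
  # estimates within one run share samples and are correlated, so the
  # valid one-sample t is across independent runs, not across edges.
  lat0 <- list(subject_id = "s1", dmn_slope_true = 0, tpn_slope_true = 0,
               base_z_dmn = 0, base_z_tpn = 0)
  w1_runs <- vapply(1:10, function(s) {
    ts0 <- simulate_bold(lat0, sched, cfg, seed = 100 + s)
    zs0 <- lapply(c("0", "1", "2"), function(cd) {
      condition_connectivity(ts0, cd, lag_volumes = 0L)
    })
    edge_load_regression(zs0, rep(c("DMN", "TPN"), each = 12))$dmn_w1
  }, numeric(1))
  expect_gt(one_sample_t(w1_runs)$p, 0.01)
})

test_that("default BOLD dimensions match the emulated design", {
  cohort <- default_cohort()
  sub <- cohort$subjects[[1]]
  expect_equal(dim(sub$bold$data), c(97L, 275L))
  expect_identical(sub$bold$node_ids, cohort$node_labels$node_id)
})

test_that("copula coupling hits the target rank correlation", {
  cfg <- cohort_config(seed = 1)
  rhos <- vapply(1:20, function(s) {
    lat <- simulate_latents(cfg, seed = 1000 + s)
    cor(lat$bp_caudate, lat$dmn_slope_true, method = "spearman")
  }, numeric(1))
  # mean over seeds close to the 0.45 target; each seed within a 3-sigma
  # band of the Spearman sampling distribution at n = 51
  expect_lt(abs(mean(rhos) - 0.45), 0.05)
  expect_true(all(abs(rhos - 0.45) < 3 * 0.12))
  # null coupling plants no association
  cfg0 <- cohort_config(rho_bp_slope = 0, seed = 1)
  rhos0 <- vapply(1:20, function(s) {
    lat <- simulate_latents(cfg0, seed = 2000 + s)
    cor(lat$bp_caudate, lat$dmn_slope_true, method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rhos0)), 0.08)
  # BP_ND values non-negative, slopes finite
  lat <- simulate_latents(cfg, seed = 77)
  expect_true(all(lat$bp_caudate >= 0 & lat$bp_snvta >= 0))
  expect_true(all(is.finite(lat$dmn_slope_true)))
})

test_that("cohort writes a complete, byte-identical directory layout", {
  cfg <- cohort_config(n_subjects = 3, seed = 42)
  d1 <- file.path(tempdir(), "coh1")
  d2 <- file.path(tempdir(), "coh2")
  on.exit(unlink(c(d1, d2), recursive = TRUE))
  suppressWarnings(simulate_cohort(cfg, out_dir = d1))
  suppressWarnings(simulate_cohort(cfg, out_dir = d2))
  files <- c("schedule.tsv", "node_labels.tsv", "latents.tsv",
             "manifest.json",
             file.path("sub-01", c("timeseries.tsv", "trials.tsv",
                                   "tacs.tsv")))
  for (f in files) {
    expect_true(file.exists(file.path(d1, f)), label = f)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  man <- jsonlite::read_json(file.path(d1, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(length(man$subjects), 3L)
  # read-back round trip preserves the data
  coh <- suppressWarnings(simulate_cohort(cfg))
  coh2 <- read_cohort(d1)
  expect_equal(coh2$latents$bp_caudate, coh$latents$bp_caudate,
               tolerance = 1e-12)
  expect_equal(unname(coh2$subjects[[1]]$bold$data[1, 1:5]),
               unname(coh$subjects[[1]]$bold$data[1, 1:5]),
               tolerance = 1e-10)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(base_corr_dmn = 1.2), "strictly in")
  expect_error(cohort_config(n_dmn_nodes = 97), "n_dmn_nodes")
  expect_error(cohort_config(n_subjects = 0), "positive")
})
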