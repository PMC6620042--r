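# Fisher-z connectivity, per-edge load regression, and network summaries.

make_ts <- function(X, tr = 2, block_len = 20, rest_len = 10) {
  n_blocks <- 18L
  sched <- data.frame(block = 1:n_blocks,
                      load = rep(0:2, 6),
                      onset = rest_len + (0:(n_blocks - 1)) *
                        (block_len + rest_len),
                      duration = block_len)
  structure(list(data = X, node_ids = sprintf("n%02d", seq_len(nrow(X))),
                 labels = NULL, tr = tr, schedule = sched),
            class = "parcel_ts")
}

test_that("perfect correlation is clamped, not infinite", {
  set.seed(2)
  x <- rnorm(560)
  X <- rbind(x, x, rnorm(560))
  ts <- make_ts(X)
  em <- condition_connectivity(ts, 0, lag_volumes = 0L)
  expect_true(is.finite(em$z[1, 2]))
  expect_equal(em$z[1, 2], atanh(1 - 1e-12))
  expect_gt(em$z[1, 2], 13)
  # constant node is an error naming the node
  X2 <- rbind(rnorm(560), rep(1, 560))
  expect_error(condition_connectivity(make_ts(X2), 0, 0L), "n02")
})

test_that("independent noise yields near-zero z at large n", {
  set.seed(3)
  # 10 nodes, long independent series: |z| small for all edges
  n_samp <- 10000
  sched <- data.frame(block = 1, load = 0, onset = 0, duration = 2 * n_samp)
  ts <- structure(list(data = matrix(rnorm(10 * n_samp), 10),
                       node_ids = sprintf("n%d", 1:10), labels = NULL,
                       tr = 2, schedule = sched),
                  class = "parcel_ts")
  em <- condition_connectivity(ts, 0, lag_volumes = 0L)
  expect_lt(max(abs(em$z), na.rm = TRUE), 0.05)
})

test_that("edge matrices are symmetric and permutation-equivariant", {
  cohort <- default_cohort()
  sub <- cohort$subjects[[1]]
  em <- condition_connectivity(sub$bold, 0)
  expect_equal(em$z, t(em$z))
  expect_equal(em$n, 60L)
  perm <- sample(97)
  ts_p <- sub$bold
  ts_p$data <- ts_p$data[perm, ]
  ts_p$node_ids <- ts_p$node_ids[perm]
  em_p <- condition_connectivity(ts_p, 0)
  expect_equal(unname(em_p$z), unname(em$z[perm, perm]))
})

test_that("per-edge load regression matches the OLS closed form", {
  z <- lapply(c(0, 1, 2), function(L) {
    structure(list(z = matrix(0.3 - 0.05 * L, 2, 2), condition = as.character(L),
                   n = 60L, node_ids = c("a", "b")), class = "edge_matrix")
  })
  lr <- edge_load_regression(z)
  expect_equal(lr$w1[1, 2], -0.05)
  expect_equal(lr$w0[1, 2], 0.3)
  # identical z across loads -> w1 = 0
  z_flat <- lapply(c(0, 1, 2), function(L) {
    structure(list(z = matrix(0.25, 2, 2), condition = as.character(L),
                   n = 60L, node_ids = c("a", "b")), class = "edge_matrix")
  })
  expect_equal(edge_load_regression(z_flat)$w1[1, 2], 0)
  # non-collinear z agrees with lm per edge
  zv <- c(0.31, 0.22, 0.18)
  z_nc <- lapply(1:3, function(k) {
    structure(list(z = matrix(zv[k], 2, 2), condition = as.character(k - 1),
                   n = 60L, node_ids = c("a", "b")), class = "edge_matrix")
  })
  lr_nc <- edge_load_regression(z_nc)
  co <- coef(lm(zv ~ c(0, 1, 2)))
  expect_equal(lr_nc$w1[1, 2], unname(co[2]))
  expect_equal(lr_nc$w0[1, 2], unname(co[1]))
  expect_error(edge_load_regression(z[1:2]), "three load conditions")
})

test_that("edge-set bookkeeping matches the reported network sizes", {
  # 42-node DMN and 53-node TPN: 861 / 1378 / 2226 edges
  networks <- rep(c("DMN", "TPN"), c(42, 53))
  m <- dopaconn:::edge_masks(networks)
  expect_equal(sum(m$dmn), 42 * 41 / 2)
  expect_equal(sum(m$tpn), 53 * 52 / 2)
  expect_equal(sum(m$between), 42 * 53)
  # network means are plain arithmetic means over the edge sets
  set.seed(4)
  W <- matrix(rnorm(95^2), 95)
  W <- (W + t(W)) / 2
  expect_equal(dopaconn:::network_edge_means(W, networks)$dmn,
               mean(W[upper.tri(W) & outer(networks == "DMN",
                                           networks == "DMN", "&")]))
})

test_that("whole-session pooling equals single conditions when flat", {
  cfg <- cohort_config(n_nodes = 20, n_dmn_nodes = 10, seed = 3)
  lat <- list(subject_id = "s", dmn_slope_true = 0, tpn_slope_true = 0,
              base_z_dmn = 0, base_z_tpn = 0)
  sched <- make_block_schedule(cfg, seed = 2)
  ts <- simulate_bold(lat, sched, cfg, seed = 6)
  nets <- rep(c("DMN", "TPN"), each = 10)
  ws <- whole_session_connectivity(ts, nets)
  c0 <- condition_connectivity(ts, 0)
  m0 <- dopaconn:::network_edge_means(c0$z, nets)
  expect_equal(ws$n, 180L)
  # pooling identity up to sampling error (60 vs 180 samples)
  expect_lt(abs(ws$dmn - m0$dmn), 3 * sqrt(1 / 57))
  # planted slope: whole-session mean sits at the mean-load (load 1)
  # value, which the centred planting makes slope-independent
  lat2 <- list(subject_id = "s", dmn_slope_true = -0.1,
               tpn_slope_true = 0.05, base_z_dmn = 0, base_z_tpn = 0)
  ts2 <- simulate_bold(lat2, sched, cfg, seed = 7)
  ws2 <- whole_session_connectivity(ts2, nets)
  expect_lt(abs(ws2$dmn - atanh(cfg$base_corr_dmn)), 0.1)
  # empty schedule is an error
  ts_empty <- ts
  ts_empty$schedule <- ts$schedule[0, ]
  expect_error(whole_session_connectivity(ts_empty, nets), "no task blocks")
})

test_that("block-wise DMN strength tracks planted block differences", {
  cohort <- default_cohort()
  sub <- cohort$subjects[[1]]
  nets <- planted_networks(cohort)
  st <- blockwise_network_strength(sub$bold, nets)
  expect_length(st, 18L)
  expect_true(all(is.finite(st)))
  # determinism
  expect_identical(blockwise_network_strength(sub$bold, nets), st)
  # constructed case: stronger DMN correlation planted in even blocks ->
  # even-block strengths exceed odd-block strengths (sign test over 10
  # seeds: all 10 must agree, binomial p < 0.01)
  n_nodes <- 12
  sched <- data.frame(block = 1:18, load = rep(0:2, 6),
                      onset = 10 + (0:17) * 30, duration = 20)
  chol_for <- function(r) {
    R <- matrix(r, n_nodes, n_nodes)
    diag(R) <- 1
    chol(R)
  }
  ch_hi <- chol_for(0.5)
  ch_lo <- chol_for(0.2)
  hits <- vapply(1:10, function(s) {
    set.seed(400 + s)
    X <- matrix(rnorm(n_nodes * 275), n_nodes)
    for (b in 1:18) {
      idx <- (sched$onset[b] / 2 + 1):((sched$onset[b] + 20) / 2)
      ch <- if (b %% 2 == 0) ch_hi else ch_lo
      X[, idx] <- crossprod(ch, matrix(rnorm(n_nodes * 10), n_nodes))
    }
    ts <- structure(list(data = X, node_ids = sprintf("n%02d", 1:n_nodes),
                         labels = NULL, tr = 2, schedule = sched),
                    class = "parcel_ts")
    sti <- blockwise_network_strength(ts, rep("DMN", n_nodes),
                                      lag_volumes = 0L)
    mean(sti[seq(2, 18, 2)]) > mean(sti[seq(1, 17, 2)])
  }, logical(1))
  expect_equal(sum(hits), 10L)
})
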