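# Synthetic cohort generator: seeded cohorts (block schedule, trial-level
# behaviour, parcellated BOLD with condition-dependent covariance, PET
# time-activity curves) with planted effect structure so every downstream
# stage of the analysis has known ground truth.

#' Cohort configuration
#'
#' Builds and validates the configuration of a synthetic PET/fMRI working
#' memory cohort. Defaults mirror the study design being emulated: 51
#' subjects, 97 cortical nodes (42 default mode network, 53 task-positive),
#' 275 BOLD volumes at TR = 2 s, 18 n-back task blocks of 20 s (six each of
#' 0-, 1- and 2-back) interleaved with 10 s rest.
#'
#' Load-dependent connectivity is planted linearly on the Fisher z scale,
#' centred on the session-mean load (exactly 1 with six blocks per load):
#' the within-DMN correlation at load L is
#' `tanh(atanh(base_corr_dmn) + base_z + dmn_slope_true * (L - 1))`, so
#' the per-edge load regression slope w1 recovers `dmn_slope_true` exactly
#' in expectation while whole-session (mean-load) connectivity stays
#' independent of the slope, emulating the null whole-session control. A latent caudate BP_ND is coupled to the DMN slope through a
#' Gaussian copula targeting a Spearman rank correlation of `rho_bp_slope`,
#' and behavioural load-robustness is generated from the DMN slope
#' (mediated path) plus an optional direct BP_ND effect.
#'
#' @param n_subjects number of subjects (default 51).
#' @param n_nodes number of cortical nodes (default 97).
#' @param n_dmn_nodes number of nodes planted in the DMN (default 42; the
#'   remaining nodes form the task-positive network).
#' @param tr repetition time in seconds (default 2).
#' @param n_volumes BOLD volumes per session (default 275).
#' @param block_len task block length, seconds (default 20).
#' @param rest_len rest block length, seconds (default 10).
#' @param blocks_per_load task blocks per n-back load level (default 6).
#' @param trials_per_block trials per task block (default 10; one letter
#'   every 2 s).
#' @param base_corr_dmn,base_corr_tpn,base_corr_between Pearson
#'   correlations within DMN, within TPN, and between networks at the
#'   session-mean load (load 1).
#' @param base_z_sd between-subject s.d. of the baseline connectivity on
#'   the Fisher z scale (subject-level stable trait, independent of BP_ND;
#'   this is what makes whole-session connectivity a poor proxy for the
#'   load-dependent change).
#' @param mean_dmn_slope,sd_dmn_slope mean and between-subject s.d. of the
#'   planted within-DMN Fisher-z slope per load level (default -0.1,
#'   0.12: heterogeneity dominates the ~0.03 w1 sampling noise of the
#'   60-volumes-per-condition design, so between-subject correlations on
#'   measured w1 are essentially unattenuated).
#' @param mean_tpn_slope planted within-TPN slope (default +0.05, no
#'   between-subject spread).
#' @param bp_mean,bp_sd mean and s.d. of caudate BP_ND (truncated at 0).
#' @param rho_bp_slope target Spearman correlation between caudate BP_ND
#'   and the DMN slope (default 0.45).
#' @param behav_slope_coupling seconds of load-robustness (-dpRT) per
#'   z-unit of DMN slope: the mediated path (default 1).
#' @param direct_bp_behaviour direct BP_ND -> behaviour path in
#'   pRT-seconds per BP_ND unit (default 0: pure mediation).
#' @param behav_noise_sd s.d. of subject-level behavioural noise added to
#'   the load-robustness target, seconds per load level (default 0.02).
#' @param hrf_delay_volumes delay, in volumes, with which a block's
#'   condition is expressed in the BOLD covariance (default 2 volumes =
#'   4 s), emulating haemodynamic delay; the analysis side compensates
#'   with its `lag_volumes` window shift.
#' @param noise_sd BOLD signal amplitude (node s.d., arbitrary units).
#' @param tac_noise_frac PET frame noise fraction; frame s.d. is
#'   `tac_noise_frac * max(TAC) * sqrt(300 / frame_duration)` so variance
#'   scales as 1/frame duration (conventional PET approximation).
#' @param seed master integer seed.
#' @return an object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_subjects = 51, n_nodes = 97, n_dmn_nodes = 42,
                          tr = 2, n_volumes = 275, block_len = 20,
                          rest_len = 10, blocks_per_load = 6,
                          trials_per_block = 10,
                          base_corr_dmn = 0.4, base_corr_tpn = 0.3,
                          base_corr_between = 0.05, base_z_sd = 0.1,
                          mean_dmn_slope = -0.1, sd_dmn_slope = 0.12,
                          mean_tpn_slope = 0.05,
                          bp_mean = 2.0, bp_sd = 0.4, rho_bp_slope = 0.45,
                          behav_slope_coupling = 1.0,
                          direct_bp_behaviour = 0,
                          behav_noise_sd = 0.02,
                          hrf_delay_volumes = 2L,
                          noise_sd = 1.0, tac_noise_frac = 0.05,
                          seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_nodes = as.integer(n_nodes),
    n_dmn_nodes = as.integer(n_dmn_nodes), tr = tr,
    n_volumes = as.integer(n_volumes), block_len = block_len,
    rest_len = rest_len, blocks_per_load = as.integer(blocks_per_load),
    trials_per_block = as.integer(trials_per_block),
    base_corr_dmn = base_corr_dmn, base_corr_tpn = base_corr_tpn,
    base_corr_between = base_corr_between, base_z_sd = base_z_sd,
    mean_dmn_slope = mean_dmn_slope, sd_dmn_slope = sd_dmn_slope,
    mean_tpn_slope = mean_tpn_slope,
    bp_mean = bp_mean, bp_sd = bp_sd, rho_bp_slope = rho_bp_slope,
    behav_slope_coupling = behav_slope_coupling,
    direct_bp_behaviour = direct_bp_behaviour,
    behav_noise_sd = behav_noise_sd,
    hrf_delay_volumes = as.integer(hrf_delay_volumes),
    noise_sd = noise_sd, tac_noise_frac = tac_noise_frac,
    seed = as.integer(seed)
  )
  counts <- c("n_subjects", "n_nodes", "n_dmn_nodes", "n_volumes",
              "blocks_per_load", "trials_per_block")
  for (nm in counts) {
    if (cfg[[nm]] < 1L) stopf("configuration error: %s must be positive", nm)
  }
  if (cfg$n_dmn_nodes >= cfg$n_nodes) {
    stopf("configuration error: n_dmn_nodes must be < n_nodes")
  }
  for (nm in c("base_corr_dmn", "base_corr_tpn", "base_corr_between")) {
    if (abs(cfg[[nm]]) >= 1) {
      stopf("configuration error: %s must lie strictly in (-1, 1)", nm)
    }
  }
  if (abs(cfg$rho_bp_slope) >= 1) {
    stopf("configuration error: rho_bp_slope must lie strictly in (-1, 1)")
  }
  n_blocks <- 3L * cfg$blocks_per_load
  session <- cfg$n_volumes * cfg$tr
  needed <- cfg$rest_len + n_blocks * cfg$block_len +
    (n_blocks - 1L) * cfg$rest_len
  if (needed > session) {
    stopf(paste0(
      "configuration error: schedule (%g s: %d blocks of %g s with %g s ",
      "rest) exceeds session length %g s"),
      needed, n_blocks, cfg$block_len, cfg$rest_len, session)
  }
  class(cfg) <- "cohort_config"
  cfg
}

#' Pseudo-random block schedule
#'
#' Permutes the load labels (six blocks each of 0-, 1- and 2-back under the
#' defaults) over the task blocks of a session, with a rest period of
#' `rest_len` seconds before the first block and between consecutive
#' blocks. Deterministic given the seed.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed for the block permutation.
#' @return a data frame with columns `block` (1..n), `load` (0/1/2),
#'   `onset` and `duration` (seconds).
#' @export
make_block_schedule <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  n_blocks <- 3L * config$blocks_per_load
  loads <- with_seed(seed, sample(rep(0:2, each = config$blocks_per_load)))
  onsets <- config$rest_len +
    (seq_len(n_blocks) - 1L) * (config$block_len + config$rest_len)
  schedule <- data.frame(
    block = seq_len(n_blocks), load = loads,
    onset = onsets, duration = config$block_len
  )
  if (max(schedule$onset + schedule$duration) > config$n_volumes * config$tr) {
    stopf("configuration error: schedule exceeds session length")
  }
  schedule
}

#' Volume-wise condition labels
#'
#' Derives, at TR resolution, the condition ("rest", "0", "1", "2") of each
#' BOLD volume from a block schedule. A volume is assigned to a block if its
#' acquisition onset falls inside the block window.
#'
#' @param schedule a block schedule from [make_block_schedule()].
#' @param config the matching [cohort_config()].
#' @return character vector of length `n_volumes`.
#' @export
volume_labels <- function(schedule, config) {
  t0 <- (seq_len(config$n_volumes) - 1L) * config$tr
  lab <- rep("rest", config$n_volumes)
  for (b in seq_len(nrow(schedule))) {
    sel <- t0 >= schedule$onset[b] &
      t0 < schedule$onset[b] + schedule$duration[b]
    lab[sel] <- as.character(schedule$load[b])
  }
  lab
}

# Quantile function of a Normal(mean, sd) truncated below at 0.
qtruncnorm0 <- function(p, mean, sd) {
  a <- pnorm(0, mean, sd)
  qnorm(a + p * (1 - a), mean, sd)
}

#' Draw subject latent parameters
#'
#' Generates the per-subject ground-truth record: regional BP_ND values,
#' the true DMN/TPN connectivity slopes, baseline connectivity offsets and
#' the behavioural ability parameter. Caudate BP_ND and the DMN slope are
#' coupled through a Gaussian copula so their Spearman correlation targets
#' `rho_bp_slope` (latent Pearson correlation `2*sin(pi*rho/6)`); both
#' margins are monotone in their latent normals, which preserves the rank
#' correlation exactly in population.
#'
#' The `ability` field is the subject's target load-robustness -dpRT in
#' seconds per load level:
#' `behav_slope_coupling * dmn_slope_true + direct_bp_behaviour * bp_caudate
#'  + Normal(0, behav_noise_sd)`,
#' and drives both the reaction-time load slope and error rates in
#' [simulate_trials()].
#'
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return data frame with one row per subject.
#' @export
simulate_latents <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  with_seed(seed, {
    rp <- 2 * sin(pi * config$rho_bp_slope / 6) # Spearman -> Pearson (copula)
    u1 <- rnorm(n)
    u2 <- rp * u1 + sqrt(1 - rp^2) * rnorm(n)
    bp_caudate <- qtruncnorm0(pnorm(u1), config$bp_mean, config$bp_sd)
    dmn_slope <- config$mean_dmn_slope + config$sd_dmn_slope * u2
    # Other striatal regions: correlated with caudate but (conditionally)
    # independent of the DMN slope; SN/VTA independent (negative control).
    mix <- function(r, mu_scale) {
      uu <- r * u1 + sqrt(1 - r^2) * rnorm(n)
      qtruncnorm0(pnorm(uu), mu_scale * config$bp_mean, config$bp_sd)
    }
    bp_putamen <- mix(0.6, 1.25)
    bp_accumbens <- mix(0.5, 1.60)
    bp_snvta <- qtruncnorm0(pnorm(rnorm(n)), 0.9 * config$bp_mean,
                            config$bp_sd)
    bp_striatum <- 0.38 * bp_caudate + 0.48 * bp_putamen +
      0.14 * bp_accumbens
    ability <- config$behav_slope_coupling * dmn_slope +
      config$direct_bp_behaviour * bp_caudate +
      rnorm(n, 0, config$behav_noise_sd)
    data.frame(
      subject_id = sprintf("sub-%02d", seq_len(n)),
      bp_caudate = bp_caudate, bp_putamen = bp_putamen,
      bp_accumbens = bp_accumbens, bp_striatum = bp_striatum,
      bp_snvta = bp_snvta,
      dmn_slope_true = dmn_slope,
      tpn_slope_true = rep(config$mean_tpn_slope, n),
      base_z_dmn = rnorm(n, 0, config$base_z_sd),
      base_z_tpn = rnorm(n, 0, config$base_z_sd),
      ability = ability,
      stringsAsFactors = FALSE
    )
  })
}

#' A-priori node labels
#'
#' Node identifiers and their a-priori network assignment: the first
#' `n_dmn_nodes` nodes are DMN, the remaining task-positive nodes are split
#' between the dorsal attention (DAN) and frontoparietal (FPN) networks.
#'
#' @param config a [cohort_config()].
#' @return data frame with columns `node_id`, `apriori_network`.
#' @export
node_labels <- function(config) {
  n <- config$n_nodes
  ndmn <- config$n_dmn_nodes
  ntpn <- n - ndmn
  ndan <- ntpn %/% 2L
  data.frame(
    node_id = sprintf("node_%03d", seq_len(n)),
    apriori_network = c(rep("DMN", ndmn), rep("DAN", ndan),
                        rep("FPN", ntpn - ndan)),
    stringsAsFactors = FALSE
  )
}

#' Simulate trial-level n-back behaviour
#'
#' Generates `trials_per_block` trials per task block. Each trial has a
#' target-present flag (30% targets), a response (`target`, `non-target` or
#' `omitted`) and a reaction time in (0, 2] s for non-omitted trials. The
#' mean RT increases with load and decreases with the subject's
#' load-robustness (`ability`, seconds/load: the RT load slope is
#' `-ability`); error and omission probabilities increase with load and
#' decrease with ability.
#'
#' @param latents one row of [simulate_latents()] (or a list with
#'   `subject_id` and `ability`).
#' @param schedule block schedule from [make_block_schedule()].
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @param base_err baseline error probability at load 0 (default 0.03).
#' @param rt_base mean correct RT at load 0, seconds (default 0.45).
#' @param rt_sd trial RT s.d., seconds (default 0.1).
#' @return data frame with columns `subject_id`, `block`, `load`, `trial`,
#'   `target` (0/1), `response`, `rt` (NA when omitted).
#' @export
simulate_trials <- function(latents, schedule, config, seed,
                            base_err = 0.03, rt_base = 0.45, rt_sd = 0.1) {
  stopifnot(inherits(config, "cohort_config"))
  ability <- latents$ability %||% 0
  ntr <- config$trials_per_block
  with_seed(seed, {
    out <- lapply(seq_len(nrow(schedule)), function(b) {
      load <- schedule$load[b]
      target <- rbinom(ntr, 1, 0.3)
      p_err <- plogis(qlogis(base_err) + 0.9 * load - 5 * ability)
      err <- runif(ntr) < p_err
      omit <- err & runif(ntr) < 0.5
      response <- ifelse(target == 1, "target", "non-target")
      response[err & !omit] <- ifelse(target[err & !omit] == 1,
                                      "non-target", "target")
      response[omit] <- "omitted"
      mu <- rt_base + (0.02 - ability) * load
      rt <- pmin(pmax(rnorm(ntr, mu, rt_sd), 0.05), 2)
      rt[omit] <- NA_real_
      data.frame(
        subject_id = latents$subject_id %||% "sub-01",
        block = schedule$block[b], load = load, trial = seq_len(ntr),
        target = target, response = response, rt = rt,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, out)
  })
}

# Condition-dependent target correlation matrix on the observed series.
# Correlations are planted directly: within-DMN Fisher z is
# atanh(base) + base_z + slope*(load - 1), analogously for the TPN. The
# load-centring keeps whole-session (mean-load) connectivity independent
# of the slope and keeps low-load correlations away from the
# equicorrelation positive-definiteness wall.
target_corr <- function(config, load, dmn_slope, tpn_slope,
                        base_z_dmn = 0, base_z_tpn = 0) {
  n <- config$n_nodes
  ndmn <- config$n_dmn_nodes
  r_dmn <- tanh(fisher_z(config$base_corr_dmn) + base_z_dmn +
                  dmn_slope * (load - 1))
  r_tpn <- tanh(fisher_z(config$base_corr_tpn) + base_z_tpn +
                  tpn_slope * (load - 1))
  r_bet <- config$base_corr_between
  R <- matrix(r_bet, n, n)
  R[seq_len(ndmn), seq_len(ndmn)] <- r_dmn
  R[(ndmn + 1L):n, (ndmn + 1L):n] <- r_tpn
  diag(R) <- 1
  R
}

#' Simulate parcellated BOLD time series
#'
#' Draws each BOLD volume from a zero-mean multivariate normal whose
#' correlation structure depends on the volume's condition: the planted
#' within-network correlation at load L is
#' `tanh(atanh(base_corr) + base_z + slope * (L - 1))`; rest volumes use
#' the load-0 structure. The planted correlations are the *observed* sampling
#' correlations, so the per-edge load regression recovers the planted slope
#' exactly in expectation; `noise_sd` only scales the signal amplitude.
#' There is no haemodynamic convolution: the generator emulates denoised
#' residual time series from which task-evoked mean effects have already
#' been removed.
#'
#' If a target correlation matrix is not positive definite it is repaired
#' with the nearest positive-definite correlation matrix
#' ([Matrix::nearPD()]) and a warning is emitted; failure after repair is a
#' generation error.
#'
#' @inheritParams simulate_trials
#' @return object of class `parcel_ts`: list with `data` (nodes x volumes
#'   matrix), `node_ids`, `labels` (volume-wise conditions), `tr` and the
#'   `schedule`.
#' @export
simulate_bold <- function(latents, schedule, config, seed) {
  stopifnot(inherits(config, "cohort_config"))
  labels <- volume_labels(schedule, config)
  dmn_slope <- latents$dmn_slope_true %||% 0
  tpn_slope <- latents$tpn_slope_true %||% 0
  bz_d <- latents$base_z_dmn %||% 0
  bz_t <- latents$base_z_tpn %||% 0
  chols <- lapply(0:2, function(L) {
    R <- target_corr(config, L, dmn_slope, tpn_slope, bz_d, bz_t)
    ch <- tryCatch(chol(R), error = function(e) NULL)
    if (is.null(ch)) {
      warning(sprintf(
        "target covariance at load %d not positive definite; applying nearest-PD repair", L
      ), call. = FALSE)
      R2 <- as.matrix(Matrix::nearPD(R, corr = TRUE, posd.tol = 1e-6)$mat)
      ch <- tryCatch(chol(R2), error = function(e) NULL)
      if (is.null(ch)) { # ridge fallback for a barely-PSD repair
        R2 <- (R2 + 1e-8 * diag(nrow(R2))) / (1 + 1e-8)
        ch <- tryCatch(chol(R2), error = function(e) NULL)
      }
      if (is.null(ch)) {
        stopf("generation error: load-%d covariance not positive definite after repair", L)
      }
    }
    ch
  })
  delay <- config$hrf_delay_volumes %||% 0L
  eff <- c(rep("rest", delay), labels)[seq_len(config$n_volumes)]
  cond <- ifelse(eff == "rest", "0", eff)
  with_seed(seed, {
    Z <- matrix(rnorm(config$n_nodes * config$n_volumes),
                nrow = config$n_nodes)
    X <- matrix(0, config$n_nodes, config$n_volumes)
    for (L in 0:2) {
      sel <- cond == as.character(L)
      if (any(sel)) {
        X[, sel] <- config$noise_sd * crossprod(chols[[L + 1L]], Z[, sel])
      }
    }
    structure(
      list(data = X, node_ids = node_labels(config)$node_id,
           labels = labels, tr = config$tr, schedule = schedule),
      class = "parcel_ts"
    )
  })
}

#' @export
print.parcel_ts <- function(x, ...) {
  cat(sprintf("Parcellated BOLD time series: %d nodes x %d volumes (TR %g s)\n",
              nrow(x$data), ncol(x$data), x$tr))
  cat(sprintf("Conditions: %s\n",
              paste(sprintf("%s=%d", names(table(x$labels)),
                            as.integer(table(x$labels))), collapse = ", ")))
  invisible(x)
}

#' Simulate a full cohort
#'
#' Generates the complete synthetic cohort: subject latents, a shared block
#' schedule, and per subject a trial table, a parcellated BOLD time series
#' and regional PET time-activity curves generated from the SRTM forward
#' model with the subject's latent BP_ND values. If `out_dir` is given, the
#' cohort is written as plain-text TSV files plus a JSON manifest
#' (see Details); generation is byte-identical for a fixed config and seed.
#'
#' @details Output layout: `<out>/sub-XX/timeseries.tsv` (nodes x volumes),
#' `<out>/sub-XX/trials.tsv`, `<out>/sub-XX/tacs.tsv` (frame_start_s,
#' frame_dur_s, ref_activity, one column per region), `<out>/schedule.tsv`,
#' `<out>/node_labels.tsv`, `<out>/latents.tsv`, `<out>/manifest.json`.
#'
#' @param config a [cohort_config()].
#' @param out_dir optional output directory.
#' @return (invisibly, when writing) an object of class `cohort`: list with
#'   `config`, `schedule`, `latents`, `node_labels` and `subjects` (each a
#'   list with `trials`, `bold`, `tacs`).
#' @export
simulate_cohort <- function(config = cohort_config(), out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  seed <- config$seed
  latents <- simulate_latents(config, spawn_seed(seed, 1L, "latents"))
  schedule <- make_block_schedule(config, spawn_seed(seed, 2L, "schedule"))
  labels <- node_labels(config)
  fs <- frame_schedule()
  subjects <- lapply(seq_len(config$n_subjects), function(i) {
    li <- latents[i, ]
    list(
      trials = simulate_trials(li, schedule, config,
                               spawn_seed(seed, i, "trials")),
      bold = simulate_bold(li, schedule, config,
                           spawn_seed(seed, i, "bold")),
      tacs = simulate_tacs(li, config, fs, spawn_seed(seed, i, "tacs"))
    )
  })
  names(subjects) <- latents$subject_id
  cohort <- structure(
    list(config = config, schedule = schedule, latents = latents,
         node_labels = labels, subjects = subjects),
    class = "cohort"
  )
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  invisible(cohort)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, %d nodes (%d DMN / %d TPN), %d volumes\n",
              x$config$n_subjects, x$config$n_nodes, x$config$n_dmn_nodes,
              x$config$n_nodes - x$config$n_dmn_nodes, x$config$n_volumes))
  cat(sprintf("Planted: dmn slope %.3f (sd %.3f), tpn slope %.3f, rho(BP, slope) %.2f\n",
              x$config$mean_dmn_slope, x$config$sd_dmn_slope,
              x$config$mean_tpn_slope, x$config$rho_bp_slope))
  invisible(x)
}

write_tsv <- function(df, path) {
  tryCatch(
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE),
    error = function(e) stopf("I/O failure writing %s: %s", path,
                              conditionMessage(e))
  )
}

#' Write a cohort to disk
#'
#' @param cohort a [simulate_cohort()] result.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(cohort$schedule, file.path(out_dir, "schedule.tsv"))
  write_tsv(cohort$node_labels, file.path(out_dir, "node_labels.tsv"))
  write_tsv(cohort$latents, file.path(out_dir, "latents.tsv"))
  files <- c("schedule.tsv", "node_labels.tsv", "latents.tsv")
  for (sid in names(cohort$subjects)) {
    sdir <- file.path(out_dir, sid)
    dir.create(sdir, showWarnings = FALSE)
    sub <- cohort$subjects[[sid]]
    ts <- as.data.frame(t(sub$bold$data))
    names(ts) <- sub$bold$node_ids
    write_tsv(ts, file.path(sdir, "timeseries.tsv"))
    write_tsv(sub$trials, file.path(sdir, "trials.tsv"))
    write_tsv(sub$tacs, file.path(sdir, "tacs.tsv"))
    files <- c(files, file.path(sid, c("timeseries.tsv", "trials.tsv",
                                       "tacs.tsv")))
  }
  manifest <- list(
    package = "dopaconn",
    seed = cohort$config$seed,
    n_subjects = cohort$config$n_subjects,
    subjects = names(cohort$subjects),
    config = unclass(cohort$config),
    planted = list(
      mean_dmn_slope = cohort$config$mean_dmn_slope,
      mean_tpn_slope = cohort$config$mean_tpn_slope,
      rho_bp_slope = cohort$config$rho_bp_slope,
      behav_slope_coupling = cohort$config$behav_slope_coupling,
      direct_bp_behaviour = cohort$config$direct_bp_behaviour
    ),
    files = files
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Read a cohort directory
#'
#' Reads a cohort previously written by [simulate_cohort()] /
#' [write_cohort()] back into the in-memory representation.
#'
#' @param dir cohort directory.
#' @return an object of class `cohort` (the `tacs` element is the framed
#'   TSV; latent BOLD objects are reconstructed with schedule and labels).
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cfg <- do.call(cohort_config, manifest$config[setdiff(
    names(manifest$config), character(0))])
  schedule <- read.delim(file.path(dir, "schedule.tsv"))
  labels <- read.delim(file.path(dir, "node_labels.tsv"))
  latents <- read.delim(file.path(dir, "latents.tsv"))
  subjects <- lapply(manifest$subjects, function(sid) {
    sdir <- file.path(dir, sid)
    ts <- as.matrix(read.delim(file.path(sdir, "timeseries.tsv"),
                               check.names = FALSE))
    bold <- structure(
      list(data = t(ts), node_ids = colnames(ts),
           labels = volume_labels(schedule, cfg), tr = cfg$tr,
           schedule = schedule),
      class = "parcel_ts"
    )
    list(trials = read.delim(file.path(sdir, "trials.tsv")),
         bold = bold,
         tacs = read.delim(file.path(sdir, "tacs.tsv")))
  })
  names(subjects) <- manifest$subjects
  structure(
    list(config = cfg, schedule = schedule, latents = latents,
         node_labels = labels, subjects = subjects),
    class = "cohort"
  )
}
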