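# Pipeline orchestration: simulate -> behaviour -> connectivity -> network
# detection -> PET fit -> statistics, with deterministic seed fan-out and a
# machine-readable report.

#' Simulate a cohort to disk
#'
#' Thin wrapper over [simulate_cohort()] that always writes the cohort
#' directory and manifest.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory.
#' @return the cohort, invisibly.
#' @export
run_simulate <- function(config = cohort_config(), out_dir) {
  simulate_cohort(config, out_dir = out_dir)
}

# Spearman helper returning a flat named list for the report.
sp_item <- function(x, y) {
  r <- spearman_ci(x, y)
  list(rho = r$rho, ci_low = r$ci_low, ci_high = r$ci_high, df = r$df,
       p = r$p)
}

#' Run the full analysis on a cohort
#'
#' Executes every stage of the analysis on a simulated (or re-read)
#' cohort: behavioural metrics (pRT at each penalization ratio, -dpRT,
#' d'), condition-wise Fisher-z connectivity with per-edge load regression
#' and network means, DMN/TPN detection (subject-level consensus Louvain
#' clustering of the 0-back matrix with negative weights zeroed, followed
#' by group consensus; or the a-priori labels), SRTM BP_ND fits, and the
#' inferential layer: group tests on w1, Spearman correlations of regional
#' BP_ND with network w1 and of dmn_w1 with -dpRT, Meng comparisons,
#' whole-session control correlations, block-wise within-subject
#' regression, and mediation (BP_ND -> dmn_w1 -> -dpRT) per region.
#'
#' @param cohort a `cohort` from [simulate_cohort()] or [read_cohort()].
#' @param ratios pRT penalization ratios (default `c(2.5, 3, 3.5, 4)`).
#' @param lag_volumes haemodynamic lag in volumes (default 2).
#' @param detection `"consensus"` for data-driven network detection or
#'   `"apriori"` to use the a-priori node labels directly.
#' @param n_iter,threshold,gamma,max_rounds consensus parameters.
#' @param n_boot mediation bootstrap draws (default 999).
#' @param seed master analysis seed (fans out to named sub-seeds for the
#'   Louvain and bootstrap stages).
#' @return object of class `analysis_report` (a nested list; see
#'   [write_report()]).
#' @export
run_analysis <- function(cohort, ratios = c(2.5, 3, 3.5, 4),
                         lag_volumes = 2L,
                         detection = c("consensus", "apriori"),
                         n_iter = 200L, threshold = 0.5, gamma = 1,
                         max_rounds = 50L, n_boot = 999L, seed = 1L) {
  detection <- match.arg(detection)
  t_start <- Sys.time()
  cfg <- cohort$config
  subj_ids <- names(cohort$subjects)

  # --- behaviour ---------------------------------------------------------
  trials <- do.call(rbind, lapply(cohort$subjects, `[[`, "trials"))
  behav <- behavior_summary(trials, ratios = ratios)
  r1lab <- sprintf("%g", ratios[1])
  prt_mat <- do.call(rbind, lapply(subj_ids, function(s) {
    b <- behav$by_load[behav$by_load$subject_id == s, ]
    b[[sprintf("prt_%s", r1lab)]][order(b$load)]
  }))
  neg_dprt <- behav$by_subject[[sprintf("neg_delta_prt_%s", r1lab)]]

  # --- connectivity ------------------------------------------------------
  zmats <- lapply(cohort$subjects, function(sub) {
    lapply(c("0", "1", "2"), function(cd) {
      condition_connectivity(sub$bold, cd, lag_volumes)
    })
  })

  # --- network detection -------------------------------------------------
  apriori <- cohort$node_labels
  if (detection == "consensus") {
    subj_parts <- lapply(seq_along(subj_ids), function(i) {
      g <- weighted_graph(zmats[[i]][[1]]$z,
                          node_ids = cohort$subjects[[i]]$bold$node_ids)
      consensus_partition(g, n_iter = n_iter, threshold = threshold,
                          gamma = gamma,
                          seed = spawn_seed(seed, i, "consensus"),
                          max_rounds = max_rounds)
    })
    grp <- group_consensus(subj_parts, n_iter = n_iter,
                           threshold = threshold, gamma = gamma,
                           seed = spawn_seed(seed, 0L, "group"),
                           max_rounds = max_rounds)
    networks <- label_networks(grp, apriori)
    detection_info <- list(
      method = "consensus", n_iter = n_iter, threshold = threshold,
      gamma = gamma, n_communities = length(unique(grp$membership)),
      Q = grp$Q, dsc_dmn = unname(attr(networks, "dsc")["dmn"]),
      dsc_tpn = unname(attr(networks, "dsc")["tpn"])
    )
  } else {
    networks <- ifelse(apriori$apriori_network == "DMN", "DMN", "TPN")
    names(networks) <- apriori$node_id
    detection_info <- list(method = "apriori")
  }

  # --- load regression and whole-session control -------------------------
  w1 <- do.call(rbind, lapply(seq_along(subj_ids), function(i) {
    lr <- edge_load_regression(zmats[[i]], networks)
    c(dmn = lr$dmn_w1, tpn = lr$tpn_w1, between = lr$between_w1)
  }))
  whole <- do.call(rbind, lapply(cohort$subjects, function(sub) {
    ws <- whole_session_connectivity(sub$bold, networks, lag_volumes)
    c(dmn = ws$dmn, tpn = ws$tpn, between = ws$between)
  }))

  # --- PET ---------------------------------------------------------------
  bp <- fit_cohort_bp(cohort)
  bp_wide <- lapply(c("caudate", "accumbens", "striatum", "snvta"),
                    function(rg) {
    bp$bp_nd[bp$region == rg][match(subj_ids,
                                    bp$subject_id[bp$region == rg])]
  })
  names(bp_wide) <- c("caudate", "accumbens", "striatum", "snvta")

  # --- inferential layer -------------------------------------------------
  w1_tests <- list(
    dmn = one_sample_t(w1[, "dmn"]),
    tpn = one_sample_t(w1[, "tpn"]),
    between = one_sample_t(w1[, "between"]),
    anova = rm_anova(w1),
    dmn_vs_tpn = paired_t(w1[, "dmn"], w1[, "tpn"])
  )
  bp_w1 <- lapply(bp_wide, function(v) {
    list(dmn = sp_item(v, w1[, "dmn"]),
         tpn = sp_item(v, w1[, "tpn"]),
         between = sp_item(v, w1[, "between"]))
  })
  meng <- list(
    caudate_vs_accumbens_dmn = meng_compare(
      spearman_ci(bp_wide$caudate, w1[, "dmn"])$rho,
      spearman_ci(bp_wide$accumbens, w1[, "dmn"])$rho,
      spearman_ci(bp_wide$caudate, bp_wide$accumbens)$rho,
      length(subj_ids)),
    caudate_vs_snvta_dmn = meng_compare(
      spearman_ci(bp_wide$caudate, w1[, "dmn"])$rho,
      spearman_ci(bp_wide$snvta, w1[, "dmn"])$rho,
      spearman_ci(bp_wide$caudate, bp_wide$snvta)$rho,
      length(subj_ids))
  )
  behav_corr <- lapply(ratios, function(r) {
    nd <- behav$by_subject[[sprintf("neg_delta_prt_%g", r)]]
    list(ratio = r, dmn_w1 = sp_item(w1[, "dmn"], nd),
         caudate_bp = sp_item(bp_wide$caudate, nd))
  })
  names(behav_corr) <- sprintf("ratio_%g", ratios)
  whole_session <- lapply(bp_wide, function(v) {
    list(dmn = sp_item(v, whole[, "dmn"]),
         tpn = sp_item(v, whole[, "tpn"]))
  })
  mediation <- lapply(names(bp_wide), function(rg) {
    m <- mediation_bootstrap(bp_wide[[rg]], w1[, "dmn"], neg_dprt,
                             n_boot = n_boot,
                             seed = spawn_seed(seed, 0L,
                                               paste0("boot_", rg)))
    list(region = rg, acme = m$acme, ade = m$ade, total = m$total)
  })
  names(mediation) <- names(bp_wide)

  # --- within-subject block regression -----------------------------------
  strengths <- lapply(cohort$subjects, function(sub) {
    blockwise_network_strength(sub$bold, networks, lag_volumes)
  })
  # block-wise pRT: the penalty baseline stays subject- and
  # condition-specific (mean correct RT over all same-load blocks), so a
  # block with few or no correct trials is still well-defined
  block_prt <- lapply(subj_ids, function(s) {
    tt <- cohort$subjects[[s]]$trials
    ok <- (tt$target == 1 & tt$response == "target") |
      (tt$target == 0 & tt$response == "non-target")
    base <- tapply(tt$rt[ok], tt$load[ok], mean)
    contrib <- ifelse(ok, tt$rt, ratios[1] * base[as.character(tt$load)])
    as.numeric(tapply(contrib, tt$block, mean))
  })
  block_load <- cohort$schedule$load[order(cohort$schedule$block)]
  ws_fit <- within_subject_regression(block_prt, strengths, block_load)

  # --- behaviour-by-load ANOVA ------------------------------------------
  behav_anova <- rm_anova(prt_mat)

  report <- structure(list(
    meta = list(
      package_version = as.character(packageVersion("dopaconn")),
      seed = seed, cohort_seed = cfg$seed,
      config_hash = config_hash(cfg),
      n_subjects = length(subj_ids), ratios = ratios,
      lag_volumes = lag_volumes, n_boot = n_boot,
      wall_clock_s = as.numeric(difftime(Sys.time(), t_start,
                                         units = "secs"))
    ),
    detection = detection_info,
    behaviour = list(
      prt_by_load_mean = colMeans(prt_mat),
      anova_load = behav_anova,
      mean_neg_delta_prt = mean(neg_dprt)
    ),
    w1 = list(
      group_mean = list(dmn = mean(w1[, "dmn"]), tpn = mean(w1[, "tpn"]),
                        between = mean(w1[, "between"])),
      tests = w1_tests
    ),
    bp_vs_w1 = bp_w1,
    meng = meng,
    behaviour_correlations = behav_corr,
    whole_session_controls = whole_session,
    mediation = mediation,
    within_subject = list(
      group_simple = ws_fit$group$simple,
      group_adjusted = ws_fit$group$adjusted
    )
  ), class = "analysis_report")
  attr(report, "subject_tables") <- list(
    w1 = w1, whole = whole, bp = bp_wide, neg_delta_prt = neg_dprt,
    behaviour = behav
  )
  report
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Analysis report\n")
  cat(sprintf("  subjects: %d, analysis seed %s, config %s\n",
              x$meta$n_subjects, x$meta$seed,
              substr(x$meta$config_hash, 1, 8)))
  cat(sprintf("  group w1: DMN %.4f (t = %.2f, p = %.3g), TPN %.4f (t = %.2f, p = %.3g)\n",
              x$w1$group_mean$dmn, x$w1$tests$dmn$t, x$w1$tests$dmn$p,
              x$w1$group_mean$tpn, x$w1$tests$tpn$t, x$w1$tests$tpn$p))
  cat(sprintf("  rho(caudate BP, dmn w1) = %.3f (p = %.3g)\n",
              x$bp_vs_w1$caudate$dmn$rho, x$bp_vs_w1$caudate$dmn$p))
  b <- x$behaviour_correlations[[1]]
  cat(sprintf("  rho(dmn w1, -dpRT(%g)) = %.3f (p = %.3g)\n",
              b$ratio, b$dmn_w1$rho, b$dmn_w1$p))
  m <- x$mediation$caudate
  cat(sprintf("  caudate ACME = %.4f [%.4f, %.4f], p = %.3g\n",
              m$acme$est, m$acme$ci_low, m$acme$ci_high, m$acme$p))
  invisible(x)
}

#' Write an analysis report
#'
#' Serialises the report to JSON (all numeric fields, deterministic
#' ordering) and/or a human-readable markdown summary that embeds the same
#' JSON in a fenced block, so a json -> markdown -> json round trip
#' preserves every numeric field.
#'
#' @param report an `analysis_report`.
#' @param path output file path (extension added per format).
#' @param format `"json"`, `"markdown"`, or both.
#' @return named character vector of the files written.
#' @export
write_report <- function(report, path, format = c("json", "markdown")) {
  stopifnot(inherits(report, "analysis_report"))
  if (length(report) == 0L || is.null(report$meta)) {
    stopf("refusing to write an empty report")
  }
  format <- match.arg(format, several.ok = TRUE)
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
  out <- character(0)
  if ("json" %in% format) {
    f <- paste0(path, ".json")
    writeLines(json, f)
    out["json"] <- f
  }
  if ("markdown" %in% format) {
    f <- paste0(path, ".md")
    lines <- c(
      "# Analysis report",
      "",
      sprintf("- subjects: %d", report$meta$n_subjects),
      sprintf("- analysis seed: %s", report$meta$seed),
      sprintf("- config hash: %s", report$meta$config_hash),
      sprintf("- group mean w1: DMN %.4f, TPN %.4f",
              report$w1$group_mean$dmn, report$w1$group_mean$tpn),
      sprintf("- rho(caudate BP_ND, DMN w1) = %.3f (p = %.3g)",
              report$bp_vs_w1$caudate$dmn$rho,
              report$bp_vs_w1$caudate$dmn$p),
      sprintf("- caudate ACME = %.4f (p = %.3g)",
              report$mediation$caudate$acme$est,
              report$mediation$caudate$acme$p),
      "",
      "## Full report (JSON)",
      "",
      "```json",
      strsplit(as.character(json), "\n")[[1]],
      "```"
    )
    writeLines(lines, f)
    out["markdown"] <- f
  }
  out
}

#' Read the JSON block back out of a markdown report
#'
#' @param path a markdown report written by [write_report()].
#' @return the parsed report list.
#' @export
read_report_md <- function(path) {
  lines <- readLines(path)
  open <- which(lines == "```json")[1]
  close <- which(lines == "```")
  close <- close[close > open][1]
  jsonlite::fromJSON(paste(lines[(open + 1):(close - 1)], collapse = "\n"),
                     simplifyVector = TRUE)
}
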