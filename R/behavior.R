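# Behavioural performance metrics for the n-back task: proportional
# penalized reaction time (pRT), load-robustness slope (-dpRT), and the
# discriminability index d' with perfect-score adjustment.

check_trials <- function(trials) {
  need <- c("subject_id", "load", "target", "response", "rt")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stopf("trial table lacks columns: %s",
                          paste(miss, collapse = ", "))
  invisible(trials)
}

# A trial is correct iff the response matches the target flag and is not
# omitted.
trial_correct <- function(trials) {
  (trials$target == 1 & trials$response == "target") |
    (trials$target == 0 & trials$response == "non-target")
}

#' Proportional penalized reaction time
#'
#' For each subject-by-load cell, incorrect or omitted trials are assigned
#' a penalty reaction time equal to `ratio` times the cell's mean correct
#' RT (the subject- and condition-specific baseline); correct trials
#' contribute their own RT. pRT is the mean over all trials of the cell.
#' With no errors, pRT equals the mean RT and is independent of the ratio.
#'
#' @param trials trial table (columns subject_id, load, target, response,
#'   rt).
#' @param ratio penalization ratio, >= 1 (the emulated analysis uses 2.5 to
#'   4).
#' @return data frame with columns `subject_id`, `load`, `prt`,
#'   `n_trials`, `n_correct`.
#' @export
penalized_rt <- function(trials, ratio = 2.5) {
  check_trials(trials)
  if (ratio < 1) stopf("penalization ratio must be >= 1")
  ok <- trial_correct(trials)
  key <- interaction(trials$subject_id, trials$load, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(trials)), key), function(idx) {
    cell <- trials[idx, ]
    correct <- ok[idx]
    if (!any(correct)) {
      stopf("pRT undefined: no correct trials for subject %s at load %s",
            cell$subject_id[1], cell$load[1])
    }
    baseline <- mean(cell$rt[correct])
    contrib <- ifelse(correct, cell$rt, ratio * baseline)
    data.frame(subject_id = cell$subject_id[1], load = cell$load[1],
               prt = mean(contrib), n_trials = nrow(cell),
               n_correct = sum(correct), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$subject_id, out$load), ]
  rownames(out) <- NULL
  out
}

#' Load-robustness slope of performance
#'
#' Ordinary least squares of pRT on working memory load (0, 1, 2). The
#' slope dpRT quantifies performance degradation per load level; the
#' negated slope -dpRT is the "robustness" measure: 0 means performance is
#' unaffected by load, increasingly negative values mean performance
#' degrades with increasing cognitive demands.
#'
#' @param prt_by_load data frame with columns `load` (exactly 0, 1, 2) and
#'   `prt`, for one subject.
#' @return list with `delta_prt` (the OLS slope), `neg_delta_prt` and the
#'   intercept.
#' @export
performance_slope <- function(prt_by_load) {
  if (!setequal(prt_by_load$load, 0:2) || nrow(prt_by_load) != 3L) {
    stopf("performance_slope needs exactly loads 0, 1 and 2")
  }
  o <- order(prt_by_load$load)
  y <- prt_by_load$prt[o]
  slope <- (y[3] - y[1]) / 2 # OLS slope on equally spaced loads 0,1,2
  list(delta_prt = slope, neg_delta_prt = -slope,
       intercept = mean(y) - slope)
}

#' Discriminability index d' with perfect-score adjustment
#'
#' For each subject-by-load cell, the hit rate is the proportion of targets
#' answered "target" and the false-alarm rate the proportion of non-targets
#' answered "target" (omissions count as non-"target" answers). Perfect
#' rates are adjusted before the Gaussian quantile: a rate of 1 becomes
#' `1 - 1/(2n)` and a rate of 0 becomes `1/(2n)`, where n is the count of
#' targets (for hits) or non-targets (for false alarms) over the entire
#' task (`scope = "whole-task"`, the default) or within the load level
#' (`scope = "per-load"`). d' = Z(hit) - Z(fa).
#'
#' @param trials trial table.
#' @param scope adjustment denominator scope: `"whole-task"` or
#'   `"per-load"`.
#' @return data frame with columns `subject_id`, `load`, `hit_rate`,
#'   `fa_rate` (adjusted), `dprime`.
#' @export
dprime <- function(trials, scope = c("whole-task", "per-load")) {
  check_trials(trials)
  scope <- match.arg(scope)
  adjust <- function(rate, n) {
    if (n == 0L) stopf("d' undefined: empty target or non-target set")
    if (rate >= 1) rate <- 1 - 1 / (2 * n)
    if (rate <= 0) rate <- 1 / (2 * n)
    rate
  }
  rows <- lapply(split(trials, trials$subject_id), function(tt) {
    n_t_task <- sum(tt$target == 1)
    n_n_task <- sum(tt$target == 0)
    do.call(rbind, lapply(sort(unique(tt$load)), function(L) {
      cell <- tt[tt$load == L, ]
      n_t <- sum(cell$target == 1)
      n_n <- sum(cell$target == 0)
      if (n_t == 0L || n_n == 0L) {
        stopf("d' undefined for subject %s load %s: no %s trials",
              cell$subject_id[1], L,
              if (n_t == 0L) "target" else "non-target")
      }
      hit <- sum(cell$target == 1 & cell$response == "target") / n_t
      fa <- sum(cell$target == 0 & cell$response == "target") / n_n
      if (scope == "whole-task") {
        hit <- adjust(hit, n_t_task)
        fa <- adjust(fa, n_n_task)
      } else {
        hit <- adjust(hit, n_t)
        fa <- adjust(fa, n_n)
      }
      data.frame(subject_id = cell$subject_id[1], load = L,
                 hit_rate = hit, fa_rate = fa,
                 dprime = qnorm(hit) - qnorm(fa),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-subject behavioural summary
#'
#' Combines [penalized_rt()], [performance_slope()] and [dprime()] into one
#' long table: one row per subject and load with pRT (at each requested
#' ratio) and d', plus the subject-level -dpRT per ratio and the d' load
#' slope.
#'
#' @param trials trial table.
#' @param ratios penalization ratios (default `c(2.5, 3, 3.5, 4)`).
#' @return list with `by_load` (subject x load table) and `by_subject`
#'   (one row per subject: `neg_delta_prt_<ratio>` columns and
#'   `dprime_slope`).
#' @export
behavior_summary <- function(trials, ratios = c(2.5, 3, 3.5, 4)) {
  check_trials(trials)
  dp <- dprime(trials)
  prts <- lapply(ratios, function(r) penalized_rt(trials, r))
  by_load <- dp[, c("subject_id", "load", "dprime")]
  for (k in seq_along(ratios)) {
    col <- sprintf("prt_%g", ratios[k])
    by_load[[col]] <- prts[[k]]$prt[match(
      interaction(by_load$subject_id, by_load$load),
      interaction(prts[[k]]$subject_id, prts[[k]]$load))]
  }
  subj <- sort(unique(trials$subject_id))
  by_subject <- data.frame(subject_id = subj, stringsAsFactors = FALSE)
  for (k in seq_along(ratios)) {
    col <- sprintf("neg_delta_prt_%g", ratios[k])
    by_subject[[col]] <- vapply(subj, function(s) {
      cell <- prts[[k]][prts[[k]]$subject_id == s, ]
      performance_slope(cell)$neg_delta_prt
    }, numeric(1))
  }
  by_subject$dprime_slope <- vapply(subj, function(s) {
    cell <- dp[dp$subject_id == s, ]
    o <- order(cell$load)
    (cell$dprime[o][3] - cell$dprime[o][1]) / 2
  }, numeric(1))
  list(by_load = by_load, by_subject = by_subject)
}
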