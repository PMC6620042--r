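# Simplified reference tissue model (SRTM): forward simulation of regional
# time-activity curves and basis-function fitting of (R1, k2, BP_ND).
#
# Operational model: C_T(t) = R1 * C_R(t) + (k2 - R1*k2a) * (C_R (x) exp(-k2a t)),
# with k2a = k2 / (1 + BP_ND). The convolution is evaluated on a fine time
# grid by an exact-exponential recursion and then averaged over each frame
# window.

#' PET frame schedule
#'
#' Frame start times and durations. The default is the 31-frame schedule of
#' a 90-min acquisition: 8 x 15 s, 3 x 60 s, 5 x 120 s, 15 x 300 s.
#'
#' @param durations frame durations in seconds.
#' @return data frame with columns `frame_start_s`, `frame_dur_s`.
#' @export
frame_schedule <- function(durations = c(rep(15, 8), rep(60, 3),
                                         rep(120, 5), rep(300, 15))) {
  if (any(durations <= 0)) stopf("frame durations must be positive")
  data.frame(frame_start_s = cumsum(c(0, durations[-length(durations)])),
             frame_dur_s = durations)
}

#' Biexponential reference-region input curve
#'
#' A conventional cerebellar reference time-activity curve,
#' `a * (exp(-l1 t) - exp(-l2 t))`, shaped to peak at about 5 minutes.
#' Rate constants are arbitrary simulation choices, not study values.
#'
#' @param t_end end of the sampling window, seconds.
#' @param dt fine-grid step, seconds (must be <= 1 s for convolution
#'   accuracy downstream).
#' @param peak_amp peak activity (arbitrary kBq/mL calibration).
#' @param l1,l2 washout/uptake rate constants, 1/min.
#' @return list with `t` (seconds) and `c` (activity), class `fine_tac`.
#' @export
reference_tac <- function(t_end = 5400, dt = 1, peak_amp = 30,
                          l1 = 0.08, l2 = 0.6) {
  t <- seq(0, t_end, by = dt)
  tm <- t / 60
  c_raw <- exp(-l1 * tm) - exp(-l2 * tm)
  structure(list(t = t, c = peak_amp * c_raw / max(c_raw)),
            class = "fine_tac")
}

# Exact-exponential convolution of a finely sampled curve with
# exp(-k2a * t) (k2a in 1/min, t in seconds), trapezoidal within steps.
# Requires a uniform grid; the recursion runs at C speed via
# stats::filter(method = "recursive").
conv_exp <- function(t, c, k2a_per_min) {
  dt <- t[2] - t[1]
  k <- k2a_per_min / 60
  e <- exp(-k * dt)
  n <- length(t)
  b <- dt * 0.5 * (c + c(0, c[-n]) * e)
  b[1] <- 0
  as.numeric(stats::filter(b, e, method = "recursive"))
}

# Precomputed sample-to-frame grouping for fast repeated frame averaging.
frame_groups <- function(t, schedule) {
  lapply(seq_len(nrow(schedule)), function(f) {
    which(t >= schedule$frame_start_s[f] &
            t < schedule$frame_start_s[f] + schedule$frame_dur_s[f])
  })
}

fa_groups <- function(x, groups) {
  vapply(groups, function(i) mean(x[i]), numeric(1))
}

#' Frame-average a finely sampled curve
#'
#' Mean of the fine-grid samples falling inside each frame window.
#'
#' @param t sample times, seconds.
#' @param x sample values.
#' @param schedule a [frame_schedule()].
#' @return numeric vector, one value per frame.
#' @export
frame_average <- function(t, x, schedule) {
  fa_groups(x, frame_groups(t, schedule))
}

#' SRTM forward model
#'
#' Generates a target-region TAC from a finely sampled reference curve and
#' kinetic parameters, frame-averaged over the schedule. With `r1 = 1` and
#' `bp = 0` the target equals the reference exactly.
#'
#' @param ref a `fine_tac` from [reference_tac()] (sampling step must be
#'   <= 1 s).
#' @param r1 delivery ratio K1/K1' (unitless).
#' @param k2 reference-region efflux constant, 1/min (> 0).
#' @param bp non-displaceable binding potential BP_ND (> -1).
#' @param schedule a [frame_schedule()].
#' @return numeric vector of frame-averaged target activities.
#' @export
srtm_forward <- function(ref, r1, k2, bp, schedule) {
  if (!inherits(ref, "fine_tac")) stopf("ref must be a fine_tac")
  if (max(diff(ref$t)) > 1 + 1e-9) {
    stopf("reference TAC must be sampled at <= 1 s resolution")
  }
  if (bp <= -1) stopf("BP_ND must exceed -1")
  if (k2 <= 0) stopf("k2 must be positive")
  if (max(ref$t) + 1e-9 <
      max(schedule$frame_start_s + schedule$frame_dur_s)) {
    stopf("reference TAC does not cover the frame schedule")
  }
  k2a <- k2 / (1 + bp)
  ct <- r1 * ref$c + (k2 - r1 * k2a) / 60 * conv_exp(ref$t, ref$c, k2a)
  frame_average(ref$t, ct, schedule)
}

# Weighted linear fit of target ~ r1*ref + phi*basis for one k2a value.
srtm_basis_fit <- function(target, ref_f, basis_f, wts) {
  X <- cbind(ref_f, basis_f)
  XtW <- t(X * wts)
  fit <- tryCatch(solve(XtW %*% X, XtW %*% target),
                  error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  resid <- target - X %*% fit
  list(theta = drop(fit), rss = sum(wts * resid^2))
}

#' Basis-function SRTM fit
#'
#' Fits the SRTM to a frame-averaged target TAC: for each k2a value on a
#' log-spaced grid the convolution basis `C_R (x) exp(-k2a t)` is computed
#' once and (R1, k2 - R1*k2a) obtained by weighted linear least squares
#' (weights proportional to frame duration); the basis with the smallest
#' weighted residual is selected and refined by a local 1-D optimisation
#' of k2a. BP_ND = k2/k2a - 1.
#'
#' @param target numeric vector of frame-averaged target activities.
#' @param ref reference curve: either a `fine_tac` or a numeric vector of
#'   frame-averaged reference activities (then upsampled to a 1-s grid by
#'   monotone-safe linear interpolation of frame midpoints).
#' @param schedule a [frame_schedule()] (>= 10 frames).
#' @param k2a_grid basis k2a values, 1/min (default 100 log-spaced in
#'   `[0.001, 1]`).
#' @param refine locally optimise k2a around the best grid point (default
#'   TRUE).
#' @param basis optional precomputed [srtm_basis()] (shared across fits
#'   with a common reference and schedule; `ref` and `k2a_grid` are then
#'   ignored).
#' @return object of class `srtm_fit` with elements `r1`, `k2`, `k2a`,
#'   `bp_nd`, `rss`, `converged`, `fitted`, and the residual vector.
#' @export
srtm_fit <- function(target, ref, schedule,
                     k2a_grid = exp(seq(log(0.001), log(1),
                                        length.out = 100)),
                     refine = TRUE, basis = NULL) {
  if (nrow(schedule) < 10L) stopf("SRTM fit needs >= 10 frames")
  if (length(target) != nrow(schedule)) {
    stopf("target TAC length does not match frame schedule")
  }
  if (is.null(basis)) basis <- srtm_basis(ref, schedule, k2a_grid)
  wts <- schedule$frame_dur_s / sum(schedule$frame_dur_s)
  ref_f <- basis$ref_f
  k2a_grid <- basis$k2a_grid
  eval_basis <- function(basis_f) srtm_basis_fit(target, ref_f, basis_f, wts)
  eval_k2a <- function(k2a) {
    eval_basis(fa_groups(conv_exp(basis$ref$t, basis$ref$c, k2a) / 60,
                         basis$groups))
  }
  fits <- lapply(seq_along(k2a_grid),
                 function(j) eval_basis(basis$B[, j]))
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stopf("SRTM fit failed: all basis fits singular")
  rss <- rep(Inf, length(fits))
  rss[ok] <- vapply(fits[ok], `[[`, numeric(1), "rss")
  best <- which.min(rss)
  k2a <- k2a_grid[best]
  best_fit <- fits[[best]]
  if (refine) {
    lo <- k2a_grid[max(1L, best - 1L)]
    hi <- k2a_grid[min(length(k2a_grid), best + 1L)]
    opt <- optimize(function(lk) {
      f <- eval_k2a(exp(lk))
      if (is.null(f)) Inf else f$rss
    }, lower = log(lo), upper = log(hi), tol = 1e-8)
    if (is.finite(opt$objective) && opt$objective < rss[best]) {
      k2a <- exp(opt$minimum)
      best_fit <- eval_k2a(k2a)
    }
  }
  r1 <- best_fit$theta[1]
  k2 <- best_fit$theta[2] + r1 * k2a
  basis_f <- fa_groups(conv_exp(basis$ref$t, basis$ref$c, k2a) / 60,
                       basis$groups)
  fitted <- r1 * ref_f + best_fit$theta[2] * basis_f
  structure(
    list(r1 = r1, k2 = k2, k2a = k2a, bp_nd = k2 / k2a - 1,
         rss = best_fit$rss, converged = TRUE, fitted = fitted,
         residuals = target - fitted, grid_rss = rss, weights = wts),
    class = "srtm_fit"
  )
}

#' Precompute the SRTM basis set
#'
#' Computes, once, the frame-averaged convolution bases
#' `C_R (x) exp(-k2a t)` for every k2a on the grid, for reuse across many
#' [srtm_fit()] calls that share a reference curve and schedule.
#'
#' @inheritParams srtm_fit
#' @param ref a `fine_tac`, or framed reference activities (upsampled to a
#'   1-s grid by linear interpolation of frame midpoints).
#' @return list with the fine `ref`, `ref_f`, frame `groups`, `k2a_grid`
#'   and basis matrix `B` (frames x grid).
#' @export
srtm_basis <- function(ref, schedule,
                       k2a_grid = exp(seq(log(0.001), log(1),
                                          length.out = 100))) {
  if (!inherits(ref, "fine_tac")) {
    if (length(ref) != nrow(schedule)) {
      stopf("framed reference TAC length does not match schedule")
    }
    if (any(ref < 0) || max(ref) <= 0) {
      stopf("reference activity must be positive")
    }
    mid <- schedule$frame_start_s + schedule$frame_dur_s / 2
    tend <- max(schedule$frame_start_s + schedule$frame_dur_s)
    tg <- seq(0, tend, by = 1)
    ref <- structure(
      list(t = tg, c = approx(c(0, mid), c(0, ref), xout = tg,
                              rule = 2)$y),
      class = "fine_tac"
    )
  }
  groups <- frame_groups(ref$t, schedule)
  B <- vapply(k2a_grid, function(k2a) {
    fa_groups(conv_exp(ref$t, ref$c, k2a) / 60, groups)
  }, numeric(nrow(schedule)))
  list(ref = ref, ref_f = fa_groups(ref$c, groups), groups = groups,
       k2a_grid = k2a_grid, B = B)
}

#' @export
print.srtm_fit <- function(x, ...) {
  cat(sprintf("SRTM fit: BP_ND = %.3f, R1 = %.3f, k2 = %.3f /min (k2a = %.4f, wRSS = %.3g)\n",
              x$bp_nd, x$r1, x$k2, x$k2a, x$rss))
  invisible(x)
}

#' @export
coef.srtm_fit <- function(object, ...) {
  c(r1 = object$r1, k2 = object$k2, bp_nd = object$bp_nd)
}

#' Simulate regional time-activity curves for one subject
#'
#' Generates framed TACs for the caudate, putamen, accumbens and SN/VTA
#' from the SRTM forward model using the subject's latent BP_ND values,
#' with per-region delivery `R1 ~ N(0.9, 0.05)` and
#' `k2 ~ N(0.35, 0.03) /min`, plus Gaussian frame noise whose variance
#' scales inversely with frame duration.
#'
#' @param latents one row of [simulate_latents()].
#' @param config a [cohort_config()].
#' @param schedule a [frame_schedule()].
#' @param seed integer seed.
#' @return data frame: `frame_start_s`, `frame_dur_s`, `ref_activity`, one
#'   activity column per region.
#' @export
simulate_tacs <- function(latents, config, schedule = frame_schedule(),
                          seed = 1L) {
  ref <- reference_tac()
  regions <- c(caudate = latents$bp_caudate %||% 2,
               putamen = latents$bp_putamen %||% 2.5,
               accumbens = latents$bp_accumbens %||% 3,
               snvta = latents$bp_snvta %||% 1.8)
  out <- data.frame(frame_start_s = schedule$frame_start_s,
                    frame_dur_s = schedule$frame_dur_s,
                    ref_activity = frame_average(ref$t, ref$c, schedule))
  with_seed(seed, {
    for (rg in names(regions)) {
      r1 <- rnorm(1, 0.9, 0.05)
      k2 <- rnorm(1, 0.35, 0.03)
      ct <- srtm_forward(ref, r1, k2, regions[[rg]], schedule)
      noise_sd <- config$tac_noise_frac * max(ct) *
        sqrt(300 / schedule$frame_dur_s)
      out[[rg]] <- ct + rnorm(nrow(schedule), 0, noise_sd)
    }
  })
  out
}

#' Fit BP_ND for every subject and region of a cohort
#'
#' Runs [srtm_fit()] on each subject's framed TACs (caudate, putamen,
#' accumbens, SN/VTA) against the framed reference activity, and derives a
#' whole-striatum BP_ND as the volume-weighted mean of the caudate,
#' putamen and accumbens fits (weights 0.38/0.48/0.14).
#'
#' @param cohort a [simulate_cohort()] result (or [read_cohort()]).
#' @return data frame: subject, region, bp_nd, r1, k2, converged.
#' @export
fit_cohort_bp <- function(cohort) {
  fs_cols <- c("frame_start_s", "frame_dur_s", "ref_activity")
  basis <- NULL
  basis_key <- NULL
  rows <- lapply(names(cohort$subjects), function(sid) {
    tacs <- cohort$subjects[[sid]]$tacs
    schedule <- tacs[, c("frame_start_s", "frame_dur_s")]
    regions <- setdiff(names(tacs), fs_cols)
    key <- c(tacs$ref_activity, schedule$frame_start_s)
    if (is.null(basis_key) || !isTRUE(all.equal(basis_key, key))) {
      basis <<- srtm_basis(tacs$ref_activity, schedule)
      basis_key <<- key
    }
    fits <- lapply(regions, function(rg) {
      srtm_fit(tacs[[rg]], tacs$ref_activity, schedule, basis = basis)
    })
    names(fits) <- regions
    df <- data.frame(
      subject_id = sid, region = regions,
      bp_nd = vapply(fits, `[[`, numeric(1), "bp_nd"),
      r1 = vapply(fits, `[[`, numeric(1), "r1"),
      k2 = vapply(fits, `[[`, numeric(1), "k2"),
      converged = vapply(fits, `[[`, logical(1), "converged"),
      stringsAsFactors = FALSE
    )
    if (all(c("caudate", "putamen", "accumbens") %in% regions)) {
      wts <- c(caudate = 0.38, putamen = 0.48, accumbens = 0.14)
      bp_str <- sum(wts * df$bp_nd[match(names(wts), df$region)])
      df <- rbind(df, data.frame(
        subject_id = sid, region = "striatum", bp_nd = bp_str,
        r1 = NA_real_, k2 = NA_real_, converged = TRUE,
        stringsAsFactors = FALSE
      ))
    }
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
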