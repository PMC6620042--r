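# Condition-wise and block-wise Fisher-z functional connectivity,
# per-edge load regression (zFC = w0 + w1 * load) and network-level
# summaries.

# Volume indices of one block window, shifted forward by `lag_volumes`
# (default 2 volumes = 4 s) to account for haemodynamic delay.
block_volumes <- function(onset, duration, tr, n_volumes, lag_volumes) {
  first <- floor(onset / tr) + 1L + lag_volumes
  len <- floor(duration / tr)
  idx <- first:(first + len - 1L)
  idx[idx >= 1L & idx <= n_volumes]
}

# Fisher-z correlation matrix of a nodes x samples matrix, with constant
# node detection and a clamped atanh.
zcor <- function(X, node_ids) {
  sds <- apply(X, 1, sd)
  if (any(sds == 0)) {
    stopf("constant signal in node(s): %s",
          paste(node_ids[sds == 0], collapse = ", "))
  }
  Z <- fisher_z(cor(t(X)))
  diag(Z) <- NA_real_
  Z
}

#' Condition-wise Fisher-z connectivity
#'
#' Concatenates the samples of all blocks of one task condition (each block
#' window shifted forward by `lag_volumes` volumes), computes the Pearson
#' correlation for every node pair, and Fisher z-transforms it (clamped at
#' +/-(1-1e-12) so perfect correlations stay finite).
#'
#' @param ts a `parcel_ts` (see [simulate_bold()]).
#' @param condition load label: `"0"`, `"1"` or `"2"` (or numeric).
#' @param lag_volumes haemodynamic lag in volumes (default 2 = 4 s at
#'   TR 2 s).
#' @return object of class `edge_matrix`: list with `z` (symmetric matrix,
#'   NA diagonal), `condition`, `n` (samples used) and `node_ids`.
#' @export
condition_connectivity <- function(ts, condition, lag_volumes = 2L) {
  stopifnot(inherits(ts, "parcel_ts"))
  condition <- as.character(condition)
  sched <- ts$schedule[as.character(ts$schedule$load) == condition, ]
  if (nrow(sched) == 0L) stopf("condition '%s' not present", condition)
  idx <- unlist(lapply(seq_len(nrow(sched)), function(b) {
    block_volumes(sched$onset[b], sched$duration[b], ts$tr,
                  ncol(ts$data), lag_volumes)
  }))
  if (length(idx) < 10L) {
    stopf("condition '%s': only %d usable samples after lag shift",
          condition, length(idx))
  }
  structure(
    list(z = zcor(ts$data[, idx, drop = FALSE], ts$node_ids),
         condition = condition, n = length(idx), node_ids = ts$node_ids),
    class = "edge_matrix"
  )
}

#' @export
print.edge_matrix <- function(x, ...) {
  cat(sprintf("Fisher-z edge matrix: %d nodes, condition '%s', %d samples\n",
              length(x$node_ids), x$condition, x$n))
  invisible(x)
}

#' Whole-session network connectivity
#'
#' Pools the samples of all task blocks (every non-rest condition, each
#' block shifted by the haemodynamic lag) into a single correlation
#' estimate and returns the mean Fisher z over within-DMN, within-TPN and
#' between-network edges. This is the control analysis contrasting
#' load-*dependent* connectivity change with connectivity averaged over the
#' whole task session.
#'
#' @param ts a `parcel_ts`.
#' @param networks character vector, one of `"DMN"`/`"TPN"` per node.
#' @param lag_volumes haemodynamic lag in volumes.
#' @return list with `dmn`, `tpn`, `between` mean z and `n` samples.
#' @export
whole_session_connectivity <- function(ts, networks, lag_volumes = 2L) {
  stopifnot(inherits(ts, "parcel_ts"))
  sched <- ts$schedule
  if (nrow(sched) == 0L) stopf("no task blocks in schedule")
  idx <- unlist(lapply(seq_len(nrow(sched)), function(b) {
    block_volumes(sched$onset[b], sched$duration[b], ts$tr,
                  ncol(ts$data), lag_volumes)
  }))
  Z <- zcor(ts$data[, idx, drop = FALSE], ts$node_ids)
  means <- network_edge_means(Z, networks)
  c(means, list(n = length(idx)))
}

# Masks of the three edge sets (upper triangle only).
edge_masks <- function(networks) {
  dmn <- networks == "DMN"
  up <- upper.tri(diag(length(networks)))
  list(
    dmn = up & outer(dmn, dmn, "&"),
    tpn = up & outer(!dmn, !dmn, "&"),
    between = up & (outer(dmn, !dmn, "&") | outer(!dmn, dmn, "&"))
  )
}

network_edge_means <- function(M, networks) {
  m <- edge_masks(networks)
  list(dmn = mean(M[m$dmn]), tpn = mean(M[m$tpn]),
       between = mean(M[m$between]))
}

#' Per-edge load regression of connectivity
#'
#' Fits, for every edge, the linear model zFC = w0 + w1 * load over the
#' three load conditions (load coded 0/1/2, so w0 is the fitted 0-back
#' value), and summarises w1 as its arithmetic mean over the within-DMN,
#' within-TPN and between-network edge sets.
#'
#' @param z_by_condition list of three `edge_matrix` objects for loads 0,
#'   1, 2 (any order; matched by their `condition` field).
#' @param networks character vector of `"DMN"`/`"TPN"` per node; if `NULL`
#'   network means are omitted.
#' @return object of class `load_regression`: list with matrices `w0`,
#'   `w1` and scalars `dmn_w1`, `tpn_w1`, `between_w1`.
#' @export
edge_load_regression <- function(z_by_condition, networks = NULL) {
  conds <- vapply(z_by_condition, function(e) e$condition, character(1))
  if (!setequal(conds, c("0", "1", "2"))) {
    stopf("edge_load_regression needs all three load conditions, got: %s",
          paste(conds, collapse = ", "))
  }
  z0 <- z_by_condition[[which(conds == "0")]]$z
  z1 <- z_by_condition[[which(conds == "1")]]$z
  z2 <- z_by_condition[[which(conds == "2")]]$z
  w1 <- (z2 - z0) / 2 # OLS slope on loads 0,1,2
  w0 <- (z0 + z1 + z2) / 3 - w1
  out <- list(w0 = w0, w1 = w1,
              node_ids = z_by_condition[[1]]$node_ids)
  if (!is.null(networks)) {
    means <- network_edge_means(w1, networks)
    out$dmn_w1 <- means$dmn
    out$tpn_w1 <- means$tpn
    out$between_w1 <- means$between
  }
  structure(out, class = "load_regression")
}

#' @export
print.load_regression <- function(x, ...) {
  cat("Per-edge load regression (zFC = w0 + w1 * load)\n")
  if (!is.null(x$dmn_w1)) {
    cat(sprintf("  mean w1: DMN %.4f, TPN %.4f, DMN-TPN %.4f\n",
                x$dmn_w1, x$tpn_w1, x$between_w1))
  }
  invisible(x)
}

#' Block-wise DMN connectivity strength
#'
#' Estimates a separate correlation matrix from each task block's samples
#' only (after the haemodynamic lag shift) and returns the mean Fisher z
#' over within-DMN edges, one value per block. This feeds the
#' within-subject regression of block-specific performance on
#' block-specific DMN strength.
#'
#' @param ts a `parcel_ts`.
#' @param networks character vector of `"DMN"`/`"TPN"` per node.
#' @param lag_volumes haemodynamic lag in volumes.
#' @return numeric vector, one DMN strength per task block (length 18
#'   under the default design).
#' @export
blockwise_network_strength <- function(ts, networks, lag_volumes = 2L) {
  stopifnot(inherits(ts, "parcel_ts"))
  m <- edge_masks(networks)
  vapply(seq_len(nrow(ts$schedule)), function(b) {
    idx <- block_volumes(ts$schedule$onset[b], ts$schedule$duration[b],
                         ts$tr, ncol(ts$data), lag_volumes)
    if (length(idx) < 8L) {
      stopf("block %d provides only %d samples (< 8)", b, length(idx))
    }
    Z <- zcor(ts$data[, idx, drop = FALSE], ts$node_ids)
    mean(Z[m$dmn])
  }, numeric(1))
}
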