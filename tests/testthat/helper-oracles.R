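# Independent oracles and shared fixtures, built in code at test time.

# All set partitions of n elements as restricted-growth strings.
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, kmax) {
    i <- length(prefix) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (c in seq_len(kmax + 1L)) rec(c(prefix, c), max(kmax, c))
  }
  rec(integer(0), 0L)
  out
}

# Direct double-sum evaluation of modularity (independent of the package's
# per-community implementation).
modularity_oracle <- function(W, membership, gamma = 1) {
  v <- sum(W)
  s <- rowSums(W)
  q <- 0
  n <- nrow(W)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (membership[i] == membership[j]) {
        q <- q + W[i, j] - gamma * s[i] * s[j] / v
      }
    }
  }
  q / v
}

# Exhaustive maximum-modularity search on small graphs. Returns the best Q.
brute_force_best_q <- function(W, gamma = 1) {
  v <- sum(W)
  s <- rowSums(W)
  B <- W - gamma * outer(s, s) / v
  best <- -Inf
  for (p in all_partitions(nrow(W))) {
    q <- sum(B[outer(p, p, "==")]) / v
    if (q > best) best <- q
  }
  best
}

# Random symmetric non-negative weighted graph for oracle tests.
random_graph <- function(n, density = 0.6) {
  W <- matrix(0, n, n)
  up <- which(upper.tri(W))
  on <- runif(length(up)) < density
  W[up[on]] <- runif(sum(on), 0.1, 2)
  W <- W + t(W)
  if (sum(W) == 0) W[1, 2] <- W[2, 1] <- 1
  W
}

# Tiny trial-table builder for behavioural oracles.
make_trials <- function(subject = "s1", load = 0, rts, correct,
                        target = NULL, block = 1) {
  n <- length(rts)
  if (is.null(target)) target <- rep(0, n)
  response <- ifelse(correct,
                     ifelse(target == 1, "target", "non-target"),
                     "omitted")
  rt <- ifelse(response == "omitted", NA_real_, rts)
  data.frame(subject_id = subject, block = block, load = load,
             trial = seq_len(n), target = target, response = response,
             rt = rt, stringsAsFactors = FALSE)
}

# Shared default cohort (the stated world), built once per test run.
.fixtures <- new.env(parent = emptyenv())
default_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    .fixtures$cohort <- suppressWarnings(
      simulate_cohort(cohort_config(seed = 20260917L)))
  }
  .fixtures$cohort
}

planted_networks <- function(cohort) {
  nets <- ifelse(cohort$node_labels$apriori_network == "DMN", "DMN", "TPN")
  names(nets) <- cohort$node_labels$node_id
  nets
}

# Subject-level condition connectivity for all three loads.
subject_zmats <- function(sub, lag = 2L) {
  lapply(c("0", "1", "2"), function(cd) {
    condition_connectivity(sub$bold, cd, lag)
  })
}
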