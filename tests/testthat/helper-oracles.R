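# Fixture builders and independent oracles used across the suite.

# Small Cq table from a numeric matrix; default names filled in.
make_cq <- function(m, mirnas = NULL, samples = NULL, ...) {
  if (is.null(mirnas)) mirnas <- sprintf("hsa-miR-t%02d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("S%d", seq_len(ncol(m)))
  dimnames(m) <- list(mirnas, samples)
  cq_table(m, ...)
}

# Random fully specified Cq table (some cells censored above `censor_frac`).
random_cq <- function(n_mirna, n_sample, censor = FALSE) {
  m <- matrix(runif(n_mirna * n_sample, 20, if (censor) 42 else 38),
              n_mirna, n_sample)
  make_cq(m)
}

make_sheet <- function(sample_ids, groups, set_id = "set1") {
  sample_sheet(data.frame(sample_id = sample_ids, group = groups,
                          set_id = set_id, stringsAsFactors = FALSE))
}

# Brute-force M values: explicit double loop over candidate pairs,
# sd() of the per-sample Cq differences. Independent of the package's
# covariance-based computation.
oracle_m_values <- function(X) {
  n <- nrow(X)
  M <- numeric(n)
  for (j in seq_len(n)) {
    sds <- numeric(0)
    for (k in seq_len(n)) if (k != j) sds <- c(sds, sd(X[j, ] - X[k, ]))
    M[j] <- mean(sds)
  }
  names(M) <- rownames(X)
  M
}

# Brute-force iterative exclusion, recomputing all M values at every step
# with the loop-based oracle; same tie rule (drop lexicographically last).
oracle_genorm <- function(X, k) {
  remaining <- rownames(X)
  excl <- character(0)
  while (length(remaining) > k) {
    M <- oracle_m_values(X[remaining, , drop = FALSE])
    worst <- names(M)[M == max(M)]
    drop <- sort(canonical_mirna(worst), decreasing = TRUE)[1]
    drop <- worst[canonical_mirna(worst) == drop][1]
    excl <- c(excl, drop)
    remaining <- setdiff(remaining, drop)
  }
  M <- oracle_m_values(X[remaining, , drop = FALSE])
  list(selected = remaining[order(M, canonical_mirna(remaining))],
       exclusion_order = excl)
}

# Literal step-up definition: q(i) = min over j with p(j) >= p(i) of
# m * p(j) / rank(j), capped at 1. O(n^2), no sorting tricks shared with
# the implementation.
oracle_bh <- function(p) {
  ok <- !is.na(p)
  pv <- p[ok]
  m <- length(pv)
  # for tied p the min over the tied block is attained at its largest
  # sorted position, so max-rank reproduces the step-up minimum exactly
  r <- rank(pv, ties.method = "max")
  q <- vapply(pv, function(pi) {
    min(1, min(m * pv[pv >= pi] / r[pv >= pi]))
  }, numeric(1))
  out <- rep(NA_real_, length(p))
  out[ok] <- q
  out
}
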