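# Independent oracles and small fixture builders used across the suite.

# Brute-force Benjamini-Hochberg: sort, step-up, cumulative minimum.
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- pmin(1, rev(cummin(rev(ranked))))
  out <- numeric(n)
  out[o] <- adj
  out
}

# Exhaustive FPR threshold sweep: walk every distinct control value
# (plus -Inf) and take the smallest threshold whose whole suffix keeps
# NC/(NC+PC) at or below the target.
oracle_fpr_threshold <- function(pc_lfc, nc_lfc, target) {
  cand <- c(-Inf, sort(unique(c(pc_lfc, nc_lfc))))
  fpr <- vapply(cand, function(t) {
    np <- sum(pc_lfc >= t)
    nn <- sum(nc_lfc >= t)
    if (np + nn == 0) 0 else nn / (np + nn)
  }, numeric(1))
  for (i in seq_along(cand)) {
    if (all(fpr[i:length(cand)] <= target)) return(cand[i])
  }
  NA_real_
}

# Upper-tail hypergeometric by exhaustive enumeration of all C(N, n)
# draws from a population where elements 1..K are the successes.
enum_hyper_upper <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Small complete reporter matrix with explicit values.
toy_reporter <- function(x, n_pep = NULL) {
  if (is.null(rownames(x))) rownames(x) <- sprintf("P%02d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- tmtpro_tags(ncol(x))
  if (is.null(n_pep)) n_pep <- rep(5L, nrow(x))
  reporter_matrix(x, n_pep)
}

# Two-condition design (A experimental, B reference), n_rep each.
two_group_design <- function(n_rep = 3) {
  study_design(
    channel = tmtpro_tags(2 * n_rep),
    condition = rep(c("A", "B"), each = n_rep),
    replicate = rep(seq_len(n_rep), 2),
    reference = "B"
  )
}

# Random column-stochastic, diagonally dominant mixing matrix.
random_mixing_matrix <- function(n_ch) {
  m <- matrix(stats::runif(n_ch^2, 0, 0.05), n_ch, n_ch)
  diag(m) <- 0
  diag(m) <- 1 - colSums(m)
  m
}
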