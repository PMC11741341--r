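#' Invert the trigamma function
#'
#' Newton iteration for `x` such that `trigamma(x) = y`, used by the
#' moment estimator of the variance-prior degrees of freedom.
#'
#' @param y Positive numeric vector.
#' @param tol Relative convergence tolerance.
#' @return Numeric vector of solutions.
#' @keywords internal
trigamma_inverse <- function(y, tol = 1e-8) {
  out <- y
  for (i in seq_along(y)) {
    yi <- y[i]
    if (!is.finite(yi) || yi <= 0) {
      out[i] <- NA_real_
      next
    }
    if (yi > 1e7) {        # trigamma(x) ~ 1/x + 1/(2x^2) for small x
      out[i] <- 1 / sqrt(yi)
      next
    }
    if (yi < 1e-6) {       # trigamma(x) ~ 1/x for large x
      out[i] <- 1 / yi
      next
    }
    x <- 0.5 + 1 / yi
    repeat {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (abs(dif) < tol * x) break
    }
    out[i] <- x
  }
  out
}

#' Moment estimation of the variance prior
#'
#' Fits the scaled F / inverse-chi-square prior of the empirical-Bayes
#' variance model to observed sample variances: given `s2 ~ s0^2 *
#' chisq(df)/df * F(df, d0)`-type spread, matches the mean and variance
#' of `log(s2)` using digamma/trigamma identities and inverts the
#' trigamma to obtain the prior degrees of freedom `d0` and prior
#' variance `s0^2`. Estimates of `d0` above `1e6` are reported as
#' infinite (fully pooled variance).
#'
#' @param s2 Sample variances (non-negative).
#' @param df Residual degrees of freedom, scalar or per-variance vector.
#' @return List with `d0` and `s0_sq`.
#' @export
fit_variance_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (sum(ok) < 2) stop("need at least 2 positive variances to fit the prior")
  s2 <- s2[ok]
  df <- df[ok]
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  n <- length(e)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(df / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    if (!is.finite(d0) || d0 > 1e6) {
      d0 <- Inf
      s0_sq <- exp(emean)
    } else {
      s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    }
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

resolve_groups <- function(data, design, contrast) {
  if (length(contrast) != 2L || contrast[1] == contrast[2]) {
    stop("'contrast' must name two distinct conditions (group_a, group_b)")
  }
  if (inherits(data, "ratio_table")) {
    ref <- data$reference
    get_cols <- function(cond) {
      ch <- data$samples$channel[data$samples$condition == cond]
      data$ratios[, ch, drop = FALSE]
    }
    if (contrast[2] == ref) {
      if (!contrast[1] %in% data$samples$condition) {
        stop("condition '", contrast[1], "' not present in the ratio table")
      }
      return(list(a = get_cols(contrast[1]), b = NULL,
                  ids = rownames(data$ratios)))
    }
    if (!all(contrast %in% data$samples$condition)) {
      stop("contrast conditions not present in the ratio table")
    }
    return(list(a = get_cols(contrast[1]), b = get_cols(contrast[2]),
                ids = rownames(data$ratios)))
  }
  if (!is.matrix(data) || is.null(design)) {
    stop("'data' must be a ratio_table, or a log2 matrix with a design")
  }
  stopifnot(inherits(design, "study_design"))
  if (!all(contrast %in% design$condition)) {
    stop("contrast conditions not present in the design")
  }
  cols <- function(cond) {
    ch <- intersect(condition_channels(design, cond), colnames(data))
    if (length(ch) == 0) stop("no data columns for condition '", cond, "'")
    data[, ch, drop = FALSE]
  }
  list(a = cols(contrast[1]), b = cols(contrast[2]), ids = rownames(data))
}

row_var <- function(x, means, n) {
  v <- rowSums((x - means)^2, na.rm = TRUE) / (n - 1)
  v[n < 2] <- NA_real_
  v
}

#' Empirical-Bayes moderated t-test per protein
#'
#' Two-group (or one-sample, for ratio tables tested against their
#' reference) t-tests whose per-protein variance is shrunk toward a
#' common prior: the prior `(d0, s0^2)` is estimated from all sample
#' variances by the moment method of [fit_variance_prior()], the
#' posterior variance is `(d0 s0^2 + df s2) / (d0 + df)`, and the
#' moderated statistic is referred to a Student t distribution with
#' `d0 + df` degrees of freedom. `d0 = 0` gives the ordinary pooled t;
#' `d0 = Inf` pools the variance completely.
#'
#' @param data A [ratio_table], or a numeric log2 matrix (proteins x
#'   channels) accompanied by `design`.
#' @param design A [study_design]; required when `data` is a matrix.
#' @param contrast Character pair `c(group_a, group_b)`: the experimental
#'   and reference condition of the comparison. When `data` is a ratio
#'   table and `group_b` is its reference condition, a one-sample test of
#'   the `group_a` ratios against 0 is performed.
#' @param d0,s0_sq Optional fixed prior; when `NULL` (default) both are
#'   estimated from the data. Supplying `d0 = 0` disables shrinkage.
#' @return A data frame of class `diff_test_table` with columns
#'   `protein_id`, `logFC`, `s2`, `t_mod`, `df_total`, `p`, `p_adj` and
#'   attributes `d0`, `s0_sq`, `contrast`. Proteins with fewer than two
#'   observations in a group are reported untested (`NA` statistics).
#' @export
moderated_t <- function(data, design = NULL, contrast, d0 = NULL,
                        s0_sq = NULL) {
  gr <- resolve_groups(data, design, contrast)
  a <- gr$a
  if (ncol(a) < 2) stop("group '", contrast[1], "' has fewer than 2 replicates")
  n_a <- rowSums(!is.na(a))
  mean_a <- rowMeans(a, na.rm = TRUE)
  if (is.null(gr$b)) {
    # one-sample on ratios versus 0
    logfc <- mean_a
    s2 <- row_var(a, mean_a, n_a)
    df <- n_a - 1
    sefac <- 1 / n_a
    tested <- n_a >= 2
  } else {
    b <- gr$b
    if (ncol(b) < 2) {
      stop("group '", contrast[2], "' has fewer than 2 replicates")
    }
    n_b <- rowSums(!is.na(b))
    mean_b <- rowMeans(b, na.rm = TRUE)
    logfc <- mean_a - mean_b
    s2 <- ((n_a - 1) * row_var(a, mean_a, n_a) +
           (n_b - 1) * row_var(b, mean_b, n_b)) / (n_a + n_b - 2)
    df <- n_a + n_b - 2
    sefac <- 1 / n_a + 1 / n_b
    tested <- n_a >= 2 & n_b >= 2
  }
  if (all(!tested)) stop("no protein has >= 2 replicates per group")
  if (all(s2[tested] == 0)) {
    stop("zero variance for every tested protein; degenerate fit")
  }
  if (is.null(d0) && !is.null(s0_sq)) {
    stop("'s0_sq' supplied without 'd0'")
  }
  if (!is.null(d0) && is.null(s0_sq) && d0 != 0) {
    stop("supply 's0_sq' with 'd0' (d0 = 0 needs no s0_sq)")
  }
  if (is.null(d0)) {
    prior <- fit_variance_prior(s2[tested], df[tested])
    d0 <- prior$d0
    s0_sq <- prior$s0_sq
  } else if (d0 == 0 && is.null(s0_sq)) {
    s0_sq <- 0
  }
  if (d0 > 1e6) d0 <- Inf
  if (is.infinite(d0)) {
    s2_post <- rep_len(s0_sq, length(s2))
    df_total <- rep_len(Inf, length(s2))
  } else {
    s2_post <- (d0 * s0_sq + df * s2) / (d0 + df)
    df_total <- d0 + df
  }
  t_mod <- logfc / sqrt(s2_post * sefac)
  p <- ifelse(is.infinite(df_total),
              2 * stats::pnorm(abs(t_mod), lower.tail = FALSE),
              2 * stats::pt(abs(t_mod), df_total, lower.tail = FALSE))
  t_mod[!tested] <- NA_real_
  p[!tested] <- NA_real_
  logfc[!tested] <- NA_real_
  df_total[!tested] <- NA_real_
  out <- data.frame(
    protein_id = gr$ids,
    logFC = logfc,
    s2 = s2,
    t_mod = t_mod,
    df_total = df_total,
    p = p,
    p_adj = bh_adjust(p),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  attr(out, "contrast") <- contrast
  class(out) <- c("diff_test_table", "data.frame")
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment. Missing values propagate as
#' missing and are excluded from the number of tests; input order is
#' preserved.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Vector of adjusted p-values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.001, 0.5, 1.0))
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("'p' must be numeric")
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  out <- p
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}
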