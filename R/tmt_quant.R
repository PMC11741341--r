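#' Correct reporter-ion intensities for isotope impurities
#'
#' Inverts the channel-mixing matrix per protein: for each protein with
#' all channels observed, solves `M x = y` where `y` is the observed
#' intensity vector and column `j` of `M` gives the fraction of channel
#' `j`'s true signal observed in each channel. Small negative solutions
#' (noise pushing a corrected value below zero) are clamped to 0 and
#' flagged. Proteins with any missing channel pass through uncorrected
#' and are flagged.
#'
#' @param raw A [reporter_matrix] of observed intensities.
#' @param impurity Square channel-mixing matrix (dimension = channel
#'   count, entries in `[0, 1]`, columns summing to at most 1,
#'   nonsingular with condition number below `1e8`).
#' @return A [reporter_matrix] of corrected intensities with attribute
#'   `flags`: a data frame (`protein_id`, `uncorrected`, `clamped`).
#' @export
correct_impurities <- function(raw, impurity) {
  stopifnot(inherits(raw, "reporter_matrix"))
  n_ch <- length(raw$channel_names)
  if (!is.matrix(impurity) || !is.numeric(impurity) ||
      any(dim(impurity) != n_ch)) {
    stop("'impurity' must be a numeric ", n_ch, " x ", n_ch, " matrix")
  }
  if (any(impurity < 0) || any(impurity > 1)) {
    stop("impurity fractions must be in [0, 1]")
  }
  if (any(colSums(impurity) > 1 + 1e-6)) {
    stop("impurity matrix columns must each sum to at most 1")
  }
  k <- tryCatch(kappa(impurity, exact = TRUE), error = function(e) Inf)
  if (!is.finite(k) || k >= 1e8) {
    stop("impurity matrix is singular or ill-conditioned (condition number ",
         format(k), ")")
  }
  x <- raw$intensities
  complete <- !apply(is.na(x), 1L, any)
  out <- x
  if (any(complete)) {
    # solve M t(X) = t(Y) for all complete proteins at once
    out[complete, ] <- t(solve(impurity, t(x[complete, , drop = FALSE])))
  }
  clamped <- complete & apply(out < 0 & !is.na(out), 1L, any)
  out[out < 0 & !is.na(out)] <- 0
  res <- reporter_matrix(out, raw$n_unique_peptides)
  attr(res, "flags") <- data.frame(
    protein_id = raw$protein_ids,
    uncorrected = !complete,
    clamped = clamped,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  res
}

#' Filter proteins on peptide support and quantification completeness
#'
#' Retains proteins supported by at least `min_unique_peptides` distinct
#' peptide sequences and, when `require_complete` is set, quantified in
#' every channel ("fully quantified"). Row order is preserved.
#'
#' @param m A [reporter_matrix].
#' @param min_unique_peptides Minimum unique-peptide count (default 2,
#'   i.e. proteins with more than one unique peptide).
#' @param require_complete Drop proteins with any missing channel.
#' @return The filtered [reporter_matrix] with attribute `filter_report`:
#'   a list with `n_input`, `n_low_peptides`, `n_incomplete`,
#'   `n_retained`.
#' @export
filter_proteins <- function(m, min_unique_peptides = 2,
                            require_complete = TRUE) {
  stopifnot(inherits(m, "reporter_matrix"))
  pep_ok <- m$n_unique_peptides >= min_unique_peptides
  complete <- !apply(is.na(m$intensities), 1L, any)
  keep <- pep_ok & (complete | !require_complete)
  res <- reporter_matrix(m$intensities[keep, , drop = FALSE],
                         m$n_unique_peptides[keep])
  attr(res, "filter_report") <- list(
    n_input = length(keep),
    n_low_peptides = sum(!pep_ok),
    n_incomplete = if (require_complete) sum(pep_ok & !complete) else 0L,
    n_retained = sum(keep)
  )
  res
}

#' Log2 ratios versus the reference condition
#'
#' For protein `g` and each non-reference channel `s`,
#' `r[g, s] = log2(I[g, s]) - summary over reference channels c of
#' log2(I[g, c])`, where the summary is the mean (geometric-mean
#' intensity) or, optionally, the median of the reference-channel log2
#' intensities. Reference channels do not appear as samples.
#'
#' @param m A [reporter_matrix], complete (no missing, no zero) for all
#'   retained proteins.
#' @param design A [study_design] covering all channels of `m`.
#' @param ref_summary Summary of the reference-channel log2 intensities:
#'   `"mean"` (default) or `"median"`.
#' @return An unnormalized [ratio_table].
#' @export
compute_log_ratios <- function(m, design, ref_summary = c("mean", "median")) {
  stopifnot(inherits(m, "reporter_matrix"), inherits(design, "study_design"))
  ref_summary <- match.arg(ref_summary)
  if (!all(m$channel_names %in% design$channel)) {
    stop("design does not cover all channels of the reporter matrix")
  }
  ref <- reference_condition(design)
  ref_ch <- condition_channels(design, ref)
  sample_ch <- setdiff(m$channel_names, ref_ch)
  bad <- which(is.na(m$intensities) | m$intensities == 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "zero or missing intensity for protein %s in channel %s; filter first",
      m$protein_ids[bad[1, 1]], m$channel_names[bad[1, 2]]
    ))
  }
  l2 <- log2(m$intensities)
  ref_l2 <- l2[, ref_ch, drop = FALSE]
  ref_stat <- switch(ref_summary,
    mean = rowMeans(ref_l2),
    median = apply(ref_l2, 1L, stats::median)
  )
  ratios <- l2[, sample_ch, drop = FALSE] - ref_stat
  samples <- design[match(sample_ch, design$channel),
                    c("channel", "condition", "replicate")]
  rownames(samples) <- NULL
  ratio_table(ratios, samples, reference = ref, normalized = FALSE)
}

#' Median-normalize a ratio table
#'
#' Subtracts each sample column's median (over observed entries), centring
#' the aggregate distribution of protein-level log2 ratios at 0.
#' Idempotent.
#'
#' @param r A [ratio_table].
#' @return The normalized [ratio_table] (`normalized = TRUE`).
#' @export
median_normalize <- function(r) {
  stopifnot(inherits(r, "ratio_table"))
  meds <- apply(r$ratios, 2L, stats::median, na.rm = TRUE)
  if (any(is.na(meds))) {
    stop("sample column(s) with no observed entries: ",
         paste(colnames(r$ratios)[is.na(meds)], collapse = ", "))
  }
  ratio_table(sweep(r$ratios, 2L, meds), r$samples, r$reference,
              normalized = TRUE)
}

#' Median-centred log2 intensity matrix
#'
#' Convenience for two-sample testing against the reference condition:
#' log2-transforms the intensities and subtracts each channel's median,
#' the channel-level analogue of [median_normalize()].
#'
#' @param m A complete [reporter_matrix] (no missing or zero cells).
#' @param center Subtract per-channel medians (default `TRUE`).
#' @return Numeric matrix of (centred) log2 intensities.
#' @export
log2_channel_matrix <- function(m, center = TRUE) {
  stopifnot(inherits(m, "reporter_matrix"))
  if (any(is.na(m$intensities) | m$intensities == 0)) {
    stop("reporter matrix has missing or zero intensities; filter first")
  }
  l2 <- log2(m$intensities)
  if (center) l2 <- sweep(l2, 2L, apply(l2, 2L, stats::median))
  l2
}
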