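#' Label proteins as positive or negative controls
#'
#' Matches protein identifiers against the positive-control (annotated
#' secreted) and negative-control (annotated transcription factor) gene
#' lists by exact identifier match after case normalization. A protein
#' appearing in both lists is ambiguous: it is labeled `"none"` and
#' counted in the ambiguity report.
#'
#' @param proteins Character vector of protein identifiers.
#' @param pc_list,nc_list Character vectors of control gene identifiers.
#' @return A data frame of class `control_annotation` with columns
#'   `protein_id` and `label` (`"PC"`, `"NC"`, `"none"`), and attribute
#'   `n_ambiguous`.
#' @export
annotate_controls <- function(proteins, pc_list, nc_list) {
  lp <- tolower(proteins)
  pc <- unique(tolower(pc_list))
  nc <- unique(tolower(nc_list))
  both <- intersect(pc, nc)
  label <- rep("none", length(proteins))
  label[lp %in% pc] <- "PC"
  label[lp %in% nc] <- "NC"
  label[lp %in% both] <- "none"
  out <- data.frame(protein_id = proteins, label = label,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_ambiguous") <- sum(lp %in% both)
  class(out) <- c("control_annotation", "data.frame")
  out
}

#' False-positive-rate curve over enrichment-ratio thresholds
#'
#' Sweeps candidate log2-ratio thresholds (the distinct control logFC
#' values, plus `-Inf`) and computes at each threshold `t` the control
#' false-positive rate
#' `FPR(t) = n_NC(logFC >= t) / (n_NC(logFC >= t) + n_PC(logFC >= t))`
#' (0 when no control is at or above `t`). The calibrated threshold is
#' the smallest `t` such that `FPR(t') <= target_fpr` for every candidate
#' `t' >= t`, guarding against non-monotone empirical curves; it is `NA`
#' if no such threshold exists.
#'
#' @param test A `diff_test_table` from [moderated_t()] (or any data
#'   frame with `protein_id` and `logFC`).
#' @param ann A `control_annotation` from [annotate_controls()].
#' @param target_fpr Target false-positive rate (default 0.10).
#' @return An object of class `fpr_curve`: list with `curve` (data frame
#'   `threshold`, `n_pc_above`, `n_nc_above`, `fpr`), `target_fpr`, and
#'   `threshold` (the calibrated value, or `NA`).
#' @export
fpr_curve <- function(test, ann, target_fpr = 0.10) {
  if (target_fpr <= 0 || target_fpr >= 1) {
    stop("'target_fpr' must be in (0, 1)")
  }
  lab <- ann$label[match(test$protein_id, ann$protein_id)]
  lab[is.na(lab)] <- "none"
  ok <- !is.na(test$logFC)
  pc_lfc <- test$logFC[ok & lab == "PC"]
  nc_lfc <- test$logFC[ok & lab == "NC"]
  if (length(pc_lfc) == 0 || length(nc_lfc) == 0) {
    stop("calibration needs at least one PC and one NC among tested proteins")
  }
  thresholds <- c(-Inf, sort(unique(c(pc_lfc, nc_lfc))))
  n_pc <- vapply(thresholds, function(t) sum(pc_lfc >= t), integer(1))
  n_nc <- vapply(thresholds, function(t) sum(nc_lfc >= t), integer(1))
  denom <- n_pc + n_nc
  fpr <- ifelse(denom == 0, 0, n_nc / denom)
  # smallest threshold whose entire suffix stays at or below the target
  ok_suffix <- rev(cumprod(rev(fpr <= target_fpr))) == 1
  calibrated <- if (any(ok_suffix)) thresholds[which(ok_suffix)[1]] else NA_real_
  structure(
    list(
      curve = data.frame(threshold = thresholds, n_pc_above = n_pc,
                         n_nc_above = n_nc, fpr = fpr,
                         row.names = NULL),
      target_fpr = target_fpr,
      threshold = calibrated
    ),
    class = "fpr_curve"
  )
}

#' @export
print.fpr_curve <- function(x, ...) {
  cat(sprintf(
    "fpr_curve: %d candidate thresholds, target FPR %.3f, calibrated threshold %s\n",
    nrow(x$curve), x$target_fpr,
    if (is.na(x$threshold)) "undefined" else format(x$threshold)
  ))
  invisible(x)
}

#' Call secretome hits from a differential test table
#'
#' A protein is a hit when its BH-adjusted p-value is below `alpha` and
#' its logFC is at or above `threshold` (enrichment direction only;
#' depleted proteins are never hits). All proteins are returned, sorted
#' by logFC descending with ties broken by protein identifier, with
#' per-criterion pass flags.
#'
#' @param test A `diff_test_table` (or data frame with `protein_id`,
#'   `logFC`, `p_adj`).
#' @param threshold Log2-ratio threshold (e.g. the calibrated value from
#'   [fpr_curve()]).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @return A data frame of class `hit_table`, sorted, with columns
#'   `protein_id`, `logFC`, `p_adj`, `pass_p_adj`, `pass_ratio`, `hit`,
#'   and attributes `threshold`, `alpha`.
#' @export
call_hits <- function(test, threshold, alpha = 0.05) {
  pass_p <- !is.na(test$p_adj) & test$p_adj < alpha
  pass_r <- !is.na(test$logFC) & test$logFC >= threshold
  out <- data.frame(
    protein_id = test$protein_id,
    logFC = test$logFC,
    p_adj = test$p_adj,
    pass_p_adj = pass_p,
    pass_ratio = pass_r,
    hit = pass_p & pass_r,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$logFC, out$protein_id, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "alpha") <- alpha
  class(out) <- c("hit_table", "data.frame")
  out
}

#' Hit identifiers, in hit-table order
#' @param hits A `hit_table` (or a character vector, returned as is).
#' @return Character vector of hit protein identifiers.
#' @export
hit_ids <- function(hits) {
  if (is.character(hits)) return(hits)
  stopifnot(inherits(hits, "hit_table"))
  hits$protein_id[hits$hit]
}

#' Overlap between two hit sets
#'
#' @param hits_a,hits_b `hit_table` objects or character vectors of
#'   identifiers.
#' @return List with `n_a`, `n_b`, `n_shared`, `jaccard`,
#'   `pct_of_smaller` (both ratios are 0 when undefined on empty sets).
#' @export
overlap_summary <- function(hits_a, hits_b) {
  a <- unique(hit_ids(hits_a))
  b <- unique(hit_ids(hits_b))
  shared <- length(intersect(a, b))
  uni <- length(union(a, b))
  list(
    n_a = length(a),
    n_b = length(b),
    n_shared = shared,
    jaccard = if (uni == 0) 0 else shared / uni,
    pct_of_smaller = if (min(length(a), length(b)) == 0) 0 else
      shared / min(length(a), length(b))
  )
}

#' Category composition of the top-k hits
#'
#' Takes the first `min(k, n_hits)` hits in hit-table order and returns
#' the fraction of each category among them; proteins without a category
#' are counted under `"other"`. Fractions sum to 1.
#'
#' @param hits A `hit_table` or ordered character vector of hit ids.
#' @param categories Named character vector mapping protein id to
#'   category label.
#' @param k Number of top hits to consider (default 100).
#' @return Named numeric vector of fractions, decreasing.
#' @export
top_k_composition <- function(hits, categories, k = 100) {
  if (k < 1) stop("'k' must be at least 1")
  ids <- utils::head(hit_ids(hits), k)
  if (length(ids) == 0) return(stats::setNames(numeric(0), character(0)))
  cat_lab <- categories[ids]
  cat_lab[is.na(cat_lab)] <- "other"
  tab <- table(cat_lab) / length(ids)
  frac <- as.numeric(tab)
  names(frac) <- names(tab)
  sort(frac, decreasing = TRUE)
}
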