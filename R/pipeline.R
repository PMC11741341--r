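#' End-to-end secretome hit calling
#'
#' Runs the full quantitative workflow on a protein-level reporter
#' matrix: isotope impurity correction (when a mixing matrix is given),
#' peptide-count and completeness filtering, per-channel median-centred
#' log2 transformation, then for each requested contrast a moderated
#' t-test, control-based FPR threshold calibration, and hit calling.
#'
#' @param reporter A [reporter_matrix] of observed intensities.
#' @param design A [study_design].
#' @param pc_genes,nc_genes Character vectors of positive-control
#'   (annotated secreted) and negative-control (annotated transcription
#'   factor) gene identifiers.
#' @param contrasts List of character pairs `c(group_a, group_b)`; by
#'   default every non-reference condition is tested against the
#'   reference.
#' @param impurity Optional channel-mixing matrix; when supplied,
#'   [correct_impurities()] is applied first.
#' @param target_fpr Target false-positive rate for threshold
#'   calibration (default 0.10).
#' @param alpha Adjusted-p cutoff for hit calling (default 0.05).
#' @param min_unique_peptides Peptide-count filter (default 2).
#' @return A list with elements `filtered` (the filtered
#'   [reporter_matrix]), `annotation` (control labels over the filtered
#'   proteins), and `contrasts`: one entry per contrast holding `test`
#'   (`diff_test_table`), `fpr` (`fpr_curve`), and `hits` (`hit_table`).
#' @export
secretome_hits <- function(reporter, design, pc_genes, nc_genes,
                           contrasts = NULL, impurity = NULL,
                           target_fpr = 0.10, alpha = 0.05,
                           min_unique_peptides = 2) {
  stopifnot(inherits(reporter, "reporter_matrix"),
            inherits(design, "study_design"))
  if (!is.null(impurity)) {
    reporter <- correct_impurities(reporter, impurity)
  }
  filtered <- filter_proteins(reporter,
                              min_unique_peptides = min_unique_peptides,
                              require_complete = TRUE)
  l2 <- log2_channel_matrix(filtered, center = TRUE)
  ref <- reference_condition(design)
  if (is.null(contrasts)) {
    contrasts <- lapply(setdiff(unique(design$condition), ref),
                        function(cond) c(cond, ref))
  }
  ann <- annotate_controls(filtered$protein_ids, pc_genes, nc_genes)
  res <- lapply(contrasts, function(ctr) {
    test <- moderated_t(l2, design, contrast = ctr)
    fpr <- fpr_curve(test, ann, target_fpr = target_fpr)
    if (is.na(fpr$threshold)) {
      warning("no threshold attains the target FPR for contrast ",
              paste(ctr, collapse = " vs "))
      hits <- call_hits(test, threshold = Inf, alpha = alpha)
    } else {
      hits <- call_hits(test, threshold = fpr$threshold, alpha = alpha)
    }
    list(test = test, fpr = fpr, hits = hits)
  })
  names(res) <- vapply(contrasts, function(ctr)
    paste(ctr, collapse = "_vs_"), character(1))
  list(filtered = filtered, annotation = ann, contrasts = res)
}
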