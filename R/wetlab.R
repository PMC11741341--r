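#' qPCR Ct record
#'
#' Holds cycle-threshold values for one sample: the target gene and the
#' housekeeping reference (e.g. RP49). `ct` and `ct_ref` may be vectors
#' of technical replicates; replicate means are taken before the delta-Ct.
#'
#' @param sample Sample label.
#' @param gene Target gene name.
#' @param reference_gene Reference (housekeeping) gene name.
#' @param ct Ct value(s) for the target gene (finite, positive cycles).
#' @param ct_ref Ct value(s) for the reference gene.
#' @return An object of class `ct_record`.
#' @export
ct_record <- function(sample, gene, reference_gene, ct, ct_ref) {
  if (!all(is.finite(ct)) || !all(is.finite(ct_ref)) ||
      any(ct <= 0) || any(ct_ref <= 0)) {
    stop("Ct values must be finite and positive")
  }
  structure(
    list(sample = sample, gene = gene, reference_gene = reference_gene,
         ct = as.numeric(ct), ct_ref = as.numeric(ct_ref)),
    class = "ct_record"
  )
}

#' Relative expression by the delta-delta-Ct method
#'
#' `dCt = mean(Ct_target) - mean(Ct_reference)` per record;
#' `ddCt = dCt_experimental - dCt_control`; relative expression is
#' `2^(-ddCt)` (amplification efficiency fixed at 2).
#'
#' @param exp,ctrl [ct_record] objects for the experimental and control
#'   sample; must share target and reference genes.
#' @return Relative expression (fold change, dimensionless).
#' @export
#' @examples
#' e <- ct_record("tumor", "upd3", "RP49", ct = 20, ct_ref = 15)
#' ctl <- ct_record("ctrl", "upd3", "RP49", ct = 24, ct_ref = 16)
#' ddct(e, ctl)  # 8
ddct <- function(exp, ctrl) {
  stopifnot(inherits(exp, "ct_record"), inherits(ctrl, "ct_record"))
  if (exp$gene != ctrl$gene || exp$reference_gene != ctrl$reference_gene) {
    stop("experimental and control records must share target and reference genes")
  }
  dct_exp <- mean(exp$ct) - mean(exp$ct_ref)
  dct_ctrl <- mean(ctrl$ct) - mean(ctrl$ct_ref)
  2^(-(dct_exp - dct_ctrl))
}

#' ChIP-qPCR fold enrichment over a non-tagged control IP
#'
#' `dCt = Ct_IP - Ct_control`; fold enrichment is `2^(-dCt)`, the ChIP
#' signal as a fold increase over the background IP.
#'
#' @param ct_ip Ct of the tagged IP sample (vectorized).
#' @param ct_control Ct of the non-tagged control IP.
#' @return Fold enrichment (dimensionless).
#' @export
#' @examples
#' chip_fold_enrichment(25, 22)  # 0.125
chip_fold_enrichment <- function(ct_ip, ct_control) {
  if (!all(is.finite(ct_ip)) || !all(is.finite(ct_control))) {
    stop("Ct values must be finite")
  }
  2^(-(ct_ip - ct_control))
}
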