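#' TMTpro reporter channel tags
#'
#' Returns the first `n` TMTpro reporter tag labels in mass order
#' (126, 127N, 127C, ...). TMTpro supports up to 18 channels.
#'
#' @param n Number of channels (1-18).
#' @return Character vector of tag labels.
#' @export
#' @examples
#' tmtpro_tags(12)
tmtpro_tags <- function(n) {
  tags <- c("126", "127N", "127C", "128N", "128C", "129N", "129C",
            "130N", "130C", "131N", "131C", "132N", "132C", "133N",
            "133C", "134N", "134C", "135N")
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n > length(tags)) {
    stop("'n' must be a single integer between 1 and ", length(tags))
  }
  tags[seq_len(n)]
}

#' Protein-level reporter-ion intensity matrix
#'
#' Container for protein x channel reporter-ion intensities together with
#' per-protein unique-peptide counts. Missing observations are `NA`;
#' observed intensities must be non-negative.
#'
#' @param intensities Numeric matrix, proteins in rows (rownames are
#'   protein identifiers) and TMT channels in columns (colnames are tag
#'   labels).
#' @param n_unique_peptides Non-negative integer vector, one entry per
#'   protein (the number of distinct peptide sequences supporting the
#'   protein's quantification).
#' @return An object of class `reporter_matrix`: a list with elements
#'   `intensities`, `n_unique_peptides`, `protein_ids`, `channel_names`.
#' @export
reporter_matrix <- function(intensities, n_unique_peptides) {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop("'intensities' must be a numeric matrix")
  }
  ids <- rownames(intensities)
  channels <- colnames(intensities)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("'intensities' must have unique rownames (protein identifiers)")
  }
  if (is.null(channels) || anyDuplicated(channels)) {
    stop("'intensities' must have unique colnames (channel tags)")
  }
  if (any(intensities < 0, na.rm = TRUE)) {
    stop("observed intensities must be non-negative")
  }
  if (length(n_unique_peptides) != nrow(intensities)) {
    stop("'n_unique_peptides' must have one entry per protein")
  }
  if (any(is.na(n_unique_peptides)) || any(n_unique_peptides < 0)) {
    stop("'n_unique_peptides' must be non-negative and non-missing")
  }
  structure(
    list(
      intensities = intensities,
      n_unique_peptides = as.integer(n_unique_peptides),
      protein_ids = ids,
      channel_names = channels
    ),
    class = "reporter_matrix"
  )
}

#' @export
print.reporter_matrix <- function(x, ...) {
  cat(sprintf(
    "reporter_matrix: %d proteins x %d channels (%s...)\n",
    nrow(x$intensities), ncol(x$intensities),
    paste(utils::head(x$channel_names, 4), collapse = ", ")
  ))
  cat(sprintf("  missing cells: %d\n", sum(is.na(x$intensities))))
  invisible(x)
}

#' @export
dim.reporter_matrix <- function(x) dim(x$intensities)

#' Study design: channel-to-condition mapping
#'
#' Maps each TMT channel to a biological condition and replicate index and
#' names the reference condition (the denominator for enrichment ratios).
#'
#' @param channel Character vector of channel tags.
#' @param condition Character vector of condition labels, parallel to
#'   `channel`.
#' @param replicate Integer vector of replicate indices, parallel to
#'   `channel`.
#' @param reference Single condition label used as the ratio reference.
#' @return An object of class `study_design`: a data frame with columns
#'   `channel`, `condition`, `replicate` and attribute `reference`.
#' @export
study_design <- function(channel, condition, replicate, reference) {
  if (anyDuplicated(channel)) stop("each channel must be assigned exactly once")
  if (length(condition) != length(channel) ||
      length(replicate) != length(channel)) {
    stop("'condition' and 'replicate' must be parallel to 'channel'")
  }
  if (length(reference) != 1L || !reference %in% condition) {
    stop("'reference' must name a condition with at least one channel")
  }
  out <- data.frame(
    channel = as.character(channel),
    condition = as.character(condition),
    replicate = as.integer(replicate),
    stringsAsFactors = FALSE
  )
  attr(out, "reference") <- as.character(reference)
  class(out) <- c("study_design", "data.frame")
  out
}

#' Reference condition of a study design
#' @param design A `study_design`.
#' @return The reference condition label.
#' @export
reference_condition <- function(design) {
  stopifnot(inherits(design, "study_design"))
  attr(design, "reference")
}

#' Channels assigned to a condition
#' @param design A `study_design`.
#' @param condition A condition label.
#' @return Character vector of channel tags.
#' @export
condition_channels <- function(design, condition) {
  stopifnot(inherits(design, "study_design"))
  ch <- design$channel[design$condition == condition]
  if (length(ch) == 0L) stop("no channels assigned to condition '", condition, "'")
  ch
}

#' Log2 ratio table relative to the reference condition
#'
#' @param ratios Numeric matrix of log2 ratios, proteins in rows, one
#'   column per non-reference sample (colnames are channel tags).
#' @param samples Data frame with columns `channel`, `condition`,
#'   `replicate`, one row per ratio column.
#' @param reference Reference condition label the ratios are taken against.
#' @param normalized Logical; whether sample medians have been centred.
#' @return An object of class `ratio_table`.
#' @export
ratio_table <- function(ratios, samples, reference, normalized = FALSE) {
  if (!is.matrix(ratios) || !is.numeric(ratios)) {
    stop("'ratios' must be a numeric matrix")
  }
  if (nrow(samples) != ncol(ratios) ||
      !all(samples$channel == colnames(ratios))) {
    stop("'samples' must describe the ratio columns in order")
  }
  structure(
    list(ratios = ratios, samples = samples, reference = reference,
         normalized = isTRUE(normalized)),
    class = "ratio_table"
  )
}

#' @export
print.ratio_table <- function(x, ...) {
  cat(sprintf(
    "ratio_table: %d proteins x %d samples, reference '%s'%s\n",
    nrow(x$ratios), ncol(x$ratios), x$reference,
    if (x$normalized) ", median-normalized" else ""
  ))
  invisible(x)
}
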