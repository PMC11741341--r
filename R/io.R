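#' Write / read a reporter matrix as TSV
#'
#' Columns: `protein_id`, `n_unique_peptides`, then one column per
#' channel named by its TMT tag. Missing cells are written as `NA`.
#'
#' @param m A [reporter_matrix].
#' @param path Output path.
#' @return `write_reporter_tsv` returns `path` invisibly;
#'   `read_reporter_tsv` returns a [reporter_matrix].
#' @export
write_reporter_tsv <- function(m, path) {
  stopifnot(inherits(m, "reporter_matrix"))
  df <- data.frame(protein_id = m$protein_ids,
                   n_unique_peptides = m$n_unique_peptides,
                   m$intensities, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_reporter_tsv
#' @export
read_reporter_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("protein_id", "n_unique_peptides")
  if (!all(need %in% names(df))) {
    stop("reporter TSV must have columns: ", paste(need, collapse = ", "))
  }
  chan <- setdiff(names(df), need)
  x <- as.matrix(df[, chan, drop = FALSE])
  rownames(x) <- df$protein_id
  reporter_matrix(x, df$n_unique_peptides)
}

#' Write / read a study design as JSON
#'
#' @param design A [study_design].
#' @param path Output path.
#' @return `write_design_json` returns `path` invisibly;
#'   `read_design_json` returns a [study_design].
#' @export
write_design_json <- function(design, path) {
  stopifnot(inherits(design, "study_design"))
  obj <- list(
    reference_condition = reference_condition(design),
    channels = data.frame(channel = design$channel,
                          condition = design$condition,
                          replicate = design$replicate)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_design_json
#' @export
read_design_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  study_design(channel = obj$channels$channel,
               condition = obj$channels$condition,
               replicate = obj$channels$replicate,
               reference = obj$reference_condition)
}

#' Write / read a gene list (one identifier per line)
#'
#' Blank lines and surrounding whitespace are ignored on read.
#'
#' @param genes Character vector.
#' @param path File path.
#' @return `write_gene_list` returns `path` invisibly; `read_gene_list`
#'   returns a character vector.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' @rdname write_gene_list
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' Write a ratio table as TSV
#'
#' Columns: `protein_id`, then one column per sample channel.
#'
#' @param r A [ratio_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ratio_tsv <- function(r, path) {
  stopifnot(inherits(r, "ratio_table"))
  df <- data.frame(protein_id = rownames(r$ratios), r$ratios,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
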