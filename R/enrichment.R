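#' Read a gene-set collection in GMT format
#'
#' Each GMT line is `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Duplicate genes within a set are collapsed; sets with no genes are
#' dropped and counted. A line with fewer than two fields (no
#' description) is a parse error reported with its line number.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (the gene sets), with
#'   attribute `n_dropped` counting empty sets.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  n_dropped <- 0L
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2L) {
      stop("malformed GMT line ", i, ": expected name, description, genes")
    }
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) {
      n_dropped <- n_dropped + 1L
      next
    }
    name <- fields[1]
    if (name %in% names(sets)) stop("duplicate gene-set name '", name, "'")
    sets[[name]] <- genes
  }
  if (n_dropped > 0) {
    warning(n_dropped, " empty gene set(s) dropped")
  }
  attr(sets, "n_dropped") <- n_dropped
  sets
}

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation among a hit list drawn
#' from a universe: with population size `N = |universe|`, successes
#' `K = |set` \eqn{\cap} `universe|`, draws `n = |hits|` and observed
#' overlap `k`, the p-value is the upper-tail hypergeometric probability
#' `P(X >= k)`. P-values are BH-adjusted across the tested sets. Sets
#' whose intersection with the universe has fewer than `min_set_size`
#' genes are skipped and reported.
#'
#' @param hit_set Character vector of hit gene identifiers (must be a
#'   subset of `universe`).
#' @param universe Character vector: the sampling frame, typically all
#'   proteins quantified after filtering.
#' @param collection Named list of gene sets (e.g. from [read_gmt()]).
#' @param min_set_size Minimum in-universe set size to test (default 2).
#' @return A data frame of class `enrichment_table` with columns `set`,
#'   `k_overlap`, `set_size`, `n_hits`, `n_universe`, `p`, `p_adj`,
#'   `genes` (comma-separated overlap), sorted by `p`; attribute
#'   `skipped` names the untested sets.
#' @export
ora <- function(hit_set, universe, collection, min_set_size = 2) {
  universe <- unique(universe)
  hit_set <- unique(hit_set)
  missing_hits <- setdiff(hit_set, universe)
  if (length(missing_hits) > 0) {
    stop("hit(s) not in universe: ",
         paste(utils::head(missing_hits, 5), collapse = ", "))
  }
  if (length(collection) == 0) stop("'collection' is empty")
  if (is.null(names(collection)) || anyDuplicated(names(collection))) {
    stop("'collection' must have unique set names")
  }
  N <- length(universe)
  n <- length(hit_set)
  in_univ <- lapply(collection, intersect, universe)
  K <- lengths(in_univ)
  skipped <- names(collection)[K < min_set_size]
  tested <- names(collection)[K >= min_set_size]
  rows <- lapply(tested, function(nm) {
    set <- in_univ[[nm]]
    ov <- intersect(set, hit_set)
    k <- length(ov)
    data.frame(
      set = nm,
      k_overlap = k,
      set_size = length(set),
      n_hits = n,
      n_universe = N,
      p = stats::phyper(k - 1, length(set), N - length(set), n,
                        lower.tail = FALSE),
      genes = paste(sort(ov), collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(set = character(0), k_overlap = integer(0),
                      set_size = integer(0), n_hits = integer(0),
                      n_universe = integer(0), p = numeric(0),
                      p_adj = numeric(0), genes = character(0),
                      stringsAsFactors = FALSE)
  } else {
    out$p_adj <- bh_adjust(out$p)
    out <- out[order(out$p, out$set), c("set", "k_overlap", "set_size",
                                        "n_hits", "n_universe", "p",
                                        "p_adj", "genes")]
    rownames(out) <- NULL
  }
  attr(out, "skipped") <- skipped
  class(out) <- c("enrichment_table", "data.frame")
  out
}
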