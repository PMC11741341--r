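#' Configuration for a synthetic TMT secretome experiment
#'
#' Defines a multiplexed reporter-ion experiment with known ground truth.
#' Defaults emulate the study design this package targets: a TMTpro
#' 12-plex with 4 conditions x 3 replicates, log-normal intensity noise,
#' adjacent-channel isotope impurity mixing, a subset of truly enriched
#' "secreted" proteins, and annotated positive (secreted) / negative
#' (transcription-factor) control labels.
#'
#' @param n_proteins Number of proteins.
#' @param n_conditions Number of conditions (first is the reference).
#' @param n_replicates Replicates per condition;
#'   `n_conditions * n_replicates` must be at most 18 (TMTpro limit).
#' @param frac_enriched Fraction of proteins truly enriched in each
#'   non-reference condition (in `[0, 1]`). Enriched proteins are drawn
#'   preferentially from the positive controls (80% of PCs when the
#'   budget allows), never from negative controls. `0` means no protein
#'   is enriched anywhere.
#' @param effect_size_log2 True log2 enrichment of enriched proteins
#'   (positive).
#' @param noise_sd_log2 Standard deviation of per-cell log2 intensity
#'   noise (positive).
#' @param n_pc_controls,n_nc_controls Numbers of positive-control
#'   (annotated secreted) and negative-control (annotated transcription
#'   factor) proteins.
#' @param impurity_offdiag Fraction of each channel's true signal leaking
#'   into each adjacent channel (in `[0, 0.5)`).
#' @param missing_rate Per-cell missingness probability applied after
#'   mixing (in `[0, 1)`).
#' @param min_peptides_range Length-2 integer range; unique-peptide counts
#'   are drawn uniformly from it.
#' @param seed Integer seed; identical configurations give identical
#'   simulated experiments.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_proteins = 2000,
                       n_conditions = 4,
                       n_replicates = 3,
                       frac_enriched = 0.1,
                       effect_size_log2 = 2,
                       noise_sd_log2 = 0.3,
                       n_pc_controls = 200,
                       n_nc_controls = 200,
                       impurity_offdiag = 0.03,
                       missing_rate = 0,
                       min_peptides_range = c(1L, 12L),
                       seed = 1L) {
  chk_count <- function(x, name, min = 1) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
        x != round(x)) {
      stop("'", name, "' must be a single integer >= ", min)
    }
  }
  chk_count(n_proteins, "n_proteins")
  chk_count(n_conditions, "n_conditions")
  chk_count(n_replicates, "n_replicates")
  chk_count(n_pc_controls, "n_pc_controls", min = 0)
  chk_count(n_nc_controls, "n_nc_controls", min = 0)
  chk_count(seed, "seed", min = -.Machine$integer.max)
  if (frac_enriched < 0 || frac_enriched > 1) {
    stop("'frac_enriched' must be in [0, 1]")
  }
  if (effect_size_log2 <= 0) stop("'effect_size_log2' must be positive")
  if (noise_sd_log2 <= 0) stop("'noise_sd_log2' must be positive")
  if (impurity_offdiag < 0 || impurity_offdiag >= 0.5) {
    stop("'impurity_offdiag' must be in [0, 0.5)")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("'missing_rate' must be in [0, 1)")
  }
  if (length(min_peptides_range) != 2L ||
      any(min_peptides_range < 0) ||
      min_peptides_range[1] > min_peptides_range[2]) {
    stop("'min_peptides_range' must be an ordered non-negative integer pair")
  }
  if (n_pc_controls + n_nc_controls > n_proteins) {
    stop("control counts exceed 'n_proteins'")
  }
  n_channels <- n_conditions * n_replicates
  if (n_channels > 18L) {
    stop("n_conditions * n_replicates must be at most 18 (TMTpro limit)")
  }
  structure(
    list(n_proteins = as.integer(n_proteins),
         n_conditions = as.integer(n_conditions),
         n_replicates = as.integer(n_replicates),
         frac_enriched = frac_enriched,
         effect_size_log2 = effect_size_log2,
         noise_sd_log2 = noise_sd_log2,
         n_pc_controls = as.integer(n_pc_controls),
         n_nc_controls = as.integer(n_nc_controls),
         impurity_offdiag = impurity_offdiag,
         missing_rate = missing_rate,
         min_peptides_range = as.integer(min_peptides_range),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

default_condition_names <- function(n_conditions) {
  if (n_conditions == 4L) {
    c("Ctrl", "BirA", "RasBirA", "YkiBirA")
  } else {
    c("Ctrl", paste0("cond", seq_len(n_conditions - 1L) + 1L))
  }
}

#' Tridiagonal TMT isotope impurity matrix
#'
#' Builds the channel-mixing matrix used by the simulator: column `j`
#' gives the fraction of channel `j`'s true signal observed in each
#' channel. A fraction `offdiag` of each channel's signal leaks into each
#' adjacent channel (one neighbour at the plex edges); the diagonal keeps
#' the remainder so every column sums to 1.
#'
#' @param n_channels Number of channels.
#' @param offdiag Leak fraction per adjacent channel (in `[0, 0.5)`).
#' @return An `n_channels` x `n_channels` numeric matrix.
#' @export
tmt_impurity_matrix <- function(n_channels, offdiag = 0.03) {
  if (offdiag < 0 || offdiag >= 0.5) stop("'offdiag' must be in [0, 0.5)")
  m <- diag(n_channels)
  if (n_channels > 1L && offdiag > 0) {
    for (j in seq_len(n_channels)) {
      nb <- intersect(c(j - 1L, j + 1L), seq_len(n_channels))
      m[nb, j] <- offdiag
      m[j, j] <- 1 - length(nb) * offdiag
    }
  }
  m
}

#' Apply channel mixing to true intensities
#'
#' Given the true per-channel signal of each protein, returns the observed
#' intensities under the impurity matrix: for each protein,
#' `observed = M %*% true` (column `j` of `M` is the fate of channel `j`'s
#' signal). Missing cells stay missing.
#'
#' @param m A [reporter_matrix] of true intensities.
#' @param impurity Square mixing matrix with dimension equal to the
#'   channel count.
#' @return A [reporter_matrix] of observed (mixed) intensities.
#' @export
apply_mixing <- function(m, impurity) {
  stopifnot(inherits(m, "reporter_matrix"))
  n_ch <- length(m$channel_names)
  if (!is.matrix(impurity) || any(dim(impurity) != n_ch)) {
    stop("'impurity' must be a ", n_ch, " x ", n_ch, " matrix")
  }
  mixed <- m$intensities %*% t(impurity)
  mixed[is.na(m$intensities)] <- NA_real_
  dimnames(mixed) <- dimnames(m$intensities)
  reporter_matrix(mixed, m$n_unique_peptides)
}

#' Simulate a TMT proximity-labeling secretome experiment
#'
#' Generates protein-level reporter-ion intensities with known ground
#' truth. The intensity model is
#' `log2(I) = baseline + condition effect + noise` with per-protein
#' baselines `Normal(20, 2)`, additive `effect_size_log2` for enriched
#' proteins in non-reference conditions, and `Normal(0, noise_sd_log2)`
#' noise per cell. True intensities are then mixed by the impurity matrix
#' and cells are set missing uniformly at random.
#'
#' @param config A [sim_config].
#' @return A list with elements:
#'   \describe{
#'     \item{reporter}{[reporter_matrix] of observed (mixed) intensities.}
#'     \item{design}{[study_design] mapping channels to conditions.}
#'     \item{truth}{`ground_truth` list: `enriched` (protein x
#'       non-reference-condition logical matrix), `true_log2fc` (same
#'       shape, numeric), `control_label` (named character,
#'       `"PC"`/`"NC"`/`"none"`).}
#'     \item{impurity}{The mixing matrix applied.}
#'   }
#' @export
#' @examples
#' sim <- simulate_experiment(sim_config(n_proteins = 50, seed = 1))
#' dim(sim$reporter)
simulate_experiment <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("'config' must be created with sim_config()")
  }
  set.seed(config$seed)
  n <- config$n_proteins
  conds <- default_condition_names(config$n_conditions)
  n_ch <- config$n_conditions * config$n_replicates
  design <- study_design(
    channel = tmtpro_tags(n_ch),
    condition = rep(conds, each = config$n_replicates),
    replicate = rep(seq_len(config$n_replicates), config$n_conditions),
    reference = conds[1]
  )
  ids <- sprintf("P%05d", seq_len(n))

  # control labels: PC and NC disjoint by construction
  label <- rep("none", n)
  idx <- sample.int(n, config$n_pc_controls + config$n_nc_controls)
  label[idx[seq_len(config$n_pc_controls)]] <- "PC"
  if (config$n_nc_controls > 0) {
    label[idx[config$n_pc_controls + seq_len(config$n_nc_controls)]] <- "NC"
  }
  names(label) <- ids

  # enriched set: budget round(frac * n), preferentially 80% of the PCs,
  # remainder from unlabeled proteins, never NCs
  n_enr <- round(config$frac_enriched * n)
  enriched_idx <- integer(0)
  if (n_enr > 0) {
    pc_idx <- which(label == "PC")
    none_idx <- which(label == "none")
    n_from_pc <- min(round(0.8 * length(pc_idx)), n_enr, length(pc_idx))
    take_pc <- if (n_from_pc > 0) sample(pc_idx, n_from_pc) else integer(0)
    n_rest <- min(n_enr - n_from_pc, length(none_idx))
    take_none <- if (n_rest > 0) sample(none_idx, n_rest) else integer(0)
    enriched_idx <- sort(c(take_pc, take_none))
  }
  nonref <- conds[-1]
  enriched <- matrix(FALSE, n, length(nonref), dimnames = list(ids, nonref))
  enriched[enriched_idx, ] <- TRUE
  true_log2fc <- matrix(0, n, length(nonref), dimnames = list(ids, nonref))
  true_log2fc[enriched] <- config$effect_size_log2

  baseline <- stats::rnorm(n, mean = 20, sd = 2)
  log2_true <- matrix(baseline, n, n_ch) +
    matrix(stats::rnorm(n * n_ch, sd = config$noise_sd_log2), n, n_ch)
  for (cond in nonref) {
    cols <- match(condition_channels(design, cond), design$channel)
    log2_true[, cols] <- log2_true[, cols] + true_log2fc[, cond]
  }
  dimnames(log2_true) <- list(ids, design$channel)

  n_pep <- sample(seq(config$min_peptides_range[1],
                      config$min_peptides_range[2]), n, replace = TRUE)
  true_rm <- reporter_matrix(2^log2_true, n_pep)

  impurity <- tmt_impurity_matrix(n_ch, config$impurity_offdiag)
  observed <- apply_mixing(true_rm, impurity)
  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(n * n_ch) < config$missing_rate, n, n_ch)
    observed$intensities[drop] <- NA_real_
  }

  truth <- structure(
    list(enriched = enriched, true_log2fc = true_log2fc,
         control_label = label),
    class = "ground_truth"
  )
  list(reporter = observed, design = design, truth = truth,
       impurity = impurity)
}

#' Extract control gene lists from simulated ground truth
#'
#' @param truth A `ground_truth` object from [simulate_experiment()].
#' @return A list with character vectors `pc` (positive controls,
#'   annotated secreted) and `nc` (negative controls, annotated
#'   transcription factors); always disjoint.
#' @export
simulate_control_lists <- function(truth) {
  if (!inherits(truth, "ground_truth")) {
    stop("'truth' must be a ground_truth object")
  }
  list(
    pc = names(truth$control_label)[truth$control_label == "PC"],
    nc = names(truth$control_label)[truth$control_label == "NC"]
  )
}
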