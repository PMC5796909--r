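#' Simulation configuration for the synthetic stimulation experiment
#'
#' Defines the study conditions emulated by the count generator: a
#' multi-cytokine stimulation design (4 cytokines plus control, two time
#' points, replicate cultures from distinct donor cell lines), negative
#' binomial counts with a trended dispersion, and planted gene classes:
#' a shared up/down signature responding identically to every cytokine at
#' both times, a cytokine-specific class, and a time-flip class whose
#' response reverses sign between the early and late time point.
#'
#' @param n_genes number of genes to simulate.
#' @param n_cell_lines number of donor cell lines (replicate blocks).
#' @param replicates_per_group replicates per (treatment, time) group, one
#'   value per time point. The default `c(2, 3)` reproduces the design of
#'   the emulated study: two cultures at 8 h, three at 24 h, drawn from the
#'   first 2 or 3 cell lines respectively.
#' @param treatments treatment labels; the first is the unstimulated control.
#' @param times time-point labels, early first.
#' @param pi_shared_up,pi_shared_down,pi_specific,pi_timeflip proportions of
#'   genes planted in each response class; must sum to at most 1, the
#'   remainder is null.
#' @param effect_log2fc planted absolute log2 fold change (> 0). The default
#'   2 places true fold changes at 4x, comfortably past the FC > 2 call
#'   threshold used downstream.
#' @param phi0 dispersion intercept of the trend phi(mu) = phi0 + a / mu.
#' @param a dispersion slope of the trend (inverse-mean term).
#' @param cellline_sd standard deviation of gene-by-line Gaussian offsets on
#'   the natural-log scale (cell line is the dominant variance factor in
#'   the emulated study; the offsets are absorbed by the cell-line covariate
#'   in the differential-expression models).
#' @param baseline_logmean_range range (natural log of expected counts at
#'   unit depth) from which per-gene baseline abundances are drawn
#'   log-uniformly.
#' @param depth_fold_range sequencing-depth factors are drawn log-uniformly
#'   over this fold range across samples (default 2-fold).
#' @param seed integer seed; all generators are pure functions of
#'   (config, seed).
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 5000,
                       n_cell_lines = 3,
                       replicates_per_group = c(2, 3),
                       treatments = c("CTL", "IL1B", "IL36A", "IL36B", "IL36G"),
                       times = c("8h", "24h"),
                       pi_shared_up = 0.04,
                       pi_shared_down = 0.01,
                       pi_specific = 0.02,
                       pi_timeflip = 0.01,
                       effect_log2fc = 2,
                       phi0 = 0.04,
                       a = 1,
                       cellline_sd = 0.3,
                       baseline_logmean_range = c(log(50), log(800)),
                       depth_fold_range = 2,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_cell_lines = as.integer(n_cell_lines),
    replicates_per_group = as.integer(replicates_per_group),
    treatments = as.character(treatments), times = as.character(times),
    pi_shared_up = pi_shared_up, pi_shared_down = pi_shared_down,
    pi_specific = pi_specific, pi_timeflip = pi_timeflip,
    effect_log2fc = effect_log2fc, phi0 = phi0, a = a,
    cellline_sd = cellline_sd,
    baseline_logmean_range = baseline_logmean_range,
    depth_fold_range = depth_fold_range, seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  pis <- c(cfg$pi_shared_up, cfg$pi_shared_down, cfg$pi_specific,
           cfg$pi_timeflip)
  if (any(pis < 0)) stop("class proportions must be non-negative")
  if (sum(pis) > 1) stop("class proportions sum to more than 1")
  if (cfg$n_genes < 1 || cfg$n_cell_lines < 1)
    stop("n_genes and n_cell_lines must be at least 1")
  if (cfg$effect_log2fc < 0) stop("effect_log2fc must be non-negative")
  if (cfg$phi0 < 0 || cfg$a < 0) stop("dispersion parameters must be >= 0")
  if (cfg$cellline_sd < 0) stop("cellline_sd must be >= 0")
  if (length(cfg$replicates_per_group) == 1L)
    cfg$replicates_per_group <- rep(cfg$replicates_per_group,
                                    length(cfg$times))
  if (length(cfg$replicates_per_group) != length(cfg$times))
    stop("replicates_per_group must have one entry per time point")
  if (any(cfg$replicates_per_group < 1))
    stop("replicates_per_group must be >= 1")
  if (max(cfg$replicates_per_group) > cfg$n_cell_lines)
    stop("replicates per group cannot exceed the number of cell lines")
  if (length(cfg$treatments) < 2) stop("need a control plus >= 1 treatment")
  if (diff(cfg$baseline_logmean_range) < 0)
    stop("baseline_logmean_range must be an increasing interval")
  if (cfg$depth_fold_range < 1) stop("depth_fold_range must be >= 1")
  invisible(cfg)
}
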