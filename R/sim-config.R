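#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults describe
#' the package's reference simulation: a 500-line cell-line panel over 210
#' genes carrying one drug with 3 parent genes (direct causes of response),
#' 3 child genes (directly impacted by response), 4 confounded bystanders
#' (correlated with response only through a shared parent) and 200
#' unstructured bystander genes.
#'
#' @param n_genes number of genes in the transcriptome.
#' @param n_cell_lines number of screened cell lines in the training panel.
#' @param n_drugs number of drugs in the screen.
#' @param n_parents_per_drug genes with a direct causal effect on each drug's
#'   AUC (parent nodes of the response).
#' @param n_children_per_drug genes generated downstream of each drug's
#'   observed response (child nodes).
#' @param n_confounded_per_drug genes correlated with response only through a
#'   shared parent gene.
#' @param effect_size absolute weight of each parent gene on the raw response
#'   scale; parent signs alternate (+, -, +, ...) so both directions are
#'   always represented.
#' @param noise_sd standard deviation of the additive response noise (raw
#'   scale; gene expression is standard normal per gene).
#' @param missing_fraction fraction of cell-line x drug screen entries set to
#'   missing, completely at random, in [0, 1).
#' @param n_gbm,n_control cohort sizes for simulated patient groups.
#' @param n_sensitive_drugs number of drugs whose parent genes are shifted in
#'   the GBM cohort (true GBM-sensitive "hits"); the remaining drugs are
#'   null. Defaults to all drugs.
#' @param sensitivity_shift mean shift applied to parent-gene expression in
#'   GBM samples, in units of expression SD. The shift is applied as
#'   `-sensitivity_shift * sign(weight)` so that GBM samples image as *more*
#'   sensitive (lower AUC).
#' @param platform_distortion `"none"` or `"monotone"` (per-gene strictly
#'   increasing nonlinear distortion, emulating a platform effect).
#' @param seed integer master seed; identical config + seed gives
#'   byte-identical outputs.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 50, n_cell_lines = 40, n_drugs = 2,
#'                   n_parents_per_drug = 2, n_children_per_drug = 1,
#'                   n_confounded_per_drug = 1, seed = 7)
#' cfg$n_genes
sim_config <- function(n_genes = 210,
                       n_cell_lines = 500,
                       n_drugs = 1,
                       n_parents_per_drug = 3,
                       n_children_per_drug = 3,
                       n_confounded_per_drug = 4,
                       effect_size = 1,
                       noise_sd = 0.5,
                       missing_fraction = 0.1,
                       n_gbm = 80,
                       n_control = 80,
                       n_sensitive_drugs = n_drugs,
                       sensitivity_shift = 1,
                       platform_distortion = c("none", "monotone"),
                       seed = 1L) {
  platform_distortion <- match.arg(platform_distortion)
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_cell_lines = as.integer(n_cell_lines),
    n_drugs = as.integer(n_drugs),
    n_parents_per_drug = as.integer(n_parents_per_drug),
    n_children_per_drug = as.integer(n_children_per_drug),
    n_confounded_per_drug = as.integer(n_confounded_per_drug),
    effect_size = as.numeric(effect_size),
    noise_sd = as.numeric(noise_sd),
    missing_fraction = as.numeric(missing_fraction),
    n_gbm = as.integer(n_gbm),
    n_control = as.integer(n_control),
    n_sensitive_drugs = as.integer(n_sensitive_drugs),
    sensitivity_shift = as.numeric(sensitivity_shift),
    platform_distortion = platform_distortion,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_genes < 1L || n_cell_lines < 2L || n_drugs < 1L)
      stop("configuration error: n_genes, n_cell_lines and n_drugs must be positive", call. = FALSE)
    per_drug <- n_parents_per_drug + n_children_per_drug + n_confounded_per_drug
    if (per_drug > n_genes)
      stop("configuration error: parents + children + confounded per drug exceed n_genes", call. = FALSE)
    if (n_drugs * per_drug > n_genes)
      stop("configuration error: structured genes across drugs (disjoint assignment) exceed n_genes",
           call. = FALSE)
    if (n_parents_per_drug < 1L)
      stop("configuration error: each drug needs at least one parent gene", call. = FALSE)
    if (noise_sd < 0) stop("configuration error: noise_sd must be >= 0", call. = FALSE)
    if (missing_fraction < 0 || missing_fraction >= 1)
      stop("configuration error: missing_fraction must be in [0, 1)", call. = FALSE)
    if (n_sensitive_drugs < 0L || n_sensitive_drugs > n_drugs)
      stop("configuration error: n_sensitive_drugs must be in 0..n_drugs", call. = FALSE)
    if (n_gbm < 1L || n_control < 1L)
      stop("configuration error: cohort sizes must be positive", call. = FALSE)
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic-data configuration\n")
  cat(sprintf("  genes: %d, cell lines: %d, drugs: %d (%d sensitive)\n",
              x$n_genes, x$n_cell_lines, x$n_drugs, x$n_sensitive_drugs))
  cat(sprintf("  per drug: %d parents, %d children, %d confounded\n",
              x$n_parents_per_drug, x$n_children_per_drug, x$n_confounded_per_drug))
  cat(sprintf("  effect size: %g, noise sd: %g, missing: %.0f%%\n",
              x$effect_size, x$noise_sd, 100 * x$missing_fraction))
  cat(sprintf("  cohorts: %d GBM vs %d control, shift %g; platform: %s; seed: %d\n",
              x$n_gbm, x$n_control, x$sensitivity_shift, x$platform_distortion, x$seed))
  invisible(x)
}
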