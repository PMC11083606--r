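# Canned simulation experiments: each runs the pipeline end to end on a
# synthetic configuration with known truth and returns the headline recovery
# metrics. They back both the package's validation suite and the
# reproducibility script.

#' Null calibration of the nomination stage
#'
#' Simulates a panel with zero effect sizes and zero group shift (so every
#' drug is truly null), then evaluates each null drug on its own
#' independently drawn patient cohort (imputation + rank-sum test), making
#' the 200 downstream p-values independent replicates. Reports calibration:
#' the fraction of drugs reaching BH q <= 0.05 (at most alpha up to binomial
#' noise) and the Kolmogorov-Smirnov uniformity p-value of the raw p-values.
#' Sharing one cohort across drugs would leave the marginal p-values uniform
#' but correlated through the common expression draw, which is a property of
#' that cohort, not of the test being calibrated.
#'
#' @param seed integer seed.
#' @param n_drugs number of simulated null drugs.
#' @param n_cell_lines,n_genes,n_per_group problem sizes.
#' @return list: `q05_fraction`, `ks_p`, `n_drugs`.
#' @export
null_calibration_experiment <- function(seed, n_drugs = 200, n_cell_lines = 150,
                                        n_genes = 220, n_per_group = 50) {
  cfg <- sim_config(n_genes = n_genes, n_cell_lines = n_cell_lines,
                    n_drugs = n_drugs, n_parents_per_drug = 1,
                    n_children_per_drug = 0, n_confounded_per_drug = 0,
                    effect_size = 0, noise_sd = 1, missing_fraction = 0,
                    n_gbm = n_per_group, n_control = n_per_group,
                    sensitivity_shift = 0, seed = seed)
  panel <- simulate_cell_line_panel(cfg)
  models <- fit_drug_models(panel$expression, panel$screen)
  p <- vapply(seq_len(n_drugs), function(d) {
    coh <- simulate_patient_cohorts(cfg, panel$truth,
                                    cohort_id = sprintf("null%03d", d))
    imp <- stats::predict(models$models[[d]], coh$expression)
    wilcoxon_rank_sum(imp[coh$labels == "GBM"], imp[coh$labels == "control"])
  }, numeric(1))
  q <- bh_adjust(p)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  list(q05_fraction = mean(q <= 0.05), ks_p = unname(ks$p.value),
       n_drugs = n_drugs)
}

#' Power of consensus drug nomination on a hit-spiked screen
#'
#' Simulates a cell-line panel at the scale of a large public screen
#' (887 lines by default) carrying 100 drugs of which 20 are true
#' GBM-sensitive hits, imputes five clinical cohorts plus one avatar cohort
#' (80 samples per group), nominates per cohort and intersects via the
#' at-least-`min_clinical`-of-clinical plus avatar consensus. The effect-size
#' percentile cut is disabled here (`percentile = 1`): with exactly the
#' engineered hits passing the significance and direction gates, a top-50%
#' cut would cap per-cohort selections at half the hits by construction, so
#' the experiment measures the significance + direction + consensus
#' machinery (see the methods vignette).
#'
#' @param seed base seed; replicates use `seed + 0:(n_seeds - 1)`.
#' @param n_seeds number of independent replicates.
#' @param n_cell_lines training-panel size.
#' @param n_clinical number of clinical cohorts.
#' @param min_clinical consensus threshold.
#' @return list: `recall` (mean fraction of true hits nominated),
#'   `false_nominations` (mean count per replicate), `per_seed` data.frame,
#'   `n_drugs`, `n_hits`.
#' @export
nomination_power_experiment <- function(seed, n_seeds = 10, n_cell_lines = 887,
                                        n_clinical = 5, min_clinical = 3) {
  one <- function(s) {
    cfg <- sim_config(n_genes = 240, n_cell_lines = n_cell_lines, n_drugs = 100,
                      n_parents_per_drug = 2, n_children_per_drug = 0,
                      n_confounded_per_drug = 0, effect_size = 1, noise_sd = 0.5,
                      missing_fraction = 0.1, n_gbm = 80, n_control = 80,
                      n_sensitive_drugs = 20, sensitivity_shift = 1, seed = s)
    panel <- simulate_cell_line_panel(cfg)
    models <- fit_drug_models(panel$expression, filter_drugs(panel$screen))
    ids <- c(sprintf("clinical%d", seq_len(n_clinical)), "avatar")
    recs <- NULL
    for (cid in ids) {
      grp2 <- if (cid == "avatar") "NPC" else "control"
      coh <- simulate_patient_cohorts(cfg, panel$truth, groups = c("GBM", grp2),
                                      cohort_id = cid)
      h <- harmonize_expression(panel$expression, coh$expression)
      recs <- rbind(recs, nominate(stats::predict(models, h$test), coh$labels,
                                   dataset_id = cid, percentile = 1))
    }
    cons <- consensus(recs, clinical_datasets = sprintf("clinical%d", seq_len(n_clinical)),
                      avatar_dataset = "avatar", min_clinical = min_clinical)
    hits <- names(panel$truth$drugs)[vapply(panel$truth$drugs, `[[`, TRUE, "sensitive")]
    nominated <- cons$drug[cons$nominated]
    c(recall = mean(hits %in% nominated),
      false_nominations = sum(!(nominated %in% hits)))
  }
  per_seed <- as.data.frame(t(vapply(seed + seq_len(n_seeds) - 1, one, numeric(2))))
  list(recall = mean(per_seed$recall),
       false_nominations = mean(per_seed$false_nominations),
       per_seed = per_seed, n_drugs = 100, n_hits = 20)
}

#' Held-out imputation fidelity
#'
#' Trains the per-drug ridge models on the reference panel (500 lines) and
#' imputes 200 held-out samples drawn from the same generative model (no
#' group shift); reports the Spearman correlation between imputed and true
#' AUC.
#'
#' @param seed integer seed.
#' @return list: `spearman`, `n_test`.
#' @export
imputation_fidelity_experiment <- function(seed) {
  cfg <- sim_config(seed = seed, n_gbm = 100, n_control = 100,
                    sensitivity_shift = 0)
  panel <- simulate_cell_line_panel(cfg)
  coh <- simulate_patient_cohorts(cfg, panel$truth, cohort_id = "heldout")
  models <- fit_drug_models(panel$expression, filter_drugs(panel$screen))
  h <- harmonize_expression(panel$expression, coh$expression)
  imp <- stats::predict(models, h$test)
  list(spearman = stats::cor(imp[, 1], coh$true_auc[, 1], method = "spearman"),
       n_test = nrow(imp))
}

# Run the biomarker stage on one simulated cohort; returns scored components.
# `response = "true"` analyses the generative per-sample AUC (for scoring
# graph recovery against the generative graph); `response = "imputed"` runs
# the full train-harmonize-impute path first. The imputed score is a
# deterministic function of expression, so genes generated downstream of the
# *observed* response are conditionally independent of it given the parents;
# graph-recovery metrics are therefore defined against the true response.
run_biomarker_stage <- function(seed, n_per_group, r_min = 0.30,
                                response = c("true", "imputed")) {
  response <- match.arg(response)
  cfg <- sim_config(seed = seed, n_gbm = n_per_group, n_control = n_per_group,
                    sensitivity_shift = 0)
  panel <- simulate_cell_line_panel(cfg)
  coh <- simulate_patient_cohorts(cfg, panel$truth, cohort_id = "biomarker")
  if (response == "imputed") {
    models <- fit_drug_models(panel$expression, filter_drugs(panel$screen))
    h <- harmonize_expression(panel$expression, coh$expression)
    y <- stats::predict(models, h$test)[, 1]
  } else {
    y <- coh$true_auc[, 1]
  }
  filt <- scc_filter(coh$expression, y, r_min = r_min)
  cand <- coh$expression[filt$gene[filt$retained], , drop = FALSE]
  pc <- mmpc(y, cand)
  list(truth = panel$truth$drugs[[1]], response = y, filter = filt,
       candidates = cand, pc = pc)
}

#' Parent-child set recovery of the causal-biomarker stage
#'
#' On the reference causal configuration (3 parents, 3 children, 4 confounded
#' bystanders, 200 unstructured genes, 500 samples), runs imputation, the
#' Spearman pre-filter (|r| >= 0.30; see the methods vignette for why several
#' independent parents bound each parent's marginal correlation) and MMPC,
#' then scores the recovered PC set against the true parents and children.
#'
#' @param seed base seed; replicates use `seed + 0:(n_seeds - 1)`.
#' @param n_seeds number of replicates.
#' @param n_per_group cohort group size (total samples = 2x this).
#' @return list: `mean_f1`, `confounded_retention` (fraction of confounded
#'   genes appearing in PC sets across replicates), `per_seed` data.frame.
#' @export
causal_recovery_experiment <- function(seed, n_seeds = 20, n_per_group = 250) {
  one <- function(s) {
    st <- run_biomarker_stage(s, n_per_group)
    truth_pc <- c(names(st$truth$parent_weights), names(st$truth$child_weights))
    got <- st$pc$pc$gene
    tp <- length(intersect(got, truth_pc))
    c(f1 = 2 * tp / (length(got) + length(truth_pc)),
      confounded = mean(names(st$truth$confounded_weights) %in% got))
  }
  per_seed <- as.data.frame(t(vapply(seed + seq_len(n_seeds) - 1, one, numeric(2))))
  list(mean_f1 = mean(per_seed$f1),
       confounded_retention = mean(per_seed$confounded),
       per_seed = per_seed)
}

#' Precision of parental-node calls under collider orientation
#'
#' As [causal_recovery_experiment()] but at 2000 samples per cohort, adding
#' the PC-style orientation stage; reports the precision of parental calls
#' (called parents that are true parents) pooled over replicates.
#'
#' @param seed base seed; replicates use `seed + 0:(n_seeds - 1)`.
#' @param n_seeds number of replicates.
#' @return list: `precision`, `n_calls`, `per_seed` data.frame.
#' @export
orientation_precision_experiment <- function(seed, n_seeds = 8) {
  one <- function(s) {
    st <- run_biomarker_stage(s, n_per_group = 1000)
    ori <- orient_parents(st$response, st$pc, st$candidates)
    c(tp = sum(ori$parental_genes %in% names(st$truth$parent_weights)),
      called = length(ori$parental_genes))
  }
  per_seed <- as.data.frame(t(vapply(seed + seq_len(n_seeds) - 1, one, numeric(2))))
  n_calls <- sum(per_seed$called)
  list(precision = if (n_calls > 0) sum(per_seed$tp) / n_calls else NA_real_,
       n_calls = n_calls, per_seed = per_seed)
}

#' Directionality of a positive-weight parent gene
#'
#' Runs the full biomarker stage (train, harmonize, impute, filter, MMPC,
#' orient) on one simulated cohort and checks the
#' report row of a parent gene with a positive causal weight on AUC: it
#' should be called parental with the label "high expression -> resistance"
#' (higher AUC = less sensitive).
#'
#' @param seed integer seed.
#' @return list: `gene`, `weight`, `is_pc`, `parental`, `direction`,
#'   `correct` (logical: parental call + resistance label).
#' @export
directionality_experiment <- function(seed) {
  st <- run_biomarker_stage(seed, n_per_group = 500, response = "imputed")
  ori <- orient_parents(st$response, st$pc, st$candidates)
  rep_tbl <- biomarker_report(st$filter, st$pc, ori)
  pos <- names(st$truth$parent_weights)[st$truth$parent_weights > 0][1]
  row <- rep_tbl[rep_tbl$gene == pos, , drop = FALSE]
  found <- nrow(row) == 1
  list(gene = pos, weight = unname(st$truth$parent_weights[[pos]]),
       is_pc = found && row$is_pc,
       parental = found && isTRUE(row$parental),
       direction = if (found) row$direction else NA_character_,
       correct = found && isTRUE(row$parental) &&
         identical(row$direction, "high expression -> resistance"))
}

#' Measured dose-response comparison on synthetic viability data
#'
#' Simulates the reference viability assay (six GBM vs six NPC samples, nine
#' doses, six replicates), computes per-sample trapezoidal AUC on the log10
#' axis and compares groups by rank-sum test and Hodges-Lehmann shift.
#'
#' @param seed integer seed.
#' @return list: `p`, `hle`, `n_samples`.
#' @export
dose_response_experiment <- function(seed) {
  dr <- simulate_dose_response(seed = seed)
  aucs <- auc_by_sample(dr$measurements)
  cmp <- compare_measured(aucs$auc, aucs$group)
  list(p = cmp$p, hle = cmp$hle, n_samples = nrow(aucs))
}
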