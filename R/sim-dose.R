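#' Simulate dose-response viability (relative ATP) measurements
#'
#' Emulates a CellTiter-style viability assay: nine doses log10-equally
#' spaced across 0.015-100 nM, six technical replicates per dose, relative
#' ATP (percent of untreated control) drawn from a four-parameter logistic in
#' log10-dose plus replicate noise. GBM-like samples get low EC50s (sensitive);
#' NPC-like controls get EC50s above the tested range (resistant). The true
#' noise-free trapezoidal AUC on the log10-dose axis is recorded per sample.
#'
#' @param n_gbm,n_npc numbers of GBM and NPC samples.
#' @param doses dose grid in nM, strictly increasing; default nine points
#'   log10-spaced over 0.015-100 nM.
#' @param n_replicates technical replicates per dose (default 6).
#' @param ec50_gbm,ec50_npc EC50s in nM for the two groups.
#' @param hill Hill slope of the logistic (in log10-dose).
#' @param bottom lower viability asymptote, percent.
#' @param top upper viability asymptote, percent (100 = untreated control).
#' @param atp_noise_sd replicate noise SD in ATP percentage points.
#' @param drug drug label carried in the output.
#' @param seed integer seed.
#' @return list with `measurements` (long data.frame: sample_id, group, drug,
#'   dose_nM, replicate, relative_atp) and `truth` (data.frame: sample_id,
#'   group, ec50, true_auc — the noise-free log10-axis trapezoidal AUC).
#' @export
simulate_dose_response <- function(n_gbm = 6, n_npc = 6,
                                   doses = 10^seq(log10(0.015), log10(100), length.out = 9),
                                   n_replicates = 6,
                                   ec50_gbm = 1, ec50_npc = 500,
                                   hill = 1, bottom = 10, top = 100,
                                   atp_noise_sd = 5,
                                   drug = "drug001", seed = 1L) {
  stopifnot(length(doses) >= 2, all(diff(doses) > 0), n_replicates >= 1)
  ids <- c(sprintf("GBM_%02d", seq_len(n_gbm)), sprintf("NPC_%02d", seq_len(n_npc)))
  grp <- rep(c("GBM", "NPC"), c(n_gbm, n_npc))
  ec50 <- with_stream(seed, "dose:ec50", {
    # modest lognormal sample-to-sample EC50 spread
    c(ec50_gbm * exp(stats::rnorm(n_gbm, sd = 0.2)),
      ec50_npc * exp(stats::rnorm(n_npc, sd = 0.2)))
  })
  lx <- log10(doses)
  curves <- vapply(ec50, function(e) logistic4(lx, log10(e), hill, bottom, top),
                   numeric(length(doses)))
  true_auc <- apply(curves, 2, function(y) pracma::trapz(lx, y))

  grid <- expand.grid(replicate = seq_len(n_replicates),
                      dose_idx = seq_along(doses),
                      sample_idx = seq_along(ids))
  noise <- with_stream(seed, "dose:noise", {
    stats::rnorm(nrow(grid), sd = atp_noise_sd)
  })
  measurements <- data.frame(
    sample_id = ids[grid$sample_idx],
    group = grp[grid$sample_idx],
    drug = drug,
    dose_nM = doses[grid$dose_idx],
    replicate = grid$replicate,
    relative_atp = curves[cbind(grid$dose_idx, grid$sample_idx)] + noise,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(sample_id = ids, group = grp, ec50 = ec50,
                      true_auc = true_auc, stringsAsFactors = FALSE)
  list(measurements = measurements, truth = truth)
}

# 4-parameter logistic on the log10-dose axis: decreasing viability with dose
logistic4 <- function(log10_dose, log10_ec50, hill, bottom, top) {
  bottom + (top - bottom) / (1 + 10^(hill * (log10_dose - log10_ec50)))
}
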