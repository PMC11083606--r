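#' Simulate a patient (or avatar) cohort with group structure
#'
#' Draws a genes x samples expression matrix for a two-group cohort and the
#' matching ground-truth drug responses. For every *sensitive* drug in the
#' truth, GBM samples have each parent gene's mean shifted by
#' `-sensitivity_shift * sign(weight)`, so the true (and, downstream, the
#' imputed) AUC of GBM samples is lower, i.e. GBM images as more sensitive.
#' Control/NPC samples are unshifted.
#'
#' Child genes are generated as `weight * response + noise` — downstream of
#' the *observed* response, so they correlate with it (and remain dependent
#' given the parents) without causing it. Confounded genes are generated as
#' `weight * parent + noise` from one shared parent gene, so they correlate
#' with response marginally but are conditionally independent of it given
#' that parent.
#'
#' @param config a [sim_config()]; cohort sizes and shift are taken from it.
#' @param truth a `sim_truth` from [simulate_cell_line_panel()].
#' @param groups length-2 character vector naming the shifted group and the
#'   unshifted group (the first is treated as GBM-like; the second may be
#'   `"control"`, `"non-HGG"` or `"NPC"`).
#' @param cohort_id character tag used both in sample IDs and to decorrelate
#'   this cohort's random substream from other cohorts of the same config.
#' @return list with `expression` (genes x samples), `labels` (named factor
#'   of group per sample), and `true_auc` (samples x drugs matrix on the
#'   screen's 10-20 AUC scale).
#' @export
simulate_patient_cohorts <- function(config, truth,
                                     groups = c("GBM", "control"),
                                     cohort_id = "cohort1") {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  if (length(groups) != 2L || anyDuplicated(groups))
    stop("groups must be two distinct labels (shifted group first)", call. = FALSE)
  n <- config$n_gbm + config$n_control
  genes <- truth$genes
  samples <- sprintf("%s_S%04d", cohort_id, seq_len(n))
  labels <- stats::setNames(factor(rep(groups, c(config$n_gbm, config$n_control)),
                                   levels = groups), samples)
  is_shifted <- labels == groups[1]

  stream <- paste0("cohort:", cohort_id)
  expr <- with_stream(config$seed, paste0(stream, ":expression"), {
    matrix(stats::rnorm(length(genes) * n), nrow = length(genes),
           dimnames = list(genes, samples))
  })

  # group shift on parent genes of sensitive drugs: GBM imputes as more
  # sensitive (lower AUC)
  for (d in truth$drugs) {
    if (!isTRUE(d$sensitive) || config$sensitivity_shift == 0) next
    for (g in names(d$parent_weights)) {
      expr[g, is_shifted] <- expr[g, is_shifted] -
        config$sensitivity_shift * sign(d$parent_weights[[g]])
    }
  }

  drugs <- names(truth$drugs)
  true_auc <- matrix(NA_real_, nrow = n, ncol = length(drugs),
                     dimnames = list(samples, drugs))
  noise <- with_stream(config$seed, paste0(stream, ":response-noise"), {
    matrix(stats::rnorm(n * length(drugs), sd = config$noise_sd), nrow = n)
  })
  aux <- with_stream(config$seed, paste0(stream, ":gene-noise"), {
    matrix(stats::rnorm(length(genes) * n), nrow = length(genes),
           dimnames = list(genes, samples))
  })
  for (di in seq_along(drugs)) {
    d <- truth$drugs[[di]]
    w <- d$parent_weights
    raw <- drop(crossprod(expr[names(w), , drop = FALSE], w)) + noise[, di]
    # children: linear in the observed (noisy) raw response
    for (g in names(d$child_weights)) {
      expr[g, ] <- d$child_weights[[g]] * raw + aux[g, ]
    }
    # confounded: linear in one shared parent only
    for (g in names(d$confounded_weights)) {
      expr[g, ] <- d$confounded_weights[[g]] * expr[d$confounded_parent[[g]], ] + aux[g, ]
    }
    true_auc[, di] <- apply_rescale(raw, d$rescale)
  }
  list(expression = expr, labels = labels, true_auc = true_auc)
}
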