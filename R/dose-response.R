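#' Dose-response curve container
#'
#' @param doses dose grid in nM, strictly increasing, length >= 2.
#' @param atp relative-ATP measurements, percent of control: a replicates x
#'   doses matrix, or a vector with one value per dose.
#' @param sample_id,drug identifiers carried along.
#' @return object of class `dose_curve`.
#' @export
dose_response_curve <- function(doses, atp, sample_id = NA_character_,
                                drug = NA_character_) {
  if (length(doses) < 2) stop("need at least 2 doses", call. = FALSE)
  if (any(diff(doses) <= 0)) stop("doses must be strictly increasing", call. = FALSE)
  if (is.vector(atp)) atp <- matrix(atp, nrow = 1)
  stopifnot(is.matrix(atp))
  if (ncol(atp) != length(doses))
    stop("atp must have one column per dose", call. = FALSE)
  structure(list(doses = doses, atp = atp, sample_id = sample_id, drug = drug),
            class = "dose_curve")
}

#' Trapezoidal area under a dose-response curve
#'
#' Technical replicates are averaged per dose, then the relative-ATP curve is
#' integrated by the trapezoidal rule over the chosen dose axis. The default
#' log10 axis reflects that typical viability designs span several decades of
#' dose; on a linear axis the top dose would dominate the integral. Lower AUC
#' means more drug-sensitive.
#'
#' @param curve a [dose_response_curve()].
#' @param axis `"log10_dose"` (default) or `"linear_dose"`.
#' @return the AUC (scalar; percent x axis units).
#' @export
auc_trapezoid <- function(curve, axis = c("log10_dose", "linear_dose")) {
  axis <- match.arg(axis)
  stopifnot(inherits(curve, "dose_curve"))
  ybar <- colMeans(curve$atp)
  x <- if (axis == "log10_dose") log10(curve$doses) else curve$doses
  pracma::trapz(x, ybar)
}

#' Per-sample trapezoidal AUC from long-format viability data
#'
#' @param measurements data.frame with columns `sample_id`, `dose_nM`,
#'   `relative_atp` (and optionally `group`), e.g. the output of
#'   [simulate_dose_response()].
#' @param axis integration axis, see [auc_trapezoid()].
#' @return data.frame: sample_id, (group,) auc.
#' @export
auc_by_sample <- function(measurements, axis = "log10_dose") {
  stopifnot(all(c("sample_id", "dose_nM", "relative_atp") %in% names(measurements)))
  ids <- unique(measurements$sample_id)
  auc <- vapply(ids, function(s) {
    sub <- measurements[measurements$sample_id == s, ]
    doses <- sort(unique(sub$dose_nM))
    ybar <- vapply(doses, function(d) mean(sub$relative_atp[sub$dose_nM == d]),
                   numeric(1))
    auc_trapezoid(dose_response_curve(doses, ybar, sample_id = s), axis = axis)
  }, numeric(1))
  out <- data.frame(sample_id = ids, auc = auc, row.names = NULL,
                    stringsAsFactors = FALSE)
  if ("group" %in% names(measurements))
    out$group <- measurements$group[match(ids, measurements$sample_id)]
  out
}

#' Compare measured AUC between two groups
#'
#' Wilcoxon rank-sum p-value and Hodges-Lehmann location shift of measured
#' AUC between a GBM-like group and a control group (e.g. NPC), mirroring the
#' imputed-response comparison.
#'
#' @param auc numeric AUC per sample.
#' @param labels group label per sample.
#' @param gbm_level label of the GBM-like group (shift = GBM minus control).
#' @param mode Wilcoxon mode, see [wilcoxon_rank_sum()].
#' @return list with `p` and `hle`.
#' @export
compare_measured <- function(auc, labels, gbm_level = "GBM", mode = "auto") {
  stopifnot(length(auc) == length(labels))
  is_gbm <- as.character(labels) == gbm_level
  if (!any(is_gbm) || all(is_gbm)) stop("both groups must be non-empty", call. = FALSE)
  list(p = wilcoxon_rank_sum(auc[is_gbm], auc[!is_gbm], mode = mode),
       hle = hodges_lehmann(auc[is_gbm], auc[!is_gbm]))
}
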