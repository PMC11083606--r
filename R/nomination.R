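#' Two-sided Wilcoxon rank-sum p-value
#'
#' Thin wrapper around [stats::wilcox.test()] with an explicit mode contract:
#' `"exact"` uses the exact null distribution (valid when there are no ties);
#' `"normal"` uses the tie-corrected normal approximation with continuity
#' correction; `"auto"` (default) picks exact when both groups have at most
#' 10 observations and there are no ties, normal otherwise.
#'
#' @param x,y numeric vectors (e.g. imputed AUC in GBM vs control samples).
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(x) < 1 || length(y) < 1) stop("empty group", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- switch(mode,
                  exact = TRUE,
                  normal = FALSE,
                  auto = length(x) <= 10 && length(y) <= 10 && !ties)
  if (exact && ties) {
    warning("ties present; falling back to the tie-corrected normal approximation",
            call. = FALSE)
    exact <- FALSE
  }
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment via [stats::p.adjust()]; input checked to lie in
#' \[0, 1\]. `NA` p-values propagate as `NA`.
#'
#' @param p numeric vector of p-values.
#' @return vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  ok <- is.na(p) | (p >= 0 & p <= 1)
  if (!all(ok)) stop("p-values must be in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Hodges-Lehmann two-sample location shift
#'
#' The median of all pairwise differences `x_i - y_j`: a robust effect size
#' for the shift of `x` relative to `y`. With `x` = GBM and `y` = control
#' imputed AUC, a negative value means GBM is predicted more sensitive.
#'
#' @param x,y numeric vectors.
#' @return the Hodges-Lehmann estimate (scalar).
#' @export
hodges_lehmann <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) stop("empty group", call. = FALSE)
  stats::median(outer(x, y, "-"))
}

# Selection rule shared by nominate(): significance gate, direction gate,
# then the top `percentile` most-negative HLEs among the passing drugs
# (inclusive ceiling, so a lone passing drug is selected; ties at the
# boundary value are all included).
select_candidates <- function(q, hle, alpha = 0.05, percentile = 0.5,
                              percentile_scope = c("directional", "all_significant")) {
  percentile_scope <- match.arg(percentile_scope)
  sig <- !is.na(q) & q <= alpha
  directional <- sig & hle < 0
  fam <- if (percentile_scope == "directional") directional else sig
  n_pass <- sum(fam)
  if (n_pass == 0) return(rep(FALSE, length(q)))
  k <- ceiling(percentile * n_pass)
  ranked <- if (percentile_scope == "directional") hle else -abs(hle)
  cutoff <- sort(ranked[fam])[k]
  directional & fam & ranked <= cutoff
}

#' Nominate drugs for one GBM-vs-control comparison
#'
#' Per drug: two-sided Wilcoxon rank-sum p between the two groups of imputed
#' AUC, Benjamini-Hochberg q across all drugs in the dataset, and the
#' Hodges-Lehmann location shift (GBM minus control). A drug is *selected*
#' when q <= `alpha`, its shift is negative (GBM more sensitive), and its
#' shift lies in the most-negative `percentile` fraction of drugs passing the
#' first two gates (inclusive ceiling; boundary ties included).
#'
#' @param imputed samples x drugs matrix of imputed AUC.
#' @param labels factor/character per sample; `gbm_level` vs everything else.
#' @param dataset_id identifier recorded in the output.
#' @param gbm_level label of the GBM-like group (default `"GBM"`).
#' @param alpha FDR threshold (default 0.05).
#' @param percentile fraction of passing drugs kept by effect size (0.5 =
#'   the conventional top 50th percentile of largest shifts).
#' @param percentile_scope family within which the percentile is computed:
#'   `"directional"` (drugs passing significance *and* direction; default) or
#'   `"all_significant"` (all q-passing drugs, ranked by |shift|; the final
#'   selection still requires a negative shift).
#' @param mode Wilcoxon mode passed to [wilcoxon_rank_sum()].
#' @return data.frame of class `nomination_record`: drug, dataset, p, q, hle,
#'   selected.
#' @export
nominate <- function(imputed, labels, dataset_id = "dataset1",
                     gbm_level = "GBM", alpha = 0.05, percentile = 0.5,
                     percentile_scope = "directional",
                     mode = "auto") {
  stopifnot(is.matrix(imputed), nrow(imputed) == length(labels))
  is_gbm <- as.character(labels) == gbm_level
  if (!any(is_gbm) || all(is_gbm))
    stop("both groups must be non-empty", call. = FALSE)
  if (ncol(imputed) < 1) stop("need at least one drug", call. = FALSE)
  drugs <- colnames(imputed) %||% sprintf("drug%03d", seq_len(ncol(imputed)))
  p <- vapply(seq_len(ncol(imputed)), function(j)
    wilcoxon_rank_sum(imputed[is_gbm, j], imputed[!is_gbm, j], mode = mode),
    numeric(1))
  hle <- vapply(seq_len(ncol(imputed)), function(j)
    hodges_lehmann(imputed[is_gbm, j], imputed[!is_gbm, j]), numeric(1))
  q <- bh_adjust(p)
  out <- data.frame(drug = drugs, dataset = dataset_id, p = p, q = q, hle = hle,
                    selected = select_candidates(q, hle, alpha, percentile,
                                                 percentile_scope),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("nomination_record", "data.frame")
  out
}

#' Consensus drug nomination across datasets
#'
#' A drug is nominated when it is selected in at least `min_clinical` of the
#' clinical datasets and (if `require_avatar`) also selected in the avatar
#' dataset. Drugs passing the clinical consensus but failing the avatar check
#' are reported separately (`clinical_only`).
#'
#' @param records a `nomination_record` data.frame (or rbind of several), one
#'   row per drug per dataset.
#' @param clinical_datasets character vector of clinical dataset IDs.
#' @param avatar_dataset avatar dataset ID, or `NULL` when
#'   `require_avatar = FALSE`.
#' @param min_clinical minimum number of clinical datasets a drug must be
#'   selected in (default 3, i.e. a majority of five).
#' @param require_avatar must the drug also be selected in the avatar data?
#' @return data.frame of class `consensus_result`: drug, n_clinical_passed,
#'   avatar_passed, nominated, clinical_only.
#' @export
consensus <- function(records, clinical_datasets, avatar_dataset = NULL,
                      min_clinical = 3, require_avatar = TRUE) {
  stopifnot(is.data.frame(records),
            all(c("drug", "dataset", "selected") %in% names(records)))
  if (length(clinical_datasets) == 0)
    stop("no clinical datasets supplied", call. = FALSE)
  if (require_avatar && is.null(avatar_dataset))
    stop("require_avatar = TRUE needs an avatar_dataset", call. = FALSE)
  drugs <- sort(unique(records$drug))
  clin <- records[records$dataset %in% clinical_datasets & records$selected, ]
  n_clin <- vapply(drugs, function(d) sum(clin$drug == d), integer(1))
  if (!is.null(avatar_dataset)) {
    av <- records[records$dataset == avatar_dataset & records$selected, ]
    av_pass <- drugs %in% av$drug
  } else {
    av_pass <- rep(NA, length(drugs))
  }
  clin_ok <- n_clin >= min_clinical
  nominated <- clin_ok & (if (require_avatar) av_pass else TRUE)
  out <- data.frame(drug = drugs, n_clinical_passed = n_clin,
                    avatar_passed = av_pass, nominated = nominated,
                    clinical_only = clin_ok & !nominated,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("consensus_result", "data.frame")
  out
}

#' @export
print.consensus_result <- function(x, ...) {
  nom <- x$drug[x$nominated]
  cat(sprintf("Consensus over %d drugs: %d nominated", nrow(x), length(nom)))
  if (length(nom)) cat(": ", paste(utils::head(nom, 10), collapse = ", "),
                       if (length(nom) > 10) ", ..." else "", sep = "")
  cat("\n")
  co <- sum(x$clinical_only)
  if (co) cat(sprintf("  %d drug(s) passed the clinical consensus but not the avatar check\n", co))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("  ... and %d more drugs\n", nrow(x) - 10))
  invisible(x)
}
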