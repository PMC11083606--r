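#' Remove sparsely screened drugs from a drug screen
#'
#' Drugs screened across fewer than `min_fraction` of all cell lines are
#' removed (strict inequality: a drug screened in exactly `min_fraction` of
#' lines is retained), ensuring each retained drug has enough training lines
#' for a robust model. Cell lines are never removed.
#'
#' @param screen cell-lines x drugs numeric matrix, `NA` = not screened.
#' @param min_fraction minimum fraction of lines screened, in (0, 1].
#' @return the screen restricted to retained drugs.
#' @export
filter_drugs <- function(screen, min_fraction = 0.40) {
  stopifnot(is.matrix(screen))
  if (nrow(screen) == 0 || ncol(screen) == 0)
    stop("empty drug screen", call. = FALSE)
  if (!(min_fraction > 0 && min_fraction <= 1))
    stop("min_fraction must be in (0, 1]", call. = FALSE)
  frac <- colMeans(!is.na(screen))
  keep <- frac >= min_fraction
  if (!any(keep))
    warning("all drugs removed by the coverage filter", call. = FALSE)
  screen[, keep, drop = FALSE]
}

#' Harmonize a test expression matrix against a training matrix
#'
#' Cross-platform integration by per-gene rank-to-quantile mapping: both
#' matrices are restricted to their shared genes (identical order), and each
#' test gene's values are replaced by the training distribution's empirical
#' quantiles at the test values' rank positions (`(rank - 0.5) / m`,
#' piecewise-linear empirical quantile). Training values are unchanged. Any
#' per-gene strictly monotone platform distortion is removed exactly up to
#' interpolation, while the within-gene rank information consumed by the
#' downstream Spearman and rank-sum statistics is preserved.
#'
#' @param train,test genes x samples numeric matrices with gene row names.
#' @return list with elements `train` and `test`, both restricted to the
#'   shared genes; `test` is quantile-mapped onto `train`.
#' @export
harmonize_expression <- function(train, test) {
  stopifnot(is.matrix(train), is.matrix(test))
  shared <- intersect(rownames(train), rownames(test))
  if (length(shared) == 0)
    stop(sprintf("no shared gene IDs between train (e.g. %s) and test (e.g. %s)",
                 paste(utils::head(rownames(train), 3), collapse = ","),
                 paste(utils::head(rownames(test), 3), collapse = ",")), call. = FALSE)
  tr <- train[shared, , drop = FALSE]
  te <- test[shared, , drop = FALSE]
  m <- ncol(te)
  for (g in seq_along(shared)) {
    r <- rank(te[g, ], ties.method = "average")
    te[g, ] <- stats::quantile(tr[g, ], probs = (r - 0.5) / m, type = 5, names = FALSE)
  }
  list(train = tr, test = te)
}

#' Fit per-drug ridge models on a screened cell-line panel
#'
#' One [fit_ridge()] model per drug, trained only on the cell lines screened
#' for that drug. Drugs whose training size falls below `min_train` are still
#' fitted but flagged in the returned metadata.
#'
#' @param expr genes x cell-lines training expression.
#' @param screen cell-lines x drugs AUC matrix (`NA` = unscreened), typically
#'   after [filter_drugs()].
#' @param min_train flag drugs trained on fewer lines than this.
#' @inheritParams fit_ridge
#' @return object of class `drug_model_set`: list of `ridge_model`s (`models`)
#'   plus a per-drug metadata data.frame (`info`).
#' @export
fit_drug_models <- function(expr, screen,
                            lambda_mode = c("loo", "fixed"), lambda = NULL,
                            min_train = 20) {
  lambda_mode <- match.arg(lambda_mode)
  stopifnot(is.matrix(expr), is.matrix(screen))
  if (!identical(colnames(expr), rownames(screen)))
    stop("screen rows must match expression columns (same cell lines, same order)",
         call. = FALSE)
  drugs <- colnames(screen)
  models <- lapply(drugs, function(d)
    fit_ridge(expr, screen[, d], lambda_mode = lambda_mode, lambda = lambda))
  names(models) <- drugs
  info <- data.frame(
    drug = drugs,
    n_train = vapply(models, `[[`, integer(1), "n_train"),
    lambda = vapply(models, `[[`, numeric(1), "lambda"),
    low_n_flag = vapply(models, function(m) m$n_train < min_train, logical(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(models = models, info = info, lambda_mode = lambda_mode),
            class = "drug_model_set")
}

#' @export
print.drug_model_set <- function(x, ...) {
  cat(sprintf("Drug model set: %d ridge models (%s penalty)\n",
              length(x$models), x$lambda_mode))
  print(utils::head(x$info, 10))
  if (nrow(x$info) > 10) cat(sprintf("  ... and %d more drugs\n", nrow(x$info) - 10))
  invisible(x)
}

#' Impute drug response for a cohort from a fitted model set
#'
#' @param object a `drug_model_set`.
#' @param newdata genes x samples expression matrix, harmonized against the
#'   training panel.
#' @param ... unused.
#' @return samples x drugs matrix of imputed AUC (no missing entries); lower
#'   = predicted more sensitive. Carries the lambda mode as attribute
#'   `"provenance"`.
#' @export
predict.drug_model_set <- function(object, newdata, ...) {
  out <- vapply(object$models, function(m) predict(m, newdata),
                numeric(ncol(newdata)))
  if (is.null(dim(out)))  # single test sample
    out <- matrix(out, nrow = 1, dimnames = list(colnames(newdata), names(object$models)))
  attr(out, "provenance") <- paste0("ridge/", object$lambda_mode)
  out
}

#' Impute drug response (alias)
#'
#' Convenience wrapper around [predict.drug_model_set()] mirroring the
#' pipeline vocabulary.
#'
#' @inheritParams predict.drug_model_set
#' @param models a `drug_model_set` or single `ridge_model`.
#' @param test_expr genes x samples expression matrix.
#' @return samples x drugs imputed AUC matrix (or vector for a single model).
#' @export
impute_response <- function(models, test_expr) {
  stats::predict(models, test_expr)
}

#' Per-gene Spearman correlation with imputed drug response
#'
#' For one drug, correlates every gene's expression with the samples' imputed
#' AUC using Spearman's rank correlation, with the tie-aware t-approximation
#' p-value and Benjamini-Hochberg adjustment across all genes. Constant genes
#' have undefined correlation and are reported as `NA` with a warning.
#'
#' @param expr genes x samples expression matrix.
#' @param response numeric imputed AUC per sample (same order as columns).
#' @return data.frame: gene, r (Spearman), p, q (BH across genes).
#' @export
gene_response_correlation <- function(expr, response) {
  stopifnot(is.matrix(expr), ncol(expr) == length(response))
  n <- length(response)
  if (n < 4) stop("need at least 4 samples", call. = FALSE)
  rr <- spearman_vs_response(expr, response)
  data.frame(gene = rownames(expr), r = rr$r, p = rr$p,
             q = bh_adjust(rr$p), row.names = NULL, stringsAsFactors = FALSE)
}

# vectorized Spearman of each matrix row against `response`; t-approximation
# p-values (the tie-aware asymptotic test); constant rows -> NA + warning
spearman_vs_response <- function(expr, response) {
  n <- length(response)
  const <- apply(expr, 1, function(z) max(z) - min(z) < .Machine$double.eps)
  ranks <- t(apply(expr, 1, rank))
  ry <- rank(response)
  r <- suppressWarnings(drop(stats::cor(t(ranks), ry)))
  r[const] <- NA_real_
  if (any(const))
    warning(sprintf("%d constant gene(s) have undefined correlation (reported NA)",
                    sum(const)), call. = FALSE)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[is.finite(r) & abs(r) >= 1 - 1e-12] <- 0
  list(r = r, p = p)
}
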