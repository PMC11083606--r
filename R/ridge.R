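#' Fit a ridge-regression drug-response model
#'
#' Fits `y = intercept + x' beta` with an L2 penalty on `beta`, the model
#' used to transfer cell-line drug screens onto tumor transcriptomes. Genes
#' are centered and unit-scaled on the training data and the response is
#' centered, so the penalty is comparable across drugs; the intercept is the
#' training mean of the response. Cell lines with missing response are
#' dropped before fitting, so adding unscreened lines never changes a drug's
#' model. The solution is computed through the thin SVD of the standardized
#' design, which also yields the exact leave-one-out (LOO) error for every
#' candidate penalty at no extra cost; by default the penalty minimizing LOO
#' mean-squared error is selected.
#'
#' @param train_expr genes x cell-lines numeric matrix (log-scale expression).
#' @param auc numeric response per cell line (AUC); may contain `NA`.
#' @param lambda_mode `"loo"` (closed-form leave-one-out selection over
#'   `lambda_grid`) or `"fixed"` (use `lambda` as given).
#' @param lambda fixed penalty (required when `lambda_mode = "fixed"`).
#' @param lambda_grid candidate penalties for LOO selection.
#' @return an object of class `ridge_model` with elements `intercept`,
#'   `beta` (named, on the standardized-gene scale), `center`, `scale`,
#'   `genes`, `lambda`, `n_train`, `loo` (grid and LOO MSE, when selected)
#'   and `dropped_genes` (zero-variance genes excluded from the fit).
#' @seealso [predict.ridge_model()], [coef.ridge_model()], [fit_drug_models()]
#' @export
#' @examples
#' X <- matrix(rnorm(40), nrow = 2, dimnames = list(c("g1", "g2"), NULL))
#' y <- 2 * X[1, ] - X[2, ] + rnorm(20, sd = 0.01)
#' m <- fit_ridge(X, y, lambda_mode = "fixed", lambda = 1e-6)
#' coef(m, scale = "original")
fit_ridge <- function(train_expr, auc,
                      lambda_mode = c("loo", "fixed"),
                      lambda = NULL,
                      lambda_grid = 10^seq(-4, 5, length.out = 60)) {
  lambda_mode <- match.arg(lambda_mode)
  stopifnot(is.matrix(train_expr), is.numeric(train_expr))
  if (ncol(train_expr) != length(auc))
    stop("auc length must match the number of cell lines (columns)", call. = FALSE)
  if (lambda_mode == "fixed") {
    if (is.null(lambda) || !is.finite(lambda) || lambda <= 0)
      stop("lambda_mode = 'fixed' requires a finite positive lambda", call. = FALSE)
  }
  keep <- !is.na(auc)
  if (sum(keep) < 2)
    stop("need at least 2 cell lines with non-missing AUC", call. = FALSE)
  X <- t(train_expr[, keep, drop = FALSE])   # lines x genes
  y <- auc[keep]

  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  zero_var <- !is.finite(scl) | scl < .Machine$double.eps^0.5
  dropped <- colnames(X)[zero_var]
  if (any(zero_var)) {
    warning(sprintf("dropping %d zero-variance gene(s): %s", length(dropped),
                    paste(utils::head(dropped, 5), collapse = ", ")), call. = FALSE)
    X <- X[, !zero_var, drop = FALSE]
    ctr <- ctr[!zero_var]; scl <- scl[!zero_var]
  }
  if (ncol(X) == 0) stop("no usable genes after dropping zero-variance rows", call. = FALSE)
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  mu <- mean(y)
  yc <- y - mu

  sv <- svd(Xs)
  pos <- sv$d > max(sv$d) * .Machine$double.eps * max(dim(Xs))
  d <- sv$d[pos]; U <- sv$u[, pos, drop = FALSE]; V <- sv$v[, pos, drop = FALSE]
  uty <- drop(crossprod(U, yc))

  loo <- NULL
  if (lambda_mode == "loo") {
    mse <- vapply(lambda_grid, function(l) loo_mse_ridge(d, U, uty, yc, l), numeric(1))
    lambda <- lambda_grid[which.min(mse)]
    loo <- data.frame(lambda = lambda_grid, loo_mse = mse)
  }
  beta <- drop(V %*% (d / (d^2 + lambda) * uty))
  names(beta) <- colnames(X)

  structure(list(intercept = mu, beta = beta, center = ctr, scale = scl,
                 genes = colnames(X), lambda = lambda, n_train = length(y),
                 lambda_mode = lambda_mode, loo = loo, dropped_genes = dropped),
            class = "ridge_model")
}

# exact LOO MSE for ridge via hat-matrix diagonals (SVD parameterization)
loo_mse_ridge <- function(d, U, uty, yc, lambda) {
  shrink <- d^2 / (d^2 + lambda)
  fit <- drop(U %*% (shrink * uty))
  h <- drop((U^2) %*% shrink)
  mean(((yc - fit) / (1 - pmin(h, 1 - 1e-12)))^2)
}

#' Coefficients of a ridge drug-response model
#'
#' @param object a `ridge_model`.
#' @param scale `"standardized"` (per-SD gene weights as fitted) or
#'   `"original"` (weights per unit of raw expression).
#' @param ... unused.
#' @return named numeric vector of gene weights.
#' @export
coef.ridge_model <- function(object, scale = c("standardized", "original"), ...) {
  scale <- match.arg(scale)
  if (scale == "standardized") object$beta else object$beta / object$scale
}

#' Impute drug response for new expression profiles
#'
#' Applies a fitted ridge model to a genes x samples matrix: each sample's
#' expression is standardized with the *training* center/scale and scored as
#' `intercept + beta' x`. Lower imputed AUC means predicted more sensitive.
#' The test matrix must contain every gene the model was trained on
#' (harmonize first; see [harmonize_expression()]).
#'
#' @param object a `ridge_model`.
#' @param newdata genes x samples numeric matrix.
#' @param ... unused.
#' @return numeric vector of imputed AUC, one per sample.
#' @export
predict.ridge_model <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  missing_genes <- setdiff(object$genes, rownames(newdata))
  if (length(missing_genes))
    stop(sprintf("test expression lacks %d model gene(s), e.g. %s",
                 length(missing_genes), paste(utils::head(missing_genes, 5), collapse = ", ")),
         call. = FALSE)
  Xs <- (t(newdata[object$genes, , drop = FALSE]) -
           matrix(object$center, ncol(newdata), length(object$genes), byrow = TRUE)) /
    matrix(object$scale, ncol(newdata), length(object$genes), byrow = TRUE)
  out <- drop(object$intercept + Xs %*% object$beta)
  names(out) <- colnames(newdata)
  out
}

#' @export
print.ridge_model <- function(x, ...) {
  cat(sprintf("Ridge drug-response model: %d genes, %d training lines\n",
              length(x$beta), x$n_train))
  cat(sprintf("  lambda = %.4g (%s), intercept = %.3f\n",
              x$lambda, x$lambda_mode, x$intercept))
  top <- utils::head(sort(abs(x$beta), decreasing = TRUE), 5)
  cat("  largest |weights|:", paste(sprintf("%s=%.3f", names(top), x$beta[names(top)]),
                                    collapse = ", "), "\n")
  invisible(x)
}
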