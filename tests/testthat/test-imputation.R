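test_that("coverage filter removes drugs screened in <40% of lines, strictly", {
  n <- 887
  screen <- matrix(NA_real_, nrow = n, ncol = 3,
                   dimnames = list(sprintf("CL%03d", 1:n), c("below", "at", "above")))
  screen[1:350, "below"] <- 1          # 350/887 = 39.5% -> removed
  screen[1:ceiling(0.40 * n), "at"] <- 1   # >= 40% -> retained
  screen[, "above"] <- 1
  out <- filter_drugs(screen, min_fraction = 0.40)
  expect_identical(colnames(out), c("at", "above"))

  # exactly 40.0% retained on an evenly divisible panel
  s2 <- matrix(NA_real_, nrow = 10, ncol = 1, dimnames = list(NULL, "d"))
  s2[1:4, 1] <- 1
  expect_identical(colnames(filter_drugs(s2, 0.40)), "d")

  # a screen with no missing values passes through unchanged
  full <- matrix(runif(20), 5, 4, dimnames = list(NULL, paste0("d", 1:4)))
  expect_identical(filter_drugs(full), full)

  expect_error(filter_drugs(matrix(numeric(0), 0, 0)), "empty")
  empty_all <- matrix(NA_real_, 5, 2, dimnames = list(NULL, c("a", "b")))
  empty_all[1, 1] <- 1
  expect_warning(res <- filter_drugs(empty_all, 0.9), "all drugs removed")
  expect_equal(ncol(res), 0)
})

test_that("harmonization maps monotone-distorted data back onto the training scale", {
  expr <- toy_expr(n_genes = 12, n_samples = 40, seed = 2)
  # identity up to shared-gene restriction
  h <- harmonize_expression(expr, expr)
  expect_equal(h$test, expr, tolerance = 1e-12)
  expect_identical(h$train, expr)

  # round trip through a per-gene strictly monotone distortion
  dist <- apply_platform_effect(expr, "monotone", seed = 5)
  h2 <- harmonize_expression(expr, dist)
  expect_equal(h2$test, expr, tolerance = 1e-8)

  # idempotence: harmonizing an already harmonized matrix changes nothing
  h3 <- harmonize_expression(expr, h2$test)
  expect_equal(h3$test, h2$test, tolerance = 1e-10)

  # disjoint gene namespaces are an error naming both sides
  other <- expr; rownames(other) <- sprintf("x%02d", seq_len(nrow(expr)))
  expect_error(harmonize_expression(expr, other), "no shared gene IDs")
})

test_that("ridge solution matches hand-solved normal equations on a tiny system", {
  # 3 lines, 2 genes, fixed lambda = 1; oracle solves (Xs'Xs + I) b = Xs'y
  # on the same centered/scaled design the fit uses
  X <- matrix(c(1, 2,
                2, 0,
                3, 4), nrow = 2, dimnames = list(c("g1", "g2"), NULL))
  y <- c(1, 3, 2)
  Xl <- t(X)
  Xs <- scale(Xl)
  yc <- y - mean(y)
  oracle <- solve(crossprod(Xs) + diag(2), crossprod(Xs, yc))
  fit <- fit_ridge(X, y, lambda_mode = "fixed", lambda = 1)
  expect_equal(unname(fit$beta), unname(drop(oracle)), tolerance = 1e-10)
  expect_equal(fit$intercept, mean(y))
})

test_that("constant response yields zero weights and the constant as intercept", {
  X <- toy_expr(n_genes = 4, n_samples = 10, seed = 3)
  fit <- fit_ridge(X, rep(13.5, 10), lambda_mode = "fixed", lambda = 1)
  expect_true(all(abs(fit$beta) < 1e-8))
  expect_equal(fit$intercept, 13.5)
  expect_equal(unname(predict(fit, X)), rep(13.5, 10), tolerance = 1e-8)
})

test_that("a nearly unpenalized fit recovers generative weights on the original scale", {
  withr::with_seed(17, {
    X <- matrix(rnorm(2 * 200), nrow = 2, dimnames = list(c("g1", "g2"), NULL))
    y <- 2 * X["g1", ] - 1 * X["g2", ]
  })
  fit <- fit_ridge(X, y, lambda_mode = "fixed", lambda = 1e-6)
  expect_equal(unname(coef(fit, scale = "original")), c(2, -1), tolerance = 1e-3)
})

test_that("ridge shrinkage is monotone in lambda and ignores unscreened lines", {
  X <- toy_expr(n_genes = 6, n_samples = 30, seed = 5)
  y <- withr::with_seed(6, drop(crossprod(X, rnorm(6))) + rnorm(30, sd = 0.2))
  lambdas <- 10^seq(-3, 3, length.out = 15)
  norms <- vapply(lambdas, function(l)
    sqrt(sum(fit_ridge(X, y, "fixed", lambda = l)$beta^2)), numeric(1))
  expect_true(all(diff(norms) <= 1e-12))

  # appending cell lines with missing response leaves the model unchanged
  X2 <- cbind(X, toy_expr(n_genes = 6, n_samples = 5, seed = 7))
  colnames(X2) <- sprintf("S%02d", seq_len(ncol(X2)))
  y2 <- c(y, rep(NA_real_, 5))
  f1 <- fit_ridge(X, y, "fixed", lambda = 2)
  f2 <- fit_ridge(X2, y2, "fixed", lambda = 2)
  expect_equal(f1$beta, f2$beta)
  expect_equal(f1$intercept, f2$intercept)
  expect_equal(f2$n_train, 30L)
})

test_that("zero-variance genes are dropped with a warning; too few lines error", {
  X <- toy_expr(n_genes = 3, n_samples = 12, seed = 8)
  X[2, ] <- 7
  y <- withr::with_seed(9, rnorm(12))
  expect_warning(fit <- fit_ridge(X, y, "fixed", lambda = 1), "zero-variance")
  expect_identical(fit$dropped_genes, "g02")
  expect_false("g02" %in% names(fit$beta))
  expect_error(fit_ridge(X[, 1, drop = FALSE], c(1), "fixed", lambda = 1),
               "at least 2")
})

test_that("imputation interpolates noiseless training data and centers to the intercept", {
  # full-rank noiseless limit: a test profile equal to a training line gets
  # that line's AUC back
  withr::with_seed(10, {
    X <- matrix(rnorm(3 * 40), nrow = 3, dimnames = list(paste0("g", 1:3),
                                                         sprintf("S%02d", 1:40)))
    y <- drop(crossprod(X, c(1, -2, 0.5))) + 12
  })
  fit <- fit_ridge(X, y, "fixed", lambda = 1e-8)
  expect_equal(unname(predict(fit, X[, 7, drop = FALSE])), unname(y[7]),
               tolerance = 1e-6)

  # a gene-wise training-mean profile imputes exactly the intercept
  mean_profile <- matrix(fit$center, ncol = 1, dimnames = list(names(fit$center), "m"))
  expect_equal(unname(predict(fit, mean_profile)), fit$intercept, tolerance = 1e-10)

  # gene mismatch is an error
  expect_error(predict(fit, X[1:2, , drop = FALSE]), "lacks")
})

test_that("the shifted synthetic GBM cohort imputes as more sensitive than control", {
  cfg <- sim_config(n_genes = 40, n_cell_lines = 150, n_drugs = 1,
                    n_parents_per_drug = 2, n_children_per_drug = 1,
                    n_confounded_per_drug = 1, sensitivity_shift = 1.5,
                    n_gbm = 60, n_control = 60, seed = 12)
  panel <- simulate_cell_line_panel(cfg)
  coh <- simulate_patient_cohorts(cfg, panel$truth)
  models <- fit_drug_models(panel$expression, filter_drugs(panel$screen))
  h <- harmonize_expression(panel$expression, coh$expression)
  imp <- predict(models, h$test)
  expect_lt(mean(imp[coh$labels == "GBM", 1]), mean(imp[coh$labels == "control", 1]))
  expect_false(anyNA(imp))
})

test_that("gene/response Spearman correlations match a rank-then-Pearson oracle", {
  y <- c(3, 1, 4, 1.5, 5)
  expr <- rbind(self = y,
                anti = -(y^3),                # strictly decreasing transform
                tied = c(2, 2, 7, 1, 0),      # one tie
                flat = rep(1, 5))
  colnames(expr) <- paste0("S", 1:5)
  expect_warning(res <- gene_response_correlation(expr, y), "constant")
  expect_equal(res$r[res$gene == "self"], 1)
  expect_equal(res$r[res$gene == "anti"], -1)
  expect_equal(res$r[res$gene == "tied"],
               cor(rank(c(2, 2, 7, 1, 0)), rank(y)), tolerance = 1e-12)
  expect_true(is.na(res$r[res$gene == "flat"]))
  # p for the tied row matches cor.test's tie-aware asymptotic value
  ct <- suppressWarnings(cor.test(c(2, 2, 7, 1, 0), y, method = "spearman",
                                  exact = FALSE))
  expect_equal(res$p[res$gene == "tied"], unname(ct$p.value), tolerance = 1e-10)
  expect_true(all(res$q >= res$p, na.rm = TRUE))
})

test_that("fixed-penalty ridge agrees with an independent ridge solver", {
  skip_if_not_installed("MASS")
  withr::with_seed(14, {
    X <- matrix(rnorm(8 * 100), nrow = 8, dimnames = list(paste0("g", 1:8), NULL))
    y <- drop(crossprod(X, rnorm(8))) + rnorm(100, sd = 0.3)
  })
  n <- 100; lam <- 5
  fit <- fit_ridge(X, y, "fixed", lambda = lam)
  # lm.ridge standardizes X with the 1/n variance; our design uses 1/(n-1),
  # so its penalty must be inflated by n/(n-1), and its original-scale
  # coefficients multiplied by the gene SDs to land on our standardized scale
  m <- MASS::lm.ridge(y ~ t(X), lambda = lam * n / (n - 1))
  b_std <- coef(m)[-1] * apply(t(X), 2, sd)
  expect_equal(unname(fit$beta), unname(b_std), tolerance = 1e-8)
})
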