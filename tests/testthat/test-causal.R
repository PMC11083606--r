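test_that("the Spearman pre-filter applies both the FDR and the |r| gates", {
  withr::with_seed(41, {
    n <- 500
    y <- rnorm(n)
    expr <- rbind(
      strong_pos = y + rnorm(n, sd = 0.5),    # |r| well above 0.6
      moderate  = y + rnorm(n, sd = 1.6),     # significant but |r| < 0.6
      noise     = rnorm(n)
    )
    colnames(expr) <- paste0("S", seq_len(n))
  })
  res <- scc_filter(expr, y)
  expect_true(res$retained[res$gene == "strong_pos"])
  expect_gt(abs(res$r[res$gene == "strong_pos"]), 0.6)
  # the moderate gene is highly significant yet fails the |r| >= 0.6 gate
  expect_lt(res$q[res$gene == "moderate"], 0.001)
  expect_lt(abs(res$r[res$gene == "moderate"]), 0.6)
  expect_false(res$retained[res$gene == "moderate"])
  expect_false(res$retained[res$gene == "noise"])
  # the retained flag is exactly the conjunction of the two gates
  expect_identical(res$retained, !is.na(res$r) & res$q < 0.05 & abs(res$r) >= 0.6)
  expect_error(scc_filter(expr, rep(1, n)), "constant")
})

test_that("residual-regression partial correlation matches the matrix-inversion formula", {
  withr::with_seed(42, {
    for (i in 1:40) {
      n <- 60
      kz <- sample(1:2, 1)
      Z <- matrix(rnorm(n * kz), ncol = kz)
      x <- drop(Z %*% rnorm(kz)) + rnorm(n)
      y <- drop(Z %*% rnorm(kz)) + 0.5 * x + rnorm(n)
      expect_equal(partial_correlation(x, y, Z), pcor_matrix(x, y, Z),
                   tolerance = 1e-8)
    }
  })
  # empty conditioning set reduces to Pearson
  withr::with_seed(43, { x <- rnorm(30); y <- rnorm(30); z <- rnorm(30) })
  expect_equal(partial_correlation(x, y), cor(x, y), tolerance = 1e-12)
  # identical variables have residual correlation 1
  expect_equal(partial_correlation(x, x, matrix(z)), 1, tolerance = 1e-10)
  # rank-deficient conditioning set is an error
  expect_error(partial_correlation(x, y, cbind(z, 2 * z)), "rank-deficient")
  expect_error(partial_correlation(x[1:4], y[1:4], cbind(z[1:4], x[1:4] + 1)),
               "too few samples")
})

test_that("the trivariate shared-confounder case matches the closed form", {
  # with r_xy = 0.8 and r_xz = r_yz = 0.9 the partial correlation is
  # (0.8 - 0.81) / (1 - 0.81) ~= -0.0526; build data realizing those sample
  # correlations exactly via a rotation, then compare both routes
  withr::with_seed(44, {
    n <- 200
    M <- matrix(rnorm(n * 3), ncol = 3)
    M <- scale(qr.Q(qr(scale(M, scale = FALSE))) * sqrt(n - 1))  # orthonormal columns
    R <- matrix(c(1, 0.8, 0.9,
                  0.8, 1, 0.9,
                  0.9, 0.9, 1), 3, 3)
    L <- chol(R)
    D <- M %*% L
  })
  x <- D[, 1]; y <- D[, 2]; z <- D[, 3]
  expect_equal(cor(x, y), 0.8, tolerance = 1e-10)
  closed <- (0.8 - 0.9 * 0.9) / sqrt((1 - 0.81) * (1 - 0.81))
  expect_equal(partial_correlation(x, y, matrix(z)), closed, tolerance = 1e-10)
})

test_that("Fisher-z statistics and p-values follow the transform exactly", {
  expect_equal(fisher_z_test(0, 50, 1), list(statistic = 0, p = 1))
  ft <- fisher_z_test(0.5, 50, 1)
  expect_equal(ft$statistic, sqrt(46) * atanh(0.5), tolerance = 1e-12)
  expect_equal(ft$statistic, 3.7256, tolerance = 1e-4)
  expect_equal(ft$p, 2 * pnorm(-sqrt(46) * atanh(0.5)), tolerance = 1e-12)
  expect_equal(ft$p, 1.95e-4, tolerance = 1e-2)
  # sign is carried through
  expect_equal(fisher_z_test(-0.5, 50, 1)$statistic, -ft$statistic)
  # p strictly decreasing in |rho| at fixed n, k
  ps <- vapply(seq(0.05, 0.95, by = 0.05),
               function(r) fisher_z_test(r, 40, 2)$p, numeric(1))
  expect_true(all(diff(ps) < 0))
  # |rho| = 1 sentinel
  s <- fisher_z_test(1, 20, 0)
  expect_identical(s$statistic, Inf)
  expect_identical(s$p, 0)
  expect_error(fisher_z_test(0.2, 5, 2), "n > k")
})

test_that("MMPC keeps direct causes and drops a near-duplicate bystander", {
  withr::with_seed(45, {
    n <- 2000
    x1 <- rnorm(n); x2 <- rnorm(n)
    y <- x1 + x2 + rnorm(n, sd = 0.8)
    x3 <- x1 + rnorm(n, sd = 0.3)   # proxy of x1, no direct effect
    cand <- rbind(X1 = x1, X2 = x2, X3 = x3)
    colnames(cand) <- paste0("S", seq_len(n))
  })
  res <- mmpc(y, cand)
  expect_setequal(res$pc$gene, c("X1", "X2"))
  # and the exclusion is verifiable directly: X3 _||_ y | X1
  p_given_x1 <- fisher_z_test(partial_correlation(cand["X3", ], y,
                                                  matrix(cand["X1", ])),
                              n = 2000, k = 1)$p
  expect_gt(p_given_x1, 0.05)
  # every surviving gene carries a signed statistic consistent with its rho
  expect_true(all(sign(res$pc$statistic) == sign(res$pc$rho)))
  expect_true(all(res$pc$p <= res$alpha))
})

test_that("MMPC returns an empty PC set when nothing is associated", {
  withr::with_seed(46, {
    cand <- matrix(rnorm(6 * 150), nrow = 6,
                   dimnames = list(paste0("N", 1:6), paste0("S", 1:150)))
    y <- rnorm(150)
  })
  res <- mmpc(y, cand)
  expect_equal(nrow(res$pc), 0)
  # empty candidate matrix short-circuits
  res0 <- mmpc(y, cand[0, , drop = FALSE])
  expect_equal(nrow(res0$pc), 0)
})

test_that("the PC set only grows with alpha on identical data", {
  cfg <- sim_config(seed = 19)
  panel <- simulate_cell_line_panel(cfg)
  coh <- simulate_patient_cohorts(cfg, panel$truth)
  y <- coh$true_auc[, 1]
  filt <- scc_filter(coh$expression, y, r_min = 0.3)
  cand <- coh$expression[filt$gene[filt$retained], , drop = FALSE]
  pc_strict <- mmpc(y, cand, alpha = 0.01)
  pc_loose <- mmpc(y, cand, alpha = 0.05)
  expect_true(all(pc_strict$pc$gene %in% pc_loose$pc$gene))
})

test_that("colliders orient both true parents into the response", {
  withr::with_seed(47, {
    n <- 2000
    x1 <- rnorm(n); x2 <- rnorm(n)
    y <- x1 - x2 + rnorm(n, sd = 0.8)
    cand <- rbind(X1 = x1, X2 = x2)
    colnames(cand) <- paste0("S", seq_len(n))
  })
  pc <- mmpc(y, cand)
  ori <- orient_parents(y, pc, cand)
  expect_setequal(ori$parental_genes, c("X1", "X2"))
  into_y <- ori$edges[ori$edges$to == ".response", ]
  expect_true(all(into_y$oriented))
})

test_that("a single PC gene with no collider evidence stays undirected", {
  withr::with_seed(48, {
    n <- 800
    x <- rnorm(n)
    y <- x + rnorm(n, sd = 0.5)
    cand <- rbind(X1 = x)
    colnames(cand) <- paste0("S", seq_len(n))
  })
  pc <- mmpc(y, cand)
  expect_identical(pc$pc$gene, "X1")
  ori <- orient_parents(y, pc, cand)
  expect_length(ori$parental_genes, 0)
  expect_false(any(ori$edges$oriented))
})

test_that("the biomarker report combines filter, PC membership and orientation", {
  cfg <- sim_config(seed = 23, n_gbm = 250, n_control = 250, sensitivity_shift = 0)
  panel <- simulate_cell_line_panel(cfg)
  coh <- simulate_patient_cohorts(cfg, panel$truth)
  y <- coh$true_auc[, 1]
  filt <- scc_filter(coh$expression, y, r_min = 0.3)
  cand <- coh$expression[filt$gene[filt$retained], , drop = FALSE]
  pc <- mmpc(y, cand)
  ori <- orient_parents(y, pc, cand)
  rep_tbl <- biomarker_report(filt, pc, ori)
  tr <- panel$truth$drugs[[1]]

  # only filter-retained genes appear
  expect_setequal(rep_tbl$gene, filt$gene[filt$retained])
  # parental calls are a subset of PC membership
  expect_true(all(rep_tbl$gene[rep_tbl$parental] %in% rep_tbl$gene[rep_tbl$is_pc]))
  # a positive-weight parent reads as resistance via up-regulation
  pos_parent <- names(tr$parent_weights)[tr$parent_weights > 0][1]
  row <- rep_tbl[rep_tbl$gene == pos_parent, ]
  expect_true(row$is_pc)
  expect_identical(row$direction, "high expression -> resistance")
  # children that pass the filter are PC members but not parental
  kids <- intersect(names(tr$child_weights), rep_tbl$gene)
  expect_gt(length(kids), 0)
  expect_true(all(rep_tbl$is_pc[rep_tbl$gene %in% kids]))
  expect_false(any(rep_tbl$parental[rep_tbl$gene %in% kids]))
})
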