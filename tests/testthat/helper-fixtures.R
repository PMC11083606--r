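# Shared fixtures, built in code.

# Small named expression matrix with reproducible content.
toy_expr <- function(n_genes = 5, n_samples = 8, seed = 1) {
  withr::with_seed(seed, {
    matrix(rnorm(n_genes * n_samples), nrow = n_genes,
           dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                           sprintf("S%02d", seq_len(n_samples))))
  })
}

# Brute-force two-sided Wilcoxon rank-sum p by full enumeration of the
# equally likely rank assignments (tie-free inputs only). Independent oracle:
# enumerates combn(n, nx) group assignments of the pooled ranks and counts
# rank sums at least as extreme as observed.
enum_wrs_p <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  nx <- length(x)
  obs <- sum(r[seq_len(nx)])
  splits <- combn(length(pooled), nx)
  sums <- colSums(matrix(r[splits], nrow = nx))
  mu <- nx * (length(pooled) + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu))
}

# Textbook BH step-up construction (sort, cumulative min), the oracle for
# bh_adjust().
stepup_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Partial correlation from the inverse of the correlation matrix (oracle for
# the residual-regression implementation).
pcor_matrix <- function(x, y, Z) {
  M <- cbind(x = x, y = y, Z)
  Om <- solve(stats::cor(M))
  -Om[1, 2] / sqrt(Om[1, 1] * Om[2, 2])
}
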