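#' Spearman pre-filter for causal candidate genes
#'
#' Univariate dimensionality reduction before network learning: keeps genes
#' whose Spearman correlation with the (imputed) drug response is both
#' significant after Benjamini-Hochberg adjustment (q < `q_max`) and at least
#' moderately strong (|r| >= `r_min`). Defaults follow the common practice of
#' FDR < 0.05 with |SCC| >= 0.60; note that with k independent same-strength
#' direct causes no single cause can exceed 1/sqrt(k) marginal correlation,
#' so simulation studies with several parents per drug use a lower `r_min`.
#'
#' @param expr genes x samples expression matrix.
#' @param response numeric response per sample (imputed AUC for one drug).
#' @param r_min minimum |Spearman r| (default 0.60).
#' @param q_max BH-FDR threshold (default 0.05, strict `<`).
#' @return data.frame of class `gene_filter`: gene, r, p, q, retained.
#' @export
scc_filter <- function(expr, response, r_min = 0.60, q_max = 0.05) {
  stopifnot(is.matrix(expr))
  if (length(response) != ncol(expr))
    stop("response length must match the number of samples", call. = FALSE)
  if (length(response) < 4) stop("need at least 4 samples", call. = FALSE)
  if (max(response) - min(response) < .Machine$double.eps)
    stop("constant response", call. = FALSE)
  res <- gene_response_correlation(expr, response)
  res$retained <- !is.na(res$r) & res$q < q_max & abs(res$r) >= r_min
  class(res) <- c("gene_filter", "data.frame")
  attr(res, "r_min") <- r_min
  attr(res, "q_max") <- q_max
  res
}

#' Partial correlation by double residualization
#'
#' Pearson correlation between the residuals of `x` regressed on `Z` and of
#' `y` regressed on `Z` (with intercept). With an empty conditioning set this
#' is the plain Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param Z numeric matrix of conditioning variables (columns), or `NULL` /
#'   zero-column matrix for no conditioning.
#' @return partial correlation coefficient.
#' @export
partial_correlation <- function(x, y, Z = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  k <- if (is.null(Z)) 0L else ncol(as.matrix(Z))
  if (n <= k + 3) stop("too few samples for the conditioning-set size", call. = FALSE)
  if (k == 0L) return(stats::cor(x, y))
  Z <- as.matrix(Z)
  qz <- qr(cbind(1, Z))
  if (qz$rank < ncol(Z) + 1L)
    stop("rank-deficient conditioning set", call. = FALSE)
  rx <- qr.resid(qz, x)
  ry <- qr.resid(qz, y)
  stats::cor(rx, ry)
}

#' Fisher-z conditional-independence test
#'
#' Variance-stabilizing test of a (partial) correlation:
#' `T = sqrt(n - k - 3) * atanh(rho)`, two-sided p from the standard normal.
#' The sign of `T` carries the directionality of the association (positive
#' against AUC = expression rises with resistance). `|rho| = 1` is reported
#' as an infinite statistic with p = 0.
#'
#' @param rho (partial) correlation coefficient.
#' @param n sample size.
#' @param k conditioning-set size.
#' @return list with `statistic` (signed T) and `p`.
#' @export
fisher_z_test <- function(rho, n, k = 0) {
  if (n <= k + 3) stop("need n > k + 3", call. = FALSE)
  if (abs(rho) >= 1)
    return(list(statistic = sign(rho) * Inf, p = 0))
  T <- sqrt(n - k - 3) * atanh(rho)
  list(statistic = T, p = 2 * stats::pnorm(-abs(T)))
}

# One conditional-independence query: partial correlation + Fisher-z.
# `data` is a samples x variables matrix; i, j column names; Z a character
# vector of conditioning columns.
ci_test <- function(data, i, j, Z = character(0)) {
  rho <- partial_correlation(data[, i], data[, j],
                             if (length(Z)) data[, Z, drop = FALSE] else NULL)
  ft <- fisher_z_test(rho, nrow(data), length(Z))
  list(rho = rho, statistic = ft$statistic, p = ft$p, Z = Z, n = nrow(data))
}

#' MMPC: discover the parent-child set of a drug response
#'
#' Constraint-based selection of the genes directly connected to the response
#' in a Bayesian network (its direct causes and direct effects), using
#' Fisher-z partial-correlation independence tests. Forward phase: candidates
#' are scanned in a fixed order (descending |Spearman| with the response,
#' ties by gene ID, neutralizing variable-order dependence) and the candidate
#' with the *largest minimum association* over all conditioning subsets of
#' the current PC set (up to `max_k`) is added while that minimum association
#' is significant at `alpha`. Backward phase: any member that is independent
#' of the response given some subset of the other members is removed. Each
#' surviving gene is reported with the signed Fisher-z statistic of its
#' weakest surviving test, whose sign gives the association's direction.
#'
#' @param response numeric response per sample (imputed AUC for one drug).
#' @param candidates genes x samples expression matrix of candidate genes
#'   (typically the [scc_filter()]-retained set).
#' @param alpha significance level of the independence tests (default 0.05).
#' @param max_k maximum conditioning-set size (default 3).
#' @return object of class `pc_result`: data.frame `pc` (gene, rho,
#'   statistic, p, cond_set, n — the weakest surviving test per gene) plus
#'   `alpha`, `max_k` and the candidate order.
#' @export
mmpc <- function(response, candidates, alpha = 0.05, max_k = 3) {
  stopifnot(is.matrix(candidates))
  n <- length(response)
  if (ncol(candidates) != n)
    stop("candidates columns must match response length", call. = FALSE)
  empty <- function(order = character(0)) {
    structure(list(
      pc = data.frame(gene = character(0), rho = numeric(0), statistic = numeric(0),
                      p = numeric(0), cond_set = character(0), n = integer(0),
                      stringsAsFactors = FALSE),
      alpha = alpha, max_k = max_k, candidate_order = order), class = "pc_result")
  }
  if (nrow(candidates) == 0) return(empty())
  if (n <= max_k + 3) stop("need n > max_k + 3", call. = FALSE)

  # fixed processing order: descending |SCC|, ties by gene ID
  scc <- suppressWarnings(spearman_vs_response(candidates, response)$r)
  scc[is.na(scc)] <- 0
  ord <- order(-abs(scc), rownames(candidates))
  genes <- rownames(candidates)[ord]

  data <- cbind(.response = response, t(candidates))
  colnames(data)[1] <- ".response"

  # forward: track, per remaining candidate, its weakest association so far
  # (max p over the subsets evaluated); subsets are evaluated incrementally
  # as the PC set grows
  worst <- lapply(genes, function(g) ci_test(data, ".response", g))
  names(worst) <- genes
  pc <- character(0)
  remaining <- genes
  while (length(remaining)) {
    ps <- vapply(worst[remaining], `[[`, numeric(1), "p")
    eligible <- ps <= alpha
    if (!any(eligible)) break
    # max-min heuristic: smallest worst-case p; ties resolved by fixed order
    best <- remaining[eligible][which.min(ps[eligible])]
    pc <- c(pc, best)
    remaining <- setdiff(remaining, best)
    if (!length(remaining)) break
    new_subsets <- Filter(function(z) best %in% z, subsets_up_to(pc, max_k))
    for (g in remaining) {
      for (Z in new_subsets) {
        if (length(Z) > nrow(data) - 4) next
        tst <- ci_test(data, ".response", g, Z)
        if (tst$p > worst[[g]]$p) worst[[g]] <- tst
        if (worst[[g]]$p > alpha) break
      }
    }
  }

  # backward: prune members independent given a subset of the others
  repeat {
    removed <- FALSE
    for (g in pc) {
      for (Z in subsets_up_to(setdiff(pc, g), max_k)) {
        tst <- ci_test(data, ".response", g, Z)
        if (tst$p > alpha) {
          pc <- setdiff(pc, g)
          removed <- TRUE
          break
        }
      }
      if (removed) break
    }
    if (!removed) break
  }

  if (!length(pc)) return(empty(genes))
  rows <- lapply(pc, function(g) {
    weakest <- NULL
    for (Z in subsets_up_to(setdiff(pc, g), max_k)) {
      tst <- ci_test(data, ".response", g, Z)
      if (is.null(weakest) || tst$p > weakest$p) weakest <- tst
    }
    data.frame(gene = g, rho = weakest$rho, statistic = weakest$statistic,
               p = weakest$p, cond_set = paste(weakest$Z, collapse = ","),
               n = weakest$n, stringsAsFactors = FALSE)
  })
  pc_df <- do.call(rbind, rows)
  pc_df <- pc_df[order(-abs(pc_df$statistic)), , drop = FALSE]
  rownames(pc_df) <- NULL
  structure(list(pc = pc_df, alpha = alpha, max_k = max_k,
                 candidate_order = genes), class = "pc_result")
}

#' @export
print.pc_result <- function(x, ...) {
  cat(sprintf("MMPC parent-child set: %d gene(s) (alpha = %g, max_k = %d)\n",
              nrow(x$pc), x$alpha, x$max_k))
  if (nrow(x$pc)) print.data.frame(x$pc, digits = 4)
  invisible(x)
}

#' Orient PC genes: which are parental (causal) for the response?
#'
#' PC-style orientation restricted to the local neighbourhood of the
#' response: the skeleton over {response} + PC genes + each PC gene's own
#' parent-child set is learned by Fisher-z conditional-independence tests
#' with conditioning sets drawn from current adjacencies (up to `max_k`),
#' v-structures (colliders) are oriented from recorded separating sets, and
#' orientations are propagated by the standard acyclicity-preserving rules.
#' PC genes with an edge oriented *into* the response are called parental;
#' edges whose direction cannot be determined stay undirected.
#'
#' @param response numeric response per sample.
#' @param pc_result a `pc_result` from [mmpc()] on the same data.
#' @param candidates the same candidate expression matrix given to [mmpc()].
#' @param alpha significance level for the skeleton's independence tests.
#' @param max_k maximum conditioning-set size.
#' @return object of class `pc_orientation`: `parental_genes`, `edges`
#'   (data.frame from, to, oriented) and the variable set used.
#' @export
orient_parents <- function(response, pc_result, candidates,
                           alpha = 0.05, max_k = 3) {
  stopifnot(inherits(pc_result, "pc_result"), is.matrix(candidates))
  pc_genes <- pc_result$pc$gene
  if (!length(pc_genes)) {
    return(structure(list(parental_genes = character(0),
                          edges = data.frame(from = character(0), to = character(0),
                                             oriented = logical(0)),
                          variables = ".response"), class = "pc_orientation"))
  }
  # local variable set: response, PC genes, and each PC gene's own PC set
  vars <- pc_genes
  for (g in pc_genes) {
    others <- candidates[setdiff(rownames(candidates), g), , drop = FALSE]
    own <- mmpc(candidates[g, ], others, alpha = alpha, max_k = max_k)
    vars <- union(vars, own$pc$gene)
  }
  data <- cbind(.response = response, t(candidates[vars, , drop = FALSE]))
  colnames(data)[1] <- ".response"
  V <- colnames(data)
  nv <- length(V)

  # skeleton: complete graph, edges removed by CI tests of increasing order
  adj <- matrix(TRUE, nv, nv, dimnames = list(V, V)); diag(adj) <- FALSE
  sepset <- list()
  pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")
  for (l in 0:max_k) {
    for (i in V) {
      for (j in V) {
        if (i >= j || !adj[i, j]) next
        nbrs <- union(setdiff(V[adj[i, ]], j), setdiff(V[adj[j, ]], i))
        if (length(nbrs) < l) next
        for (Z in utils::combn(nbrs, l, simplify = FALSE)) {
          if (nrow(data) <= length(Z) + 3) next
          if (ci_test(data, i, j, Z)$p > alpha) {
            adj[i, j] <- adj[j, i] <- FALSE
            sepset[pair_key(i, j)] <- list(Z)
            break
          }
        }
      }
    }
  }

  # v-structures: i - k - j with i,j non-adjacent and k not in sepset(i, j)
  # arrows[i, j] = TRUE means edge oriented i -> j
  arrows <- matrix(FALSE, nv, nv, dimnames = list(V, V))
  pairs <- which(upper.tri(adj) & !adj, arr.ind = TRUE)
  for (r in seq_len(nrow(pairs))) {
    i <- V[pairs[r, 1]]; j <- V[pairs[r, 2]]
    Z <- sepset[[pair_key(i, j)]] %||% character(0)
    for (k in V[adj[i, ] & adj[j, ]]) {
      if (!(k %in% Z)) {
        arrows[i, k] <- TRUE
        arrows[j, k] <- TRUE
      }
    }
  }
  arrows <- propagate_meek(adj, arrows)

  parental <- pc_genes[vapply(pc_genes, function(g)
    adj[g, ".response"] && arrows[g, ".response"] && !arrows[".response", g],
    logical(1))]

  ut <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  edges <- do.call(rbind, lapply(seq_len(nrow(ut)), function(r) {
    a <- V[ut[r, 1]]; b <- V[ut[r, 2]]
    if (arrows[a, b] && !arrows[b, a]) data.frame(from = a, to = b, oriented = TRUE)
    else if (arrows[b, a] && !arrows[a, b]) data.frame(from = b, to = a, oriented = TRUE)
    else data.frame(from = a, to = b, oriented = FALSE)
  })) %||% data.frame(from = character(0), to = character(0), oriented = logical(0))
  structure(list(parental_genes = parental, edges = edges, variables = V),
            class = "pc_orientation")
}

# Meek orientation-propagation rules 1-3 to a fixed point
propagate_meek <- function(adj, arrows) {
  V <- rownames(adj)
  directed <- function(a, b) adj[a, b] && arrows[a, b] && !arrows[b, a]
  undirected <- function(a, b) adj[a, b] && !arrows[a, b] && !arrows[b, a]
  repeat {
    changed <- FALSE
    for (a in V) for (b in V) {
      if (a == b || !undirected(a, b)) next
      # R1: c -> a, c not adjacent b  =>  a -> b
      r1 <- any(vapply(V, function(cc)
        cc != b && directed(cc, a) && !adj[cc, b], logical(1)))
      # R2: a -> c -> b  =>  a -> b
      r2 <- any(vapply(V, function(cc)
        cc != a && cc != b && directed(a, cc) && directed(cc, b), logical(1)))
      # R3: a - c -> b and a - d -> b, c,d non-adjacent  =>  a -> b
      r3 <- FALSE
      cand <- V[vapply(V, function(cc)
        cc != a && cc != b && undirected(a, cc) && directed(cc, b), logical(1))]
      if (length(cand) >= 2) {
        for (c1 in cand) for (c2 in cand) {
          if (c1 < c2 && !adj[c1, c2]) { r3 <- TRUE; break }
        }
      }
      if (r1 || r2 || r3) {
        arrows[a, b] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  arrows
}

#' @export
print.pc_orientation <- function(x, ...) {
  cat(sprintf("Orientation over %d variables: %d parental gene(s)%s\n",
              length(x$variables), length(x$parental_genes),
              if (length(x$parental_genes))
                paste0(" (", paste(x$parental_genes, collapse = ", "), ")") else ""))
  if (nrow(x$edges)) print.data.frame(x$edges)
  invisible(x)
}

#' Tidy biomarker report for one drug
#'
#' Combines the Spearman pre-filter, MMPC parent-child set and orientation
#' into one table over the retained genes. A PC gene's directionality label
#' reads the sign of its Fisher-z statistic against AUC: positive means high
#' expression tracks higher AUC, i.e. resistance; negative means sensitivity.
#'
#' @param filter a `gene_filter` from [scc_filter()].
#' @param pc a `pc_result` from [mmpc()].
#' @param oriented a `pc_orientation` from [orient_parents()] (optional).
#' @return data.frame: gene, scc, q, is_pc, statistic, p, parental, direction.
#' @export
biomarker_report <- function(filter, pc, oriented = NULL) {
  stopifnot(inherits(filter, "gene_filter"), inherits(pc, "pc_result"))
  kept <- filter[filter$retained, , drop = FALSE]
  idx <- match(kept$gene, pc$pc$gene)
  parental <- if (!is.null(oriented)) kept$gene %in% oriented$parental_genes
              else rep(FALSE, nrow(kept))
  stat <- pc$pc$statistic[idx]
  out <- data.frame(
    gene = kept$gene, scc = kept$r, q = kept$q,
    is_pc = !is.na(idx), statistic = stat, p_ci = pc$pc$p[idx],
    parental = parental,
    direction = ifelse(is.na(idx), NA_character_,
                       ifelse(stat > 0, "high expression -> resistance",
                              "high expression -> sensitivity")),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out[order(-out$is_pc, -abs(ifelse(is.na(out$statistic), 0, out$statistic))), ,
      drop = FALSE]
}
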