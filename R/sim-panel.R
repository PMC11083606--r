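#' Simulate a cell-line drug-screening panel with known causal truth
#'
#' Generates (i) a gene x cell-line expression matrix with standard-normal
#' marginals per gene, (ii) a cell-line x drug AUC screen in which every
#' drug's AUC is an affine function of its parent genes' expression plus
#' noise, min-max rescaled into the 10-20 band typical of cell-line screen
#' sensitivity scores (lower = more sensitive), with entries removed
#' completely at random, and (iii) a ground-truth object recording parent /
#' child / confounded gene assignments, signed weights and the per-drug
#' rescaling, so downstream recovery can be scored exactly.
#'
#' Structured genes (parents, children, confounded) are assigned disjointly
#' across drugs; in the panel itself all genes are marginally standard normal
#' and only parents feed the AUC — child and confounded structure is realised
#' in patient cohorts (see [simulate_patient_cohorts()]), mirroring the fact
#' that a screened line's transcriptome is measured before treatment.
#'
#' @param config a [sim_config()].
#' @return a list with elements `expression` (genes x lines), `screen`
#'   (lines x drugs, `NA` for unscreened pairs) and `truth` (class
#'   `sim_truth`).
#' @export
simulate_cell_line_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  lines <- sprintf("CL%04d", seq_len(config$n_cell_lines))
  drugs <- sprintf("drug%03d", seq_len(config$n_drugs))

  truth <- with_stream(config$seed, "truth", make_truth(config, genes, drugs))

  expr <- with_stream(config$seed, "panel-expression", {
    matrix(stats::rnorm(config$n_genes * config$n_cell_lines),
           nrow = config$n_genes, dimnames = list(genes, lines))
  })

  screen <- matrix(NA_real_, nrow = config$n_cell_lines, ncol = config$n_drugs,
                   dimnames = list(lines, drugs))
  noise <- with_stream(config$seed, "panel-noise", {
    matrix(stats::rnorm(config$n_cell_lines * config$n_drugs, sd = config$noise_sd),
           nrow = config$n_cell_lines)
  })
  for (d in seq_along(drugs)) {
    w <- truth$drugs[[d]]$parent_weights
    raw <- drop(crossprod(expr[names(w), , drop = FALSE], w)) + noise[, d]
    sc <- rescale_to_band(raw)
    truth$drugs[[d]]$rescale <- sc$par
    screen[, d] <- sc$values
  }
  if (config$missing_fraction > 0) {
    mask <- with_stream(config$seed, "panel-missing", {
      stats::runif(length(screen)) < config$missing_fraction
    })
    screen[mask] <- NA_real_
  }
  list(expression = expr, screen = screen, truth = truth)
}

# Assign disjoint parent/child/confounded gene sets and signed weights.
make_truth <- function(config, genes, drugs) {
  per_drug <- config$n_parents_per_drug + config$n_children_per_drug +
    config$n_confounded_per_drug
  pool <- sample(genes, config$n_drugs * per_drug)
  out <- vector("list", config$n_drugs)
  names(out) <- drugs
  for (d in seq_len(config$n_drugs)) {
    block <- pool[((d - 1) * per_drug + 1):(d * per_drug)]
    parents <- block[seq_len(config$n_parents_per_drug)]
    children <- block[config$n_parents_per_drug + seq_len(config$n_children_per_drug)]
    confounded <- block[config$n_parents_per_drug + config$n_children_per_drug +
                          seq_len(config$n_confounded_per_drug)]
    # alternating signs keep both directions represented at every seed
    psign <- rep_len(c(1, -1), length(parents))
    pw <- stats::setNames(psign * config$effect_size, parents)
    csign <- rep_len(c(1, -1), length(children))
    cw <- stats::setNames(csign * config$effect_size, children)
    conf_parent <- if (length(confounded))
      stats::setNames(rep_len(parents, length(confounded)), confounded)
    else stats::setNames(character(0), character(0))
    conf_w <- stats::setNames(rep_len(c(1, -1), length(confounded)) * config$effect_size,
                              confounded)
    out[[d]] <- list(
      drug = drugs[d],
      parent_weights = pw,
      child_weights = cw,
      confounded_parent = conf_parent,
      confounded_weights = conf_w,
      sensitive = d <= config$n_sensitive_drugs,
      rescale = c(intercept = NA_real_, slope = NA_real_)
    )
  }
  structure(list(drugs = out, genes = genes, config = config), class = "sim_truth")
}

# affine map of `raw` onto [10, 20]; returns values + (intercept, slope) so
# the same map can be applied to cohort responses
rescale_to_band <- function(raw, lo = 10, hi = 20) {
  rng <- range(raw)
  if (diff(rng) < .Machine$double.eps) {
    par <- c(intercept = (lo + hi) / 2, slope = 0)
  } else {
    slope <- (hi - lo) / diff(rng)
    par <- c(intercept = lo - slope * rng[1], slope = slope)
  }
  list(values = par["intercept"] + par["slope"] * raw, par = par)
}

apply_rescale <- function(raw, par) unname(par["intercept"] + par["slope"] * raw)

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("Synthetic ground truth: %d drugs over %d genes\n",
              length(x$drugs), length(x$genes)))
  for (d in x$drugs[seq_len(min(3, length(x$drugs)))]) {
    cat(sprintf("  %s%s: parents {%s}, children {%s}, confounded {%s}\n",
                d$drug, if (d$sensitive) " [GBM-sensitive]" else "",
                paste(names(d$parent_weights), collapse = ","),
                paste(names(d$child_weights), collapse = ","),
                paste(names(d$confounded_weights), collapse = ",")))
  }
  if (length(x$drugs) > 3) cat(sprintf("  ... and %d more drugs\n", length(x$drugs) - 3))
  invisible(x)
}

#' Apply a simulated platform effect to an expression matrix
#'
#' `"monotone"` applies, per gene, a strictly increasing nonlinear map
#' (random positive-slope signed cubic plus offset), emulating the kind of
#' cross-platform distortion that rank-based harmonization removes; per-gene
#' cross-sample rank order is preserved exactly. `"none"` returns the input.
#'
#' @param expr genes x samples numeric matrix.
#' @param distortion `"none"` or `"monotone"`.
#' @param seed integer seed for the per-gene distortion coefficients.
#' @return a matrix of the same shape and dimnames.
#' @export
apply_platform_effect <- function(expr, distortion = c("none", "monotone"), seed = 1L) {
  distortion <- match.arg(distortion)
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (distortion == "none") return(expr)
  G <- nrow(expr)
  co <- with_stream(seed, "platform", {
    list(a = stats::runif(G, 0.5, 2),   # linear slope > 0
         b = stats::runif(G, 0.05, 0.4), # cubic coefficient >= 0
         d = stats::rnorm(G, sd = 2))    # offset
  })
  out <- co$a * expr + co$b * expr^3 + co$d
  dimnames(out) <- dimnames(expr)
  out
}
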