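# Delimited-text readers/writers and the end-to-end pipeline driver.

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read an expression matrix from delimited text
#'
#' Genes as rows (first column gene IDs), header row of sample IDs; tab or
#' comma delimiter auto-detected. IDs must be unique and all cells numeric;
#' violations are reported with their location.
#'
#' @param path file path.
#' @return genes x samples numeric matrix.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  sep <- detect_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "",
                          na.strings = c("NA", ""))
  ids <- df[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop(sprintf("duplicate gene ID(s): %s", paste(utils::head(dup, 5), collapse = ", ")),
         call. = FALSE)
  sdup <- unique(colnames(df)[-1][duplicated(colnames(df)[-1])])
  if (length(sdup))
    stop(sprintf("duplicate sample ID(s): %s", paste(utils::head(sdup, 5), collapse = ", ")),
         call. = FALSE)
  vals <- suppressWarnings(
    vapply(df[-1], function(col) as.numeric(col), numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(ids, colnames(df)[-1]))
  raw_na <- vapply(df[-1], is.na, logical(nrow(df)))
  bad <- which(is.na(vals) & !raw_na, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric value at gene '%s', sample '%s'",
                 ids[bad[1, 1]], colnames(vals)[bad[1, 2]]), call. = FALSE)
  vals
}

#' Write an expression (or any genes x samples) matrix as TSV
#'
#' @param expr genes x samples matrix.
#' @param path output path.
#' @param id_column header for the first (ID) column.
#' @export
write_expression <- function(expr, path, id_column = "gene_id") {
  stopifnot(is.matrix(expr))
  df <- data.frame(expr, check.names = FALSE)
  df <- cbind(stats::setNames(data.frame(rownames(expr)), id_column), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a drug screen (cell lines x drugs) from delimited text
#'
#' First column = cell line IDs; `NA`/empty cells = unscreened.
#'
#' @param path file path.
#' @return cell-lines x drugs numeric matrix with `NA` for missing screens.
#' @export
read_screen <- function(path) {
  m <- read_expression(path)
  m
}

#' @rdname read_screen
#' @param screen cell-lines x drugs matrix.
#' @export
write_screen <- function(screen, path) {
  write_expression(screen, path, id_column = "cell_line_id")
}

#' Read / write sample group labels (two-column TSV: sample_id, group)
#'
#' @param path file path.
#' @return named character vector of group per sample.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("label file needs columns sample_id, group", call. = FALSE)
  stats::setNames(df[[2]], df[[1]])
}

#' @rdname read_labels
#' @param labels named vector/factor of group per sample.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(
    data.frame(sample_id = names(labels), group = as.character(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read the simulation ground truth as a JSON sidecar
#'
#' @param truth a `sim_truth`.
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  payload <- list(
    genes = truth$genes,
    config = unclass(truth$config),
    drugs = lapply(truth$drugs, function(d) list(
      drug = d$drug, sensitive = d$sensitive,
      parent_weights = as.list(d$parent_weights),
      child_weights = as.list(d$child_weights),
      confounded_parent = as.list(d$confounded_parent),
      confounded_weights = as.list(d$confounded_weights),
      rescale = as.list(d$rescale)))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  drugs <- lapply(payload$drugs, function(d) list(
    drug = d$drug, sensitive = d$sensitive,
    parent_weights = unlist(d$parent_weights),
    child_weights = unlist(d$child_weights) %||% stats::setNames(numeric(0), character(0)),
    confounded_parent = unlist(d$confounded_parent) %||% stats::setNames(character(0), character(0)),
    confounded_weights = unlist(d$confounded_weights) %||% stats::setNames(numeric(0), character(0)),
    rescale = unlist(d$rescale)))
  names(drugs) <- vapply(drugs, `[[`, character(1), "drug")
  cfg <- payload$config
  cfg <- do.call(sim_config, cfg[setdiff(names(cfg), character(0))])
  structure(list(drugs = drugs, genes = unlist(payload$genes), config = cfg),
            class = "sim_truth")
}

#' Run the full synthetic pipeline end to end
#'
#' Simulates a cell-line panel and patient cohorts, filters and fits the
#' per-drug ridge models, imputes each cohort, nominates drugs per cohort,
#' intersects selections into a consensus, runs the causal-biomarker stage on
#' the first drug in the first clinical cohort, and computes measured
#' dose-response AUCs with a GBM-vs-NPC comparison. Every intermediate table
#' is written under `out_dir` as TSV (plus the ground truth as JSON), and a
#' plain-text log records per-stage record counts and the thresholds applied.
#'
#' @param config a [sim_config()]; its `seed` drives all randomness.
#' @param out_dir output directory (created if needed).
#' @param n_clinical number of simulated clinical cohorts (default 5).
#' @param min_fraction drug coverage filter threshold.
#' @param alpha FDR threshold for nomination and CI-test level for MMPC.
#' @param percentile HLE percentile for selection.
#' @param min_clinical consensus threshold.
#' @param r_min,q_max Spearman pre-filter thresholds for the biomarker stage.
#' @param max_k maximum conditioning-set size.
#' @param lambda_mode ridge penalty selection mode.
#' @param axis dose-response integration axis.
#' @return invisibly, a list with the main result objects and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir,
                         n_clinical = 5,
                         min_fraction = 0.40, alpha = 0.05, percentile = 0.5,
                         min_clinical = 3, r_min = 0.30, q_max = 0.05,
                         max_k = 3, lambda_mode = "loo", axis = "log10_dose") {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "pipeline.log")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = logf, append = TRUE)
  cat("", file = logf)

  log_line("[simulate] seed=%d genes=%d lines=%d drugs=%d", config$seed,
           config$n_genes, config$n_cell_lines, config$n_drugs)
  panel <- simulate_cell_line_panel(config)
  write_expression(panel$expression, file.path(out_dir, "panel_expression.tsv"))
  write_screen(panel$screen, file.path(out_dir, "panel_screen.tsv"))
  write_truth(panel$truth, file.path(out_dir, "truth.json"))

  screen <- filter_drugs(panel$screen, min_fraction = min_fraction)
  log_line("[filter_drugs] min_fraction=%.2f retained=%d/%d", min_fraction,
           ncol(screen), ncol(panel$screen))

  models <- fit_drug_models(panel$expression, screen, lambda_mode = lambda_mode)
  log_line("[fit] lambda_mode=%s drugs=%d", lambda_mode, length(models$models))

  cohort_ids <- c(sprintf("clinical%d", seq_len(n_clinical)), "avatar")
  records <- NULL
  cohorts <- list()
  for (cid in cohort_ids) {
    grp2 <- if (cid == "avatar") "NPC" else "control"
    coh <- simulate_patient_cohorts(config, panel$truth,
                                    groups = c("GBM", grp2), cohort_id = cid)
    cohorts[[cid]] <- coh
    h <- harmonize_expression(panel$expression, coh$expression)
    imp <- predict(models, h$test)
    write_expression(t(imp), file.path(out_dir, sprintf("imputed_%s.tsv", cid)),
                     id_column = "drug")
    write_labels(coh$labels, file.path(out_dir, sprintf("labels_%s.tsv", cid)))
    rec <- nominate(imp, coh$labels, dataset_id = cid, alpha = alpha,
                    percentile = percentile)
    records <- rbind(records, rec)
    log_line("[nominate:%s] alpha=%.3f percentile=%.2f selected=%d/%d", cid,
             alpha, percentile, sum(rec$selected), nrow(rec))
  }
  utils::write.table(records, file.path(out_dir, "nomination_records.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cons <- consensus(records, clinical_datasets = sprintf("clinical%d", seq_len(n_clinical)),
                    avatar_dataset = "avatar", min_clinical = min_clinical)
  utils::write.table(cons, file.path(out_dir, "consensus.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_line("[consensus] min_clinical=%d require_avatar=TRUE nominated=%d",
           min_clinical, sum(cons$nominated))

  # biomarker stage: first retained drug in the first clinical cohort
  coh <- cohorts[[1]]
  h <- harmonize_expression(panel$expression, coh$expression)
  imp <- predict(models, h$test)
  drug1 <- colnames(screen)[1]
  filt <- scc_filter(coh$expression, imp[, drug1], r_min = r_min, q_max = q_max)
  cand <- coh$expression[filt$gene[filt$retained], , drop = FALSE]
  pc <- mmpc(imp[, drug1], cand, alpha = alpha, max_k = max_k)
  ori <- orient_parents(imp[, drug1], pc, cand, alpha = alpha, max_k = max_k)
  rep_tbl <- biomarker_report(filt, pc, ori)
  utils::write.table(rep_tbl, file.path(out_dir, "biomarker_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(ori$edges))
    utils::write.table(ori$edges, file.path(out_dir, "biomarker_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  log_line("[biomarker:%s] r_min=%.2f q_max=%.2f retained=%d pc=%d parental=%d",
           drug1, r_min, q_max, sum(filt$retained), nrow(pc$pc),
           length(ori$parental_genes))

  dr <- simulate_dose_response(seed = derive_seed(config$seed, "dose"),
                               drug = drug1)
  aucs <- auc_by_sample(dr$measurements, axis = axis)
  utils::write.table(aucs, file.path(out_dir, "measured_auc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cmp <- compare_measured(aucs$auc, aucs$group)
  log_line("[doseresp] axis=%s samples=%d p=%.3g hle=%.3f", axis, nrow(aucs),
           cmp$p, cmp$hle)

  invisible(list(out_dir = out_dir, records = records, consensus = cons,
                 biomarker = rep_tbl, orientation = ori, measured = aucs,
                 measured_comparison = cmp))
}
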