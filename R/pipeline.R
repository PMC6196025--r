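#' Pipeline configuration
#'
#' One object driving an end-to-end run in simulation mode: cohort
#' configuration, stage toggles and stage parameters.
#'
#' @param cohort a [cohort_config()]; its `seed` is overridden by `seed`.
#' @param stages character vector of stages to run, any of
#'   `"ewas"`, `"twas"`, `"integrate"`, `"cessation"`, `"predict"`,
#'   `"qtl"`, `"phenotype"` (simulation and preprocessing always run).
#' @param fdr_level FDR level for the association scans.
#' @param reversal a [reversal_spec()].
#' @param n_repeats prediction splits.
#' @param qtl_window,qtl_alpha cis scan parameters.
#' @param seed global seed; expanded into per-stage substreams.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            stages = c("ewas", "twas", "integrate",
                                       "cessation", "predict", "qtl",
                                       "phenotype"),
                            fdr_level = 0.01,
                            reversal = reversal_spec(),
                            n_repeats = 1000,
                            qtl_window = 1e5,
                            qtl_alpha = 5e-5,
                            seed = 1L) {
  cohort$seed <- as.integer(seed)
  structure(list(cohort = cohort, stages = stages, fdr_level = fdr_level,
                 reversal = reversal, n_repeats = n_repeats,
                 qtl_window = qtl_window, qtl_alpha = qtl_alpha,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pipeline on a simulated cohort
#'
#' Executes simulate, preprocess (QC + residualization), EWAS, TWAS,
#' integration, cessation reversal, prediction, cis-meQTL mapping and the
#' longitudinal phenotype scan in order, skipping disabled stages.
#' Identical configuration and seed give identical results. When
#' `out_dir` is given, every stage table is written as TSV together with
#' a JSON manifest (seed, per-stage row counts, package version).
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return A named list of stage results (`sim`, `qc`, `ewas`, `twas`,
#'   `overlap`, `correlations`, `reversal`, `prediction`, `qtl`,
#'   `phenotype`, `manifest`); disabled stages are `NULL`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  on <- function(stage) stage %in% config$stages
  res <- list()

  sim <- simulate_cohort(config$cohort)
  res$sim <- sim

  qc <- qc_filter(sim$methylation)
  meth <- qc$matrix
  res$qc <- qc$report

  spec <- model_spec()
  if (on("ewas")) {
    res$ewas <- run_association(meth, sim$subjects, spec,
                                fdr_level = config$fdr_level)
  }
  if (on("twas")) {
    res$twas <- run_association(sim$expression, sim$subjects, spec,
                                fdr_level = config$fdr_level)
  }

  need_meth_resid <- on("integrate") || on("cessation") || on("qtl") ||
    on("phenotype")
  meth_resid <- NULL
  if (need_meth_resid) {
    meth_resid <- residualize_matrix(meth, sim$subjects)
  }
  expr_resid <- NULL
  if (on("integrate") || on("cessation")) {
    expr_log <- sim$expression
    expr_log$values <- log(expr_log$values + 1e-8)
    expr_resid <- residualize_matrix(expr_log, sim$subjects,
                                     transform = "rank_int")
  }

  if (on("integrate") && !is.null(res$ewas) && !is.null(res$twas)) {
    res$overlap <- overlap_dms_des(res$ewas, res$twas)
    pairs <- sim$truth$coupling[, c("probe_id", "gene_id")]
    pairs <- pairs[pairs$probe_id %in% rownames(meth_resid), , drop = FALSE]
    if (nrow(pairs) > 0) {
      cur <- sim$subjects$subject_id[
        sim$subjects$smoking_status == "current"]
      nev <- sim$subjects$subject_id[
        sim$subjects$smoking_status == "never"]
      res$correlations <- meth_expr_correlation(
        meth_resid, expr_resid, pairs,
        groups = list(current = cur, never = nev))
    }
  }

  if (on("cessation")) {
    sig_sites <- if (!is.null(res$ewas)) {
      res$ewas$site_id[res$ewas$significant]
    } else character()
    if (length(sig_sites) == 0) {
      sig_sites <- utils::head(rownames(meth_resid), 5)
    }
    res$reversal <- reversal_summary(meth_resid, sim$subjects,
                                     sites = sig_sites,
                                     spec = config$reversal)
  }

  if (on("predict")) {
    keep <- sim$subjects$smoking_status %in% c("current", "never")
    y <- sim$subjects$smoking_status[keep] == "current"
    feat_sites <- if (!is.null(res$ewas)) {
      utils::head(res$ewas$site_id[order(res$ewas$p)], 14)
    } else utils::head(rownames(meth$values), 14)
    feat_genes <- if (!is.null(res$twas)) {
      utils::head(res$twas$site_id[order(res$twas$p)], 5)
    } else utils::head(rownames(sim$expression$values), 5)
    X <- cbind(t(meth$values[feat_sites, keep, drop = FALSE]),
               t(log(sim$expression$values[feat_genes, keep,
                                           drop = FALSE] + 1e-8)))
    n_pos <- sum(y); n_neg <- sum(!y)
    res$prediction <- repeated_split_auc(
      X, y,
      n_train_pos = min(27, max(2, floor(n_pos / 2))),
      n_train_neg = min(145, max(2, floor(n_neg / 2))),
      n_repeats = config$n_repeats,
      seed = seed_stream(config$seed, 5L))
  }

  if (on("qtl")) {
    pos_tbl <- meth$annotation[, c("probe_id", "chrom", "pos")]
    res$qtl <- map_cis_qtl(meth_resid, sim$genotypes, pos_tbl,
                           window = config$qtl_window,
                           alpha = config$qtl_alpha)
  }

  if (on("phenotype")) {
    ids <- intersect(sim$phenotypes$subject_id, colnames(meth_resid))
    markers <- meth_resid[sim$truth$interaction$probe_id, ids,
                          drop = FALSE]
    res$phenotype <- scan_future_change(markers, sim$phenotypes,
                                        delta_from = "vfm")
  }

  res$manifest <- list(
    package_version = as.character(utils::packageVersion("adipotwin")),
    seed = config$seed,
    stages_run = intersect(c("ewas", "twas", "integrate", "cessation",
                             "predict", "qtl", "phenotype"),
                           config$stages),
    stages_skipped = setdiff(c("ewas", "twas", "integrate", "cessation",
                               "predict", "qtl", "phenotype"),
                             config$stages),
    n_subjects = nrow(sim$subjects),
    row_counts = list(
      ewas = if (is.null(res$ewas)) 0L else nrow(res$ewas),
      twas = if (is.null(res$twas)) 0L else nrow(res$twas),
      overlap = if (is.null(res$overlap)) 0L else nrow(res$overlap),
      reversal = if (is.null(res$reversal)) 0L else nrow(res$reversal),
      qtl = if (is.null(res$qtl)) 0L else nrow(res$qtl),
      phenotype = if (is.null(res$phenotype)) 0L
                  else nrow(res$phenotype)
    )
  )

  if (!is.null(out_dir)) write_bundle(res, sim, out_dir)
  res
}

# write each stage table as TSV plus a JSON manifest
write_bundle <- function(res, sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    if (!is.null(df)) {
      df <- tibble::as_tibble(df)
      listcols <- vapply(df, is.list, logical(1))
      df[listcols] <- lapply(df[listcols], function(col) {
        vapply(col, paste, character(1), collapse = ";")
      })
      readr::write_tsv(df, file.path(out_dir, paste0(name, ".tsv")))
    }
  }
  readr::write_tsv(sim$subjects, file.path(out_dir, "subjects.tsv"))
  w(res$ewas, "ewas")
  w(res$twas, "twas")
  w(res$overlap, "overlap")
  w(res$correlations, "correlations")
  w(res$reversal, "reversal")
  w(res$qtl, "qtl")
  w(res$phenotype, "phenotype")
  if (!is.null(res$prediction)) {
    readr::write_tsv(tibble::tibble(repeat_id =
                                      seq_along(res$prediction$aucs),
                                    auc = res$prediction$aucs),
                     file.path(out_dir, "prediction_aucs.tsv"))
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
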