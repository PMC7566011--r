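# Pipeline orchestration: a run configuration holding every tunable, and a
# run_pipeline() driver executing preprocess -> gene filter -> ensemble
# importance -> panel classification -> downstream stages, writing every
# stage output plus a reproducibility manifest.

#' Build a run configuration
#'
#' Collects every pipeline tunable with its standard default: Fisher-ratio
#' threshold 0.5, redundancy threshold 0.7, 500 trees with 5-fold CV, nine
#' hybrid datasets of 100 samples, an 80/20 split, 3 subtypes and 100
#' representative genes per subtype. Every random stage derives its seed
#' from the single master seed.
#'
#' @param fisher_threshold minimum Fisher ratio.
#' @param rho_threshold redundancy cut-off on |Spearman rho|.
#' @param n_trees ensemble size.
#' @param cv_folds folds for perturbation importance.
#' @param n_hybrid_datasets balanced datasets for the voting classifier.
#' @param hybrid_size samples per balanced dataset (even).
#' @param train_frac training fraction of the split.
#' @param k_subtypes clusters for subtype discovery.
#' @param top_n_representatives representative genes per subtype.
#' @param frac_threshold zero-fraction threshold of the preprocess filter.
#' @param perturb perturbation operator (`"mean"` or `"permute"`).
#' @param sampling ensemble balancing (`"bootstrap"` or `"hybrid"`).
#' @param seed master seed.
#' @param ... path entries (`expression`, `labels`, `survival`, `maf`,
#'   `methylation`) or overrides of any field.
#' @return a validated `RunConfig` list.
#' @export
run_config <- function(fisher_threshold = 0.5, rho_threshold = 0.7,
                       n_trees = 500, cv_folds = 5,
                       n_hybrid_datasets = 9, hybrid_size = 100,
                       train_frac = 0.8, k_subtypes = 3,
                       top_n_representatives = 100, frac_threshold = 0.5,
                       perturb = "mean", sampling = "bootstrap",
                       seed = 1, ...) {
  cfg <- list(fisher_threshold = fisher_threshold,
              rho_threshold = rho_threshold, n_trees = n_trees,
              cv_folds = cv_folds, n_hybrid_datasets = n_hybrid_datasets,
              hybrid_size = hybrid_size, train_frac = train_frac,
              k_subtypes = k_subtypes,
              top_n_representatives = top_n_representatives,
              frac_threshold = frac_threshold, perturb = perturb,
              sampling = sampling, seed = seed)
  cfg <- utils::modifyList(cfg, list(...))
  stopifnot(cfg$fisher_threshold >= 0, cfg$rho_threshold >= 0,
            cfg$rho_threshold <= 1, cfg$n_trees >= 1, cfg$cv_folds >= 2,
            cfg$train_frac > 0, cfg$train_frac < 1,
            cfg$hybrid_size %% 2 == 0, cfg$k_subtypes >= 2)
  structure(cfg, class = "RunConfig")
}

#' Load a run configuration from YAML (or JSON)
#'
#' @param path YAML or JSON config file; keys mirror [run_config()]
#'   arguments.
#' @param ... overrides applied after the file is read.
#' @return a `RunConfig`.
#' @export
load_run_config <- function(path, ...) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(run_config, utils::modifyList(vals, list(...)))
}

stage_failed <- function(out_dir, stage, err) {
  writeLines(paste0("FAILED at stage '", stage, "': ",
                    conditionMessage(err)),
             file.path(out_dir, "FAILED"))
  stop("pipeline failed at stage '", stage, "': ", conditionMessage(err),
       call. = FALSE)
}

#' Run the full pipeline on an expression matrix
#'
#' Executes preprocess, gene filter, ensemble importance / DEG selection,
#' panel classification, and (when the inputs are available) subtype
#' clustering, representative genes, survival comparison, methylation
#' correlation and mutation enrichment. Every stage output is written under
#' `out_dir` together with a JSON manifest of the configuration, derived
#' seeds, per-stage gene/sample counts and output checksums; re-running
#' with the same inputs and configuration reproduces identical outputs.
#'
#' @param m a labeled [expression_matrix()] (or a path readable by
#'   [load_expression()]; then `config$labels` must point to a label file).
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @param surv optional survival table (data.frame or TSV path).
#' @param mut optional mutation matrix (binary matrix or MAF path).
#' @param meth optional methylation beta matrix (matrix or TSV path).
#' @param stages stages to run after the mandatory selection stages;
#'   subset of `c("classify", "subtype", "enrich")`.
#' @return a `RunManifest` list (also written to `out_dir/manifest.json`).
#' @export
run_pipeline <- function(m, config = run_config(), out_dir = tempfile(),
                         surv = NULL, mut = NULL, meth = NULL,
                         stages = c("classify", "subtype", "enrich")) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(out_dir, "FAILED"))
  if (is.character(m)) {
    m <- load_expression(m, labels_path = config$labels)
  }
  if (is.character(surv)) surv <- load_survival(surv)
  if (is.character(mut)) mut <- load_maf(mut)
  if (is.character(meth)) {
    meth_m <- load_expression(meth)
    meth <- meth_m$values
  }
  if ("subtype" %in% stages && is.null(surv)) {
    stop("subtype stage requested but no survival table given; pass ",
         "`surv` or drop 'subtype' from `stages`", call. = FALSE)
  }
  if ("enrich" %in% stages && is.null(mut)) {
    stop("enrich stage requested but no mutation data given; pass `mut` ",
         "or drop 'enrich' from `stages`", call. = FALSE)
  }
  counts <- list(genes_in = nrow(m$values), samples = ncol(m$values))

  pp <- tryCatch(preprocess(m, frac_threshold = config$frac_threshold,
                            seed = derive_seed(config$seed, "preprocess")),
                 error = function(e) stage_failed(out_dir, "preprocess", e))
  counts$genes_after_preprocess <- nrow(pp$matrix$values)
  write_expression(pp$matrix, file.path(out_dir, "preprocessed.tsv"))

  gf <- tryCatch(filter_genes(pp$matrix,
                              fisher_threshold = config$fisher_threshold,
                              rho_threshold = config$rho_threshold),
                 error = function(e) stage_failed(out_dir, "gene_filter", e))
  counts$genes_after_fisher <- sum(gf$table$retained_after_fisher)
  counts$genes_after_redundancy <- length(gf$retained)
  utils::write.table(gf$table, file.path(out_dir, "gene_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  imp <- tryCatch(dt_ensemble_importance(
    pp$matrix, genes = gf$retained, n_trees = config$n_trees,
    cv = config$cv_folds, seed = derive_seed(config$seed, "ensemble"),
    perturb = config$perturb, sampling = config$sampling),
    error = function(e) stage_failed(out_dir, "dt_ensemble", e))
  degs <- select_degs(imp, pp$matrix)
  counts$n_degs <- nrow(degs)
  utils::write.table(degs, file.path(out_dir, "degs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(tree = seq_along(imp$weights), weight = imp$weights),
    file.path(out_dir, "tree_weights.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  results <- list(counts = counts)
  panel <- degs$gene_id

  if ("classify" %in% stages && length(panel) >= 1L) {
    ev <- tryCatch(evaluate_panel(
      pp$matrix, panel, train_frac = config$train_frac,
      n_datasets = config$n_hybrid_datasets, size = config$hybrid_size,
      seed = derive_seed(config$seed, "classify")),
      error = function(e) stage_failed(out_dir, "classify_eval", e))
    results$auc <- as.list(ev$auc)
    results$accuracy <- as.list(ev$accuracy)
    jsonlite::write_json(results["auc"], file.path(out_dir, "auc.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  assignment <- NULL
  if ("subtype" %in% stages && length(panel) >= config$k_subtypes) {
    assignment <- tryCatch(cluster_subtypes(
      pp$matrix, panel = panel, k = config$k_subtypes,
      seed = derive_seed(config$seed, "subtype")),
      error = function(e) stage_failed(out_dir, "downstream", e))
    utils::write.table(
      data.frame(sample_id = names(assignment$subtype),
                 subtype = unname(assignment$subtype)),
      file.path(out_dir, "subtypes.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    reps <- representative_genes(pp$matrix, assignment,
                                 top_n = config$top_n_representatives)
    for (s in names(reps)) {
      utils::write.table(reps[[s]],
                         file.path(out_dir,
                                   paste0("representative_subtype", s,
                                          ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    surv_matched <- surv[surv$sample_id %in% names(assignment$subtype), ,
                         drop = FALSE]
    lr <- logrank_test(surv_matched, assignment)
    results$logrank <- lr
    for (s in sort(unique(assignment$subtype))) {
      ids <- names(assignment$subtype)[assignment$subtype == s]
      km <- km_curve(surv_matched[surv_matched$sample_id %in% ids, ,
                                  drop = FALSE])
      utils::write.table(km, file.path(out_dir,
                                       paste0("km_subtype", s, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(meth)) {
      mc <- methylation_correlation(em_subset(pp$matrix, genes =
                                                intersect(panel,
                                                          rownames(meth))),
                                    meth)
      results$n_negative_methylation <- sum(mc$negative_flag)
      utils::write.table(mc, file.path(out_dir, "methylation_corr.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if ("enrich" %in% stages && !is.null(assignment)) {
    enr <- tryCatch(mutation_enrichment(mut, assignment),
                    error = function(e) stage_failed(out_dir, "downstream",
                                                     e))
    results$n_enriched_mutations <- sum(enr$q < 0.05)
    utils::write.table(enr, file.path(out_dir, "mutation_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- outputs[!grepl("manifest\\.json$", outputs)]
  manifest <- list(config = unclass(config),
                   seeds = list(
                     preprocess = derive_seed(config$seed, "preprocess"),
                     ensemble = derive_seed(config$seed, "ensemble"),
                     classify = derive_seed(config$seed, "classify"),
                     subtype = derive_seed(config$seed, "subtype")),
                   results = results,
                   checksums = as.list(tools::md5sum(sort(outputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(manifest, class = "RunManifest")
}
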