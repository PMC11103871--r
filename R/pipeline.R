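#' Pipeline configuration
#'
#' Bundles the per-stage parameters of [run_pipeline()]. The `test`
#' profile scales down only the stochastic workloads (number of random
#' candidate panels and EPC replicates); every analytical threshold is
#' identical between profiles.
#'
#' @param sim a [sim_config()] describing the synthetic study (ignored
#'   when real input files are supplied to [run_pipeline()]).
#' @param max_missing_ratio,knn_k preprocessing parameters.
#' @param dep_alpha,dep_fc_cut,dep_method DEP-calling thresholds.
#' @param enrich_alpha,enrich_q_alpha enrichment thresholds.
#' @param score_threshold PPI combined-score cutoff.
#' @param top_n_hubs per-metric list length for hub intersection.
#' @param epc_replicates,epc_keep_prob EPC Monte-Carlo settings.
#' @param mcode an [mcode_params()].
#' @param n_candidates,combo_size,n_folds,top_k,l1_strength,l2_strength
#'   combination-search parameters.
#' @param profile `"test"` (default: 2600 candidates, 200 EPC replicates)
#'   or `"full"` (26000 and 1000).
#' @param seed master seed; all stage seeds derive from it.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            max_missing_ratio = 0.5, knn_k = 5L,
                            dep_alpha = 0.05, dep_fc_cut = 0.58,
                            dep_method = "BH",
                            enrich_alpha = 0.05, enrich_q_alpha = 0.05,
                            score_threshold = 0.15, top_n_hubs = 10L,
                            epc_replicates = NULL, epc_keep_prob = 0.5,
                            mcode = mcode_params(),
                            n_candidates = NULL, combo_size = 5L,
                            n_folds = 5L, top_k = 25L,
                            l1_strength = 1, l2_strength = 1,
                            profile = c("test", "full"), seed = 1L) {
  profile <- match.arg(profile)
  if (is.null(n_candidates))
    n_candidates <- if (profile == "full") 26000L else 2600L
  if (is.null(epc_replicates))
    epc_replicates <- if (profile == "full") 1000L else 200L
  structure(list(sim = sim, max_missing_ratio = max_missing_ratio,
                 knn_k = as.integer(knn_k), dep_alpha = dep_alpha,
                 dep_fc_cut = dep_fc_cut, dep_method = dep_method,
                 enrich_alpha = enrich_alpha,
                 enrich_q_alpha = enrich_q_alpha,
                 score_threshold = score_threshold,
                 top_n_hubs = as.integer(top_n_hubs),
                 epc_replicates = as.integer(epc_replicates),
                 epc_keep_prob = epc_keep_prob, mcode = mcode,
                 n_candidates = as.integer(n_candidates),
                 combo_size = as.integer(combo_size),
                 n_folds = as.integer(n_folds), top_k = as.integer(top_k),
                 l1_strength = l1_strength, l2_strength = l2_strength,
                 profile = profile, seed = as.integer(seed)),
            class = "PipelineConfig")
}

.stage_log <- function(manifest, stage, ...) {
  info <- list(...)
  message(sprintf("[%s] %s", stage,
                  paste(names(info), unlist(info), sep = "=",
                        collapse = " ")))
  manifest$stages[[stage]] <- info
  manifest
}

#' Run the end-to-end pipeline on synthetic data
#'
#' Fixed stage order: simulate, preprocess, differential expression,
#' enrichment, network hubs, combination search, independent-cohort
#' validation, clinical correlation. Every stage writes its TSV output
#' before the next stage starts, and a JSON manifest records the seed,
#' parameters and per-stage row counts so a run can be audited and
#' reproduced byte-for-byte.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with all in-memory stage results plus
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempdir()) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)
  manifest <- list(seed = config$seed, profile = config$profile,
                   r_version = as.character(getRversion()),
                   stages = list())

  # -- simulate ------------------------------------------------------------
  sim <- config$sim
  sim$seed <- config$seed
  study <- simulate_study(sim)
  write_quant_matrix(study$discovery$quant, path("discovery_matrix.tsv"))
  write_quant_matrix(study$validation$quant, path("validation_matrix.tsv"))
  write_sample_table(rbind(study$discovery$samples,
                           study$validation$samples),
                     path("samples.tsv"))
  write_edge_list(study$edges, path("ppi_edges.tsv"))
  write_gmt(study$gene_sets, path("gene_sets.gmt"))
  jsonlite::write_json(
    list(dep_ids = study$truth$dep_ids,
         effects = as.list(study$truth$effects),
         panel_ids = study$truth$panel_ids,
         modules = study$truth$modules,
         planted_set = study$truth$planted_set),
    path("ground_truth.json"), auto_unbox = TRUE, digits = NA)
  manifest <- .stage_log(manifest, "simulate",
                         proteins = sim$n_proteins,
                         discovery_samples = nrow(study$discovery$samples),
                         validation_samples = nrow(study$validation$samples))

  # -- preprocess ----------------------------------------------------------
  proc <- preprocess_quant(study$discovery$quant, study$discovery$samples,
                           config$max_missing_ratio, config$knn_k)
  write_quant_matrix(proc, path("processed_matrix.tsv"))
  utils::write.table(attr(proc, "filter_report"),
                     path("filter_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- .stage_log(manifest, "preprocess",
                         proteins_in = sim$n_proteins,
                         proteins_kept = nrow(proc$values))

  # -- differential expression --------------------------------------------
  dep <- call_deps(differential_stats(proc, study$discovery$samples),
                   config$dep_alpha, config$dep_fc_cut, config$dep_method)
  utils::write.table(dep, path("dep_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- .stage_log(manifest, "dep", tested = nrow(dep),
                         deps = sum(dep$is_dep),
                         up = sum(dep$direction == "up"),
                         down = sum(dep$direction == "down"))

  # -- enrichment ----------------------------------------------------------
  enr <- fisher_enrichment(dep$protein[dep$is_dep], dep$protein,
                           study$gene_sets, config$enrich_alpha,
                           config$enrich_q_alpha)
  utils::write.table(enr, path("enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- .stage_log(manifest, "enrich", sets_tested = nrow(enr),
                         enriched = sum(enr$enriched))

  # -- network hubs --------------------------------------------------------
  graph <- build_ppi_graph(study$edges, dep$protein[dep$is_dep],
                           config$score_threshold)
  cent <- centrality_table(graph, config$epc_replicates,
                           config$epc_keep_prob,
                           epc_seed = config$seed + 1L,
                           mcode_params = config$mcode)
  hubs <- select_hubs(cent, config$top_n_hubs)
  utils::write.table(cent[order(-cent$degree, cent$protein), ],
                     path("centrality_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(hubs$hubs, path("hubs.txt"))
  manifest <- .stage_log(manifest, "hubs",
                         nodes = igraph::vcount(graph),
                         edges = igraph::ecount(graph),
                         connected = sum(igraph::degree(graph) > 0),
                         hubs = length(hubs$hubs))

  # -- combination search --------------------------------------------------
  ibm <- run_ibm(proc, study$discovery$samples, dep,
                 config$n_candidates, config$combo_size, config$n_folds,
                 config$top_k, config$l1_strength, config$l2_strength,
                 seed = config$seed + 2L)
  rec_df <- do.call(rbind, lapply(ibm$records, function(r)
    data.frame(candidate = paste(r$candidate, collapse = ";"),
               survivors = paste(sort(r$survivors), collapse = ";"),
               total_auc = r$total_auc, total_rmse = r$total_rmse,
               stringsAsFactors = FALSE)))
  utils::write.table(rec_df, path("candidates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(rec_df[ibm$priority$top, ], path("top_combos.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(rec_df[ibm$priority$top_dedup, ],
                     path("top_combos_dedup.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- .stage_log(manifest, "ibm", pool = length(ibm$pool),
                         candidates = config$n_candidates,
                         reserved = length(ibm$priority$reserved),
                         top_dedup = length(ibm$priority$top_dedup))

  # -- validation ----------------------------------------------------------
  val_proc <- preprocess_quant(study$validation$quant,
                               study$validation$samples,
                               config$max_missing_ratio, config$knn_k)
  val_dep <- call_deps(differential_stats(val_proc,
                                          study$validation$samples),
                       config$dep_alpha, config$dep_fc_cut,
                       config$dep_method)
  disc_labels <- stats::setNames(
    as.integer(study$discovery$samples$group == "case"),
    study$discovery$samples$sample_id)
  val_labels <- stats::setNames(
    as.integer(study$validation$samples$group == "case"),
    study$validation$samples$sample_id)
  val_rows <- list(); n_val <- 0L
  for (i in ibm$priority$top_dedup) {
    rec <- ibm$records[[i]]
    if (!all(rec$candidate %in% protein_ids(val_proc))) next
    v <- validate_combination(rec, proc, disc_labels, val_proc,
                              val_labels,
                              l1_strength = config$l1_strength,
                              l2_strength = config$l2_strength)
    n_val <- n_val + 1L
    val_rows[[n_val]] <- data.frame(
      candidate = paste(rec$candidate, collapse = ";"),
      discovery_auc = rec$total_auc, discovery_rmse = rec$total_rmse,
      validation_auc = v$auc, stringsAsFactors = FALSE)
  }
  val_df <- if (n_val) do.call(rbind, val_rows) else
    data.frame(candidate = character(), discovery_auc = numeric(),
               discovery_rmse = numeric(), validation_auc = numeric())
  utils::write.table(val_df, path("validation_auc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  shared <- intersect(union(hubs$hubs,
                            unlist(lapply(ibm$records[ibm$priority$top_dedup],
                                          `[[`, "survivors"))),
                      val_dep$protein)
  cons <- if (length(shared)) consistency_table(dep, val_dep, shared)
          else NULL
  if (!is.null(cons))
    utils::write.table(cons, path("consistency.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  manifest <- .stage_log(manifest, "validate", combos_validated = n_val,
                         consistency_rows =
                           if (is.null(cons)) 0L else nrow(cons))

  # -- clinical correlation ------------------------------------------------
  corr <- NULL
  cc <- sim$clinical_couplings
  if (!is.null(cc) && nrow(cc)) {
    targets <- unique(union(hubs$hubs, cc$protein))
    targets <- intersect(targets, protein_ids(proc))
    pieces <- list()
    for (cov in unique(cc$covariate)) {
      grp <- if (cov == "diabetes_years") "case" else c("case", "control")
      pieces[[cov]] <- spearman_correlate(proc, study$discovery$samples,
                                          targets, cov, groups = grp)
    }
    corr <- do.call(rbind, pieces)
    utils::write.table(corr, path("clinical_correlation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- .stage_log(manifest, "correlate",
                         rows = if (is.null(corr)) 0L else nrow(corr))

  jsonlite::write_json(manifest, path("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(study = study, processed = proc, dep = dep,
                 enrichment = enr, graph = graph, centrality = cent,
                 hubs = hubs, ibm = ibm, validation = val_df,
                 consistency = cons, correlation = corr,
                 manifest = manifest, out_dir = out_dir))
}
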