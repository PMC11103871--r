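#' Simulation configuration for the synthetic two-cohort study
#'
#' Defaults mirror the study design the pipeline targets: a discovery
#' cohort of 16 cases vs 10 controls and an independent validation cohort
#' of 8 vs 4; 874 quantified proteins of which 217 carry a planted group
#' effect of |log2FC| = 1.0 (128 up in cases, 89 down); log-normal
#' intensities; intensity-dependent (MNAR) missingness plus a small random
#' (MCAR) component; optionally a small fully separating "panel" of
#' high-abundance marker proteins and clinical covariates rank-correlated
#' with chosen proteins via a Gaussian copula.
#'
#' @param n_case,n_control discovery-cohort group sizes.
#' @param n_case_val,n_control_val validation-cohort group sizes.
#' @param n_proteins number of simulated proteins.
#' @param n_dep number of planted differentially abundant proteins.
#' @param effect_log2fc planted absolute case-vs-control shift, log2 units.
#' @param frac_up fraction of planted effects that are positive (up in
#'   cases).
#' @param protein_mean_range,protein_sd_range uniform ranges for per-protein
#'   baseline mean and standard deviation (log2 units).
#' @param mnar_intercept,mnar_slope logistic law for intensity-dependent
#'   missingness: a cell with true log2 intensity `x` is censored with
#'   probability `plogis(mnar_intercept - mnar_slope * x)`.
#' @param mcar_rate additional completely-random missingness probability.
#' @param n_panel number of planted panel proteins (`0` disables). Panel
#'   proteins sit at the top of the abundance range (`panel_mean`, so they
#'   are essentially never censored) with a tight `panel_sd` and a large
#'   `panel_effect`, which makes the two groups disjoint on each marker.
#' @param panel_effect,panel_sd,panel_mean panel parameters, log2 units.
#' @param clinical_couplings `data.frame` with columns `protein`,
#'   `covariate` (`"bcva_logmar"` or `"diabetes_years"`) and `rho` (target
#'   Spearman correlation across case samples), or `NULL`.
#' @param ppi list of PPI-simulation parameters: `n_modules`,
#'   `module_size`, `background_edge_prob`, `within_score_range`,
#'   `background_score_range`.
#' @param gene_sets list of gene-set-simulation parameters: `n_sets`,
#'   `set_size`, `planted_overlap_fraction`.
#' @param val_shift_sd sd of the per-protein baseline shift applied to the
#'   validation cohort, emulating a quantification-platform change
#'   (effect directions and sizes are reused, baselines are not).
#' @param seed integer master seed; every random draw in the generator
#'   flows from it through fixed substreams.
#' @return a `SimConfig` list.
#' @export
sim_config <- function(n_case = 16L, n_control = 10L,
                       n_case_val = 8L, n_control_val = 4L,
                       n_proteins = 874L, n_dep = 217L,
                       effect_log2fc = 1.0, frac_up = 128 / 217,
                       protein_mean_range = c(16, 26),
                       protein_sd_range = c(0.25, 0.6),
                       mnar_intercept = 14.4, mnar_slope = 0.8,
                       mcar_rate = 0.02,
                       n_panel = 0L, panel_effect = 3.0, panel_sd = 0.25,
                       panel_mean = 25,
                       clinical_couplings = NULL,
                       ppi = list(n_modules = 3L, module_size = 8L,
                                  background_edge_prob = 0.01,
                                  within_score_range = c(0.7, 0.99),
                                  background_score_range = c(0.15, 0.4)),
                       gene_sets = list(n_sets = 50L, set_size = 30L,
                                        planted_overlap_fraction = 0.8),
                       val_shift_sd = 1.0,
                       seed = 1L) {
  cfg <- list(n_case = as.integer(n_case), n_control = as.integer(n_control),
              n_case_val = as.integer(n_case_val),
              n_control_val = as.integer(n_control_val),
              n_proteins = as.integer(n_proteins), n_dep = as.integer(n_dep),
              effect_log2fc = effect_log2fc, frac_up = frac_up,
              protein_mean_range = protein_mean_range,
              protein_sd_range = protein_sd_range,
              mnar_intercept = mnar_intercept, mnar_slope = mnar_slope,
              mcar_rate = mcar_rate,
              n_panel = as.integer(n_panel), panel_effect = panel_effect,
              panel_sd = panel_sd, panel_mean = panel_mean,
              clinical_couplings = clinical_couplings,
              ppi = ppi, gene_sets = gene_sets,
              val_shift_sd = val_shift_sd, seed = as.integer(seed))
  stopifnot(cfg$n_dep + cfg$n_panel <= cfg$n_proteins,
            cfg$frac_up >= 0, cfg$frac_up <= 1,
            cfg$mcar_rate >= 0, cfg$mcar_rate <= 1,
            cfg$ppi$module_size >= 3L,
            all(cfg$protein_sd_range > 0))
  class(cfg) <- "SimConfig"
  cfg
}

# Deterministic substream seeds: all randomness flows from config$seed.
# Offsets keep derived seeds well inside 32-bit integer range.
.sub_seed <- function(seed, stream) {
  offsets <- c(proteins = 11L, discovery = 23L, validation = 37L,
               ppi = 53L, gene_sets = 71L, clinical = 89L, shift = 101L)
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stream]]
}

# Protein-level parameters shared by both cohorts: baselines, planted DEP
# identities and signed effects, panel membership. Drawn from a dedicated
# substream so discovery and validation see identical effects.
.protein_params <- function(config) {
  set.seed(.sub_seed(config$seed, "proteins"))
  n <- config$n_proteins
  ids <- sprintf("PROT%04d", seq_len(n))
  mu <- stats::runif(n, config$protein_mean_range[1],
                     config$protein_mean_range[2])
  sd <- stats::runif(n, config$protein_sd_range[1],
                     config$protein_sd_range[2])
  pool <- sample(ids)
  panel_ids <- if (config$n_panel > 0L) pool[seq_len(config$n_panel)]
               else character()
  dep_ids <- setdiff(pool, panel_ids)[seq_len(config$n_dep)]
  n_up <- round(config$frac_up * config$n_dep)
  effect <- stats::setNames(rep(0, n), ids)
  effect[dep_ids] <- config$effect_log2fc *
    rep(c(1, -1), c(n_up, config$n_dep - n_up))
  if (config$n_panel > 0L) {
    mu[match(panel_ids, ids)] <- config$panel_mean
    sd[match(panel_ids, ids)] <- config$panel_sd
    effect[panel_ids] <- config$panel_effect *
      sample(c(-1, 1), config$n_panel, replace = TRUE)
  }
  list(ids = ids, mu = mu, sd = sd, effect = effect,
       dep_ids = dep_ids, panel_ids = panel_ids)
}

#' Simulate one cohort of the synthetic study
#'
#' Baseline log2 intensities are Normal(mu_p, sd_p) per protein; planted
#' proteins add their signed effect to case samples. Each cell is then
#' censored with probability `plogis(mnar_intercept - mnar_slope * x)`
#' (missing-not-at-random, low-abundance cells vanish more often) and
#' additionally with `mcar_rate`. Protein effects (not values) are shared
#' across cohorts; the validation cohort draws fresh baselines plus a
#' per-protein shift, emulating a platform change. Clinical covariates are
#' attached to case samples through a Gaussian copula that targets the
#' configured Spearman correlation.
#'
#' @param config a [sim_config()].
#' @param cohort `"discovery"` or `"validation"`.
#' @return list with `quant` (a [quant_matrix()]), `samples` (sample
#'   table), and `truth`: the ground-truth ledger (`effects`, `dep_ids`,
#'   `panel_ids`, `true_values` before censoring, realized clinical
#'   couplings).
#' @export
simulate_cohort <- function(config, cohort = c("discovery", "validation")) {
  cohort <- match.arg(cohort)
  pp <- .protein_params(config)
  n_case <- if (cohort == "discovery") config$n_case else config$n_case_val
  n_ctrl <- if (cohort == "discovery") config$n_control else
    config$n_control_val
  mu <- pp$mu
  if (cohort == "validation") {
    set.seed(.sub_seed(config$seed, "shift"))
    mu <- mu + stats::rnorm(length(mu), 0, config$val_shift_sd)
  }
  set.seed(.sub_seed(config$seed, cohort))
  n <- config$n_proteins
  sid <- c(sprintf("%s_case_%02d", cohort, seq_len(n_case)),
           sprintf("%s_ctrl_%02d", cohort, seq_len(n_ctrl)))
  grp <- rep(c("case", "control"), c(n_case, n_ctrl))
  true <- matrix(stats::rnorm(n * length(sid), mean = mu, sd = pp$sd),
                 nrow = n, ncol = length(sid),
                 dimnames = list(pp$ids, sid))
  true[, grp == "case"] <- true[, grp == "case"] + pp$effect
  p_miss <- stats::plogis(config$mnar_intercept - config$mnar_slope * true)
  obs <- true
  obs[stats::runif(length(obs)) < p_miss] <- NA_real_
  obs[stats::runif(length(obs)) < config$mcar_rate] <- NA_real_

  samples <- data.frame(sample_id = sid, cohort = cohort, group = grp,
                        bcva_logmar = NA_real_, diabetes_years = NA_real_,
                        stringsAsFactors = FALSE)
  couplings <- NULL
  if (!is.null(config$clinical_couplings) &&
      nrow(config$clinical_couplings)) {
    set.seed(.sub_seed(config$seed, "clinical") +
               (cohort == "validation"))
    couplings <- config$clinical_couplings
    unknown <- setdiff(couplings$protein, pp$ids)
    if (length(unknown))
      stop("clinical coupling references unknown protein: ", unknown[[1L]])
    case_idx <- which(grp == "case")
    for (i in seq_len(nrow(couplings))) {
      prot <- couplings$protein[i]
      rho_s <- couplings$rho[i]
      # Gaussian copula: latent Pearson r reproducing the target Spearman.
      r <- 2 * sin(pi * rho_s / 6)
      x <- true[prot, case_idx]
      zx <- stats::qnorm((rank(x) - 0.5) / length(x))
      z <- r * zx + sqrt(1 - r^2) * stats::rnorm(length(x))
      cov_name <- couplings$covariate[i]
      val <- switch(cov_name,
                    bcva_logmar = pmax(0, 1.6 + 1.0 * z),
                    diabetes_years = pmax(0, 14.8 + 6.0 * z),
                    stop("unknown covariate: ", cov_name))
      samples[[cov_name]][case_idx] <- val
      couplings$realized_rho[i] <-
        stats::cor(x, val, method = "spearman")
    }
    # controls: BCVA near-normal vision, no diabetes history
    ctrl_idx <- which(grp == "control")
    if ("bcva_logmar" %in% couplings$covariate)
      samples$bcva_logmar[ctrl_idx] <-
        pmax(0, stats::rnorm(length(ctrl_idx), 0.2, 0.3))
  }
  truth <- list(effects = pp$effect[pp$effect != 0],
                dep_ids = pp$dep_ids, panel_ids = pp$panel_ids,
                true_values = true, couplings = couplings)
  list(quant = quant_matrix(obs, scale = "log2"),
       samples = validate_sample_table(samples), truth = truth)
}

#' Simulate a STRING-like PPI edge list with planted modules
#'
#' Plants `n_modules` node-disjoint cliques over planted DEP nodes, with
#' within-module combined scores drawn from `within_score_range`;
#' background edges appear independently with `background_edge_prob` and
#' scores from `background_score_range`.
#'
#' @param config a [sim_config()].
#' @param node_ids nodes of the network (must contain enough planted DEP
#'   nodes to host the modules).
#' @param truth ground-truth ledger from [simulate_cohort()]; module
#'   memberships are appended to it by the caller via the return value.
#' @return list with `edges` (canonical edge-list `data.frame`) and
#'   `modules` (list of member-id vectors).
#' @export
simulate_ppi <- function(config, node_ids, truth = NULL) {
  p <- config$ppi
  need <- p$n_modules * p$module_size
  if (need > length(node_ids))
    stop("module_size * n_modules exceeds number of nodes")
  set.seed(.sub_seed(config$seed, "ppi"))
  hosts <- intersect(node_ids,
                     if (!is.null(truth)) truth$dep_ids else node_ids)
  if (length(hosts) < need) hosts <- node_ids
  picked <- sample(hosts, need)
  modules <- split(picked, rep(seq_len(p$n_modules), each = p$module_size))
  names(modules) <- sprintf("module_%d", seq_len(p$n_modules))
  ea <- character(); eb <- character(); es <- numeric()
  for (m in modules) {
    prs <- utils::combn(sort(m), 2L)
    ea <- c(ea, prs[1L, ]); eb <- c(eb, prs[2L, ])
    es <- c(es, stats::runif(ncol(prs), p$within_score_range[1],
                             p$within_score_range[2]))
  }
  if (p$background_edge_prob > 0 && length(node_ids) >= 2L) {
    prs <- utils::combn(sort(node_ids), 2L)
    in_mod <- paste(prs[1L, ], prs[2L, ]) %in% paste(ea, eb)
    draw <- stats::runif(ncol(prs)) < p$background_edge_prob & !in_mod
    ea <- c(ea, prs[1L, draw]); eb <- c(eb, prs[2L, draw])
    es <- c(es, stats::runif(sum(draw), p$background_score_range[1],
                             p$background_score_range[2]))
  }
  list(edges = edge_list(ea, eb, es), modules = modules)
}

#' Simulate a gene-set collection with one planted enriched set
#'
#' The planted set draws `planted_overlap_fraction` of its members from the
#' planted DEPs (so it is genuinely over-represented in any query that
#' recovers them); the remaining sets are uniform draws from all proteins.
#'
#' @param config a [sim_config()].
#' @param truth ground-truth ledger from [simulate_cohort()].
#' @param all_ids all protein ids (the annotation universe).
#' @return a `GeneSetCollection`; the planted set is named
#'   `"planted_set"`.
#' @export
simulate_gene_sets <- function(config, truth, all_ids) {
  g <- config$gene_sets
  if (g$set_size > length(all_ids)) stop("set_size exceeds protein universe")
  n_from_dep <- round(g$planted_overlap_fraction * g$set_size)
  if (n_from_dep > length(truth$dep_ids))
    stop("planted_overlap_fraction * set_size exceeds number of planted DEPs")
  set.seed(.sub_seed(config$seed, "gene_sets"))
  non_dep <- setdiff(all_ids, truth$dep_ids)
  planted <- c(sample(truth$dep_ids, n_from_dep),
               sample(non_dep, g$set_size - n_from_dep))
  members <- c(list(sample(planted)),
               replicate(g$n_sets - 1L, sample(all_ids, g$set_size),
                         simplify = FALSE))
  nm <- c("planted_set", sprintf("random_set_%03d", seq_len(g$n_sets - 1L)))
  gene_set_collection(nm, rep("synthetic gene set", g$n_sets), members)
}

#' Simulate the complete synthetic study
#'
#' Convenience wrapper producing both cohorts plus the PPI network and
#' gene-set collection, with a merged ground-truth ledger.
#'
#' @param config a [sim_config()].
#' @return list with `discovery`, `validation` (each as in
#'   [simulate_cohort()]), `edges`, `gene_sets`, and `truth` (ledger
#'   including planted module memberships).
#' @export
simulate_study <- function(config) {
  disc <- simulate_cohort(config, "discovery")
  val <- simulate_cohort(config, "validation")
  ppi <- simulate_ppi(config, protein_ids(disc$quant), disc$truth)
  gs <- simulate_gene_sets(config, disc$truth, protein_ids(disc$quant))
  truth <- disc$truth
  truth$true_values <- NULL
  truth$modules <- ppi$modules
  truth$planted_set <- "planted_set"
  list(discovery = disc, validation = val, edges = ppi$edges,
       gene_sets = gs, truth = truth)
}
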