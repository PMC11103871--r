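#' Score a combination on an independent validation cohort
#'
#' Refits the two-stage penalized logistic model on the full discovery
#' cohort (default; `refit = FALSE` reuses the weights stored in the
#' record), then scores the validation samples and computes the ROC.
#' Validation features are z-scored with validation-cohort statistics:
#' discovery and validation matrices may come from different
#' quantification platforms, so only within-cohort standardized values
#' are comparable (the score is thus invariant to per-protein affine
#' rescaling of the validation matrix).
#'
#' @param record a [cross_validate_combo()] record.
#' @param disc_qm,disc_labels imputed discovery matrix and named 0/1
#'   labels.
#' @param val_qm,val_labels validation matrix (complete for the panel
#'   proteins) and named 0/1 labels.
#' @param refit refit on discovery data (default) or reuse stored weights.
#' @param l1_strength,l2_strength see [fit_plr()].
#' @param standardize `"validation"` (default) or `"discovery"`: which
#'   cohort's statistics standardize the validation features.
#' @return list with `auc`, `scores` (per validation sample), and `roc`
#'   (`data.frame` of the ROC step curve: `fpr` = 1 - specificity,
#'   `tpr` = sensitivity).
#' @export
validate_combination <- function(record, disc_qm, disc_labels,
                                 val_qm, val_labels, refit = TRUE,
                                 l1_strength = 1, l2_strength = 1,
                                 standardize = c("validation",
                                                 "discovery")) {
  standardize <- match.arg(standardize)
  panel <- record$candidate
  missing <- setdiff(panel, protein_ids(val_qm))
  if (length(missing))
    stop("protein absent from validation matrix: ", missing[[1L]])
  if (refit) {
    Xd <- t(disc_qm$values[panel, names(disc_labels), drop = FALSE])
    zs_d <- .zscore_fit(Xd)
    fit <- fit_plr(.zscore_apply(Xd, zs_d), as.integer(disc_labels),
                   l1_strength, l2_strength)
  } else {
    fit <- list(weights = record$weights, intercept = record$intercept)
  }
  Xv <- t(val_qm$values[panel, names(val_labels), drop = FALSE])
  if (anyNA(Xv)) stop("validation matrix has missing values for the panel")
  zs <- if (standardize == "validation") .zscore_fit(Xv)
        else .zscore_fit(t(disc_qm$values[panel, names(disc_labels),
                                          drop = FALSE]))
  scores <- predict_plr(fit, .zscore_apply(Xv, zs))
  y <- as.integer(val_labels)
  ord <- order(-scores)
  tpr <- cumsum(y[ord] == 1L) / sum(y == 1L)
  fpr <- cumsum(y[ord] == 0L) / sum(y == 0L)
  list(auc = roc_auc(scores, y), scores = stats::setNames(scores,
                                                          names(val_labels)),
       roc = data.frame(fpr = c(0, fpr), tpr = c(0, tpr)))
}

#' Cross-platform consistency of differential calls
#'
#' Compares log2 fold changes of selected proteins between a discovery
#' and a validation DEP table. A protein is `"Yes"`-consistent iff the
#' two fold changes have the same nonzero sign; significance is carried
#' through for reporting but plays no part in the call (the convention of
#' targeted-validation summaries, where the small validation cohort
#' rarely reaches significance).
#'
#' @param discovery,validation DEP tables from [call_deps()] (only
#'   `protein`, `log2fc`, `p_adj` are used).
#' @param proteins proteins to compare.
#' @return `data.frame` with `protein`, `log2fc_discovery`,
#'   `p_adj_discovery`, `log2fc_validation`, `p_adj_validation`,
#'   `consistent` (`"Yes"`/`"No"`, `NA` when absent from either table,
#'   flagged in `note`).
#' @export
consistency_table <- function(discovery, validation, proteins) {
  rows <- lapply(proteins, function(p) {
    di <- match(p, discovery$protein)
    vi <- match(p, validation$protein)
    lfc_d <- if (is.na(di)) NA_real_ else discovery$log2fc[di]
    lfc_v <- if (is.na(vi)) NA_real_ else validation$log2fc[vi]
    cons <- if (is.na(lfc_d) || is.na(lfc_v)) NA_character_
            else if (sign(lfc_d) != 0 && sign(lfc_d) == sign(lfc_v)) "Yes"
            else "No"
    data.frame(protein = p,
               log2fc_discovery = lfc_d,
               p_adj_discovery = if (is.na(di)) NA_real_
                                 else discovery$p_adj[di],
               log2fc_validation = lfc_v,
               p_adj_validation = if (is.na(vi)) NA_real_
                                  else validation$p_adj[vi],
               consistent = cons,
               note = if (is.na(di)) "absent from discovery"
                      else if (is.na(vi)) "absent from validation" else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Spearman correlation of protein abundance with a clinical covariate
#'
#' Tie-corrected Spearman rho (rank transform then Pearson) with a
#' two-sided p-value from the t approximation on n - 2 degrees of
#' freedom. Samples without the covariate are dropped; constant inputs
#' are flagged rather than erroring.
#'
#' @param qm a [quant_matrix()].
#' @param samples sample table carrying the covariate column.
#' @param proteins proteins to correlate.
#' @param covariate covariate column name (e.g. `"bcva_logmar"`,
#'   `"diabetes_years"`).
#' @param groups which sample groups to use (default both; diabetes
#'   duration is typically case-only since controls have none).
#' @return `data.frame` with `protein`, `covariate`, `rho`, `p`, `n`,
#'   `note`.
#' @export
spearman_correlate <- function(qm, samples, proteins, covariate,
                               groups = c("case", "control")) {
  if (!covariate %in% colnames(samples))
    stop("unknown covariate: ", covariate)
  use <- samples[samples$group %in% groups &
                   !is.na(samples[[covariate]]), , drop = FALSE]
  use <- use[use$sample_id %in% sample_ids(qm), , drop = FALSE]
  if (nrow(use) < 4L) stop("covariate defined for fewer than 4 samples")
  cov_vals <- use[[covariate]]
  rows <- lapply(proteins, function(p) {
    x <- qm$values[p, use$sample_id]
    ok <- !is.na(x)
    x <- x[ok]; yv <- cov_vals[ok]
    n <- length(x)
    if (n < 4L || stats::sd(x) == 0 || stats::sd(yv) == 0) {
      return(data.frame(protein = p, covariate = covariate,
                        rho = NA_real_, p = NA_real_, n = n,
                        note = "undefined (constant or too few values)",
                        stringsAsFactors = FALSE))
    }
    rho <- stats::cor(rank(x), rank(yv))
    pval <- if (abs(rho) >= 1) 0 else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * stats::pt(-abs(tstat), df = n - 2)
    }
    data.frame(protein = p, covariate = covariate, rho = rho, p = pval,
               n = n, note = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
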