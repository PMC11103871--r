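#' Per-protein two-group statistics
#'
#' Computes, for every protein, the log2 fold change (case mean minus
#' control mean, both on the log2 scale) and a two-sided Student's t-test
#' p-value. The classical pooled-variance test is the default; Welch's
#' unequal-variance variant is available behind `var_equal = FALSE`.
#' When both groups are constant with equal means the statistic is
#' undefined and p = 1 by convention.
#'
#' @param qm an imputed [quant_matrix()] (no missing values).
#' @param samples sample table; groups must each have >= 2 samples.
#' @param var_equal pooled-variance t-test if `TRUE` (default).
#' @return `data.frame` with columns `protein`, `log2fc`, `p_raw`.
#' @export
differential_stats <- function(qm, samples, var_equal = TRUE) {
  stopifnot(inherits(qm, "QuantMatrix"))
  v <- qm$values
  if (anyNA(v)) stop("matrix must be imputed before testing")
  grp <- samples$group[match(sample_ids(qm), samples$sample_id)]
  if (anyNA(grp)) stop("sample(s) missing from the sample table")
  if (sum(grp == "case") < 2L || sum(grp == "control") < 2L)
    stop("each group needs >= 2 samples")
  case <- v[, grp == "case", drop = FALSE]
  ctrl <- v[, grp == "control", drop = FALSE]
  log2fc <- rowMeans(case) - rowMeans(ctrl)
  p <- vapply(seq_len(nrow(v)), function(i) {
    x <- case[i, ]; y <- ctrl[i, ]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      if (mean(x) == mean(y)) return(1)
      return(0)
    }
    stats::t.test(x, y, var.equal = var_equal)$p.value
  }, numeric(1))
  data.frame(protein = protein_ids(qm), log2fc = log2fc, p_raw = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Adjust p-values for multiple testing
#'
#' Benjamini-Hochberg step-up by default (with the usual monotonicity
#' enforcement and cap at 1); `"bonferroni"` and `"BY"` are available.
#' Input order is preserved.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param method one of `"BH"`, `"bonferroni"`, `"BY"`.
#' @return adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p, method = c("BH", "bonferroni", "BY")) {
  method <- match.arg(method)
  if (any(!is.finite(p) | p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = method)
}

#' Call differentially expressed proteins
#'
#' A protein is a DEP iff its adjusted p-value is strictly below `alpha`
#' and |log2FC| strictly exceeds `fc_cut` (defaults 0.05 and 0.58, i.e.
#' a fold change of ~1.5x). Direction follows the sign of log2FC.
#'
#' @param stats output of [differential_stats()].
#' @param alpha adjusted-p threshold (strict `<`).
#' @param fc_cut absolute log2 fold-change threshold (strict `>`).
#' @param method multiple-testing method, see [bh_adjust()].
#' @return `DEPTable`: `stats` plus columns `p_adj`, `is_dep`, `direction`.
#' @export
call_deps <- function(stats, alpha = 0.05, fc_cut = 0.58, method = "BH") {
  stopifnot(all(c("protein", "log2fc", "p_raw") %in% colnames(stats)))
  out <- stats
  out$p_adj <- bh_adjust(pmax(stats$p_raw, .Machine$double.xmin),
                         method = method)
  out$is_dep <- out$p_adj < alpha & abs(out$log2fc) > fc_cut
  out$direction <- ifelse(!out$is_dep, "none",
                          ifelse(out$log2fc > 0, "up", "down"))
  out
}
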