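#' Filter proteins by per-group missing ratio
#'
#' A protein is retained iff its missing fraction is at most
#' `max_missing_ratio` within *each* group (the boundary is kept, i.e. the
#' rule is drop-if-strictly-greater; set `strict = FALSE` to drop the
#' boundary too). Row order of retained proteins is preserved.
#'
#' @param qm a [quant_matrix()].
#' @param samples sample table covering all columns of `qm`.
#' @param max_missing_ratio maximum tolerated per-group missing fraction
#'   (default 0.5).
#' @param strict if `TRUE` (default) drop only when the ratio strictly
#'   exceeds the threshold.
#' @return a filtered `QuantMatrix`; the filter report (per-group missing
#'   ratios and the keep decision for every protein) is attached as
#'   attribute `"filter_report"`.
#' @export
filter_missing <- function(qm, samples, max_missing_ratio = 0.5,
                           strict = TRUE) {
  stopifnot(inherits(qm, "QuantMatrix"),
            max_missing_ratio >= 0, max_missing_ratio <= 1)
  grp <- samples$group[match(sample_ids(qm), samples$sample_id)]
  if (anyNA(grp)) stop("sample(s) missing from the sample table")
  ratios <- do.call(cbind, lapply(c(case = "case", control = "control"),
                                  function(g) {
    cols <- grp == g
    if (!any(cols)) stop("group '", g, "' has zero samples")
    rowMeans(is.na(qm$values[, cols, drop = FALSE]))
  }))
  keep <- if (strict) rowSums(ratios <= max_missing_ratio) == 2L
          else rowSums(ratios < max_missing_ratio) == 2L
  report <- data.frame(protein = protein_ids(qm),
                       missing_ratio_case = ratios[, "case"],
                       missing_ratio_control = ratios[, "control"],
                       kept = keep, stringsAsFactors = FALSE)
  out <- quant_matrix(qm$values[keep, , drop = FALSE])
  attr(out, "filter_report") <- report
  out
}

#' Median-normalize samples to the grand median
#'
#' Shifts each sample's observed log2 values additively so that every
#' per-sample median equals the grand median of all observed values.
#' Missing cells are untouched. On log2 data an additive shift is a
#' per-sample scale factor on the raw scale, the standard correction for
#' between-run loading differences.
#'
#' @param qm a [quant_matrix()].
#' @return normalized `QuantMatrix`.
#' @export
median_normalize <- function(qm) {
  stopifnot(inherits(qm, "QuantMatrix"))
  v <- qm$values
  n_obs <- colSums(!is.na(v))
  if (any(n_obs == 0L))
    stop("sample with zero observed values: ",
         colnames(v)[n_obs == 0L][[1L]])
  grand <- stats::median(v, na.rm = TRUE)
  meds <- apply(v, 2L, stats::median, na.rm = TRUE)
  quant_matrix(sweep(v, 2L, meds - grand))
}

#' Impute missing values by k-nearest-neighbour proteins
#'
#' For each missing cell `(p, s)` the k proteins observed at sample `s`
#' with smallest root-mean-square log2 distance to `p` over their jointly
#' observed samples are averaged (unweighted). Scaling the Euclidean
#' distance by the square root of the shared-sample count makes distances
#' comparable across neighbour pairs with different overlap. Ties are
#' broken by row order; fewer than `k` eligible neighbours triggers a
#' warning and uses all available; zero eligible neighbours is an error.
#' Observed cells are never modified.
#'
#' @param qm a [quant_matrix()] (normally already filtered so every protein
#'   retains observations in both groups).
#' @param k number of neighbours (default 5).
#' @return a complete `QuantMatrix` with no missing cells.
#' @export
knn_impute <- function(qm, k = 5L) {
  stopifnot(inherits(qm, "QuantMatrix"), k >= 1L)
  v <- qm$values
  if (!anyNA(v)) return(qm)
  n <- nrow(v)
  need <- which(rowSums(is.na(v)) > 0L)
  out <- v
  warned <- FALSE
  for (p in need) {
    # RMS distance of every other protein to p over shared observed samples
    diffs <- sweep(v, 2L, v[p, ])
    d2 <- rowMeans(diffs^2, na.rm = TRUE)   # mean over jointly observed
    shared <- rowSums(!is.na(diffs))
    d2[shared == 0L] <- Inf
    d2[p] <- Inf
    for (s in which(is.na(v[p, ]))) {
      elig <- which(!is.na(v[, s]) & is.finite(d2))
      if (!length(elig))
        stop("no eligible neighbour for protein ", rownames(v)[p],
             " at sample ", colnames(v)[s])
      if (length(elig) < k && !warned) {
        warning("fewer than k eligible neighbours for some cells; ",
                "using all available")
        warned <- TRUE
      }
      ord <- elig[order(d2[elig], elig)]
      nb <- ord[seq_len(min(k, length(ord)))]
      out[p, s] <- mean(v[nb, s])
    }
  }
  quant_matrix(out)
}

#' Run the full preprocessing chain
#'
#' Fixed order: per-group missing-ratio filter, median normalization,
#' k-NN imputation. Normalization precedes imputation so imputed values
#' inherit the corrected sample medians. The output has no missing cells.
#'
#' @param qm a [quant_matrix()].
#' @param samples sample table for `qm`.
#' @param max_missing_ratio,knn_k,normalize preprocessing parameters
#'   (defaults 0.5, 5, `TRUE`).
#' @return imputed `QuantMatrix` with the `"filter_report"` attribute of
#'   [filter_missing()] carried through.
#' @export
preprocess_quant <- function(qm, samples, max_missing_ratio = 0.5,
                             knn_k = 5L, normalize = TRUE) {
  filt <- filter_missing(qm, samples, max_missing_ratio)
  rep <- attr(filt, "filter_report")
  if (normalize) filt <- median_normalize(filt)
  out <- knn_impute(filt, knn_k)
  attr(out, "filter_report") <- rep
  out
}
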