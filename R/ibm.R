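#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the fraction of (positive, negative)
#' score pairs ordered concordantly, counting ties as half. Identical to
#' the trapezoidal area under the (1 - specificity, sensitivity) step
#' curve, and invariant under strictly monotone transforms of the scores.
#'
#' @param scores numeric predictions (higher = more case-like).
#' @param labels 0/1 (or logical) class labels; both classes required.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels),
            all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Root-mean-squared error of probabilistic predictions
#' @param scores predicted class-1 probabilities in `[0, 1]`.
#' @param labels 0/1 class labels.
#' @return `sqrt(mean((scores - labels)^2))`.
#' @export
rmse_score <- function(scores, labels) {
  if (!length(scores)) stop("empty input")
  stopifnot(length(scores) == length(labels))
  sqrt(mean((scores - as.numeric(labels))^2))
}

#' Confusion counts at a probability threshold
#' @param scores predicted class-1 probabilities.
#' @param labels 0/1 class labels.
#' @param threshold decision threshold (default 0.5, predicted positive
#'   iff score >= threshold).
#' @return one-row `data.frame` with `tp`, `tn`, `fp`, `fn`, `sn`, `sp`.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  data.frame(tp = tp, tn = tn, fp = fp, fn = fn,
             sn = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
             sp = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Feature pool for the combination search (MDS step)
#'
#' The mutual-DEP selection pool: all proteins called differentially
#' expressed that are fully quantified in the processed matrix, in matrix
#' row order (deterministic).
#'
#' @param dep_table a DEP table from [call_deps()].
#' @param qm the imputed [quant_matrix()] the table was computed on.
#' @return character vector of protein ids.
#' @export
mds_pool <- function(dep_table, qm) {
  deps <- dep_table$protein[dep_table$is_dep]
  pool <- intersect(protein_ids(qm), deps)
  complete <- rowSums(is.na(qm$values[pool, , drop = FALSE])) == 0L
  pool <- pool[complete]
  if (!length(pool)) stop("empty feature pool: no fully quantified DEPs")
  pool
}

#' Generate random candidate combinations (CCG step)
#'
#' Draws `n_candidates` panels; each panel is `combo_size` distinct
#' proteins sampled uniformly from the pool. Repeated panels across draws
#' are allowed (and expected), matching a random search with duplicates.
#'
#' @param pool feature pool from [mds_pool()].
#' @param n_candidates number of random draws (default 26000; a study-scale
#'   run — scale down for quick profiles).
#' @param combo_size panel size per draw (default 5).
#' @param seed integer seed.
#' @return list of character vectors.
#' @export
generate_combinations <- function(pool, n_candidates = 26000L,
                                  combo_size = 5L, seed = 1L) {
  if (length(pool) < combo_size)
    stop("pool smaller than combo_size")
  set.seed(as.integer(seed))
  replicate(n_candidates, sample(pool, combo_size), simplify = FALSE)
}

# z-score columns with training statistics; zero-variance columns are
# centred only (scale 1) so a constant feature cannot produce NaN
.zscore_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[sd == 0 | is.na(sd)] <- 1
  list(mu = mu, sd = sd)
}
.zscore_apply <- function(X, zs) {
  sweep(sweep(X, 2L, zs$mu), 2L, zs$sd, "/")
}

#' Two-stage penalized logistic regression (L1 select, L2 refit)
#'
#' Stage 1 fits an L1-penalized (lasso) logistic model and deletes
#' features whose weight is exactly zero; stage 2 refits the survivors
#' with an L2 (ridge) penalty and returns the ridge weights. Features are
#' assumed already z-scored with training statistics. Penalty strengths
#' are expressed as inverse regularization C (sklearn-style); the glmnet
#' lambda is `1 / (n * C)`.
#'
#' @param X numeric matrix, samples x features, z-scored.
#' @param y 0/1 labels (both classes required).
#' @param l1_strength,l2_strength inverse regularization strengths
#'   (default 1).
#' @return list with `weights` (named, zeros for deleted features),
#'   `intercept`, `survivors` (feature names with nonzero stage-1 weight),
#'   `intercept_only` flag (TRUE when stage 1 deleted everything).
#' @export
fit_plr <- function(X, y, l1_strength = 1, l2_strength = 1) {
  y <- as.integer(y)
  stopifnot(is.matrix(X), nrow(X) == length(y),
            all(y %in% c(0L, 1L)), l1_strength > 0, l2_strength > 0)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  n <- nrow(X)
  feats <- colnames(X)
  if (is.null(feats)) feats <- paste0("f", seq_len(ncol(X)))
  pad <- function(M) if (ncol(M) >= 2L) M else
    cbind(M, `.pad.` = rep(0, nrow(M)))  # glmnet needs >= 2 columns
  f1 <- glmnet::glmnet(pad(X), y, family = "binomial", alpha = 1,
                       lambda = 1 / (n * l1_strength),
                       standardize = FALSE)
  w1 <- as.numeric(f1$beta)[seq_len(ncol(X))]
  survivors <- feats[w1 != 0]
  weights <- stats::setNames(rep(0, ncol(X)), feats)
  if (!length(survivors)) {
    return(list(weights = weights,
                intercept = stats::qlogis(mean(y == 1L)),
                survivors = character(), intercept_only = TRUE))
  }
  Xs <- X[, w1 != 0, drop = FALSE]
  f2 <- glmnet::glmnet(pad(Xs), y, family = "binomial", alpha = 0,
                       lambda = 1 / (n * l2_strength),
                       standardize = FALSE)
  weights[survivors] <- as.numeric(f2$beta)[seq_len(ncol(Xs))]
  list(weights = weights, intercept = as.numeric(f2$a0),
       survivors = survivors, intercept_only = FALSE)
}

#' Predict class-1 probabilities from a fitted PLR model
#' @param fit a [fit_plr()] result.
#' @param X samples x features matrix on the same (z-scored) scale and
#'   with the same columns as the training matrix.
#' @return numeric vector of probabilities.
#' @export
predict_plr <- function(fit, X) {
  as.numeric(stats::plogis(fit$intercept +
                             X %*% fit$weights[colnames(X)]))
}

# stratified fold assignment; returns integer folds, redrawing (seed + 1,
# ...) until every training set holds both classes
.stratified_folds <- function(y, n_folds, seed) {
  for (try in 0:100) {
    set.seed(as.integer(seed) + try)
    folds <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    ok <- all(vapply(seq_len(n_folds), function(f)
      length(unique(y[folds != f])) == 2L, TRUE))
    if (ok) {
      if (try > 0) message("fold partition redrawn ", try, " time(s)")
      return(folds)
    }
  }
  stop("could not stratify folds with both classes in every training set")
}

#' Cross-validate one candidate combination (FCP scoring)
#'
#' Stratified k-fold cross-validation (the default 5 folds gives the
#' 4:1 train:test split): per fold, features are z-scored with training
#' statistics, a two-stage penalized logistic model is fitted on the
#' training samples only, and the held-out samples are scored. The pooled
#' out-of-fold scores give the total AUC and total RMSE; per-fold
#' confusion counts at threshold 0.5 are recorded.
#'
#' @param candidate character vector of protein ids.
#' @param qm imputed [quant_matrix()] holding them.
#' @param labels named 0/1 vector (1 = case), names = sample ids.
#' @param n_folds folds (default 5).
#' @param l1_strength,l2_strength see [fit_plr()].
#' @param seed integer seed for the fold partition.
#' @param folds optional precomputed fold assignment (integer vector in
#'   `1:n_folds`, aligned with `labels`); bypasses the seeded draw.
#' @param refit_full also fit the model on the full data for reporting
#'   weights (default `TRUE`; the out-of-fold scores never depend on it).
#' @return a `CombinationRecord` list: `candidate`, `survivors` (union of
#'   per-fold survivors), `weights`, `intercept` (full-data refit),
#'   `total_auc`, `total_rmse`, `fold_assignments`, `pooled_oof_scores`,
#'   `fold_confusion`.
#' @export
cross_validate_combo <- function(candidate, qm, labels, n_folds = 5L,
                                 l1_strength = 1, l2_strength = 1,
                                 seed = 1L, folds = NULL,
                                 refit_full = TRUE) {
  X <- t(qm$values[candidate, names(labels), drop = FALSE])
  y <- as.integer(labels)
  if (is.null(folds)) folds <- .stratified_folds(y, n_folds, seed)
  oof <- numeric(length(y))
  confusion <- vector("list", n_folds)
  surv <- character()
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    zs <- .zscore_fit(X[tr, , drop = FALSE])
    fit <- fit_plr(.zscore_apply(X[tr, , drop = FALSE], zs), y[tr],
                   l1_strength, l2_strength)
    surv <- union(surv, fit$survivors)
    sc <- predict_plr(fit, .zscore_apply(X[!tr, , drop = FALSE], zs))
    oof[!tr] <- sc
    confusion[[f]] <- confusion_counts(sc, y[!tr])
  }
  # full-data refit: reporting weights only, never used for the
  # out-of-fold scores above
  full <- if (refit_full) {
    zs <- .zscore_fit(X)
    fit_plr(.zscore_apply(X, zs), y, l1_strength, l2_strength)
  } else list(weights = NULL, intercept = NULL)
  list(candidate = candidate, survivors = surv,
       weights = full$weights, intercept = full$intercept,
       total_auc = roc_auc(oof, y), total_rmse = rmse_score(oof, y),
       fold_assignments = folds, pooled_oof_scores = oof,
       fold_confusion = do.call(rbind, confusion))
}

#' Prioritize cross-validated combinations (FCP ranking)
#'
#' Reserves every record whose total AUC equals 1 (within 1e-12), sorts
#' the reserve by total RMSE ascending (ties by candidate order), takes
#' the `top_k` smallest, and removes duplicates by surviving-protein set.
#'
#' @param records list of [cross_validate_combo()] results.
#' @param top_k size of the RMSE-ranked shortlist (default 25).
#' @return list with `reserved` (indices into `records`, RMSE-sorted),
#'   `top` (first `top_k` of them) and `top_dedup` (after removing
#'   records whose survivor set duplicates an earlier one). Empty reserve
#'   yields empty vectors with a warning.
#' @export
prioritize_combinations <- function(records, top_k = 25L) {
  auc <- vapply(records, `[[`, 0, "total_auc")
  rmse <- vapply(records, `[[`, 0, "total_rmse")
  reserved <- which(auc >= 1 - 1e-12)
  if (!length(reserved)) {
    warning("no combination reached total AUC = 1")
    return(list(reserved = integer(), top = integer(),
                top_dedup = integer()))
  }
  reserved <- reserved[order(rmse[reserved], reserved)]
  top <- reserved[seq_len(min(top_k, length(reserved)))]
  key <- vapply(records[top],
                function(r) paste(sort(r$survivors), collapse = ";"), "")
  list(reserved = reserved, top = top, top_dedup = top[!duplicated(key)])
}

#' Run the full combination search
#'
#' MDS pool, CCG candidate generation and FCP cross-validated scoring and
#' prioritization in one call.
#'
#' @param qm imputed [quant_matrix()].
#' @param samples sample table (the `case` group is class 1).
#' @param dep_table DEP table from [call_deps()].
#' @param n_candidates,combo_size,n_folds,top_k,l1_strength,l2_strength
#'   search parameters; see the step functions.
#' @param seed integer master seed (candidate generation and each
#'   candidate's fold partition derive from it).
#' @return list with `pool`, `candidates`, `records`, and `priority`
#'   (see [prioritize_combinations()]).
#' @export
run_ibm <- function(qm, samples, dep_table, n_candidates = 26000L,
                    combo_size = 5L, n_folds = 5L, top_k = 25L,
                    l1_strength = 1, l2_strength = 1, seed = 1L) {
  pool <- mds_pool(dep_table, qm)
  candidates <- generate_combinations(pool, n_candidates, combo_size,
                                      seed = seed)
  labels <- stats::setNames(
    as.integer(samples$group == "case"), samples$sample_id)
  labels <- labels[intersect(sample_ids(qm), names(labels))]
  folds <- .stratified_folds(as.integer(labels), n_folds, seed + 1L)
  records <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    records[[i]] <- cross_validate_combo(
      candidates[[i]], qm, labels, n_folds,
      l1_strength, l2_strength, folds = folds, refit_full = FALSE)
  }
  priority <- prioritize_combinations(records, top_k)
  # reporting weights are needed only for the shortlisted records
  for (i in priority$top) {
    records[[i]] <- cross_validate_combo(
      candidates[[i]], qm, labels, n_folds,
      l1_strength, l2_strength, folds = folds, refit_full = TRUE)
  }
  list(pool = pool, candidates = candidates, records = records,
       priority = priority, folds = folds)
}
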