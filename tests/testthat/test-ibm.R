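test_that("AUC equals the pair-counting oracle and its closed forms", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 1, 0, 0, 1, 0)), 0.5)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  set.seed(13)
  for (i in 1:30) {
    n <- sample(4:30, 1)
    y <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) y <- c(0, 1, y[-(1:2)])
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # force ties
    expect_equal(roc_auc(sc, y), bf_auc(sc, y), tolerance = 1e-12)
    # invariance under strictly monotone transforms
    expect_equal(roc_auc(qlogis(pmin(pmax(sc, 0.01), 0.99)), y),
                 roc_auc(pmin(pmax(sc, 0.01), 0.99), y))
  }
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(14)
  for (i in 1:5) {
    y <- rep(c(0, 1), c(7, 9))
    sc <- rnorm(16)
    ref <- suppressMessages(as.numeric(pROC::auc(y, sc,
                                                 direction = "<")))
    expect_equal(roc_auc(sc, y), ref, tolerance = 1e-12)
  }
})

test_that("RMSE closed forms and permutation invariance", {
  expect_equal(rmse_score(c(0, 1, 1), c(0, 1, 1)), 0)
  expect_equal(rmse_score(rep(0.5, 4), c(0, 1, 0, 1)), 0.5)
  set.seed(15)
  sc <- runif(10); y <- sample(c(0, 1), 10, replace = TRUE)
  p <- sample(10)
  expect_equal(rmse_score(sc, y), rmse_score(sc[p], y[p]))
  expect_error(rmse_score(numeric(), numeric()), "empty")
})

test_that("confusion counts define Sn and Sp correctly", {
  cc <- confusion_counts(c(0.9, 0.6, 0.4, 0.2, 0.7), c(1, 0, 1, 0, 1))
  expect_equal(unlist(cc[c("tp", "tn", "fp", "fn")]),
               c(tp = 2, tn = 1, fp = 1, fn = 1))
  expect_equal(cc$sn, 2 / 3)
  expect_equal(cc$sp, 1 / 2)
})

test_that("the MDS feature pool is the fully quantified DEPs, order-stable", {
  v <- matrix(rnorm(40, 20), 4, 10)
  qm <- qm_fixture(v)
  dep <- data.frame(protein = protein_ids(qm),
                    is_dep = c(TRUE, FALSE, TRUE, TRUE))
  expect_identical(mds_pool(dep, qm), c("P01", "P03", "P04"))
  # sample order permutation leaves the pool unchanged
  qm2 <- quant_matrix(qm$values[, sample(10)])
  expect_identical(mds_pool(dep, qm), mds_pool(dep, qm2))
  dep$is_dep <- FALSE
  expect_error(mds_pool(dep, qm), "empty feature pool")
})

test_that("candidate generation is seeded, sized and duplicate-permitting", {
  pool <- sprintf("P%03d", 1:8)
  a <- generate_combinations(pool, 50, 5, seed = 3)
  b <- generate_combinations(pool, 50, 5, seed = 3)
  expect_identical(a, b)
  expect_true(all(lengths(a) == 5))
  expect_true(all(vapply(a, anyDuplicated, 0L) == 0L))
  # pool of exactly combo_size: every candidate is that set
  e <- generate_combinations(pool[1:5], 10, 5, seed = 1)
  expect_true(all(vapply(e, setequal, TRUE, y = pool[1:5])))
  expect_error(generate_combinations(pool[1:3], 5, 5), "smaller")
  # duplicate rate over many draws from a small space is substantial
  d <- generate_combinations(pool, 500, 5, seed = 9)
  keys <- vapply(d, function(x) paste(sort(x), collapse = ";"), "")
  expect_gt(mean(duplicated(keys)), 0.5)   # only C(8,5)=56 distinct panels
})

test_that("two-stage PLR keeps a separating feature with the right sign", {
  set.seed(19)
  n <- 26
  y <- rep(c(1, 0), c(16, 10))
  X <- cbind(sig = y * 3 + rnorm(n, 0, 0.3), noise = rnorm(n))
  zs <- proteopanel:::.zscore_fit(X)
  fit <- fit_plr(proteopanel:::.zscore_apply(X, zs), y)
  expect_true("sig" %in% fit$survivors)
  expect_gt(fit$weights["sig"], 0)
  expect_false(fit$intercept_only)
  # label flip negates the model and complements the probabilities
  fit2 <- fit_plr(proteopanel:::.zscore_apply(X, zs), 1 - y)
  pr1 <- predict_plr(fit, proteopanel:::.zscore_apply(X, zs))
  pr2 <- predict_plr(fit2, proteopanel:::.zscore_apply(X, zs))
  expect_equal(pr1, 1 - pr2, tolerance = 1e-4)
})

test_that("duplicated feature columns leave predictions essentially unchanged", {
  set.seed(20)
  y <- rep(c(1, 0), c(10, 10))
  x1 <- y * 2 + rnorm(20, 0, 0.5)
  X1 <- cbind(a = x1)
  X2 <- cbind(a = x1, b = x1)
  z1 <- proteopanel:::.zscore_fit(X1); z2 <- proteopanel:::.zscore_fit(X2)
  f1 <- fit_plr(proteopanel:::.zscore_apply(X1, z1), y)
  f2 <- fit_plr(proteopanel:::.zscore_apply(X2, z2), y)
  expect_gt(length(f2$survivors), 0)
  p1 <- predict_plr(f1, proteopanel:::.zscore_apply(X1, z1))
  p2 <- predict_plr(f2, proteopanel:::.zscore_apply(X2, z2))
  expect_equal(rank(p1), rank(p2))
  expect_lt(mean(abs(p1 - p2)), 0.15)
})

test_that("an uninformative fit degrades to a flagged intercept-only model", {
  set.seed(22)
  y <- rep(c(1, 0), 10)
  X <- cbind(n1 = rnorm(20, 0, 1e-4))
  zs <- proteopanel:::.zscore_fit(X)
  fit <- fit_plr(proteopanel:::.zscore_apply(X, zs), y, l1_strength = 0.01)
  expect_true(fit$intercept_only)
  expect_equal(unname(fit$weights), 0)
  expect_equal(predict_plr(fit, proteopanel:::.zscore_apply(X, zs)),
               rep(0.5, 20), tolerance = 1e-9)
})

test_that("cross-validation produces consistent, leakage-free records", {
  set.seed(25)
  v <- matrix(rnorm(8 * 26, 20, 1), 8, 26)
  v[1, ] <- v[1, ] + rep(c(3, 0), c(16, 10))  # separating protein
  qm <- qm_fixture(v)
  labels <- setNames(rep(c(1L, 0L), c(16, 10)), sample_ids(qm))
  rec <- cross_validate_combo(protein_ids(qm)[1:5], qm, labels, seed = 2)
  # internal consistency: stored totals recompute from the pooled scores
  expect_equal(rec$total_auc, roc_auc(rec$pooled_oof_scores, labels))
  expect_equal(rec$total_rmse, rmse_score(rec$pooled_oof_scores, labels))
  expect_equal(rec$total_auc, 1)   # disjoint groups on protein 1
  # stratification: every fold holds both classes in training
  for (f in 1:5)
    expect_equal(length(unique(labels[rec$fold_assignments != f])), 2L)
  # determinism
  rec2 <- cross_validate_combo(protein_ids(qm)[1:5], qm, labels, seed = 2)
  expect_identical(rec$pooled_oof_scores, rec2$pooled_oof_scores)
  # out-of-fold scores do not change when the full-data refit is skipped
  rec3 <- cross_validate_combo(protein_ids(qm)[1:5], qm, labels, seed = 2,
                               refit_full = FALSE)
  expect_identical(rec3$pooled_oof_scores, rec$pooled_oof_scores)
  expect_null(rec3$weights)
})

test_that("shuffled labels drive the cross-validated AUC to chance", {
  set.seed(26)
  v <- matrix(rnorm(30 * 26, 20, 1), 30, 26)
  qm <- qm_fixture(v)
  aucs <- sapply(1:50, function(s) {
    set.seed(1000 + s)
    labels <- setNames(sample(rep(c(1L, 0L), c(16, 10))), sample_ids(qm))
    cand <- sample(protein_ids(qm), 5)
    cross_validate_combo(cand, qm, labels, seed = s,
                         refit_full = FALSE)$total_auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("prioritization reserves AUC = 1, ranks by RMSE and dedups survivors", {
  mk <- function(auc, rmse, surv)
    list(total_auc = auc, total_rmse = rmse, survivors = surv,
         candidate = surv)
  recs <- list(mk(1, 0.30, c("a", "b")), mk(0.99, 0.01, "z"),
               mk(1, 0.10, c("b", "a")), mk(1, 0.20, "c"),
               mk(1, 0.10, "d"))
  pr <- prioritize_combinations(recs, top_k = 3)
  expect_false(2 %in% pr$reserved)              # AUC below 1 not reserved
  expect_identical(pr$reserved, c(3L, 5L, 4L, 1L))
  expect_identical(pr$top, c(3L, 5L, 4L))
  pr2 <- prioritize_combinations(recs, top_k = 5)
  expect_identical(pr2$top_dedup, c(3L, 5L, 4L))  # {a,b} duplicate removed
  expect_warning(pr0 <- prioritize_combinations(list(mk(0.9, 0.1, "a"))),
                 "no combination")
  expect_length(pr0$reserved, 0)
})
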