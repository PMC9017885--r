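test_that("feature assembly matches the standalone metric operations", {
  ch <- make_structure("random_compact", n = 10, seed = 23)
  fun <- functional_sites(c(3, 8))
  A <- perturbation_matrix(pseudo_inverse(build_hessian(ch)))
  fv <- assemble_features(ch, A, fun, 5)
  ids <- ch$residue_ids
  expect_equal(fv[["dfi_i"]], dfi(A, ids)$values[5])
  to_site <- dci(A, "5", ids)
  expect_equal(fv[["pct_dci_ji"]], mean(to_site$ranks[c(3, 8)]))
  expect_equal(fv[["dci_asym"]],
               dci(A, fun, ids)$values[5] - mean(to_site$values[c(3, 8)]))
  nb <- match(neighborhood(ch, 5, 7), ids)
  expect_equal(fv[["avg_dfi_7A"]], mean(dfi(A, ids)$values[nb]))
  # purity: identical inputs give identical features
  expect_identical(fv, assemble_features(ch, A, fun, 5))
})

test_that("tetrahedral symmetry and a tiny radius degenerate the features", {
  ch <- make_structure("tetrahedron")
  A <- perturbation_matrix(pseudo_inverse(build_hessian(ch)))
  fv <- assemble_features(ch, A, functional_sites(2), 4)
  expect_equal(fv[["dci_asym"]], 0, tolerance = 1e-12)
  fv0 <- assemble_features(ch, A, functional_sites(2), 4, radius = 0.1)
  expect_equal(fv0[["avg_dfi_7A"]], fv0[["dfi_i"]])
})

test_that("confusion-count metrics follow the printed formulas exactly", {
  # 8 TP, 7 TN, 2 FP, 3 FN encoded as scores around a 0.5 threshold
  truth <- c(rep(1, 8), rep(0, 7), rep(0, 2), rep(1, 3))
  scores <- c(rep(0.9, 8), rep(0.1, 7), rep(0.9, 2), rep(0.1, 3))
  ev <- evaluate_binary(scores, truth)
  expect_equal(c(ev$tp, ev$tn, ev$fp, ev$fn), c(8, 7, 2, 3))
  expect_equal(ev$accuracy, 0.75)
  expect_equal(ev$precision, 0.8)
  expect_equal(ev$recall, 8 / 11)
  # perfect separation
  ev2 <- evaluate_binary(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(c(ev2$accuracy, ev2$precision, ev2$recall, ev2$auc),
               c(1, 1, 1, 1))
  expect_warning(ev3 <- evaluate_binary(c(0.2, 0.8), c(1, 1)), "one class")
  expect_true(is.nan(ev3$auc))
})

test_that("the trapezoidal AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  for (k in 1:5) {
    truth <- rbinom(60, 1, 0.4)
    scores <- round(runif(60) + 0.5 * truth, 1)  # coarse grid injects ties
    ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(scores, truth), ref, tolerance = 1e-12)
  }
})

test_that("label-independent scores give chance-level AUC at large n", {
  set.seed(4)
  truth <- rbinom(20000, 1, 0.5)
  scores <- runif(20000)
  expect_equal(roc_auc(scores, truth), 0.5, tolerance = 0.02)
})

test_that("the network separates trivially separable features perfectly", {
  set.seed(2)
  n <- 60
  X <- cbind(f1 = c(rnorm(n / 2, -2), rnorm(n / 2, 2)), f2 = rnorm(n))
  y <- rep(0:1, each = n / 2)
  cv <- cross_validate(X, y, mlp_config(seed = 5), n_repeats = 1)
  expect_equal(cv$metrics$accuracy, 1)
  expect_equal(cv$metrics$auc, 1)
})

test_that("training is bit-reproducible under a fixed seed", {
  set.seed(9)
  X <- matrix(rnorm(120), 30, 4)
  y <- rbinom(30, 1, 0.5)
  cfg <- mlp_config(epochs = 50, seed = 31)
  f1 <- mlp_fit(X, y, cfg)
  f2 <- mlp_fit(X, y, cfg)
  expect_identical(f1$params, f2$params)
  expect_identical(predict(f1, X), predict(f2, X))
  expect_lt(tail(f1$loss, 1), f1$loss[1])  # loss decreases
  cv1 <- cross_validate(X, y, cfg, n_repeats = 2)
  cv2 <- cross_validate(X, y, cfg, n_repeats = 2)
  expect_identical(cv1$metrics, cv2$metrics)
})

test_that("standardisation is learned on training data and re-applied", {
  set.seed(13)
  X <- cbind(a = rnorm(40, 100, 5), b = rnorm(40, 0, 1e-3))
  y <- as.integer(X[, "a"] > 100)
  fit <- mlp_fit(X, y, mlp_config(epochs = 200, seed = 1), standardize = TRUE)
  expect_equal(unname(fit$scaling$center), unname(colMeans(X)))
  p <- predict(fit, X)
  expect_gt(roc_auc(p, y), 0.95)
})

test_that("feature tables carry the variant schema end to end", {
  ch <- make_structure("random_compact", n = 15, seed = 3)
  fun <- functional_sites(c(4, 11))
  A <- perturbation_matrix(pseudo_inverse(build_hessian(ch)))
  coh <- make_variant_cohort(ch, fun, 10, signal = 1, seed = 6, A = A)
  ft <- feature_table(ch, A, fun, coh$site, labels = coh$label,
                      protein_id = "toy")
  expect_named(ft, c("pdb_id", "residue_id", "dfi_i", "pct_dci_ji",
                     "dci_asym", "avg_dfi_7A", "disease"))
  expect_equal(nrow(ft), 10L)
  expect_true(all(ft$pct_dci_ji > 0 & ft$pct_dci_ji <= 1))
  expect_equal(ft$disease, coh$label)
})
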