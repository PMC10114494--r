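test_that("feature matrix has one row per image and a constant bias column", {
  fx <- get_test_cohort()
  X <- fx$features
  expect_equal(nrow(X), length(fx$preprocessed))
  expect_true(all(X[, ncol(X)] == 1))
  expect_false(anyNA(X))
  # duplicated image gives identical rows; row order follows input order
  imgs <- fx$preprocessed[c(1, 2, 1)]
  names(imgs) <- c("a", "b", "a2")
  Xd <- extract_features(imgs)
  expect_equal(Xd["a", ], Xd["a2", ])
  perm <- sample(length(fx$preprocessed))
  Xp <- extract_features(fx$preprocessed[perm])
  expect_equal(Xp, X[perm, ])
})

test_that("backbone dimension contract violations are caught", {
  bad <- list(p = 10L, id = "bad", fun = function(img) rep(1, 7))
  expect_error(extract_features(list(a = matrix(0, 4, 4)), bad), "declared p")
  expect_error(default_backbone(p = 30L), "multiple")
})

test_that("ridge interpolates square full-rank systems at lambda 0", {
  set.seed(10)
  X <- cbind(matrix(rnorm(20), 5, 4), 1)
  y <- rnorm(5)
  w <- fit_ridge(X, y, lambda2 = 0)
  expect_equal(predict_linear(X, w), y, tolerance = 1e-8)
})

test_that("extreme penalty shrinks weights and predictions to zero", {
  set.seed(11)
  X <- cbind(matrix(rnorm(200), 50, 4), 1)
  y <- rnorm(50, mean = 30, sd = 10)
  w <- fit_ridge(X, y, lambda2 = 1e9)
  expect_lt(sqrt(sum(w$w^2)), 1e-3)
  expect_lt(max(abs(predict_linear(X, w))), 0.1)
})

test_that("rank-deficient designs at lambda 0 raise an actionable error", {
  X <- cbind(1:6, (1:6) * 2, 1)
  expect_error(fit_ridge(X, rnorm(6), lambda2 = 0), "lambda2 > 0")
})

test_that("ridge weights match the iterative least-squares oracle", {
  set.seed(12)
  X <- cbind(matrix(rnorm(50 * 10), 50, 10), 1)
  y <- rnorm(50, 50, 20)
  w <- fit_ridge(X, y, lambda2 = 1)
  expect_lt(max(abs(w$w - cg_ridge(X, y, 1))), 1e-6)
})

test_that("prediction contracts hold", {
  X <- cbind(matrix(rnorm(20), 5, 4), 1)
  expect_equal(predict_linear(X, rep(0, 5)), rep(0, 5))
  expect_equal(predict_linear(matrix(1, 7, 1), 42), rep(42, 7))
  expect_error(predict_linear(X, rep(1, 3)), "dimension mismatch")
})

test_that("fold plans partition subjects evenly and keep subjects intact", {
  ids <- sprintf("S%02d", 1:10)
  f <- plan_folds(ids, k = 5, seed = 1)
  expect_setequal(names(f), ids)
  expect_true(all(table(f) == 2))
  # image-level subject ids collapse to one fold per subject
  imgs <- rep(ids, each = 4)
  f2 <- plan_folds(imgs, k = 5, seed = 1)
  expect_identical(f, f2)
  expect_false(identical(plan_folds(ids, 5, seed = 1),
                         plan_folds(ids, 5, seed = 2)))
  expect_error(plan_folds(ids[1:3], k = 5), "folds")
})

test_that("cross-validation yields exactly one held-out prediction per image", {
  fx <- get_test_cohort()
  meta <- fx$cohort$meta
  rows <- data.frame(image_id = meta$image_id, subject_id = meta$subject_id,
                     label = meta$true_density)
  pred <- densvar:::cv_ridge_predict(fx$features, rows, k = 5, seed = 2)
  expect_setequal(names(pred), meta$image_id)
  expect_false(anyNA(pred))
})

test_that("degenerate identical readers collapse the train/test grid", {
  fx <- get_test_cohort()
  ident <- list(reader_profile("A", noise_sd = 0, workload_weight = 1),
                reader_profile("B", noise_sd = 0, workload_weight = 1))
  lab <- assign_reader_pairs(fx$cohort, ident, seed = 3)
  g <- trts_grid(fx$features, lab, fx$cohort$meta, seed = 4)
  expect_equal(g$rank_corr, rep(g$rank_corr[1], 4), tolerance = 1e-10)
  expect_equal(g$rmse, rep(g$rmse[1], 4), tolerance = 1e-10)
})

test_that("small subsets are excluded with an explicit record", {
  fx <- get_test_cohort()
  pool <- get_test_pool()
  lab <- assign_reader_pairs(fx$cohort, pool, seed = 5)
  r <- run_subset_experiment(fx$features, lab, fx$cohort$meta,
                             subset_spec("individual", names(pool)[1],
                                         min_images = 10000))
  expect_true(r$excluded)
  expect_match(r$reason, "below the inclusion threshold")
})

test_that("with two readers the pair subset is the whole cohort", {
  fx <- get_test_cohort()
  two <- get_test_pool(m = 2)
  lab <- assign_reader_pairs(fx$cohort, two, seed = 6)
  r <- run_subset_experiment(fx$features, lab, fx$cohort$meta,
                             subset_spec("pair", names(two), min_images = 10),
                             seed = 7)
  expect_false(r$excluded)
  expect_equal(nrow(r$predictions), nrow(fx$cohort$meta))
})

test_that("testing against averaged labels beats individual labels under noise", {
  fx <- get_test_cohort()
  noisy <- lapply(c("A", "B", "C"), function(id) {
    reader_profile(id, noise_sd = 8, workload_weight = 1)
  })
  lab <- assign_reader_pairs(fx$cohort, noisy, seed = 8)
  g <- trts_grid(fx$features, lab, fx$cohort$meta, seed = 9)
  expect_lt(g$rmse[g$name == "Av-Av"], g$rmse[g$name == "Av-Ind"])
  expect_gt(g$rank_corr[g$name == "Av-Av"], g$rank_corr[g$name == "Av-Ind"])
})

test_that("rank correlation is invariant to monotone label warps", {
  fx <- get_test_cohort()
  meta <- fx$cohort$meta
  rows <- data.frame(image_id = meta$image_id, subject_id = meta$subject_id,
                     label = meta$true_density)
  pred <- densvar:::cv_ridge_predict(fx$features, rows, k = 5, seed = 10)
  pv <- pred[rows$image_id]
  keep <- !duplicated(rows$label)
  warped <- 100 * pbeta(rows$label[keep] / 100, 2.5, 0.7)
  expect_equal(spearman(pv[keep], rows$label[keep]),
               spearman(pv[keep], warped))
})
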