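test_that("empty cohort request yields empty, well-formed tables", {
  co <- generate_cohort(cohort_config(n_subjects = 0), seed = 1)
  expect_length(co$images, 0)
  expect_equal(nrow(co$meta), 0)
  expect_equal(nrow(co$subjects), 0)
})

test_that("cohort has four views per subject with bounded truths and pixels", {
  co <- generate_cohort(cohort_config(n_subjects = 10, image_size = 24), seed = 3)
  expect_equal(nrow(co$meta), 40)
  expect_true(all(table(co$meta$subject_id) == 4))
  expect_true(all(co$meta$true_density >= 0 & co$meta$true_density <= 100))
  expect_true(all(vapply(co$images, function(im) all(im >= 0 & im <= 1),
                         logical(1))))
  expect_setequal(unique(co$meta$view), c("CC", "MLO"))
  expect_setequal(unique(co$meta$laterality), c("L", "R"))
})

test_that("generation is bit-identical for a fixed seed", {
  cfg <- cohort_config(n_subjects = 5, image_size = 24)
  a <- generate_cohort(cfg, seed = 11)
  b <- generate_cohort(cfg, seed = 11)
  expect_identical(a$images, b$images)
  expect_identical(a$meta, b$meta)
})

test_that("configuration errors are caught", {
  expect_error(cohort_config(n_subjects = 10, image_size = 8), "image_size")
  expect_error(cohort_config(n_subjects = 10, missing_view_rate = -0.1),
               "missing_view_rate")
})

test_that("mean breast intensity increases with true density across the cohort", {
  co <- get_test_cohort()$cohort
  mask <- densvar:::breast_mask(32)
  mfi <- vapply(co$images, function(im) mean(im[mask]), numeric(1))
  expect_gt(nrow(co$meta), 200)
  expect_gt(spearman(mfi, co$meta$true_density), 0.9)
})

test_that("within-subject view densities are tightly correlated", {
  co <- get_test_cohort()$cohort
  spread <- tapply(co$meta$true_density, co$meta$subject_id, sd)
  # per-view jitter SD is 2 VAS points plus rendering discretization
  expect_lt(median(spread), 5)
})

test_that("reader score reduces to the warped truth without bias and noise", {
  img <- list(true_density = 37.5, tx_blobs = 0, tx_radius = 0, tx_cluster = 0)
  ident <- reader_profile("I", warp_shape = c(1, 1), noise_sd = 0)
  expect_equal(simulate_reader_score(ident, img), 37.5)
  # quadratic warp: 100 * (x/100)^2 is the Beta(2,1) CDF scaled to the VAS
  quad <- reader_profile("Q", warp_shape = c(2, 1), noise_sd = 0)
  truths <- seq(10, 90, by = 10)
  scores <- vapply(truths, function(td) {
    simulate_reader_score(quad, list(true_density = td, tx_blobs = 0,
                                     tx_radius = 0, tx_cluster = 0))
  }, numeric(1))
  expect_equal(scores, 100 * (truths / 100)^2)
  expect_true(all(diff(scores) > 0))
  expect_equal(spearman(scores, truths), 1)
})

test_that("reader score dimension mismatch is an error", {
  bad <- reader_profile("B", bias_weights = c(1, 2))
  img <- list(true_density = 50, tx_blobs = 0, tx_radius = 0, tx_cluster = 0)
  expect_error(simulate_reader_score(bad, img), "match")
})

test_that("random-error component has the configured moments", {
  prof <- reader_profile("N", noise_sd = 5)
  img <- list(true_density = 50, tx_blobs = 0, tx_radius = 0, tx_cluster = 0)
  set.seed(99)
  draws <- replicate(10000, simulate_reader_score(prof, img))
  # truth 50, sd 5: the clip at [0,100] is inactive
  expect_equal(mean(draws), 50, tolerance = 0.01)
  expect_equal(sd(draws), 5, tolerance = 0.05)
})

test_that("two readers differing only in warp agree on the image order", {
  co <- get_test_cohort()$cohort
  a <- reader_profile("A", warp_shape = c(0.6, 1.4), noise_sd = 0)
  b <- reader_profile("B", warp_shape = c(2.2, 0.8), noise_sd = 0)
  sa <- densvar:::score_images(a, co$meta)
  sb <- densvar:::score_images(b, co$meta)
  keep <- !duplicated(co$meta$true_density)  # ties would be artefactual
  expect_equal(spearman(sa[keep], sb[keep]), 1)
})

test_that("bias-only readers differ by exactly the texture term", {
  co <- get_test_cohort()$cohort
  a <- reader_profile("A", bias_weights = c(2, -1, 3), noise_sd = 0)
  b <- reader_profile("B", bias_weights = c(-1, 0, 1), noise_sd = 0)
  tx <- texture_attributes(co)
  sa <- densvar:::score_images(a, co$meta)
  sb <- densvar:::score_images(b, co$meta)
  expected <- as.numeric(tx %*% (a$bias_weights - b$bias_weights))
  inactive <- sa > 0 & sa < 100 & sb > 0 & sb < 100
  expect_equal((sa - sb)[inactive], expected[inactive])
})

test_that("paired RMSE under pure noise is about noise_sd * sqrt(2)", {
  co <- get_test_cohort()$cohort
  mid <- co$meta[co$meta$true_density > 20 & co$meta$true_density < 80, ]
  a <- reader_profile("A", noise_sd = 5)
  b <- reader_profile("B", noise_sd = 5)
  set.seed(5)
  diffs <- replicate(30, {
    sa <- densvar:::score_images(a, mid)
    sb <- densvar:::score_images(b, mid)
    rmse(sa, sb)
  })
  expect_equal(mean(diffs), 5 * sqrt(2), tolerance = 0.05)
})

test_that("label assignment covers every image twice with distinct readers", {
  co <- get_test_cohort()$cohort
  pool <- get_test_pool()
  lab <- assign_reader_pairs(co, pool, seed = 21)
  expect_equal(nrow(lab), 2 * nrow(co$meta))
  expect_true(all(table(lab$image_id) == 2))
  by_img <- tapply(lab$reader_id, lab$image_id, function(r) length(unique(r)))
  expect_true(all(by_img == 2))
  expect_true(all(lab$score >= 0 & lab$score <= 100))
  # determinism
  expect_identical(lab, assign_reader_pairs(co, pool, seed = 21))
})

test_that("two readers are forced onto every image; zero weight excludes", {
  co <- get_test_cohort()$cohort
  two <- get_test_pool(m = 2)
  lab2 <- assign_reader_pairs(co, two, seed = 1)
  expect_true(all(tapply(lab2$reader_id, lab2$image_id,
                         function(r) setequal(r, names(two)))))
  three <- get_test_pool(m = 3)
  three[[2]]$workload_weight <- 0
  lab3 <- assign_reader_pairs(co, three, seed = 1)
  expect_false(names(three)[2] %in% lab3$reader_id)
  one <- get_test_pool(m = 3)
  one[[1]]$workload_weight <- 0
  one[[2]]$workload_weight <- 0
  expect_error(assign_reader_pairs(co, one, seed = 1), "two readers")
})

test_that("per-reader workloads match the assignment scheme's sampling distribution", {
  co <- get_test_cohort()$cohort
  pool <- reader_pool(m = 13, seed = 31, noise_sd = 0)
  lab <- assign_reader_pairs(co, pool, seed = 55)
  obs <- table(factor(lab$reader_id, levels = names(pool)))
  # resampling oracle: replay the pair-level sampling scheme many times
  w <- vapply(pool, function(r) r$workload_weight, numeric(1))
  prs <- t(combn(13, 2))
  n <- nrow(co$meta)
  set.seed(123)
  sims <- replicate(600, {
    q <- w[prs[, 1]] * w[prs[, 2]] * exp(rnorm(nrow(prs), 0, 1.5))
    pk <- sample.int(nrow(prs), n, replace = TRUE, prob = q)
    tabulate(c(prs[pk, 1], prs[pk, 2]), nbins = 13)
  })
  lo <- apply(sims, 1, quantile, 0.005)
  hi <- apply(sims, 1, quantile, 0.995)
  expect_true(all(as.numeric(obs) >= lo & as.numeric(obs) <= hi))
})

test_that("case-control groups are exact and matching is feasible", {
  subs <- make_subjects(200, seed = 9)
  cc <- generate_case_control(subs, slope = 0.05, n_cases = 30,
                              controls_per_case = 3, seed = 4)
  expect_equal(sum(cc$is_case), 30)
  expect_equal(sum(!cc$is_case), 90)
  tab <- table(cc$match_group, cc$is_case)
  expect_true(all(tab[, "TRUE"] == 1) && all(tab[, "FALSE"] == 3))
  expect_equal(anyDuplicated(cc$subject_id), 0)
  expect_error(generate_case_control(subs, 0, n_cases = 60), "insufficient")
})
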