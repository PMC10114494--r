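test_that("masked loss follows the filtered sum-of-squares formula", {
  expect_equal(masked_loss(c(1, 2, 3), c(9, 9, 9), c(0, 0, 0)), 0)
  expect_equal(masked_loss(c(5, 99, -3), c(3, 0, 0), c(1, 0, 0)), 4)
  rho <- c(1.5, -2, 4); d <- c(1, 0, 5)
  expect_equal(masked_loss(rho, d, c(1, 1, 1)), sum((rho - d)^2))
  expect_error(masked_loss(rho, d, c(1, 0.5, 0)), "binary")
  expect_error(masked_loss(rho, d[1:2], c(1, 1)), "equal length")
})

test_that("masked-loss gradients match finite differences and vanish when masked", {
  set.seed(31)
  pred <- matrix(rnorm(12, 50, 10), 4, 3)
  d <- matrix(rnorm(12, 50, 10), 4, 3)
  phi <- matrix(rbinom(12, 1, 0.5), 4, 3)
  lb <- densvar:::masked_batch_loss(pred, d, phi)
  eps <- 1e-5
  for (i in seq_along(pred)) {
    pp <- pred; pp[i] <- pp[i] + eps
    pm <- pred; pm[i] <- pm[i] - eps
    num <- (densvar:::masked_batch_loss(pp, d, phi)$loss -
              densvar:::masked_batch_loss(pm, d, phi)$loss) / (2 * eps)
    expect_equal(lb$grad[i], num, tolerance = 1e-6)
    if (phi[i] == 0) expect_identical(lb$grad[i], 0)
  }
})

test_that("augmentation is identity, mirror, or calibrated noise as configured", {
  set.seed(32)
  img <- matrix(runif(24 * 24), 24, 24)
  none <- list(flip_prob = 0, max_rotation_deg = 0, noise_sd = 0)
  expect_identical(augment(img, none, seed = 1), img)
  flip <- list(flip_prob = 1, max_rotation_deg = 0, noise_sd = 0)
  expect_equal(augment(img, flip, seed = 1), img[, 24:1])
  big <- matrix(runif(100 * 100), 100, 100)
  noise <- list(flip_prob = 0, max_rotation_deg = 0, noise_sd = 0.05)
  diff <- augment(big, noise, seed = 2) - big
  expect_equal(mean(diff), 0, tolerance = 0.002)
  expect_equal(sd(diff), 0.05, tolerance = 0.002)
  # deterministic per seed
  expect_identical(augment(big, noise, seed = 2), augment(big, noise, seed = 2))
})

test_that("a short training run is finite, recorded, and reproducible", {
  set.seed(33)
  imgs <- lapply(1:32, function(i) matrix(runif(24 * 24), 24, 24))
  names(imgs) <- sprintf("i%02d", 1:32)
  y <- runif(32, 0, 100)
  cfg <- train_config("single", feature_dim = 8, learning_rates = 1e-3,
                      epochs = 1, batch_size = 8, patience = Inf, seed = 2,
                      augmentation = list(flip_prob = 0.5,
                                          max_rotation_deg = 5,
                                          noise_sd = 0.01))
  mod <- train_model(imgs[1:24], y[1:24], imgs[25:32], y[25:32], cfg)
  expect_s3_class(mod, "density_cnn")
  expect_equal(nrow(mod$history), 1)
  expect_true(is.finite(mod$history$train_loss))
  expect_true(is.finite(mod$best_val_rmse))
  mod2 <- train_model(imgs[1:24], y[1:24], imgs[25:32], y[25:32], cfg)
  expect_equal(mod$net, mod2$net)
})

test_that("never-observed readers keep their initial head weights exactly", {
  set.seed(34)
  imgs <- lapply(1:40, function(i) matrix(runif(24 * 24), 24, 24))
  names(imgs) <- sprintf("i%02d", 1:40)
  m <- 5
  # readers 1-4 appear; reader 5 never does
  d <- matrix(NA_real_, m, 40)
  for (j in 1:40) d[sample(4, 2), j] <- runif(2, 0, 100)
  phi <- 1 * !is.na(d)
  cfg <- train_config("multi", m = m, feature_dim = 8,
                      learning_rates = 1e-3, epochs = 2, batch_size = 8,
                      patience = Inf, seed = 6,
                      augmentation = list(flip_prob = 0, max_rotation_deg = 0,
                                          noise_sd = 0))
  mod <- train_model(imgs[1:32], d[, 1:32], imgs[33:40], d[, 33:40], cfg,
                     mask_train = phi[, 1:32], mask_val = phi[, 33:40])
  init <- densvar:::init_cnn(24, 8, m, densvar:::child_seed(6, 1),
                             densvar:::child_seed(6, 2))
  expect_identical(mod$net$head$W[, 5], init$head$W[, 5])
  expect_identical(mod$net$head$b[5], init$head$b[5])
  # observed readers did move
  expect_false(isTRUE(all.equal(mod$net$head$W[, 1], init$head$W[, 1])))
  # and the shared trunk was updated by every image
  expect_gt(sum((mod$net$conv[[1]]$W - init$conv[[1]]$W)^2), 0)
})

test_that("masked label matrices place each score at its reader and image", {
  lab <- data.frame(image_id = c("a", "a", "b", "b"),
                    reader_id = c("R1", "R3", "R2", "R3"),
                    score = c(10, 20, 30, 40))
  mk <- masked_label_matrix(lab, c("R1", "R2", "R3"), c("a", "b"))
  expect_equal(mk$d["R1", "a"], 10)
  expect_equal(mk$d["R3", "b"], 40)
  expect_equal(sum(mk$phi), 4)
  expect_true(all(colSums(mk$phi) == 2))
  expect_error(masked_label_matrix(lab, c("R1", "R2"), c("a", "b")), "missing")
})

test_that("representations are deterministic and batch-independent", {
  set.seed(35)
  imgs <- lapply(1:6, function(i) matrix(runif(24 * 24), 24, 24))
  names(imgs) <- letters[1:6]
  mod <- untrained_model(24, feature_dim = 8, seed = 9)
  r1 <- extract_representation(mod, imgs)
  expect_equal(dim(r1), c(6, 8))
  expect_identical(r1, extract_representation(mod, imgs))
  r2 <- extract_representation(mod, imgs[c(3, 1)])
  expect_equal(r2["c", ], r1["c", ])
  dup <- extract_representation(mod, list(x = imgs[[2]], y = imgs[[2]]))
  expect_equal(dup["x", ], dup["y", ])
})
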