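# Shared fixtures and independent oracles for the test suite.

# Conjugate-gradient solver for the ridge normal equations
# (X'X + lambda I) w = X'y: an iterative least-squares oracle independent of
# the QR route used by fit_ridge.
cg_ridge <- function(X, y, lambda, tol = 1e-14, max_iter = 5000L) {
  A <- crossprod(X) + diag(lambda, ncol(X))
  b <- crossprod(X, y)
  w <- rep(0, ncol(X))
  r <- b - A %*% w
  p <- r
  rs <- sum(r^2)
  for (i in seq_len(max_iter)) {
    Ap <- A %*% p
    alpha <- rs / sum(p * Ap)
    w <- w + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r^2)
    if (sqrt(rs_new) < tol) break
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  as.numeric(w)
}

# Brute-force Spearman oracle: average ranks, then the Pearson formula
# written out directly.
spearman_bruteforce <- function(a, b) {
  ra <- rank(a, ties.method = "average")
  rb <- rank(b, ties.method = "average")
  num <- sum((ra - mean(ra)) * (rb - mean(rb)))
  den <- sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  num / den
}

# Subject table matching the generator's stated population (right-skewed
# Beta(2, 3.5) densities), for case-control tests that need no images.
make_subjects <- function(n, seed) {
  set.seed(seed)
  data.frame(subject_id = sprintf("S%04d", seq_len(n)),
             density = 100 * rbeta(n, 2, 3.5),
             age = round(runif(n, 47, 73)),
             stringsAsFactors = FALSE)
}

# Memoized mid-size cohort shared across test files (240 images, 32 px).
.fixtures <- new.env()
get_test_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    .fixtures$cohort <- generate_cohort(
      cohort_config(n_subjects = 60, image_size = 32), seed = 404)
    .fixtures$preprocessed <- preprocess_cohort(
      .fixtures$cohort, preprocess_config(target_size = 32))
    .fixtures$features <- extract_features(.fixtures$preprocessed)
  }
  list(cohort = .fixtures$cohort, preprocessed = .fixtures$preprocessed,
       features = .fixtures$features)
}

# A small reading panel with all three variability components active.
get_test_pool <- function(m = 5L, noise_sd = 8, seed = 77L, ...) {
  reader_pool(m = m, seed = seed, noise_sd = noise_sd, ...)
}
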