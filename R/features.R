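#' Default fixed convolutional feature backbone
#'
#' A deterministic, seeded filter bank standing behind the pluggable
#' feature-extractor interface: images are resized to `input_size`, cut into
#' dense overlapping patches, passed through random (but fixed per backbone
#' id) filters with ReLU, and mean-pooled over a `cells` x `cells` spatial
#' grid, yielding `p = cells^2 * n_filters` features per image. Small
#' patches at stride 1 respond to fine dense-tissue texture, which is what
#' survives histogram equalization. The same image always maps to the same
#' feature row, regardless of batch composition.
#'
#' @param p Feature dimension (must be a multiple of `cells^2`).
#' @param input_size Internal working resolution.
#' @param patch Patch side length.
#' @param stride Patch stride.
#' @param cells Pooling grid side (default 4, i.e. 16 spatial cells).
#' @param seed Seed fixing the filter bank; part of the backbone identity.
#' @return Object of class `feature_backbone`: a function-bearing list with
#'   fields `p`, `id` and `fun(image_matrix) -> numeric(p)`.
#' @export
default_backbone <- function(p = 256L, input_size = 32L, patch = 3L,
                             stride = 1L, cells = 4L, seed = 20201L) {
  if (p %% (cells^2) != 0L) {
    stop(sprintf("`p` must be a multiple of cells^2 = %d", cells^2),
         call. = FALSE)
  }
  n_filters <- as.integer(p / cells^2)
  filt <- with_seed(seed, {
    matrix(stats::rnorm(patch * patch * n_filters), patch * patch, n_filters)
  })
  pos <- seq(1L, input_size - patch + 1L, by = stride)
  np <- length(pos)
  # index matrix: rows of the im2col matrix for one image
  idx <- matrix(0L, patch * patch, np * np)
  k <- 1L
  for (j in pos) for (i in pos) {
    idx[, k] <- as.integer(outer(i:(i + patch - 1L),
                                 (j:(j + patch - 1L) - 1L) * input_size, `+`))
    k <- k + 1L
  }
  ci <- pmin(ceiling(rep(seq_len(np), times = np) / (np / cells)), cells)
  cj <- pmin(ceiling(rep(seq_len(np), each = np) / (np / cells)), cells)
  cell <- (cj - 1L) * cells + ci
  fun <- function(img) {
    if (!all(dim(img) == c(input_size, input_size))) {
      img <- as.matrix(EBImage::resize(img, w = input_size, h = input_size))
    }
    cols <- matrix(img[idx], nrow(idx))
    a <- pmax(crossprod(filt, cols), 0)         # n_filters x positions
    pooled <- vapply(seq_len(cells^2),
                     function(q) rowMeans(a[, cell == q, drop = FALSE]),
                     numeric(n_filters))
    as.numeric(pooled)
  }
  structure(list(p = as.integer(p), id = sprintf("fixed-convbank-%d-%d", p, seed),
                 fun = fun),
            class = "feature_backbone")
}

#' Extract a feature matrix from preprocessed images
#'
#' Runs every image through the (deterministic) backbone and appends a
#' constant bias column of ones, giving the n x (p+1) design matrix used by
#' the closed-form ridge mapping.
#'
#' @param images Named list of preprocessed image matrices.
#' @param backbone A `feature_backbone` (default [default_backbone()]); any
#'   list with fields `p` and `fun` satisfies the contract.
#' @return n x (p+1) numeric matrix; rownames are image ids; the last
#'   column is the all-ones bias.
#' @export
extract_features <- function(images, backbone = default_backbone()) {
  n <- length(images)
  X <- matrix(NA_real_, n, backbone$p + 1L)
  for (i in seq_len(n)) {
    f <- backbone$fun(images[[i]])
    if (length(f) != backbone$p) {
      stop(sprintf("backbone returned %d features but declared p = %d",
                   length(f), backbone$p), call. = FALSE)
    }
    X[i, ] <- c(f, 1)
  }
  rownames(X) <- names(images)
  X
}
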