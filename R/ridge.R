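#' Closed-form ridge mapping from features to density
#'
#' Solves `w = (X'X + lambda2 I)^{-1} X' y`, the unique minimizer of the
#' L2-penalized squared error, via QR of the sqrt(lambda2)-augmented design
#' rather than an explicit inverse. The penalty applies to every column of
#' `X`, including the bias column.
#'
#' @param X n x (p+1) design matrix (features plus bias column).
#' @param y Length-n label vector.
#' @param lambda2 Non-negative ridge strength (default 1).
#' @return Object of class `ridge_weights`: list with `w` (named by `X`
#'   columns when present) and `lambda2`.
#' @export
fit_ridge <- function(X, y, lambda2 = 1) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("rows of X must align with y", call. = FALSE)
  assert_scalar_number(lambda2, "lambda2", lo = 0)
  p1 <- ncol(X)
  if (lambda2 == 0) {
    qrX <- qr(X)
    if (qrX$rank < p1) {
      stop("X is rank-deficient and lambda2 = 0: the ridge system is singular; set lambda2 > 0",
           call. = FALSE)
    }
    w <- qr.coef(qrX, y)
  } else {
    Xa <- rbind(X, diag(sqrt(lambda2), p1))
    ya <- c(y, rep(0, p1))
    w <- qr.coef(qr(Xa), ya)
  }
  structure(list(w = as.numeric(w), lambda2 = lambda2),
            class = "ridge_weights")
}

#' Linear prediction from ridge weights
#'
#' Returns `X w`. Predictions are reported as-is and may fall outside
#' \[0,100\]; no clipping is applied.
#'
#' @param X Design matrix with the same column count as the fitted weights.
#' @param w A [fit_ridge()] result (or bare numeric weight vector).
#' @return Numeric prediction vector, named by `X` rownames when present.
#' @export
predict_linear <- function(X, w) {
  wv <- if (inherits(w, "ridge_weights")) w$w else as.numeric(w)
  X <- as.matrix(X)
  if (ncol(X) != length(wv)) {
    stop(sprintf("dimension mismatch: X has %d columns, w has length %d",
                 ncol(X), length(wv)), call. = FALSE)
  }
  drop(X %*% wv)
}

#' Plan subject-level cross-validation folds
#'
#' Assigns every subject (woman) to exactly one of `k` folds so that all
#' images of a subject share a fold and no subject leaks across the
#' train/test boundary. Fold sizes differ by at most one subject.
#'
#' @param subject_ids Character vector of subject ids (one entry per image
#'   or per subject; duplicates collapse to one subject).
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Named integer vector mapping each unique subject id to a fold in
#'   `1..k`.
#' @export
plan_folds <- function(subject_ids, k = 5L, seed = 1L) {
  subs <- unique(as.character(subject_ids))
  if (length(subs) < k) {
    stop(sprintf("cannot split %d subjects into %d folds", length(subs), k),
         call. = FALSE)
  }
  with_seed(seed, {
    fold <- rep(seq_len(k), length.out = length(subs))
    names(fold) <- sample(subs)
    fold[order(names(fold))]
  })
}

# Held-out ridge predictions for a set of training rows.
#
# `rows` is a data.frame with columns image_id, subject_id, label; images may
# appear more than once (individual-label training uses each (image, score)
# pair as a row). The ridge strength is scaled by the rows-per-image ratio of
# the training fold so that duplicating an image's rows does not weaken the
# effective per-image regularization: training on both reader scores is then
# exactly equivalent to training on their per-image mean, as the squared
# loss implies. Every *distinct* image receives exactly one held-out
# prediction from the model whose training fold excluded its subject.
cv_ridge_predict <- function(X, rows, k = 5L, lambda2 = 1, seed = 1L) {
  folds <- plan_folds(rows$subject_id, k = k, seed = seed)
  fold_of <- folds[rows$subject_id]
  img_idx <- match(rows$image_id, rownames(X))
  if (anyNA(img_idx)) stop("label rows refer to images missing from X", call. = FALSE)
  uniq <- !duplicated(rows$image_id)
  pred <- rep(NA_real_, sum(uniq))
  names(pred) <- rows$image_id[uniq]
  for (f in seq_len(k)) {
    tr <- fold_of != f
    te <- which(uniq & fold_of == f)
    if (!length(te)) next
    ratio <- sum(tr) / length(unique(rows$image_id[tr]))
    wfit <- fit_ridge(X[img_idx[tr], , drop = FALSE], rows$label[tr],
                      lambda2 * ratio)
    pred[rows$image_id[te]] <- predict_linear(X[img_idx[te], , drop = FALSE], wfit)
  }
  pred
}
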