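#' Cross-validation fold plan
#'
#' Assigns each trial to one of \code{k} folds after randomizing trial order,
#' so folds partition the trials with sizes differing by at most one and each
#' trial is tested exactly once.
#'
#' @param n_trials number of trials
#' @param k number of folds (default 10)
#' @param seed shuffle seed
#' @param y optional class labels; when given, the assignment is stratified
#'   (each class dealt round-robin after shuffling) so every fold contains
#'   both classes even at small trial counts
#' @return integer vector of fold indices in 1..k, length \code{n_trials}
#' @export
make_fold_plan <- function(n_trials, k = 10, seed = 1L, y = NULL) {
  if (n_trials < k)
    stop("fewer trials (", n_trials, ") than folds (", k, ")", call. = FALSE)
  with_seed(seed, {
    if (is.null(y)) {
      fold <- rep_len(seq_len(k), n_trials)
      fold[sample.int(n_trials)]
    } else {
      stopifnot(length(y) == n_trials)
      fold <- integer(n_trials)
      offset <- sample.int(k, 1L)
      for (cl in sample(unique(y))) {
        idx <- which(y == cl)
        idx <- idx[sample.int(length(idx))]
        fold[idx] <- (seq_along(idx) + offset) %% k + 1L
        offset <- offset + length(idx)
      }
      fold
    }
  })
}

#' Within-class balancing by undersampling
#'
#' Within each class of the decoded dimension, undersamples trials at random
#' so the two levels of the orthogonal dimension are equally frequent. This
#' prevents the classifier for one target from exploiting information about
#' the other target's position.
#'
#' @param trials per-trial metadata with \code{h_class} and \code{v_class}
#' @param dimension "horizontal" (decode left/right, balance top/bottom
#'   within each class) or "vertical" (the converse)
#' @param seed undersampling seed
#' @return integer vector of retained trial indices (sorted)
#' @export
balance_within_class <- function(trials, dimension = c("horizontal",
                                                       "vertical"),
                                 seed = 1L) {
  dimension <- match.arg(dimension)
  dec <- if (dimension == "horizontal") trials$h_class else trials$v_class
  oth <- if (dimension == "horizontal") trials$v_class else trials$h_class
  if (length(unique(dec)) < 2L)
    stop("both classes of the decoded dimension must be present",
         call. = FALSE)
  with_seed(seed, {
    keep <- integer(0)
    for (cl in unique(dec)) {
      idx <- which(dec == cl)
      tab <- split(idx, oth[idx])
      if (length(tab) < 2L || any(lengths(tab) == 0L))
        stop("class ", cl, " lacks trials on one level of the orthogonal ",
             "dimension; cannot balance", call. = FALSE)
      m <- min(lengths(tab))
      keep <- c(keep, unlist(lapply(tab, function(i)
        if (length(i) > m) sample(i, m) else i), use.names = FALSE))
    }
    sort(keep)
  })
}

#' Between-class balancing by interpolation-based oversampling
#'
#' Equalizes class counts by adding synthetic minority-class samples, each a
#' convex combination of a minority sample and one of its k nearest minority
#' neighbors (SMOTE-style interpolation). Applied to training folds only,
#' never to test folds. With a single minority sample, duplication is used
#' with a warning.
#'
#' @param x training data: matrix (trials x features) or 3-d array
#'   (trials x channels x samples); synthetic trials interpolate the whole
#'   tensor
#' @param y class labels, two levels
#' @param k number of nearest neighbors among the minority class (default 5)
#' @param seed interpolation seed
#' @return list with augmented \code{x} (same layout as input), \code{y}, and
#'   \code{n_synthetic}
#' @export
balance_between_class <- function(x, y, k = 5, seed = 1L) {
  dims <- dim(x)
  flat <- if (length(dims) == 3L) matrix(x, nrow = dims[1L]) else as.matrix(x)
  tab <- table(y)
  if (length(tab) != 2L) stop("exactly two classes required", call. = FALSE)
  n_add <- max(tab) - min(tab)
  if (n_add == 0L)
    return(list(x = x, y = y, n_synthetic = 0L))
  minority <- names(tab)[which.min(tab)]
  mi <- which(y == minority)
  synth <- with_seed(seed, {
    if (length(mi) == 1L) {
      warning("single minority sample; duplicating instead of interpolating",
              call. = FALSE)
      flat[rep(mi, n_add), , drop = FALSE]
    } else {
      m <- flat[mi, , drop = FALSE]
      # squared distances via the Gram-matrix identity
      sq <- rowSums(m^2)
      d2 <- outer(sq, sq, "+") - 2 * tcrossprod(m)
      diag(d2) <- Inf
      kk <- min(k, length(mi) - 1L)
      nn <- apply(d2, 1L, function(r) order(r)[seq_len(kk)])
      nn <- matrix(nn, ncol = length(mi)) # kk x n_min
      base <- sample.int(length(mi), n_add, replace = TRUE)
      pick <- vapply(base, function(i) nn[sample.int(kk, 1L), i], integer(1))
      u <- stats::runif(n_add)
      m[base, , drop = FALSE] +
        u * (m[pick, , drop = FALSE] - m[base, , drop = FALSE])
    }
  })
  out_flat <- rbind(flat, synth)
  out <- if (length(dims) == 3L)
    array(out_flat, dim = c(nrow(out_flat), dims[2L], dims[3L]))
  else out_flat
  list(x = out, y = c(y, rep(minority, n_add)), n_synthetic = n_add)
}

# Ledoit-Wolf shrinkage of a covariance toward a scaled identity.
# z: rows already centered (per class for pooled LDA); returns the shrunk
# covariance. Closed form avoids per-sample outer products.
shrink_covariance <- function(z) {
  n <- nrow(z); p <- ncol(z)
  s <- crossprod(z) / n
  m <- sum(diag(s)) / p
  d2 <- sum((s - diag(m, p))^2) / p
  if (d2 < .Machine$double.eps) return(diag(m, p))
  # sum_i ||z_i z_i' - S||_F^2 = sum_i ||z_i||^4 - n ||S||_F^2
  b2 <- min(d2, (sum(rowSums(z^2)^2) / n - sum(s^2)) / (n * p))
  lambda <- b2 / d2
  lambda * diag(m, p) + (1 - lambda) * s
}

#' Train a regularized linear discriminant classifier
#'
#' Pooled-covariance LDA with equal priors. With 64 channels and a few
#' hundred trials the pooled covariance is ill-conditioned, so by default it
#' is regularized by Ledoit-Wolf shrinkage toward a scaled identity; the
#' closed-form shrinkage intensity is estimated from the training data, so a
#' singular covariance is never an error.
#'
#' @param x training matrix, trials x channels
#' @param y labels with two levels
#' @param classes optional length-2 character vector fixing class order; the
#'   first is the positive class (decision scores > 0 predict it)
#' @param shrinkage "ledoit" (default) or "none" (plain pooled covariance)
#' @return list with \code{w} (channel weights), \code{b} (intercept),
#'   \code{classes}; the decision score of a sample \code{v} is
#'   \code{sum(w * v) + b}
#' @export
train_lda <- function(x, y, classes = NULL, shrinkage = c("ledoit", "none")) {
  shrinkage <- match.arg(shrinkage)
  if (!is.matrix(x)) x <- as.matrix(x)
  if (is.null(classes)) classes <- sort(unique(as.character(y)))
  stopifnot(length(classes) == 2L, all(y %in% classes))
  i1 <- y == classes[1L]; i2 <- y == classes[2L]
  n1 <- sum(i1); n2 <- sum(i2); n <- n1 + n2; p <- ncol(x)
  if (n1 < 2L || n2 < 2L)
    stop("need at least 2 samples per class", call. = FALSE)
  mu1 <- colMeans(x[i1, , drop = FALSE])
  mu2 <- colMeans(x[i2, , drop = FALSE])
  # pooled within-class scatter without forming the centered matrix
  scatter <- crossprod(x) - n1 * tcrossprod(mu1) - n2 * tcrossprod(mu2)
  sigma <- if (shrinkage == "ledoit") {
    s <- scatter / n
    m <- sum(diag(s)) / p
    d2 <- sum((s - diag(m, p))^2) / p
    if (d2 < .Machine$double.eps) diag(m, p) else {
      # ||z_i||^2 of the class-centered rows, computed from the raw rows
      rs <- rowSums(x^2)
      zi2 <- numeric(n)
      zi2[i1] <- rs[i1] - 2 * drop(x[i1, , drop = FALSE] %*% mu1) +
        sum(mu1^2)
      zi2[i2] <- rs[i2] - 2 * drop(x[i2, , drop = FALSE] %*% mu2) +
        sum(mu2^2)
      b2 <- min(d2, (sum(zi2^2) / n - sum(s^2)) / (n * p))
      lambda <- b2 / d2
      lambda * diag(m, p) + (1 - lambda) * s
    }
  } else scatter / (n - 2L)
  w <- tryCatch(solve(sigma, mu1 - mu2),
                error = function(e) solve(sigma + diag(1e-8, ncol(x)),
                                          mu1 - mu2))
  list(w = as.vector(w), b = -sum(w * (mu1 + mu2)) / 2, classes = classes)
}

#' Area under the ROC curve from decision scores
#'
#' Rank-based AUC: the Mann-Whitney U statistic normalized by the number of
#' class pairs, with tied scores counted one half. Equals the probability
#' that a random positive-class score exceeds a random negative-class score.
#'
#' @param scores numeric decision scores
#' @param labels class labels, two levels
#' @param positive label of the positive class (default: first sorted level)
#' @return AUC in [0, 1]
#' @export
auc_from_scores <- function(scores, labels,
                            positive = sort(unique(as.character(labels)))[1L]) {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Forward-model activation pattern from classifier weights
#'
#' Multiplies the channel weights by the data covariance of the training set
#' at the same timepoint, turning the (uninterpretable) backward-model
#' weights into a forward-model pattern interpretable as neural sources.
#'
#' @param w channel weight vector
#' @param x training data at that timepoint, trials x channels
#' @return activation pattern, one value per channel
#' @export
activation_map <- function(w, x) {
  as.vector(stats::cov(as.matrix(x)) %*% w)
}

#' Per-timepoint cross-validated decoding of a target dimension
#'
#' For the chosen spatial dimension (horizontal: left vs right; vertical: top
#' vs bottom), trains one linear discriminant per timepoint and fold on nine
#' of ten folds and tests on the tenth, repeating until every fold served as
#' test set. Within-class balancing (undersampling over the orthogonal
#' dimension) is applied once before fold assignment; between-class
#' balancing (interpolation oversampling) is applied to each training fold
#' only. AUC is computed per fold and timepoint and averaged over folds;
#' every retained trial receives a confidence score (signed distance from the
#' decision boundary, positive = first class, i.e. "left"/"top") from the
#' fold in which it was test data.
#'
#' @param epochs a preprocessed \code{\link{epochs_set}}
#' @param dimension "horizontal" or "vertical"
#' @param folds number of folds (default 10)
#' @param seed seed for fold shuffling, balancing and oversampling
#' @param window_ms optional time window to decode (default: whole epoch)
#' @param shrinkage covariance regularization, see \code{\link{train_lda}}
#' @param balance apply the two balancing steps (default TRUE; disable for
#'   perfectly balanced simulated data to save time)
#' @return object of class \code{decoding_result}: \code{auc} (per-timepoint,
#'   fold-averaged), \code{confidence} (trial x timepoint), \code{weights}
#'   and \code{activation} (timepoint x channel, fold-averaged),
#'   \code{times_ms}, \code{classes}, \code{dimension}, \code{fold}
#'   (per-trial test fold), \code{trials} (metadata of retained trials)
#' @export
crossval_decode <- function(epochs, dimension = c("horizontal", "vertical"),
                            folds = 10, seed = 1L, window_ms = NULL,
                            shrinkage = c("ledoit", "none"), balance = TRUE) {
  dimension <- match.arg(dimension)
  shrinkage <- match.arg(shrinkage)
  stopifnot(inherits(epochs, "epochs_set"))
  classes <- if (dimension == "horizontal") c("left", "right") else
    c("top", "bottom")

  keep <- if (balance)
    balance_within_class(epochs$trials, dimension,
                         derive_seed(seed, "within")) else
    seq_len(nrow(epochs$trials))
  epochs <- subset_trials(epochs, keep)
  y <- if (dimension == "horizontal") epochs$trials$h_class else
    epochs$trials$v_class
  y <- as.character(y)

  tidx <- if (is.null(window_ms)) seq_along(epochs$times_ms) else
    window_index(epochs$times_ms, window_ms)
  times <- epochs$times_ms[tidx]
  n <- dim(epochs$data)[1L]
  p <- dim(epochs$data)[2L]
  nt <- length(tidx)

  fold <- make_fold_plan(n, folds, derive_seed(seed, "folds"), y = y)
  auc_f <- matrix(NA_real_, folds, nt)
  confidence <- matrix(NA_real_, n, nt)
  weights <- matrix(0, nt, p)
  activation <- matrix(0, nt, p)

  for (f in seq_len(folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    xtr <- epochs$data[tr, , tidx, drop = FALSE]
    ytr <- y[tr]
    if (balance) {
      bal <- balance_between_class(xtr, ytr,
                                   seed = derive_seed(seed, "smote", f))
      xtr <- bal$x; ytr <- bal$y
    }
    xte <- epochs$data[te, , tidx, drop = FALSE]
    yte <- y[te]
    ntr <- dim(xtr)[1L]
    for (j in seq_len(nt)) {
      xj <- xtr[, , j]
      fit <- train_lda(xj, ytr, classes = classes, shrinkage = shrinkage)
      sc <- as.vector(xte[, , j] %*% fit$w) + fit$b
      confidence[te, j] <- sc
      auc_f[f, j] <- auc_from_scores(sc, yte, positive = classes[1L])
      weights[j, ] <- weights[j, ] + fit$w / folds
      # Sigma %*% w computed as X_c' (X_c w) / (n - 1), avoiding the p x p
      # covariance; identical to activation_map() up to float order
      xc <- xj - rep(colMeans(xj), each = ntr)
      activation[j, ] <- activation[j, ] +
        as.vector(crossprod(xc, xc %*% fit$w)) / ((ntr - 1) * folds)
    }
  }

  structure(
    list(auc = colMeans(auc_f), auc_folds = auc_f, confidence = confidence,
         weights = weights, activation = activation, times_ms = times,
         classes = classes, dimension = dimension, fold = fold,
         kept_index = keep, trials = epochs$trials,
         channel_names = epochs$channel_names),
    class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat("<decoding_result> ", x$dimension, " (", paste(x$classes,
      collapse = " vs "), "), ", nrow(x$confidence), " trials, ",
      length(x$times_ms), " timepoints\n", sep = "")
  pk <- which.max(x$auc)
  cat("  peak AUC ", round(x$auc[pk], 3), " at ", round(x$times_ms[pk]),
      " ms\n", sep = "")
  invisible(x)
}

#' Orient confidence scores toward the correct class
#'
#' Flips the sign of each trial's confidence so that positive values always
#' mean evidence for the trial's true target position, making "confidence
#' about the target" comparable across left/right and top/bottom trials
#' before correlating the two dimensions.
#'
#' @param result a \code{\link{decoding_result}}
#' @return trial x timepoint matrix of correctness-referenced confidence
#' @export
orient_confidence <- function(result) {
  stopifnot(inherits(result, "decoding_result"))
  y <- if (result$dimension == "horizontal") result$trials$h_class else
    result$trials$v_class
  sgn <- ifelse(y == result$classes[1L], 1, -1)
  result$confidence * sgn
}
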