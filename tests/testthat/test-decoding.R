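test_that("fold plans partition trials into near-equal folds", {
  for (n in c(47, 100, 512)) {
    fold <- make_fold_plan(n, 10, seed = n)
    expect_equal(length(fold), n)
    expect_equal(sort(unique(fold)), 1:10)
    expect_lte(diff(range(table(fold))), 1)
  }
  expect_error(make_fold_plan(5, 10), "fewer trials")
  expect_identical(make_fold_plan(40, 10, seed = 1),
                   make_fold_plan(40, 10, seed = 1))
})

test_that("within-class balancing equalizes the orthogonal dimension", {
  tr <- data.frame(
    h_class = rep(c("left", "right"), c(56, 60)),
    v_class = c(rep(c("top", "bottom"), c(30, 26)),
                rep(c("top", "bottom"), c(30, 30))))
  keep <- balance_within_class(tr, "horizontal", seed = 2)
  kept <- tr[keep, ]
  tab <- table(kept$h_class, kept$v_class)
  expect_equal(unname(tab["left", "top"]), 26)
  expect_equal(unname(tab["left", "bottom"]), 26)
  expect_equal(unname(tab["right", "top"]), 30)
  expect_equal(unname(tab["right", "bottom"]), 30)

  # already balanced: nothing dropped
  tr2 <- data.frame(h_class = rep(c("left", "right"), each = 64),
                    v_class = rep(c("top", "bottom"), 64))
  expect_equal(balance_within_class(tr2, "horizontal", seed = 1), 1:128)

  # degenerate: one level of the orthogonal dimension empty
  tr3 <- data.frame(h_class = rep(c("left", "right"), each = 10),
                    v_class = c(rep("top", 10),
                                rep(c("top", "bottom"), 5)))
  expect_error(balance_within_class(tr3, "horizontal"), "cannot balance")
})

test_that("between-class oversampling equalizes counts with convex
           interpolants inside the minority envelope", {
  set.seed(7)
  x <- matrix(rnorm(100 * 4), 100, 4)
  y <- rep(c("a", "b"), c(40, 60))
  out <- balance_between_class(x, y, seed = 3)
  expect_equal(out$n_synthetic, 20)
  expect_equal(unname(table(out$y)["a"]), 60)
  synth <- out$x[101:120, , drop = FALSE]
  env_lo <- apply(x[1:40, ], 2, min)
  env_hi <- apply(x[1:40, ], 2, max)
  expect_true(all(sweep(synth, 2, env_lo, ">=")))
  expect_true(all(sweep(synth, 2, env_hi, "<=")))

  # balanced input is returned unchanged
  out2 <- balance_between_class(x[1:80, ], rep(c("a", "b"), each = 40))
  expect_identical(out2$x, x[1:80, ])

  # single minority sample falls back to duplication with a warning
  expect_warning(
    out3 <- balance_between_class(x[1:5, ], c("a", rep("b", 4))),
    "duplicating")
  expect_equal(out3$n_synthetic, 3)
  expect_true(all(out3$x[6:8, ] == rep(x[1, ], each = 3)))

  # 3-d input keeps its tensor layout
  x3 <- array(rnorm(10 * 2 * 3), c(10, 2, 3))
  out4 <- balance_between_class(x3, rep(c("a", "b"), c(4, 6)), seed = 1)
  expect_equal(dim(out4$x), c(12, 2, 3))
})

test_that("LDA separates well-separated clouds and matches the identity-
           covariance closed form", {
  set.seed(11)
  x <- rbind(matrix(rnorm(100, 5), 50, 2), matrix(rnorm(100, -5), 50, 2))
  y <- rep(c("a", "b"), each = 50)
  fit <- train_lda(x, y)
  sc <- x %*% fit$w + fit$b
  expect_equal(auc_from_scores(sc, y, "a"), 1.0)

  # spherical data: weights proportional to the class-mean difference
  x2 <- rbind(matrix(rnorm(4000), 2000, 2),
              sweep(matrix(rnorm(4000), 2000, 2), 2, c(2, 1), "+"))
  y2 <- rep(c("b", "a"), each = 2000)
  fit2 <- train_lda(x2, y2, shrinkage = "none")
  md <- colMeans(x2[y2 == "a", ]) - colMeans(x2[y2 == "b", ])
  cosang <- sum(fit2$w * md) / sqrt(sum(fit2$w^2) * sum(md^2))
  expect_gt(cosang, 0.99)

  expect_error(train_lda(x[1:3, ], c("a", "a", "b")), "at least 2")
})

test_that("shrinkage LDA agrees with unregularized LDA when well-
           conditioned and handles singular covariance", {
  set.seed(21)
  x <- rbind(matrix(rnorm(1000), 500, 2),
             sweep(matrix(rnorm(1000), 500, 2), 2, c(1.5, 0), "+"))
  y <- rep(c("a", "b"), each = 500)
  w1 <- train_lda(x, y, shrinkage = "ledoit")$w
  w2 <- train_lda(x, y, shrinkage = "none")$w
  cosang <- sum(w1 * w2) / sqrt(sum(w1^2) * sum(w2^2))
  expect_gt(cosang, 0.999)

  # p > n: plain pooled covariance is singular, shrinkage still trains
  xs <- matrix(rnorm(10 * 20), 10, 20)
  xs[1:5, 1] <- xs[1:5, 1] + 10
  fit <- train_lda(xs, rep(c("a", "b"), each = 5))
  expect_true(all(is.finite(fit$w)))
})

test_that("unregularized LDA matches the reference discriminant direction", {
  set.seed(13)
  sig <- matrix(c(2, 0.6, 0.6, 1), 2)
  ch <- chol(sig)
  x <- rbind(matrix(rnorm(400), 200, 2) %*% ch,
             sweep(matrix(rnorm(400), 200, 2) %*% ch, 2, c(1, 0.5), "+"))
  y <- rep(c("a", "b"), each = 200)
  w <- train_lda(x, y, shrinkage = "none")$w
  ref <- MASS::lda(x, grouping = y)$scaling[, 1]
  cosang <- abs(sum(w * ref)) / sqrt(sum(w^2) * sum(ref^2))
  expect_gt(cosang, 0.999)
})

test_that("AUC matches the exhaustive pairwise oracle on random inputs", {
  expect_equal(auc_from_scores(c(0.9, 0.8, 0.2, 0.1),
                               c("p", "p", "n", "n"), "p"), 1.0)
  expect_equal(auc_from_scores(rep(1, 6), rep(c("p", "n"), 3), "p"), 0.5)
  expect_equal(auc_from_scores(c(0.9, 0.4, 0.6, 0.1),
                               c("p", "p", "n", "n"), "p"), 0.75)
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(4:200, 1)
    labels <- sample(c("p", "n"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n), sample(0:2, 1)) # rounding induces ties
    expect_equal(auc_from_scores(scores, labels, "p"),
                 auc_oracle(scores, labels, "p"))
  }
  expect_error(auc_from_scores(1:3, rep("p", 3)), "both classes")
})

test_that("activation maps equal covariance times weights", {
  x <- matrix(rnorm(200), 100, 2)
  expect_equal(activation_map(c(1, 1), x),
               as.vector(cov(x) %*% c(1, 1)))
  # diagonal covariance example: pattern scales by the variances
  x2 <- cbind(rnorm(5000, sd = sqrt(2)), rnorm(5000, sd = 1))
  p <- activation_map(c(1, 1), x2)
  expect_equal(p, c(2, 1), tolerance = 0.15)
})

test_that("cross-validated decoding recovers signal, stays at chance on
           noise, and is deterministic", {
  ep <- baseline_correct(generate_dataset(small_config(seed = 17)))
  r <- crossval_decode(ep, "horizontal", seed = 3, window_ms = c(100, 700))
  expect_true(all(r$auc >= 0 & r$auc <= 1))
  expect_gte(max(r$auc), 0.6) # snr = 4: clearly above the reliability band
  expect_false(anyNA(r$confidence))

  r2 <- crossval_decode(ep, "horizontal", seed = 3, window_ms = c(100, 700))
  expect_identical(r$auc, r2$auc)
  expect_identical(r$confidence, r2$confidence)

  # noise-only data: time-averaged AUC within Monte-Carlo error of chance
  ep0 <- generate_dataset(small_config(seed = 19, amplitude = 0,
                                       noise_amplitude = 0.25))
  r0 <- crossval_decode(ep0, "horizontal", seed = 3,
                        window_ms = c(100, 700))
  expect_lt(abs(mean(r0$auc) - 0.5), 0.05)

  cells <- interaction(ep$trials$h_class, ep$trials$v_class)
  pick <- unlist(lapply(split(seq_along(cells), cells), head, 2))
  expect_error(crossval_decode(subset_trials(ep, pick), "horizontal",
                               folds = 10),
               "fewer trials")
})

test_that("activation at the ERP peak recovers the injected channel
           template", {
  cfg <- small_config(mode = "positive", snr = 4, n_trials = 128, seed = 23)
  ep <- baseline_correct(generate_dataset(cfg))
  r <- crossval_decode(ep, "horizontal", seed = 3, window_ms = c(350, 450))
  truth <- numeric(cfg$n_channels)
  truth[cfg$split$h_contra] <- 1
  truth[cfg$split$h_ipsi] <- -1
  pk <- which.max(r$auc)
  expect_gt(cor(r$activation[pk, ], truth), 0.9)
})

test_that("decoding permuted labels yields chance AUC on average", {
  cfg <- small_config(n_trials = 48, n_channels = 8, seed = 29)
  ep <- baseline_correct(generate_dataset(cfg))
  set.seed(5)
  aucs <- replicate(20, {
    ep$trials$h_class <- sample(ep$trials$h_class)
    r <- crossval_decode(ep, "horizontal", folds = 4, seed = 1,
                         window_ms = c(350, 450), balance = FALSE)
    mean(r$auc)
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("fold assignment never leaks test trials into training", {
  # the confidence of every trial comes from exactly one fold, and folds
  # partition the retained trials
  ep <- baseline_correct(generate_dataset(small_config(n_trials = 40,
                                                       seed = 37)))
  r <- crossval_decode(ep, "vertical", folds = 5, seed = 2,
                       window_ms = c(300, 400))
  expect_equal(sort(unique(r$fold)), 1:5)
  expect_equal(length(r$fold), nrow(r$confidence))
  expect_false(anyNA(r$confidence))
})

test_that("both dimensions decode above chance on negative-mode data", {
  # the serial-selection signature must come from trial-wise confidence,
  # not from a loss of mean decodability: each dimension carries signal on
  # half the trials
  ep <- baseline_correct(generate_dataset(small_config(mode = "negative",
                                                       seed = 41)))
  rh <- crossval_decode(ep, "horizontal", seed = 3,
                        window_ms = c(350, 450))
  rv <- crossval_decode(ep, "vertical", seed = 3, window_ms = c(350, 450))
  expect_gt(max(rh$auc), 0.6)
  expect_gt(max(rv$auc), 0.6)
})
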