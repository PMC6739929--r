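test_that("receptor-to-subtype mapping follows the IHC surrogate rules", {
  expect_equal(map_receptors_to_subtype("pos", "neg", "neg"), "LuminalA")
  expect_equal(map_receptors_to_subtype("neg", "pos", "neg"), "LuminalA")
  expect_equal(map_receptors_to_subtype("pos", "pos", "pos"), "LuminalB")
  expect_equal(map_receptors_to_subtype("neg", "neg", "pos"), "HER2E")
  expect_equal(map_receptors_to_subtype("neg", "neg", "neg"), "TN")
  expect_warning(u <- map_receptors_to_subtype("unknown", "pos", "neg"),
                 "unknown")
  expect_equal(u, "unknown")
})

test_that("the training-cohort composition reproduces the published HR+ fraction", {
  comp <- c(LuminalA = 49, LuminalB = 8, HER2E = 11, TN = 23)
  labels <- rep(names(comp), comp)
  rec <- t(vapply(labels, radtex:::subtype_to_receptors, character(3)))
  back <- map_receptors_to_subtype(rec[, "er"], rec[, "pr"], rec[, "her2"])
  expect_equal(unname(back), labels)
  hr_pos <- rec[, "er"] == "pos" | rec[, "pr"] == "pos"
  expect_equal(sum(hr_pos), 57)
  expect_equal(round(100 * mean(hr_pos), 1), 62.6)
  expect_equal(round(100 * comp[["LuminalA"]] / sum(comp), 1), 53.8)
})

test_that("LDA retains a single MDF for two classes and matches an eigensolver oracle", {
  withr::with_seed(12, {
    X <- rbind(matrix(stats::rnorm(40 * 6), 40, 6),
               matrix(stats::rnorm(40 * 6, 1.5), 40, 6))
  })
  lab <- rep(c("A", "B"), each = 40)
  fit <- lda_fit(X, lab)
  expect_equal(fit$n_retained, 1L)
  expect_lte(fit$n_retained, 1L)   # rank bound for two classes

  # oracle: dense generalized eigensolver on the same scatter matrices
  Z <- scale(X)
  Sb <- matrix(0, 6, 6); Sw <- matrix(0, 6, 6)
  mu <- colMeans(Z)
  for (cl in c("A", "B")) {
    Zc <- Z[lab == cl, ]
    mc <- colMeans(Zc)
    Sb <- Sb + nrow(Zc) * tcrossprod(mc - mu)
    Sw <- Sw + crossprod(sweep(Zc, 2, mc))
  }
  lam_oracle <- sort(Re(eigen(solve(Sw) %*% Sb)$values), decreasing = TRUE)
  expect_equal(fit$eigenvalues[1], lam_oracle[1], tolerance = 1e-8)
  expect_true(all(abs(fit$eigenvalues[-1]) < 1e-6 * lam_oracle[1]))
})

test_that("with isotropic within-scatter the MDF is the class-mean difference", {
  withr::with_seed(13, {
    base <- matrix(stats::rnorm(400 * 2), 400, 2)
  })
  delta <- c(3, 1)
  X <- rbind(base[1:200, ], sweep(base[201:400, ], 2, delta, `+`))
  lab <- rep(c("A", "B"), each = 200)
  fit <- lda_fit(X, lab)
  v <- fit$vectors[, 1]
  # compare directions in the original scale: v applies to z-scored data
  v_orig <- v / fit$scale
  cosang <- abs(sum(v_orig * delta)) / sqrt(sum(v_orig^2) * sum(delta^2))
  expect_gt(cosang, 0.98)
})

test_that("1-D two-class LDA is a single direction", {
  fit <- lda_fit(matrix(c(0, 1, 5, 6), 4, 1), c("A", "A", "B", "B"))
  expect_equal(fit$n_retained, 1L)
  expect_length(fit$eigenvalues, 1L)
})

test_that("LOOCV separates far clusters perfectly and fails the alternating toy", {
  withr::with_seed(14, {
    X <- rbind(matrix(stats::rnorm(20 * 3), 20, 3),
               matrix(stats::rnorm(20 * 3, 10), 20, 3))
  })
  lab <- rep(c("A", "B"), each = 20)
  rep1 <- knn_loocv(X, lab)
  expect_equal(rep1$accuracy, 1.0)
  expect_true(all(rep1$misclassified_per_group == 0))

  toy <- matrix(c(0, 1, 2, 3), 4, 1)
  rep2 <- knn_loocv(toy, c("A", "B", "A", "B"))
  expect_equal(rep2$accuracy, 0.0)
})

test_that("accuracy bookkeeping ties out per group", {
  withr::with_seed(15, {
    X <- rbind(matrix(stats::rnorm(12 * 2), 12, 2),
               matrix(stats::rnorm(12 * 2, 1.2), 12, 2))
  })
  lab <- rep(c("A", "B"), each = 12)
  r <- knn_loocv(X, lab)
  expect_equal(r$accuracy, 1 - sum(r$misclassified_per_group) / r$n)
  expect_length(r$fold_predictions, r$n)
})

test_that("label permutation drives accuracy to the majority fraction", {
  withr::with_seed(16, {
    X <- rbind(matrix(stats::rnorm(20 * 2), 20, 2),
               matrix(stats::rnorm(20 * 2, 6), 20, 2))
    lab <- rep(c("A", "B"), each = 20)
    accs <- vapply(1:100, function(i) {
      knn_loocv(X, sample(lab))$accuracy
    }, numeric(1))
  })
  maj <- 0.5
  expect_lt(abs(mean(accs) - maj), 0.1)
})

test_that("the held-out sample cannot leak into its fold's fit", {
  withr::with_seed(18, {
    X <- rbind(matrix(stats::rnorm(10 * 3), 10, 3),
               matrix(stats::rnorm(10 * 3, 4), 10, 3))
  })
  lab <- rep(c("A", "B"), each = 10)
  r1 <- knn_loocv(X, lab, keep_folds = TRUE)
  X2 <- X
  X2[1, ] <- c(1e6, -1e6, 1e6)    # extreme outlier as the held-out sample
  r2 <- knn_loocv(X2, lab, keep_folds = TRUE)
  expect_equal(r1$folds[[1]]$train_proj, r2$folds[[1]]$train_proj)
  expect_equal(r1$folds[[1]]$fit$center, r2$folds[[1]]$fit$center)
})

test_that("accuracy is invariant to column order and affine feature rescaling", {
  withr::with_seed(19, {
    X <- rbind(matrix(stats::rnorm(15 * 4), 15, 4),
               matrix(stats::rnorm(15 * 4, 1), 15, 4))
  })
  lab <- rep(c("A", "B"), each = 15)
  a0 <- knn_loocv(X, lab)$accuracy
  expect_equal(knn_loocv(X[, c(3, 1, 4, 2)], lab)$accuracy, a0)
  Xs <- X; Xs[, 2] <- 1000 * Xs[, 2] - 77
  expect_equal(knn_loocv(Xs, lab)$accuracy, a0)
})

test_that("frozen evaluation is idempotent on the training table and guards columns", {
  reg <- feature_registry()
  withr::with_seed(20, {
    tab <- as.data.frame(matrix(stats::rnorm(24 * 352), 24, 352))
  })
  names(tab) <- reg
  tab[[reg[1]]] <- rep(c(0, 6), each = 12)
  tab <- cbind(data.frame(sample_id = sprintf("s%d", 1:24)), tab)
  lab <- rep(c("A", "B"), each = 12)
  sel <- select_features(tab, lab, "fisher", c("A", "B"))
  direct <- knn_loocv(tab[sel$ranked$feature], lab)
  frozen <- frozen_evaluate(tab, lab, sel)
  expect_equal(frozen$accuracy, direct$accuracy)
  expect_equal(frozen$fold_predictions, direct$fold_predictions)

  sel2 <- sel
  sel2$ranked$feature[1] <- "Mean"
  names(tab)[names(tab) == "Mean"] <- "Gone"
  names(tab)[2] <- "Mean2"
  expect_error(frozen_evaluate(tab[setdiff(names(tab), "Mean")], lab, sel2),
               "Mean")
})

test_that("frozen sets generalize across same-recipe cohorts and collapse under shuffling", {
  reg <- feature_registry()
  gen_table <- function(seed) {
    withr::with_seed(seed, {
      n <- 30
      vals <- matrix(stats::rnorm(n * 352), n, 352)
      vals[, 5] <- c(stats::rnorm(n / 2, 0), stats::rnorm(n / 2, 3))
      tab <- as.data.frame(vals)
      names(tab) <- reg
      cbind(data.frame(sample_id = sprintf("s%d", 1:n)), tab)
    })
  }
  lab <- rep(c("A", "B"), each = 15)
  deltas <- vapply(1:10, function(s) {
    train <- gen_table(300 + s)
    valid <- gen_table(600 + s)
    sel <- select_features(train, lab, "fisher", c("A", "B"))
    acc_tr <- knn_loocv(train[sel$ranked$feature], lab)$accuracy
    acc_va <- frozen_evaluate(valid, lab, sel)$accuracy
    acc_tr - acc_va
  }, numeric(1))
  expect_lte(abs(stats::median(deltas)), 0.15)

  withr::with_seed(777, {
    train <- gen_table(42)
    sel <- select_features(train, lab, "fisher", c("A", "B"))
    accs <- vapply(1:20, function(i) {
      frozen_evaluate(train, sample(lab), sel)$accuracy
    }, numeric(1))
  })
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("comparison matrix enumerates pairs, formats cells, and flags small groups", {
  reg <- feature_registry()
  withr::with_seed(22, {
    n <- 4 * 8
    vals <- matrix(stats::rnorm(n * 352), n, 352)
    lab <- rep(c("A", "B", "C", "D"), each = 8)
    vals[, 1] <- as.numeric(factor(lab)) * 3 + stats::rnorm(n, 0, 0.3)
    tab <- as.data.frame(vals)
    names(tab) <- reg
    tab <- cbind(data.frame(sample_id = sprintf("s%d", 1:n)), tab)
  })
  cm <- comparison_matrix(tab, lab, criteria = "fisher")
  expect_named(cm$cells, "fisher")
  m <- cm$cells$fisher
  expect_equal(dim(m), c(5L, 5L))
  offdiag <- m[upper.tri(m)]
  expect_true(all(!is.na(offdiag)))
  expect_true(all(grepl("^\\d+\\.\\d% \\(Fisher; \\d+\\)$", offdiag)))
  expect_equal(m["A", "B"], m["B", "A"])
  # 6 pairwise + 4 vs-rest reports
  expect_length(cm$reports$fisher, 10L)
  # bookkeeping identity per cell
  for (r in cm$reports$fisher) {
    expect_equal(r$accuracy, 1 - sum(r$misclassified_per_group) / r$n)
  }
  # the 16-sample pairs use k = 2
  expect_match(m["A", "B"], "; 2\\)$")

  lab_small <- c(rep("A", 20), rep("B", 3), rep("C", 9))
  cm2 <- comparison_matrix(tab[1:32, ], lab_small, criteria = "fisher")
  expect_equal(cm2$cells$fisher["A", "B"], "NA(small)")
})
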