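#' Map immunohistochemical receptor status to molecular subtype
#'
#' Hormone-receptor positive (HR+) means estrogen or progesterone receptor
#' positive. Subtypes: luminal A = HR+/HER2-; luminal B = HR+/HER2+;
#' HER2-enriched = HR-/HER2+; triple negative = HR-/HER2-. Any unknown
#' status yields subtype `"unknown"` with a warning (such samples are
#' excluded from receptor-derived groupings).
#'
#' @param er,pr,her2 Character vectors with values `"pos"`, `"neg"`,
#'   `"unknown"` (recycled to a common length).
#' @return Character vector of subtypes.
#' @examples
#' map_receptors_to_subtype("pos", "neg", "neg")   # LuminalA
#' @export
map_receptors_to_subtype <- function(er, pr, her2) {
  n <- max(length(er), length(pr), length(her2))
  er <- normalize_status(rep_len(er, n), "er")
  pr <- normalize_status(rep_len(pr, n), "pr")
  her2 <- normalize_status(rep_len(her2, n), "her2")
  out <- rep("unknown", n)
  known <- er != "unknown" & pr != "unknown" & her2 != "unknown"
  if (any(!known)) warning(sum(!known), " sample(s) with unknown receptor status")
  hr_pos <- er == "pos" | pr == "pos"
  out[known & hr_pos & her2 == "neg"] <- "LuminalA"
  out[known & hr_pos & her2 == "pos"] <- "LuminalB"
  out[known & !hr_pos & her2 == "pos"] <- "HER2E"
  out[known & !hr_pos & her2 == "neg"] <- "TN"
  out
}

# canonical inverse of the subtype mapping, used by the synthetic generator
subtype_to_receptors <- function(subtype) {
  switch(subtype,
    LuminalA = c(er = "pos", pr = "pos", her2 = "neg"),
    LuminalB = c(er = "pos", pr = "pos", her2 = "pos"),
    HER2E    = c(er = "neg", pr = "neg", her2 = "pos"),
    TN       = c(er = "neg", pr = "neg", her2 = "neg"),
    c(er = "unknown", pr = "unknown", her2 = "unknown"))
}

#' Fit the linear discriminant (MDF) projection
#'
#' Z-scores the feature columns on the fitting samples, forms the
#' between-class scatter `Sb` (class-size-weighted outer products of class
#' mean deviations) and within-class scatter `Sw` (pooled), ridge-regularizes
#' `Sw` by `1e-6 * trace/dim` when near-singular, and solves the generalized
#' eigenproblem `Sb v = lambda Sw v` by symmetric whitening. The projection
#' axes are the most discriminating features (MDFs); the number retained is
#' the count of eigenvalues individually exceeding 97 percent of the
#' eigenvalue sum, floored at 1 and capped at `n_classes - 1` (the rank of
#' `Sb`).
#'
#' @param features Numeric matrix or data frame (samples x selected features).
#' @param labels Class labels, each class with >= 2 samples.
#' @return An object of class `mdf_projection` with elements `eigenvalues`,
#'   `vectors` (columns are MDF axes in z-scored space), `n_retained`,
#'   `center`, `scale`, `classes`.
#' @export
lda_fit <- function(features, labels) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  if (length(cls) < 2) stop("lda_fit requires at least two classes")
  if (nrow(X) < 2) stop("lda_fit requires at least two samples")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Z <- scale(X, center = ctr, scale = scl)
  p <- ncol(Z)
  mu <- colMeans(Z)
  Sb <- matrix(0, p, p); Sw <- matrix(0, p, p)
  for (cl in cls) {
    Zc <- Z[labels == cl, , drop = FALSE]
    mc <- colMeans(Zc)
    Sb <- Sb + nrow(Zc) * tcrossprod(mc - mu)
    Sw <- Sw + crossprod(sweep(Zc, 2, mc))
  }
  ridge <- 1e-6 * sum(diag(Sw)) / p
  ew <- eigen(Sw, symmetric = TRUE)
  if (min(ew$values) < ridge) {
    Sw <- Sw + diag(max(ridge, 1e-12), p)
    ew <- eigen(Sw, symmetric = TRUE)
  }
  W <- ew$vectors %*% diag(1 / sqrt(pmax(ew$values, 1e-300)), p) %*% t(ew$vectors)
  es <- eigen(W %*% Sb %*% W, symmetric = TRUE)
  lam <- pmax(es$values, 0)
  vec <- W %*% es$vectors
  max_mdf <- length(cls) - 1L
  lam <- lam[seq_len(min(length(lam), p))]
  n_ret <- sum(lam > 0.97 * sum(lam))
  n_ret <- max(1L, min(n_ret, max_mdf))
  structure(list(eigenvalues = lam, vectors = vec, n_retained = n_ret,
                 center = ctr, scale = scl, classes = cls),
            class = "mdf_projection")
}

#' @export
print.mdf_projection <- function(x, ...) {
  cat(sprintf("MDF projection: %d class(es) %s, %d axis(es) retained\n",
              length(x$classes), paste(x$classes, collapse = "/"),
              x$n_retained))
  cat("eigenvalues:", signif(x$eigenvalues[seq_len(min(5, length(x$eigenvalues)))], 4), "\n")
  invisible(x)
}

#' Project samples onto the retained MDF axes
#'
#' @param object An `mdf_projection`.
#' @param newdata Matrix or data frame with the same feature columns used to
#'   fit the projection.
#' @param ... Unused.
#' @return Numeric matrix (samples x `n_retained`).
#' @export
predict.mdf_projection <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  Z <- scale(X, center = object$center, scale = object$scale)
  Z %*% object$vectors[, seq_len(object$n_retained), drop = FALSE]
}

#' Leave-one-out k-NN classification in MDF space
#'
#' For each fold, the z-scoring parameters, the LDA scatter matrices and the
#' MDF projection are fit on the n-1 training samples only; the held-out
#' sample is projected with the training parameters and classified by
#' Euclidean k-nearest neighbors against the training projections. Vote ties
#' are broken by the nearest neighbor, and distance ties by the lower sample
#' index. The selected features must be fixed beforehand (see
#' [select_features()]).
#'
#' @param features Numeric matrix or data frame (samples x selected features).
#' @param labels Class labels per sample.
#' @param k_neighbors Number of neighbors (default 1).
#' @param keep_folds Keep per-fold training projections (for diagnostics).
#' @return An object of class `comparison_report`: list with `accuracy`,
#'   `n`, `n_mdf` (retained MDFs of the all-sample fit),
#'   `misclassified_per_group`, `fold_predictions`, `labels`.
#' @export
knn_loocv <- function(features, labels, k_neighbors = 1L, keep_folds = FALSE) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  labels <- as.character(labels)
  n <- nrow(X)
  if (k_neighbors >= n) stop("k_neighbors must be smaller than the sample count")
  pred <- character(n)
  folds <- if (keep_folds) vector("list", n) else NULL
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    fit <- lda_fit(X[tr, , drop = FALSE], labels[tr])
    ptr <- predict(fit, X[tr, , drop = FALSE])
    pte <- predict(fit, X[i, , drop = FALSE])
    pred[i] <- knn_vote(ptr, labels[tr], pte, k_neighbors)
    if (keep_folds) folds[[i]] <- list(fit = fit, train_proj = ptr)
  }
  acc <- mean(pred == labels)
  mis <- tapply(pred != labels, labels, sum)
  full_fit <- lda_fit(X, labels)
  structure(list(accuracy = acc, n = n, n_mdf = full_fit$n_retained,
                 misclassified_per_group = mis,
                 fold_predictions = pred, labels = labels,
                 k_neighbors = as.integer(k_neighbors),
                 folds = folds),
            class = "comparison_report")
}

# deterministic k-NN vote: vote ties broken by nearest neighbor, distance
# ties by lower training index
knn_vote <- function(train_proj, train_labels, test_proj, k) {
  d <- sqrt(rowSums((train_proj - matrix(test_proj, nrow(train_proj),
                                         ncol(train_proj), byrow = TRUE))^2))
  ord <- order(d, seq_along(d))
  nb <- ord[seq_len(k)]
  votes <- table(train_labels[nb])
  top <- names(votes)[votes == max(votes)]
  if (length(top) == 1) return(top)
  # tie: class of the nearest neighbor among the tied classes
  for (j in nb) {
    if (train_labels[j] %in% top) return(train_labels[j])
  }
  top[1]
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("LOOCV %d-NN on %d samples: accuracy %.1f%% (MDFs retained: %d)\n",
              x$k_neighbors, x$n, 100 * x$accuracy, x$n_mdf))
  mis <- x$misclassified_per_group
  for (g in names(mis)) {
    cat(sprintf("  %s: %d/%d misclassified\n", g, mis[[g]], sum(x$labels == g)))
  }
  invisible(x)
}

#' @export
summary.comparison_report <- function(object, ...) {
  print(object)
  tab <- table(truth = object$labels, predicted = object$fold_predictions)
  print(tab)
  invisible(object)
}

#' Evaluate a frozen feature set on a validation cohort
#'
#' Applies a previously selected feature set (no re-selection) to a new
#' feature table and runs leave-one-out k-NN classification on the
#' validation samples, mirroring an external-validation protocol where the
#' training-derived signatures are held fixed.
#'
#' @param table Validation feature table (`sample_id` + feature columns).
#' @param labels Group labels per validation row.
#' @param featureset A `selection_result` (possibly read back with
#'   [read_featureset()]).
#' @param k_neighbors Neighbors for the k-NN vote.
#' @return A `comparison_report`.
#' @export
frozen_evaluate <- function(table, labels, featureset, k_neighbors = 1L) {
  stopifnot(inherits(featureset, "selection_result"))
  feats <- featureset$ranked$feature
  missing <- setdiff(feats, names(table))
  if (length(missing) > 0) {
    stop("validation table lacks feature column(s): ",
         paste(missing, collapse = ", "))
  }
  knn_loocv(table[feats], labels, k_neighbors)
}

#' All pairwise and class-vs-rest comparisons of a cohort
#'
#' Runs, for every requested selection criterion, each class-vs-class pair
#' and each class-vs-rest comparison: feature selection on the pair samples,
#' then LDA/MDF + k-NN leave-one-out classification. Returns a
#' `comparison_matrix` holding the per-cell reports plus accuracy matrices
#' with cells formatted `accuracy% (criterion; k)` and a misclassification
#' summary. Pairs with a group of fewer than `min_group` samples are marked
#' `NA(small)`.
#'
#' @param table Feature table.
#' @param labels Class labels per row.
#' @param criteria Selection criteria to run.
#' @param k_neighbors Neighbors for the k-NN vote.
#' @param min_group Minimum per-group sample count (default 5, so that each
#'   LOOCV training fold keeps >= 2 samples per class and a quantile spread).
#' @return An object of class `comparison_matrix`: list of `cells` (one
#'   formatted character matrix per criterion), `reports` (nested list),
#'   `misclassification` (data frame).
#' @export
comparison_matrix <- function(table, labels,
                              criteria = c("fisher", "poe_acc", "mi"),
                              k_neighbors = 1L, min_group = 5L) {
  labels <- as.character(labels)
  cls <- sort(unique(labels[labels != "unknown"]))
  if (length(cls) < 2) stop("comparison_matrix requires >= 2 groups")
  groups <- c(cls, if (length(cls) > 2) "rest")
  pairs <- list()
  for (i in seq_along(cls)) {
    for (j in seq_along(cls)) {
      if (j > i) pairs[[length(pairs) + 1]] <- c(cls[i], cls[j])
    }
    if (length(cls) > 2) pairs[[length(pairs) + 1]] <- c(cls[i], "rest")
  }
  cells <- list(); reports <- list(); mis_rows <- list()
  for (crit in criteria) {
    m <- matrix(NA_character_, length(groups), length(groups),
                dimnames = list(groups, groups))
    for (pr in pairs) {
      g <- pair_groups(labels, pr)
      counts <- table(g[!is.na(g)])
      key <- paste(pr, collapse = "_vs_")
      if (length(counts) < 2 || min(counts) < min_group) {
        cell <- "NA(small)"
        rep_i <- NULL
      } else {
        sel <- select_features(table, labels, crit, pr)
        keep <- !is.na(g)
        rep_i <- knn_loocv(table[keep, sel$ranked$feature, drop = FALSE],
                           g[keep], k_neighbors)
        rep_i$pair <- pr; rep_i$criterion <- crit; rep_i$k_features <- sel$k
        cell <- sprintf("%.1f%% (%s; %d)", 100 * rep_i$accuracy,
                        criterion_label(crit), sel$k)
        mis <- rep_i$misclassified_per_group
        mis_rows[[length(mis_rows) + 1]] <- data.frame(
          criterion = crit, pair = key,
          group = names(mis), n = as.integer(table(g[keep])[names(mis)]),
          misclassified = as.integer(mis),
          stringsAsFactors = FALSE)
      }
      m[pr[1], pr[2]] <- cell
      m[pr[2], pr[1]] <- cell
      reports[[crit]][[key]] <- rep_i
    }
    cells[[crit]] <- m
  }
  mis <- if (length(mis_rows) > 0) do.call(rbind, mis_rows) else NULL
  structure(list(cells = cells, reports = reports, misclassification = mis,
                 classes = cls),
            class = "comparison_matrix")
}

criterion_label <- function(x) {
  c(fisher = "Fisher", poe_acc = "POE", mi = "MI")[[x]]
}

#' @export
print.comparison_matrix <- function(x, ...) {
  for (crit in names(x$cells)) {
    cat(sprintf("== %s ==\n", criterion_label(crit)))
    print(x$cells[[crit]], quote = FALSE)
  }
  invisible(x)
}

#' Write the comparison matrices and misclassification table as CSV
#'
#' @param cm A `comparison_matrix`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_comparison_matrix <- function(cm, dir) {
  stopifnot(inherits(cm, "comparison_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (crit in names(cm$cells)) {
    utils::write.csv(cm$cells[[crit]],
                     file.path(dir, sprintf("accuracy_%s.csv", crit)))
  }
  if (!is.null(cm$misclassification)) {
    utils::write.csv(cm$misclassification,
                     file.path(dir, "misclassification.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
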