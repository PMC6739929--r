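#' Sample-size-dependent feature subset size
#'
#' One feature for every ten samples, read as nearest-integer with halves
#' rounded up: `k = floor(n / 10 + 0.5)`. This is the reading that
#' reproduces the printed per-comparison feature counts (e.g., n = 57 -> 6,
#' n = 68 -> 7, n = 91 -> 9), whereas flooring does not. For fewer than 10
#' samples, `k = 1` with a warning.
#'
#' @param n_samples Number of samples in the comparison.
#' @return Integer subset size `k >= 1`.
#' @examples
#' subset_size(91)   # 9
#' subset_size(19)   # 2
#' @export
subset_size <- function(n_samples) {
  n_samples <- as.integer(n_samples)
  if (n_samples < 10L) {
    warning("fewer than 10 samples; using a single feature")
    return(1L)
  }
  as.integer(floor(n_samples / 10 + 0.5))
}

#' Fisher discriminant score of one feature
#'
#' Ratio of the between-class variance of the class means (weighted by class
#' size) to the pooled within-class variance, both population-weighted. A
#' feature with zero within-class variance but distinct class means receives
#' an `Inf` sentinel and ranks first.
#'
#' @param values Numeric vector, one value per sample.
#' @param labels Class labels (>= 2 classes, each with >= 2 samples).
#' @return Nonnegative score (possibly `Inf`).
#' @export
fisher_score <- function(values, labels) {
  labels <- as.character(labels)
  cls <- unique(labels)
  if (length(cls) < 2) stop("fisher_score requires at least two classes")
  n <- length(values)
  mu <- mean(values)
  between <- 0; within <- 0
  for (cl in cls) {
    v <- values[labels == cl]
    between <- between + length(v) * (mean(v) - mu)^2 / n
    within <- within + sum((v - mean(v))^2) / n
  }
  if (within <= 0) {
    if (between > 0) return(Inf)
    return(0)
  }
  between / within
}

#' Probability of classification error of a single feature
#'
#' Minimum misclassification fraction of a one-dimensional threshold rule.
#' For two classes the optimum is found by an exhaustive sweep over all
#' thresholds between consecutive sorted values (both polarities); for more
#' classes the rule is nearest-class-mean in 1-D. A constant feature yields
#' the majority-class error.
#'
#' @inheritParams fisher_score
#' @return Error fraction in `[0, 1)`.
#' @export
poe <- function(values, labels) {
  labels <- as.character(labels)
  cls <- unique(labels)
  n <- length(values)
  if (length(cls) < 2) stop("poe requires at least two classes")
  if (length(unique(values)) == 1) {
    return(1 - max(table(labels)) / n)
  }
  if (length(cls) == 2) {
    a <- cls[1]
    sv <- sort(unique(values))
    thr <- c(sv[1] - 1, (sv[-1] + sv[-length(sv)]) / 2, sv[length(sv)] + 1)
    best <- n
    for (t in thr) {
      left_a <- sum(values <= t & labels == a)
      left_b <- sum(values <= t & labels != a)
      right_a <- sum(values > t & labels == a)
      right_b <- sum(values > t & labels != a)
      best <- min(best,
                  left_b + right_a,   # A on the left
                  left_a + right_b)   # A on the right
    }
    best / n
  } else {
    mus <- tapply(values, labels, mean)
    pred <- names(mus)[apply(abs(outer(values, mus, `-`)), 1, which.min)]
    mean(pred != labels)
  }
}

#' Mutual information between a feature and the class label
#'
#' The feature is discretized into 10 equal-width bins over its observed
#' range; the mutual information of the joint empirical distribution with the
#' class label is returned in bits. A constant feature carries 0 bits.
#'
#' @inheritParams fisher_score
#' @return Mutual information in bits, >= 0.
#' @export
mutual_information <- function(values, labels) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("mutual_information requires >= 2 classes")
  rng <- range(values)
  if (diff(rng) == 0) return(0)
  bins <- pmin(floor((values - rng[1]) / diff(rng) * 10) + 1, 10)
  joint <- table(bins, labels) / length(values)
  px <- rowSums(joint); py <- colSums(joint)
  mi <- 0
  for (i in seq_along(px)) {
    for (j in seq_along(py)) {
      p <- joint[i, j]
      if (p > 0) mi <- mi + p * log2(p / (px[i] * py[j]))
    }
  }
  max(mi, 0)
}

#' Select features for a pairwise comparison
#'
#' Restricts the table to the two groups of `pair`, derives the subset size
#' `k` from the pooled sample count ([subset_size()]), and ranks features by
#' the requested criterion: `fisher` and `mi` sort their univariate scores
#' descending (ties broken by registry order); `poe_acc` greedily picks the
#' feature minimizing `POE + mean |Pearson correlation|` with the already
#' selected set (first pick minimizes POE alone; correlation with a constant
#' feature is 0). Selection is performed once on all pair samples, outside
#' cross-validation, which reproduces the source protocol and its optimistic
#' bias; see the vignette.
#'
#' @param table Feature table (data frame with `sample_id` + feature columns).
#' @param labels Character vector of group labels, one per table row.
#' @param criterion One of `"fisher"`, `"poe_acc"`, `"mi"`.
#' @param pair Length-2 character vector of group labels; the second element
#'   may be `"rest"` for a class-vs-rest comparison.
#' @return A `selection_result`: list with `criterion`, `k`, `pair`, and a
#'   `ranked` data frame (`feature`, `score`) of exactly `k` rows.
#' @export
select_features <- function(table, labels,
                            criterion = c("fisher", "poe_acc", "mi"),
                            pair) {
  criterion <- match.arg(criterion)
  stopifnot(length(pair) == 2, "sample_id" %in% names(table))
  grp <- pair_groups(labels, pair)
  keep <- !is.na(grp)
  if (min(table(grp[keep])) < 2 || length(unique(grp[keep])) < 2) {
    stop("each group of the pair needs at least 2 samples")
  }
  sub <- table[keep, setdiff(names(table), "sample_id"), drop = FALSE]
  g <- grp[keep]
  k <- subset_size(length(g))
  feats <- names(sub)
  if (criterion == "poe_acc") {
    ranked <- poe_acc_rank(sub, g, k)
  } else {
    scorer <- if (criterion == "fisher") fisher_score else mutual_information
    scores <- vapply(feats, function(f) scorer(sub[[f]], g), numeric(1))
    ord <- order(-scores, seq_along(scores))   # registry-order tie-break
    ranked <- data.frame(feature = feats[ord[seq_len(k)]],
                         score = scores[ord[seq_len(k)]],
                         stringsAsFactors = FALSE)
  }
  structure(list(criterion = criterion, k = k, pair = pair, ranked = ranked),
            class = "selection_result")
}

# greedy POE + average-correlation ranking
poe_acc_rank <- function(sub, g, k) {
  feats <- names(sub)
  poe_scores <- vapply(feats, function(f) poe(sub[[f]], g), numeric(1))
  selected <- integer(0)
  scores <- numeric(0)
  for (step in seq_len(min(k, length(feats)))) {
    if (length(selected) == 0) {
      cost <- poe_scores
    } else {
      acc <- vapply(seq_along(feats), function(i) {
        mean(vapply(selected, function(s) {
          abs_cor_safe(sub[[i]], sub[[s]])
        }, numeric(1)))
      }, numeric(1))
      cost <- poe_scores + acc
      cost[selected] <- Inf
    }
    pick <- which.min(cost)     # which.min takes the first minimum: registry order
    selected <- c(selected, pick)
    scores <- c(scores, cost[pick])
  }
  data.frame(feature = feats[selected], score = scores,
             stringsAsFactors = FALSE)
}

# |Pearson correlation|, defined as 0 when either feature is constant
abs_cor_safe <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  abs(stats::cor(a, b))
}

# map labels onto the two groups of a pair; NA = excluded
pair_groups <- function(labels, pair) {
  labels <- as.character(labels)
  g <- rep(NA_character_, length(labels))
  if (identical(tolower(pair[2]), "rest")) {
    g[labels == pair[1]] <- pair[1]
    g[labels != pair[1] & labels != "unknown"] <- "rest"
  } else {
    g[labels == pair[1]] <- pair[1]
    g[labels == pair[2]] <- pair[2]
  }
  g
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Feature selection (%s) for %s vs %s: k = %d\n",
              x$criterion, x$pair[1], x$pair[2], x$k))
  print(x$ranked, row.names = FALSE)
  invisible(x)
}
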