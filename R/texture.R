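#' First-order histogram features
#'
#' Nine statistics of the quantized gray levels inside the ROI: mean,
#' population variance, skewness, excess kurtosis, and the 1st, 10th, 50th,
#' 90th and 99th percentiles (order statistics at rank `ceiling(p * n)`).
#' Skewness and kurtosis of a zero-variance ROI are defined as 0.
#'
#' @param q A `quantized_roi` from [quantize_roi()].
#' @return Named numeric vector of length 9.
#' @export
his_features <- function(q) {
  v <- as.numeric(q$levels[q$mask])
  m <- moment_stats(v)
  pc <- percentile(v, c(0.01, 0.10, 0.50, 0.90, 0.99))
  out <- c(m[["mean"]], m[["variance"]], m[["skewness"]], m[["kurtosis"]], pc)
  names(out) <- feature_registry("HIS")
  out
}

#' Gray-level co-occurrence matrix at a fixed pixel offset
#'
#' Counts ordered pairs of masked pixels `(s, s + offset)`, symmetrizes (each
#' unordered pair is counted in both directions) and normalizes to a joint
#' probability matrix over the `n_levels` gray levels. The offset is `(dx,
#' dy)` with `dx` the column displacement and `dy` the row displacement (y
#' axis pointing down).
#'
#' @param q A `quantized_roi`.
#' @param offset Integer vector `c(dx, dy)`.
#' @return Object of class `com_matrix`: list with `offset`, probability
#'   matrix `p` (`n_levels` x `n_levels`), pair count `n_pairs`, and a
#'   `degenerate` flag (no valid pair).
#' @export
com_matrix <- function(q, offset) {
  lev <- q$levels
  n <- q$params$n_levels
  dx <- as.integer(offset[1]); dy <- as.integer(offset[2])
  nr <- nrow(lev); nc <- ncol(lev)
  ri <- seq.int(max(1L, 1L - dy), min(nr, nr - dy))
  ci <- seq.int(max(1L, 1L - dx), min(nc, nc - dx))
  p <- matrix(0, n, n)
  n_pairs <- 0L
  if (length(ri) > 0 && length(ci) > 0) {
    a <- lev[ri, ci, drop = FALSE]
    b <- lev[ri + dy, ci + dx, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (any(ok)) {
      ia <- a[ok]; ib <- b[ok]
      cnt <- tabulate((ia - 1L) * n + ib, nbins = n * n)
      m <- matrix(cnt, n, n, byrow = TRUE)
      m <- m + t(m)                       # symmetrize: both orderings
      n_pairs <- sum(m)
      p <- m / n_pairs
    }
  }
  structure(list(offset = c(dx, dy), p = p, n_pairs = n_pairs,
                 degenerate = n_pairs == 0L),
            class = "com_matrix")
}

#' Haralick statistics of a co-occurrence matrix
#'
#' Eleven statistics of the joint gray-level probability matrix: angular
#' second moment, contrast, correlation, sum of squares (variance), inverse
#' difference moment, sum average, sum variance, sum entropy, entropy,
#' difference variance, and difference entropy. Entropies use the natural
#' logarithm with the `0 log 0 = 0` convention. A degenerate matrix (no valid
#' pixel pair) yields all zeros; correlation of a zero-variance matrix is
#' defined as 0.
#'
#' @param m A `com_matrix`.
#' @return Named numeric vector of length 11 (names without the offset
#'   prefix; [extract_all()] adds the `S(dx,dy)` prefix).
#' @export
com_features <- function(m) {
  stats <- c("AngScMom", "Contrast", "Correlat", "SumOfSqs", "InvDfMom",
             "SumAverg", "SumVarnc", "SumEntrp", "Entropy", "DifVarnc",
             "DifEntrp")
  out <- stats::setNames(numeric(11), stats)
  if (m$degenerate) return(out)
  p <- m$p
  n <- nrow(p)
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  px <- rowSums(p)                    # == colSums by symmetry
  mu <- sum(seq_len(n) * px)
  sig2 <- sum((seq_len(n) - mu)^2 * px)
  # distributions of i + j and |i - j|
  psum <- as.numeric(tapply(as.numeric(p), as.numeric(i + j), sum))
  ksum <- sort(unique(as.numeric(i + j)))
  pdif <- as.numeric(tapply(as.numeric(p), as.numeric(abs(i - j)), sum))
  kdif <- sort(unique(as.numeric(abs(i - j))))
  sum_avg <- sum(ksum * psum)
  dif_avg <- sum(kdif * pdif)
  out["AngScMom"] <- sum(p^2)
  out["Contrast"] <- sum((i - j)^2 * p)
  out["Correlat"] <- if (sig2 > 0) (sum(i * j * p) - mu^2) / sig2 else 0
  out["SumOfSqs"] <- sum((i - mu)^2 * p)
  out["InvDfMom"] <- sum(p / (1 + (i - j)^2))
  out["SumAverg"] <- sum_avg
  out["SumVarnc"] <- sum((ksum - sum_avg)^2 * psum)
  out["SumEntrp"] <- entropy_nat(psum)
  out["Entropy"]  <- entropy_nat(as.numeric(p))
  out["DifVarnc"] <- sum((kdif - dif_avg)^2 * pdif)
  out["DifEntrp"] <- entropy_nat(pdif)
  out
}

#' Run-length matrix features for one direction
#'
#' Decomposes the ROI into maximal constant-gray-level runs along masked
#' collinear pixel segments in the requested direction and returns short-run
#' emphasis, long-run emphasis, gray-level non-uniformity, run-length
#' non-uniformity, and the fraction of the traversed pixels that start a run
#' (number of runs / number of masked pixels).
#'
#' @param q A `quantized_roi`.
#' @param direction One of `"Horzl"`, `"Vertl"`, `"45dgr"` (up-right
#'   diagonal), `"135dr"` (down-right diagonal).
#' @return Named numeric vector of length 5 (direction prefix included).
#' @export
rlm_features <- function(q, direction = c("Horzl", "Vertl", "45dgr", "135dr")) {
  direction <- match.arg(direction)
  runs <- rlm_runs(q$levels, direction)
  lens <- runs$lengths
  glev <- runs$values
  n_runs <- length(lens)
  n_pix <- sum(q$mask)
  out <- stats::setNames(numeric(5),
                         paste0(direction, "_",
                                c("ShrtREmp", "LngREmph", "GLevNonU",
                                  "RLNonUni", "Fraction")))
  if (n_runs > 0) {
    out[1] <- sum(1 / lens^2) / n_runs
    out[2] <- sum(lens^2) / n_runs
    out[3] <- sum(as.numeric(table(glev))^2) / n_runs
    out[4] <- sum(as.numeric(table(lens))^2) / n_runs
    out[5] <- n_runs / n_pix
  }
  out
}

# maximal constant-level runs along all masked lines of one direction
rlm_runs <- function(lev, direction) {
  nr <- nrow(lev); nc <- ncol(lev)
  lines <- switch(direction,
    Horzl = lapply(seq_len(nr), function(r) lev[r, ]),
    Vertl = lapply(seq_len(nc), function(c) lev[, c]),
    # down-right diagonal: row and column increase together
    `135dr` = {
      idx <- col(lev) - row(lev)
      lapply(split(seq_along(lev)[order(idx, row(lev))], sort(as.integer(idx))),
             function(k) lev[k])
    },
    # up-right diagonal: column increases while row decreases
    `45dgr` = {
      idx <- col(lev) + row(lev)
      lapply(split(seq_along(lev)[order(idx, -row(lev))], sort(as.integer(idx))),
             function(k) lev[k])
    })
  vals <- integer(0); lens <- integer(0)
  for (v in lines) {
    v[is.na(v)] <- -1L
    r <- rle(as.integer(v))
    keep <- r$values != -1L
    vals <- c(vals, r$values[keep])
    lens <- c(lens, r$lengths[keep])
  }
  list(values = vals, lengths = lens)
}

#' Absolute gradient features
#'
#' Central-difference gradient magnitude
#' `sqrt((I(x+1,y) - I(x-1,y))^2 + (I(x,y+1) - I(x,y-1))^2)` evaluated at
#' every interior ROI pixel (all four 4-neighbors masked), followed by mean,
#' population variance, skewness, excess kurtosis (zero-variance rule), and
#' the fraction of interior pixels with nonzero magnitude. An ROI with no
#' interior pixel yields all zeros with a warning.
#'
#' @param q A `quantized_roi`.
#' @return Named numeric vector of length 5.
#' @export
gra_features <- function(q) {
  out <- stats::setNames(numeric(5), feature_registry("GRA"))
  lev <- q$levels
  m <- q$mask
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3 || nc < 3) {
    warning("ROI has no interior pixel; GRA features set to 0")
    return(out)
  }
  core <- m[2:(nr - 1), 2:(nc - 1), drop = FALSE] &
    m[1:(nr - 2), 2:(nc - 1), drop = FALSE] &
    m[3:nr, 2:(nc - 1), drop = FALSE] &
    m[2:(nr - 1), 1:(nc - 2), drop = FALSE] &
    m[2:(nr - 1), 3:nc, drop = FALSE]
  if (!any(core)) {
    warning("ROI has no interior pixel; GRA features set to 0")
    return(out)
  }
  gx <- lev[2:(nr - 1), 3:nc, drop = FALSE] - lev[2:(nr - 1), 1:(nc - 2), drop = FALSE]
  gy <- lev[3:nr, 2:(nc - 1), drop = FALSE] - lev[1:(nr - 2), 2:(nc - 1), drop = FALSE]
  g <- sqrt(gx[core]^2 + gy[core]^2)
  ms <- moment_stats(g)
  out[1:4] <- ms
  out[5] <- mean(g > 0)
  out
}

#' Two-dimensional autoregressive model features
#'
#' Fits the causal first-order model
#' `I(s) = theta1 I(W) + theta2 I(NW) + theta3 I(N) + theta4 I(NE) + e(s)`
#' by least squares over all ROI pixels whose west, north-west, north and
#' north-east neighbors are masked. The model carries no intercept, so the
#' levels are centered by the ROI mean before fitting (the usual zero-mean
#' convention for texture AR models); the minimum-norm solution is used when
#' the normal system is singular. `Sigma` is the root-mean-square residual.
#' Fewer than 20 eligible pixels yields all zeros with a warning.
#'
#' @param q A `quantized_roi`.
#' @return Named numeric vector `Teta1..Teta4`, `Sigma`.
#' @export
arm_features <- function(q) {
  out <- stats::setNames(numeric(5), feature_registry("ARM"))
  lev <- q$levels
  m <- q$mask
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 2 || nc < 3) {
    warning("too few eligible pixels for ARM fit; features set to 0")
    return(out)
  }
  rows <- 2:nr; cols <- 2:(nc - 1)
  ok <- m[rows, cols, drop = FALSE] &
    m[rows, cols - 1, drop = FALSE] &        # W
    m[rows - 1, cols - 1, drop = FALSE] &    # NW
    m[rows - 1, cols, drop = FALSE] &        # N
    m[rows - 1, cols + 1, drop = FALSE]      # NE
  if (sum(ok) < 20) {
    warning("too few eligible pixels for ARM fit; features set to 0")
    return(out)
  }
  lev <- lev - mean(lev[m])
  y <- lev[rows, cols, drop = FALSE][ok]
  X <- cbind(W  = lev[rows, cols - 1, drop = FALSE][ok],
             NW = lev[rows - 1, cols - 1, drop = FALSE][ok],
             N  = lev[rows - 1, cols, drop = FALSE][ok],
             NE = lev[rows - 1, cols + 1, drop = FALSE][ok])
  sv <- svd(X)
  tol <- max(sv$d) * 1e-10
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  theta <- sv$v %*% (dinv * crossprod(sv$u, y))
  resid <- y - X %*% theta
  out[1:4] <- theta
  out[5] <- sqrt(mean(resid^2))
  out
}

#' Haar wavelet subband energies
#'
#' Orthonormal 2-D Haar transform of the ROI bounding box, padded with the
#' ROI mean level to the next power of two, over up to five decomposition
#' scales. `HL` denotes the subband high-pass along x (columns) and low-pass
#' along y; `LH` the converse. The energy of a subband at a scale is the mean
#' squared coefficient over the positions whose spatial support square
#' overlaps the mask; scales beyond the box size are emitted as 0. Counts of
#' contributing positions are attached as attribute `"counts"`.
#'
#' @param q A `quantized_roi`.
#' @return Named numeric vector of length 20 (`WavEnLL_s-1` ... `WavEnHH_s-5`).
#' @export
wav_features <- function(q) {
  out <- stats::setNames(numeric(20), feature_registry("WAV"))
  counts <- stats::setNames(integer(20), feature_registry("WAV"))
  bb <- mask_bbox(q$mask)
  h <- bb$r2 - bb$r1 + 1L
  w <- bb$c2 - bb$c1 + 1L
  size <- 2^ceiling(log2(max(h, w, 2)))
  roi_mean <- mean(q$levels[q$mask])
  block <- matrix(roi_mean, size, size)
  sub <- q$levels[bb$r1:bb$r2, bb$c1:bb$c2, drop = FALSE]
  sub[is.na(sub)] <- roi_mean
  block[seq_len(h), seq_len(w)] <- sub
  msk <- matrix(FALSE, size, size)
  msk[seq_len(h), seq_len(w)] <- q$mask[bb$r1:bb$r2, bb$c1:bb$c2, drop = FALSE]
  # summed-area table for fast "support square overlaps mask" queries
  sat <- apply(apply(msk, 2, cumsum), 1, cumsum)  # sat[c, r] after transpose
  sat <- t(sat)
  box_count <- function(r1, r2, c1, c2) {
    s <- sat[r2, c2]
    if (r1 > 1) s <- s - sat[r1 - 1, c2]
    if (c1 > 1) s <- s - sat[r2, c1 - 1]
    if (r1 > 1 && c1 > 1) s <- s + sat[r1 - 1, c1 - 1]
    s
  }
  n_scales <- min(5L, as.integer(log2(size)))
  A <- block
  for (s in seq_len(n_scales)) {
    m <- nrow(A)
    oi <- seq(1, m, by = 2); ei <- oi + 1
    a <- A[oi, oi, drop = FALSE]; b <- A[oi, ei, drop = FALSE]
    c_ <- A[ei, oi, drop = FALSE]; d <- A[ei, ei, drop = FALSE]
    LL <- (a + b + c_ + d) / 2
    HL <- (a - b + c_ - d) / 2   # high-pass along x
    LH <- (a + b - c_ - d) / 2   # high-pass along y
    HH <- (a - b - c_ + d) / 2
    half <- m / 2
    sup <- 2^s
    keep <- matrix(FALSE, half, half)
    for (i in seq_len(half)) {
      r1 <- (i - 1) * sup + 1; r2 <- min(i * sup, size)
      for (j in seq_len(half)) {
        c1 <- (j - 1) * sup + 1; c2 <- min(j * sup, size)
        keep[i, j] <- box_count(r1, r2, c1, c2) > 0
      }
    }
    nk <- sum(keep)
    for (sb in c("LL", "LH", "HL", "HH")) {
      nm <- sprintf("WavEn%s_s-%d", sb, s)
      coefs <- switch(sb, LL = LL, LH = LH, HL = HL, HH = HH)
      out[nm] <- if (nk > 0) mean(coefs[keep]^2) else 0
      counts[nm] <- nk
    }
    A <- LL
  }
  attr(out, "counts") <- counts
  out
}

mask_bbox <- function(mask) {
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  list(r1 = rr[1], r2 = rr[2], c1 = cc[1], c2 = cc[2])
}

#' Extract the full 352-feature radiomic signature of one lesion
#'
#' Normalizes and quantizes the ROI, then computes all seven feature
#' families (HIS, COM, RLM, GRA, ARM, WAV on the quantized levels; GEO on the
#' binary mask) and concatenates them in canonical registry order. Family
#' degeneracies (no interior pixel, too few ARM pixels, degenerate
#' co-occurrence matrices) produce zeros with a warning, never `NaN`.
#'
#' @param image Numeric matrix of pixel intensities.
#' @param mask Binary matrix of the same size; the ROI must contain at least
#'   16 pixels.
#' @param n_levels Gray levels for quantization (default 64).
#' @return Named numeric vector of length 352 in registry order.
#' @examples
#' les <- generate_lesion(class_recipe("A"), image_size = 96, seed = 1)
#' f <- extract_all(les$image, les$mask)
#' length(f)
#' @export
extract_all <- function(image, mask, n_levels = 64L) {
  mask <- check_lesion_pair(image, mask, min_pixels = 16L)
  q <- quantize_roi(image, mask,
                    compute_norm_params(image, mask, n_levels))
  com <- unlist(lapply(1:5, function(d) {
    unlist(lapply(com_offsets(d), function(o) {
      v <- com_features(com_matrix(q, o))
      stats::setNames(v, sprintf("S(%d,%d)%s", o[1], o[2], names(v)))
    }))
  }))
  rlm <- unlist(lapply(rlm_directions(), function(d) rlm_features(q, d)))
  wav <- wav_features(q)
  attributes(wav) <- list(names = names(wav))
  out <- c(his_features(q), com, rlm, gra_features(q), arm_features(q),
           wav, geo_features(mask))
  reg <- feature_registry()
  if (!identical(names(out), reg)) {
    out <- out[reg]
  }
  stopifnot(length(out) == 352L, all(is.finite(out)))
  out
}

#' Extract features for every sample of a cohort manifest
#'
#' @param manifest A `cohort_manifest` from [read_manifest()] or
#'   [generate_cohort()].
#' @param n_levels Gray levels for quantization.
#' @param verbose Print per-sample progress.
#' @return A feature table: data frame with `sample_id` plus the 352 registry
#'   columns.
#' @export
extract_cohort <- function(manifest, n_levels = 64L, verbose = FALSE) {
  stopifnot(inherits(manifest, "cohort_manifest"))
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    if (verbose) message("extracting ", manifest$sample_id[i])
    les <- read_lesion(manifest$image[i], manifest$mask[i])
    extract_all(les$image, les$mask, n_levels)
  })
  tab <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  tab <- cbind(data.frame(sample_id = manifest$sample_id,
                          stringsAsFactors = FALSE), tab)
  rownames(tab) <- NULL
  tab
}
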