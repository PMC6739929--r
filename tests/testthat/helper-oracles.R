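# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the package implementation.

# co-occurrence probabilities by exhaustive ordered-pair enumeration
oracle_com_matrix <- function(levels, mask, dx, dy, n_levels) {
  cnt <- matrix(0, n_levels, n_levels)
  nr <- nrow(levels); nc <- ncol(levels)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      r2 <- r + dy; c2 <- c + dx
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
          mask[r, c] && mask[r2, c2]) {
        i <- levels[r, c]; j <- levels[r2, c2]
        cnt[i, j] <- cnt[i, j] + 1
        cnt[j, i] <- cnt[j, i] + 1
      }
    }
  }
  if (sum(cnt) == 0) return(list(p = cnt, degenerate = TRUE))
  list(p = cnt / sum(cnt), degenerate = FALSE)
}

# Haralick statistics recomputed cell by cell from a probability matrix
oracle_com_features <- function(p) {
  n <- nrow(p)
  asm <- 0; contrast <- 0; idm <- 0; ent <- 0; cor_num <- 0
  px <- numeric(n)
  for (i in 1:n) for (j in 1:n) px[i] <- px[i] + p[i, j]
  mu <- sum((1:n) * px)
  sig2 <- sum(((1:n) - mu)^2 * px)
  ssq <- 0
  psum <- numeric(2 * n); pdif <- numeric(n)
  for (i in 1:n) {
    for (j in 1:n) {
      v <- p[i, j]
      asm <- asm + v^2
      contrast <- contrast + (i - j)^2 * v
      idm <- idm + v / (1 + (i - j)^2)
      if (v > 0) ent <- ent - v * log(v)
      cor_num <- cor_num + i * j * v
      ssq <- ssq + (i - mu)^2 * v
      psum[i + j] <- psum[i + j] + v
      pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + v
    }
  }
  savg <- sum((1:(2 * n)) * psum)
  svar <- sum(((1:(2 * n)) - savg)^2 * psum)
  sent <- -sum(psum[psum > 0] * log(psum[psum > 0]))
  davg <- sum((0:(n - 1)) * pdif)
  dvar <- sum(((0:(n - 1)) - davg)^2 * pdif)
  dent <- -sum(pdif[pdif > 0] * log(pdif[pdif > 0]))
  c(AngScMom = asm, Contrast = contrast,
    Correlat = if (sig2 > 0) (cor_num - mu^2) / sig2 else 0,
    SumOfSqs = ssq, InvDfMom = idm, SumAverg = savg, SumVarnc = svar,
    SumEntrp = sent, Entropy = ent, DifVarnc = dvar, DifEntrp = dent)
}

# run-length statistics by explicit line walking
oracle_rlm <- function(levels, mask, direction) {
  nr <- nrow(levels); nc <- ncol(levels)
  step <- switch(direction,
                 Horzl = c(0, 1), Vertl = c(1, 0),
                 `45dgr` = c(-1, 1), `135dr` = c(1, 1))
  starts <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    pr <- r - step[1]; pc <- c - step[2]
    on_line_start <- pr < 1 || pr > nr || pc < 1 || pc > nc
    if (on_line_start) starts[[length(starts) + 1]] <- c(r, c)
  }
  runs_g <- integer(0); runs_l <- integer(0)
  for (s in starts) {
    r <- s[1]; c <- s[2]
    cur_g <- NA; cur_l <- 0
    while (r >= 1 && r <= nr && c >= 1 && c <= nc) {
      v <- if (mask[r, c]) levels[r, c] else NA
      if (!is.na(v) && !is.na(cur_g) && v == cur_g) {
        cur_l <- cur_l + 1
      } else {
        if (cur_l > 0) { runs_g <- c(runs_g, cur_g); runs_l <- c(runs_l, cur_l) }
        cur_g <- v; cur_l <- if (is.na(v)) 0 else 1
      }
      r <- r + step[1]; c <- c + step[2]
    }
    if (cur_l > 0) { runs_g <- c(runs_g, cur_g); runs_l <- c(runs_l, cur_l) }
  }
  n_runs <- length(runs_l)
  n_pix <- sum(mask)
  if (n_runs == 0) return(numeric(5))
  c(ShrtREmp = sum(1 / runs_l^2) / n_runs,
    LngREmph = sum(runs_l^2) / n_runs,
    GLevNonU = sum(table(runs_g)^2) / n_runs,
    RLNonUni = sum(table(runs_l)^2) / n_runs,
    Fraction = n_runs / n_pix)
}

# full orthonormal 2-D Haar decomposition of a square matrix, one level
oracle_haar_level <- function(A) {
  m <- nrow(A)
  LL <- matrix(0, m / 2, m / 2); LH <- LL; HL <- LL; HH <- LL
  for (i in seq_len(m / 2)) {
    for (j in seq_len(m / 2)) {
      a <- A[2 * i - 1, 2 * j - 1]; b <- A[2 * i - 1, 2 * j]
      c_ <- A[2 * i, 2 * j - 1]; d <- A[2 * i, 2 * j]
      LL[i, j] <- (a + b + c_ + d) / 2
      HL[i, j] <- (a - b + c_ - d) / 2
      LH[i, j] <- (a + b - c_ - d) / 2
      HH[i, j] <- (a - b - c_ + d) / 2
    }
  }
  list(LL = LL, LH = LH, HL = HL, HH = HH)
}

# random quantized test ROI
random_quantized <- function(nr, nc, n_levels, p_mask = 0.8, seed = 1) {
  withr::with_seed(seed, {
    mask <- matrix(stats::runif(nr * nc) < p_mask, nr, nc)
    if (!any(mask)) mask[1] <- TRUE
    lev <- matrix(sample.int(n_levels, nr * nc, replace = TRUE), nr, nc)
    radtex:::quantized_from_levels(lev, mask, n_levels)
  })
}

make_manifest_csv <- function(dir, n = 3, seed = 1) {
  spec <- cohort_spec(list(class_recipe("A", mean_radius = 10),
                           class_recipe("B", mean_radius = 10,
                                        correlation_length = 4)),
                      n_per_class = n, image_size = 48, seed = seed)
  generate_cohort(spec, dir)
}
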