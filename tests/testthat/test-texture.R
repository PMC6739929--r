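ql <- function(lev, mask = NULL, n_levels = 64L) {
  lev <- as.matrix(lev)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(lev), ncol(lev))
  radtex:::quantized_from_levels(lev, mask, n_levels)
}

test_that("histogram features match hand arithmetic and the zero-variance rule", {
  q <- ql(matrix(1:4, 2, 2), n_levels = 8)
  h <- his_features(q)
  expect_equal(h[["Mean"]], 2.5)
  expect_equal(h[["Variance"]], 1.25)

  hc <- his_features(ql(matrix(5, 3, 3), n_levels = 8))
  expect_equal(hc[["Variance"]], 0)
  expect_equal(hc[["Skewness"]], 0)
  expect_equal(hc[["Kurtosis"]], 0)
})

test_that("histogram percentiles agree with a sort-based oracle", {
  withr::with_seed(5, {
    lev <- matrix(sample.int(64, 1000, replace = TRUE), 25, 40)
  })
  h <- his_features(ql(lev))
  sv <- sort(as.integer(lev))
  for (p in c(0.01, 0.10, 0.50, 0.90, 0.99)) {
    nm <- sprintf("Perc.%02d%%", round(100 * p))
    expect_equal(h[[nm]], sv[ceiling(p * 1000)])
  }
  expect_gte(h[["Perc.50%"]], 30)
  expect_lte(h[["Perc.50%"]], 35)
})

test_that("co-occurrence matrix reproduces the classic 4x4 toy image", {
  toy <- matrix(c(0, 0, 1, 1,
                  0, 0, 1, 1,
                  0, 2, 2, 2,
                  2, 2, 3, 3), 4, 4, byrow = TRUE) + 1L  # 1-based levels
  q <- ql(toy, n_levels = 4)
  m <- com_matrix(q, c(1, 0))
  expect_equal(m$n_pairs, 24)
  expect_equal(m$p[1, 1], 4 / 24)
  expect_equal(m$p[1, 2], 2 / 24)
  expect_equal(m$p[2, 1], 2 / 24)
  expect_equal(m$p[2, 2], 4 / 24)
  expect_equal(sum(m$p), 1)
  # contrast: sum p(i,j) (i-j)^2 enumerated by the brute-force oracle
  f <- com_features(m)
  o <- oracle_com_matrix(q$levels, q$mask, 1, 0, 4)
  expect_equal(f[["Contrast"]], sum(o$p * outer(1:4, 1:4, `-`)^2))
  expect_equal(f[["Contrast"]], 14 / 24, tolerance = 1e-12)
})

test_that("degenerate and forced co-occurrence matrices give the closed-form values", {
  # constant ROI: single cell
  f <- com_features(com_matrix(ql(matrix(3, 4, 4), n_levels = 8), c(1, 0)))
  expect_equal(f[["AngScMom"]], 1)
  expect_equal(f[["Contrast"]], 0)
  expect_equal(f[["Entropy"]], 0)
  expect_equal(f[["InvDfMom"]], 1)

  # checkerboard: two off-diagonal cells
  cb <- outer(1:6, 1:6, function(r, c) (r + c) %% 2 + 1)
  f <- com_features(com_matrix(ql(cb, n_levels = 4), c(1, 0)))
  expect_equal(f[["Contrast"]], 1)
  expect_equal(f[["Entropy"]], log(2))

  # no valid pair: flagged degenerate, all zeros
  single <- matrix(FALSE, 3, 3); single[2, 2] <- TRUE
  m <- com_matrix(ql(matrix(1, 3, 3), single, 4), c(1, 0))
  expect_true(m$degenerate)
  expect_true(all(com_features(m) == 0))
})

test_that("90-degree rotation maps the (1,0) matrix onto the (0,1) matrix", {
  withr::with_seed(8, {
    lev <- matrix(sample.int(6, 64, replace = TRUE), 8, 8)
    mask <- matrix(stats::runif(64) < 0.8, 8, 8)
  })
  q <- ql(lev, mask, 6)
  rot_lev <- t(lev)[, nrow(lev):1]          # 90-degree rotation
  rot_mask <- t(mask)[, nrow(mask):1]
  qr <- ql(rot_lev, rot_mask, 6)
  m1 <- com_matrix(q, c(1, 0))
  m2 <- com_matrix(qr, c(0, 1))
  expect_equal(m1$p, m2$p)
})

test_that("all COM features match brute-force enumeration on random masked images", {
  withr::with_seed(42, {
    seeds <- sample.int(1e6, 50)
  })
  offsets <- unlist(lapply(1:5, radtex:::com_offsets), recursive = FALSE)
  for (s in seeds[1:25]) {
    q <- random_quantized(8, 8, 8, p_mask = 0.75, seed = s)
    for (o in offsets) {
      got <- com_features(com_matrix(q, o))
      orc <- oracle_com_matrix(q$levels, q$mask, o[1], o[2], 8)
      want <- if (orc$degenerate) {
        stats::setNames(numeric(11), names(got))
      } else {
        oracle_com_features(orc$p)
      }
      expect_equal(unname(got), unname(want), tolerance = 1e-10)
    }
  }
})

test_that("run-length features match hand enumeration on the toy row", {
  lev <- matrix(c(1, 1, 1, 2, 2), 1, 5)
  q <- ql(lev, n_levels = 4)
  f <- rlm_features(q, "Horzl")
  expect_equal(f[["Horzl_LngREmph"]], 6.5)
  expect_equal(f[["Horzl_ShrtREmp"]], (1 / 9 + 1 / 4) / 2)
  expect_equal(f[["Horzl_Fraction"]], 0.4)

  # constant row: one run of length N
  fc <- rlm_features(ql(matrix(2, 1, 7), n_levels = 4), "Horzl")
  expect_equal(fc[["Horzl_Fraction"]], 1 / 7)
  expect_equal(fc[["Horzl_LngREmph"]], 49)

  # alternating row: all runs of length 1
  fa <- rlm_features(ql(matrix(rep(c(1, 2), 5), 1, 10), n_levels = 4), "Horzl")
  expect_equal(fa[["Horzl_Fraction"]], 1)
  expect_equal(fa[["Horzl_LngREmph"]], 1)
  expect_equal(fa[["Horzl_ShrtREmp"]], 1)
})

test_that("RLM features match the line-walking oracle in all four directions", {
  withr::with_seed(19, {
    seeds <- sample.int(1e6, 25)
  })
  for (s in seeds) {
    q <- random_quantized(8, 8, 4, p_mask = 0.7, seed = s)
    for (d in c("Horzl", "Vertl", "45dgr", "135dr")) {
      got <- rlm_features(q, d)
      want <- oracle_rlm(q$levels, q$mask, d)
      expect_equal(unname(got), unname(want), tolerance = 1e-10,
                   label = sprintf("dir %s seed %d", d, s))
    }
  }
})

test_that("run-length totals conserve the traversed pixel count", {
  withr::with_seed(23, {
    for (rep in 1:10) {
      q <- random_quantized(10, 10, 6, p_mask = stats::runif(1, 0.3, 1),
                            seed = rep * 101)
      for (d in c("Horzl", "Vertl", "45dgr", "135dr")) {
        runs <- radtex:::rlm_runs(q$levels, d)
        expect_equal(sum(runs$lengths), sum(q$mask))
      }
    }
  })
})

test_that("gradient features: constant, ramp, and random-oracle cases", {
  expect_warning(gc_ <- gra_features(ql(matrix(3, 2, 2), n_levels = 8)),
                 "interior")
  expect_true(all(gc_ == 0))

  cst <- gra_features(ql(matrix(5, 6, 6), n_levels = 8))
  expect_equal(cst[["GrMean"]], 0)
  expect_equal(cst[["GrNonZeros"]], 0)

  ramp <- matrix(rep(1:8, each = 8), 8, 8, byrow = TRUE)  # I = x
  fr <- gra_features(ql(ramp, n_levels = 16))
  expect_equal(fr[["GrMean"]], 2)
  expect_equal(fr[["GrVariance"]], 0)
  expect_equal(fr[["GrNonZeros"]], 1)

  # random ROI against a direct per-pixel loop
  q <- random_quantized(16, 16, 16, p_mask = 0.9, seed = 77)
  got <- gra_features(q)
  lev <- q$levels; mask <- q$mask
  mags <- c()
  for (r in 2:15) for (c in 2:15) {
    if (mask[r, c] && mask[r - 1, c] && mask[r + 1, c] &&
        mask[r, c - 1] && mask[r, c + 1]) {
      mags <- c(mags, sqrt((lev[r, c + 1] - lev[r, c - 1])^2 +
                           (lev[r + 1, c] - lev[r - 1, c])^2))
    }
  }
  expect_equal(got[["GrMean"]], mean(mags))
  expect_equal(got[["GrVariance"]], mean((mags - mean(mags))^2))
  expect_equal(got[["GrNonZeros"]], mean(mags > 0))
})

test_that("autoregressive fit recovers deterministic and noise structure", {
  # constant rows (I(r, c) = r): every pixel equals its west neighbor exactly
  lev <- matrix(rep(1:8, times = 8), 8, 8)
  q <- ql(lev, n_levels = 16)
  f <- arm_features(q)
  # residual oracle on mean-centered levels (the fit's convention)
  cl <- lev - mean(lev)
  resid_norm <- function(theta) {
    theta <- unname(theta)
    total <- 0
    for (r in 2:8) for (c in 2:7) {
      pred <- theta[1] * cl[r, c - 1] + theta[2] * cl[r - 1, c - 1] +
        theta[3] * cl[r - 1, c] + theta[4] * cl[r - 1, c + 1]
      total <- total + (cl[r, c] - pred)^2
    }
    total
  }
  expect_equal(resid_norm(f[1:4]), 0, tolerance = 1e-12)
  expect_equal(f[["Sigma"]], 0, tolerance = 1e-10)

  # constant ROI: zero residual forced
  fc <- arm_features(ql(matrix(4, 8, 8), n_levels = 8))
  expect_equal(fc[["Sigma"]], 0, tolerance = 1e-10)

  # white noise: all weights near zero (3 SE bound at n = 10000)
  withr::with_seed(99, {
    lev <- matrix(sample.int(64, 104 * 104, replace = TRUE), 104, 104)
  })
  fw <- arm_features(ql(lev))
  expect_true(all(abs(fw[1:4]) < 0.05))

  # too few eligible pixels
  expect_warning(fs <- arm_features(ql(matrix(1, 3, 3), n_levels = 4)),
                 "eligible")
  expect_true(all(fs == 0))
})

test_that("ARM solution matches a pseudoinverse oracle on a random ROI", {
  q <- random_quantized(12, 12, 8, p_mask = 0.95, seed = 1234)
  f <- arm_features(q)
  mask <- q$mask
  lev <- q$levels - mean(q$levels[mask])   # the fit's centering convention
  ys <- c(); Xs <- NULL
  for (r in 2:12) for (c in 2:11) {
    if (mask[r, c] && mask[r, c - 1] && mask[r - 1, c - 1] &&
        mask[r - 1, c] && mask[r - 1, c + 1]) {
      ys <- c(ys, lev[r, c])
      Xs <- rbind(Xs, c(lev[r, c - 1], lev[r - 1, c - 1],
                        lev[r - 1, c], lev[r - 1, c + 1]))
    }
  }
  theta <- MASS::ginv(Xs) %*% ys
  expect_equal(unname(f[1:4]), as.numeric(theta), tolerance = 1e-8)
  expect_equal(f[["Sigma"]], sqrt(mean((ys - Xs %*% theta)^2)), tolerance = 1e-8)
})

test_that("Haar energies: constant ROI, orientation selectivity, Parseval bookkeeping", {
  # constant ROI value c: all detail energies 0, LL scale-1 energy 4 c^2
  qc <- ql(matrix(3, 8, 8), n_levels = 8)
  w <- wav_features(qc)
  expect_equal(w[["WavEnLL_s-1"]], 36)
  detail <- grep("WavEn(LH|HL|HH)", names(w), value = TRUE)
  expect_true(all(w[detail] == 0))

  # vertical stripes (intensity varies along x): HL > 0, LH = 0 at scale 1
  stripes <- matrix(rep(c(1, 5), length.out = 8 * 8), 8, 8, byrow = TRUE)
  ws <- wav_features(ql(stripes, n_levels = 8))
  expect_gt(ws[["WavEnHL_s-1"]], 0)
  expect_equal(ws[["WavEnLH_s-1"]], 0)

  # Parseval-style bookkeeping on a random 32x32 ROI
  q <- random_quantized(32, 32, 16, p_mask = 0.85, seed = 314)
  w <- wav_features(q)
  counts <- attr(w, "counts")
  roi_mean <- mean(q$levels[q$mask])
  block <- q$levels
  block[is.na(block)] <- roi_mean
  msk <- q$mask
  A <- block
  for (s in 1:5) {
    dec <- oracle_haar_level(A)
    sup <- 2^s
    half <- nrow(dec$LL)
    for (sb in c("LL", "LH", "HL", "HH")) {
      nm <- sprintf("WavEn%s_s-%d", sb, s)
      acc <- 0; cnt <- 0
      for (i in seq_len(half)) for (j in seq_len(half)) {
        rr <- ((i - 1) * sup + 1):min(i * sup, 32)
        cc <- ((j - 1) * sup + 1):min(j * sup, 32)
        if (any(msk[rr, cc])) {
          acc <- acc + dec[[sb]][i, j]^2
          cnt <- cnt + 1
        }
      }
      expect_equal(unname(counts[nm]), cnt)
      expect_equal(unname(w[nm]) * cnt, acc, tolerance = 1e-8)
    }
    A <- dec$LL
  }
  expect_true(all(w >= 0))
})
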