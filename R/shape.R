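#' Lesion geometry features
#'
#' Computes the 73-feature geometry family from the binary ROI mask alone.
#' Pixel convention: row-major lattice, x = column index, y = row index
#' (y pointing down); a pixel is in or out of the mask, with no fractional
#' membership. If the mask has several 4-connected components the largest is
#' used with a warning.
#'
#' Feature groups (names in [feature_registry()] order):
#' \describe{
#'   \item{size/perimeter}{`GeoArea` (pixel count), `GeoPerimeter` (exposed
#'     pixel-edge count, city-block boundary), `GeoCircularity`
#'     (`4 pi A / P_b^2` with `P_b` the length of the radially sampled
#'     boundary polygon, capped at 1), `GeoCompactness` (`P_b^2 / (4 pi A)`),
#'     `GeoNormPerim` (`P_b / (2 sqrt(pi A))`), `GeoEquivDiam`, `GeoThickness`
#'     (`2 A / P_b`), `GeoExtent` (area / bounding-box area), bounding-box
#'     width, height, aspect.}
#'   \item{Feret}{max/min caliper diameter over a 1-degree sweep, their ratio
#'     restricted to the four sampled directions 0/45/90/135 (`GeoFeretRatio`,
#'     so an axis-aligned rectangle gives its exact side ratio), the mean of
#'     the four directional diameters, and the four directional diameters.}
#'   \item{principal axes}{ellipse axes from second central moments
#'     (`GeoMajorAxis`, `GeoMinorAxis` = full axes `4 sqrt(lambda)`),
#'     `GeoElongation` (major/minor), `GeoEccentricity`, `GeoOrientation`
#'     (degrees).}
#'   \item{convexity}{`GeoConvexity` = area / lattice-point count of the
#'     convex hull (Pick's theorem), `GeoConvPerimRatio` = hull polygon
#'     perimeter / `GeoPerimeter`.}
#'   \item{radial}{statistics of the boundary radius function `r(phi)`
#'     sampled at 360 equal angles from the centroid (outermost masked
#'     intersection): mean, SD, CV, min, max, min/max, skewness, kurtosis,
#'     10-bin entropy (nats), `GeoRadAreaRatio` = `pi mean(r)^2 / A`, and the
#'     circular zero-crossing count of `r - mean(r)`.}
#'   \item{symmetry}{mask overlap fraction with its 180-degree rotation about
#'     the centroid and with its reflections across the principal major and
#'     minor axes.}
#'   \item{moments}{scale-normalized central moments `GeoM20..GeoM04` (orders
#'     2 to 4), the seven Hu rotation invariants `GeoW1..GeoW7`, a
#'     third-order skew invariant (`GeoW8`), and the fourth-order trace
#'     invariant `eta40 + 2 eta22 + eta04` (`GeoW9`).}
#'   \item{boundary harmonics}{`GeoE1..GeoE12`: amplitudes of the first 12
#'     Fourier harmonics of `r(phi)`, normalized by the DC term.}
#' }
#'
#' @param mask Binary matrix; nonempty.
#' @return Named numeric vector of length 73.
#' @examples
#' m <- disk_mask(64, radius = 20)
#' geo_features(m)[c("GeoCircularity", "GeoElongation")]
#' @export
geo_features <- function(mask) {
  mask <- matrix(as.logical(mask) & (as.numeric(mask) > 0),
                 nrow(mask), ncol(mask))
  if (!any(mask)) stop("mask is empty")
  mask <- largest_component(mask)

  out <- stats::setNames(numeric(73), geo_registry())
  A <- sum(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  xs <- col(mask)[mask]; ys <- row(mask)[mask]
  cx <- mean(xs); cy <- mean(ys)

  # city-block perimeter: exposed 4-neighbor edges
  adj_h <- sum(mask[, -1] & mask[, -nc])
  adj_v <- sum(mask[-1, ] & mask[-nr, ])
  P_cb <- 4 * A - 2 * (adj_h + adj_v)

  # boundary pixels (masked, at least one unmasked 4-neighbor)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  inner <- pad[2:(nr + 1), 2:(nc + 1)] &
    pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  bmask <- mask & !inner
  bx <- col(mask)[bmask]; by <- row(mask)[bmask]

  # radial boundary function at 360 angles (outermost masked intersection)
  phi <- 2 * pi * (0:359) / 360
  rad <- radial_function(mask, cx, cy, phi)
  r_mean <- mean(rad)

  # boundary polygon perimeter from the radial samples; a circular moving
  # average over roughly +/- 1 pixel of arc at the mean radius removes
  # single-pixel staircase jitter without attenuating spiculation lobes
  # (angular wavelength >= 30 degrees)
  h_sm <- max(2L, as.integer(ceiling(180 / (pi * max(r_mean, 1)))))
  rad_s <- circular_smooth(rad, h_sm)
  pbx <- cx + rad_s * cos(phi); pby <- cy + rad_s * sin(phi)
  P_b <- sum(sqrt(diff(c(pbx, pbx[1]))^2 + diff(c(pby, pby[1]))^2))
  if (P_b <= 0) P_b <- P_cb

  out["GeoArea"] <- A
  out["GeoPerimeter"] <- P_cb
  out["GeoCircularity"] <- min(1, 4 * pi * A / P_b^2)
  out["GeoCompactness"] <- P_b^2 / (4 * pi * A)
  out["GeoNormPerim"] <- P_b / (2 * sqrt(pi * A))
  out["GeoEquivDiam"] <- 2 * sqrt(A / pi)
  out["GeoThickness"] <- 2 * A / P_b
  bbw <- diff(range(xs)) + 1; bbh <- diff(range(ys)) + 1
  out["GeoExtent"] <- A / (bbw * bbh)
  out["GeoBBWidth"] <- bbw
  out["GeoBBHeight"] <- bbh
  out["GeoBBAspect"] <- bbw / bbh

  # Feret (caliper) diameters over a 1-degree sweep of boundary projections
  th <- (0:179) * pi / 180
  proj_extent <- vapply(th, function(t) {
    p <- bx * cos(t) + by * sin(t)
    diff(range(p)) + 1
  }, numeric(1))
  out["GeoFeretMax"] <- max(proj_extent)
  out["GeoFeretMin"] <- min(proj_extent)
  f4 <- proj_extent[c(1, 46, 91, 136)]   # 0, 45, 90, 135 degrees
  out["GeoFeretRatio"] <- max(f4) / min(f4)
  out["GeoFeretMean"] <- mean(f4)
  out[c("GeoFeret0", "GeoFeret45", "GeoFeret90", "GeoFeret135")] <- f4

  # central moments
  dx <- xs - cx; dy <- ys - cy
  mu <- function(p, q) sum(dx^p * dy^q)
  m20 <- mu(2, 0) / A; m02 <- mu(0, 2) / A; m11 <- mu(1, 1) / A
  ev <- eigen(matrix(c(m20, m11, m11, m02), 2), symmetric = TRUE)$values
  ev <- pmax(ev, 0)
  out["GeoMajorAxis"] <- 4 * sqrt(ev[1])
  out["GeoMinorAxis"] <- 4 * sqrt(ev[2])
  out["GeoElongation"] <- if (ev[2] > 0) sqrt(ev[1] / ev[2]) else 1
  out["GeoEccentricity"] <- if (ev[1] > 0) sqrt(1 - ev[2] / ev[1]) else 0
  orient <- 0.5 * atan2(2 * m11, m20 - m02)
  out["GeoOrientation"] <- orient * 180 / pi

  # convex hull of boundary pixel centers
  hull <- hull_stats(bx, by)
  out["GeoConvexity"] <- min(1, A / max(hull$lattice_count, A))
  out["GeoConvPerimRatio"] <- if (P_cb > 0) hull$perimeter / P_cb else 0

  ms <- moment_stats(rad)
  out["GeoRadMean"] <- r_mean
  out["GeoRadSD"] <- sqrt(ms[["variance"]])
  out["GeoRadCV"] <- if (r_mean > 0) sqrt(ms[["variance"]]) / r_mean else 0
  out["GeoRadMin"] <- min(rad)
  out["GeoRadMax"] <- max(rad)
  out["GeoRadRatio"] <- if (max(rad) > 0) min(rad) / max(rad) else 0
  out["GeoRadSkewness"] <- ms[["skewness"]]
  out["GeoRadKurtosis"] <- ms[["kurtosis"]]
  rng <- range(rad)
  if (diff(rng) > 0) {
    h <- tabulate(pmin(floor((rad - rng[1]) / diff(rng) * 10) + 1, 10), 10)
    out["GeoRadEntropy"] <- entropy_nat(h / sum(h))
  }
  out["GeoRadAreaRatio"] <- pi * r_mean^2 / A
  out["GeoRadZeroCross"] <- circular_zero_crossings(rad_s - mean(rad_s))

  out["GeoSym180"] <- overlap_fraction(mask, xs, ys, 2 * cx - xs, 2 * cy - ys)
  # reflections across the principal axes through the centroid
  ca <- cos(orient); sa <- sin(orient)
  rx <- dx * ca + dy * sa; ry <- -dx * sa + dy * ca
  maj_x <- cx + rx * ca - (-ry) * sa; maj_y <- cy + rx * sa + (-ry) * ca
  min_x <- cx + (-rx) * ca - ry * sa; min_y <- cy + (-rx) * sa + ry * ca
  out["GeoSymMajor"] <- overlap_fraction(mask, xs, ys, maj_x, maj_y)
  out["GeoSymMinor"] <- overlap_fraction(mask, xs, ys, min_x, min_y)

  # scale-normalized central moments eta_pq = mu_pq / mu00^(1+(p+q)/2)
  eta <- function(p, q) mu(p, q) / A^(1 + (p + q) / 2)
  e20 <- eta(2, 0); e11 <- eta(1, 1); e02 <- eta(0, 2)
  e30 <- eta(3, 0); e21 <- eta(2, 1); e12 <- eta(1, 2); e03 <- eta(0, 3)
  e40 <- eta(4, 0); e31 <- eta(3, 1); e22 <- eta(2, 2); e13 <- eta(1, 3)
  e04 <- eta(0, 4)
  out[c("GeoM20", "GeoM11", "GeoM02", "GeoM30", "GeoM21", "GeoM12", "GeoM03",
        "GeoM40", "GeoM31", "GeoM22", "GeoM13", "GeoM04")] <-
    c(e20, e11, e02, e30, e21, e12, e03, e40, e31, e22, e13, e04)

  out["GeoW1"] <- e20 + e02
  out["GeoW2"] <- (e20 - e02)^2 + 4 * e11^2
  out["GeoW3"] <- (e30 - 3 * e12)^2 + (3 * e21 - e03)^2
  out["GeoW4"] <- (e30 + e12)^2 + (e21 + e03)^2
  out["GeoW5"] <- (e30 - 3 * e12) * (e30 + e12) *
    ((e30 + e12)^2 - 3 * (e21 + e03)^2) +
    (3 * e21 - e03) * (e21 + e03) * (3 * (e30 + e12)^2 - (e21 + e03)^2)
  out["GeoW6"] <- (e20 - e02) * ((e30 + e12)^2 - (e21 + e03)^2) +
    4 * e11 * (e30 + e12) * (e21 + e03)
  out["GeoW7"] <- (3 * e21 - e03) * (e30 + e12) *
    ((e30 + e12)^2 - 3 * (e21 + e03)^2) -
    (e30 - 3 * e12) * (e21 + e03) * (3 * (e30 + e12)^2 - (e21 + e03)^2)
  out["GeoW8"] <- e11 * ((e30 + e12)^2 - (e03 + e21)^2) -
    (e20 - e02) * (e30 + e12) * (e03 + e21)
  out["GeoW9"] <- e40 + 2 * e22 + e04

  # DC-normalized Fourier amplitudes of the boundary radius function
  if (r_mean > 0) {
    Fc <- stats::fft(rad)
    out[sprintf("GeoE%d", 1:12)] <- 2 * Mod(Fc[2:13]) / Mod(Fc[1])
  }

  stopifnot(all(is.finite(out)))
  out
}

# boundary radius at each angle: outermost masked point along the ray,
# sampled in 0.25-pixel steps from the centroid
radial_function <- function(mask, cx, cy, phi) {
  nr <- nrow(mask); nc <- ncol(mask)
  xs <- col(mask)[mask]; ys <- row(mask)[mask]
  r_max <- max(sqrt((xs - cx)^2 + (ys - cy)^2)) + 1
  steps <- seq(0, r_max, by = 0.25)
  vapply(phi, function(a) {
    px <- round(cx + steps * cos(a))
    py <- round(cy + steps * sin(a))
    ok <- px >= 1 & px <= nc & py >= 1 & py <= nr
    ok[ok] <- mask[cbind(py[ok], px[ok])]
    if (any(ok)) steps[max(which(ok))] else 0
  }, numeric(1))
}

# circular moving average with half-window h samples
circular_smooth <- function(v, h) {
  n <- length(v)
  out <- v
  for (k in seq(-h, h)) {
    if (k != 0) out <- out + v[((seq_len(n) - 1 + k) %% n) + 1]
  }
  out / (2 * h + 1)
}

circular_zero_crossings <- function(d) {
  s <- sign(d)
  s <- s[s != 0]
  if (length(s) < 2) return(0)
  sum(s != c(s[-1], s[1]))
}

# fraction of mapped (rounded) pixel coordinates that land inside the mask
overlap_fraction <- function(mask, xs, ys, tx, ty) {
  tx <- round(tx); ty <- round(ty)
  ok <- tx >= 1 & tx <= ncol(mask) & ty >= 1 & ty <= nrow(mask)
  inside <- logical(length(xs))
  inside[ok] <- mask[cbind(ty[ok], tx[ok])]
  mean(inside)
}

# convex hull of lattice points: polygon perimeter and the number of lattice
# points inside or on the hull (Pick's theorem: A + B/2 + 1)
hull_stats <- function(bx, by) {
  if (length(bx) < 3 || length(unique(bx)) == 1 || length(unique(by)) == 1) {
    # degenerate (line segment): count collinear lattice points
    n <- max(length(unique(bx)), length(unique(by)))
    return(list(perimeter = 2 * (n - 1), lattice_count = n))
  }
  h <- grDevices::chull(bx, by)
  hx <- bx[h]; hy <- by[h]
  k <- length(h)
  nxt <- c(2:k, 1)
  shoelace <- abs(sum(hx * hy[nxt] - hx[nxt] * hy)) / 2
  edge_dx <- hx[nxt] - hx; edge_dy <- hy[nxt] - hy
  perim <- sum(sqrt(edge_dx^2 + edge_dy^2))
  boundary_pts <- sum(vapply(seq_len(k), function(i) {
    g <- gcd_int(abs(edge_dx[i]), abs(edge_dy[i]))
    max(g, 1L)
  }, numeric(1)))
  list(perimeter = perim,
       lattice_count = shoelace + boundary_pts / 2 + 1)
}

gcd_int <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

# largest 4-connected component (flood fill); warns when the mask splits
largest_component <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0) {
      s <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (s - 1L) %% nr + 1L
      c_ <- (s - 1L) %/% nr + 1L
      for (d in list(c(r - 1L, c_), c(r + 1L, c_), c(r, c_ - 1L), c(r, c_ + 1L))) {
        if (d[1] >= 1 && d[1] <= nr && d[2] >= 1 && d[2] <= nc) {
          t <- (d[2] - 1L) * nr + d[1]
          if (mask[t] && lab[t] == 0L) {
            lab[t] <- cur
            queue <- c(queue, t)
          }
        }
      }
    }
  }
  if (cur > 1L) {
    warning(sprintf("mask has %d components; using the largest", cur))
    sizes <- tabulate(lab[lab > 0L], cur)
    mask <- lab == which.max(sizes)
  }
  mask
}

#' Discrete disk mask
#'
#' Convenience constructor for tests and examples: a centered disk of the
#' given radius (pixels whose center lies within `radius` of the image
#' center).
#'
#' @param size Image side length in pixels.
#' @param radius Disk radius in pixels.
#' @return Logical `size` x `size` matrix.
#' @export
disk_mask <- function(size, radius) {
  ctr <- (size + 1) / 2
  d2 <- (row(matrix(0, size, size)) - ctr)^2 + (col(matrix(0, size, size)) - ctr)^2
  d2 <= radius^2
}
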