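# Low-level image operations shared by the analysis modules.
# All functions work on plain numeric/logical matrices in (row, col) order.

# Shift a matrix by (dr, dc), filling exposed cells with `fill`.
.shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  sr <- max(1L, 1L + dr):min(nr, nr + dr)
  sc <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(sr) < 1L || length(sc) < 1L) return(out)
  out[sr, sc] <- m[sr - dr, sc - dc]
  out
}

# Replicate-pad then convolve with a 1-D kernel along rows (margin = 1)
# or columns (margin = 2). Kernel length must be odd.
.conv1d <- function(m, k, margin) {
  r <- (length(k) - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  if (margin == 1L) {
    pad <- m[c(rep(1L, r), seq_len(nr), rep(nr, r)), , drop = FALSE]
    out <- matrix(0, nr, nc)
    for (i in seq_along(k))
      out <- out + k[i] * pad[i:(i + nr - 1L), , drop = FALSE]
  } else {
    pad <- m[, c(rep(1L, r), seq_len(nc), rep(nc, r)), drop = FALSE]
    out <- matrix(0, nr, nc)
    for (i in seq_along(k))
      out <- out + k[i] * pad[, i:(i + nc - 1L), drop = FALSE]
  }
  out
}

.gauss_kernel <- function(sigma, radius = ceiling(3.5 * sigma)) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Second derivative of a Gaussian; adjusted to zero sum so that constant
# images (and, together with the smoothing pass, linear ramps) map to 0.
.gauss_d2_kernel <- function(sigma, radius = ceiling(3.5 * sigma)) {
  x <- (-radius):radius
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  k <- (x^2 - sigma^2) / sigma^4 * g
  k - mean(k)
}

# Scale-normalized negative Laplacian-of-Gaussian response: bright blobs of
# radius ~ sigma*sqrt(2) produce positive peaks whose height is independent
# of scale for a matched blob.
.log_filter <- function(m, sigma) {
  g  <- .gauss_kernel(sigma)
  g2 <- .gauss_d2_kernel(sigma)
  ixx <- .conv1d(.conv1d(m, g2, 1L), g, 2L)
  iyy <- .conv1d(.conv1d(m, g, 1L), g2, 2L)
  -sigma^2 * (ixx + iyy)
}

# Otsu's threshold on a numeric vector; returns a cut value such that
# foreground is (> thr).
.otsu <- function(v, nbins = 256L) {
  rng <- range(v)
  if (diff(rng) == 0) stop("cannot threshold a uniform image")
  h <- tabulate(pmin(nbins, 1L + floor((v - rng[1]) / diff(rng) * nbins)),
                nbins = nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  rng[1] + k / nbins * diff(rng)
}

# 8-connected component labelling by iterative minimum-label propagation.
# Returns an integer matrix with labels 1..k (0 = background).
.label_components <- function(bin) {
  nr <- nrow(bin); nc <- ncol(bin)
  lab <- matrix(0, nr, nc)
  lab[bin] <- seq_len(sum(bin))
  offs <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  repeat {
    nb <- lab
    for (i in seq_len(nrow(offs))) {
      s <- .shift_mat(lab, offs[i, 1], offs[i, 2], fill = 0)
      take <- bin & s > 0 & (nb == 0 | s < nb)
      nb[take] <- s[take]
    }
    if (identical(nb, lab)) break
    lab <- nb
  }
  u <- sort(unique(lab[lab > 0]))
  if (length(u)) lab[lab > 0] <- match(lab[lab > 0], u)
  lab
}

# Fill holes: background pixels not connected (4-connectivity) to the image
# border become foreground.
.fill_holes <- function(bin) {
  nr <- nrow(bin); nc <- ncol(bin)
  outside <- matrix(FALSE, nr, nc)
  bg <- !bin
  outside[1, ] <- bg[1, ]; outside[nr, ] <- bg[nr, ]
  outside[, 1] <- outside[, 1] | bg[, 1]
  outside[, nc] <- outside[, nc] | bg[, nc]
  repeat {
    grown <- outside |
      (.shift_mat(outside, 1, 0, FALSE) | .shift_mat(outside, -1, 0, FALSE) |
       .shift_mat(outside, 0, 1, FALSE) | .shift_mat(outside, 0, -1, FALSE)) & bg
    if (identical(grown, outside)) break
    outside <- grown
  }
  bin | (bg & !outside)
}

# Binary dilation with a Euclidean disk of the given radius (px).
.dilate_disk <- function(bin, radius) {
  if (radius <= 0) return(bin)
  out <- bin
  for (dr in -radius:radius) {
    span <- floor(sqrt(radius^2 - dr^2))
    for (dc in -span:span) {
      if (dr == 0 && dc == 0) next
      out <- out | .shift_mat(bin, dr, dc, FALSE)
    }
  }
  out
}

# Strict 8-neighbour local maxima above `floor`.
.local_maxima <- function(m, floor = -Inf) {
  res <- m > floor
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    res <- res & (m > .shift_mat(m, dr, dc, fill = -Inf))
  }
  res
}

# Bilinear interpolation of matrix values at fractional (row, col) positions.
.bilinear <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(r, 1), nr); c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
}

# Filled-ellipse rasterization: TRUE where the pixel centre lies inside.
.ellipse_mask <- function(shape, center, axes, theta = 0) {
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  dy <- rr - center[1]; dx <- cc - center[2]
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / axes[2])^2 + (v / axes[1])^2 <= 1
}
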