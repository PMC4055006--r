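# Independent oracles used across the test suite.

# Gauss-Legendre nodes/weights on [a, b] (Golub-Welsch, base eigen only)
gauss_legendre <- function(n, a, b) {
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  list(nodes = (b - a) / 2 * e$values + (a + b) / 2,
       weights = (b - a) / 2 * 2 * e$vectors[1, ]^2)
}

# Brute-force surface-charge field of the cylinder magnet in its own frame
# (origin at the pole-face center, axis +z, body z in [-L, 0]): direct
# quadrature of the two charged disks, Gauss-Legendre radially x uniform
# angular grid. Independent of the package's elliptic-integral evaluation.
oracle_field <- function(points, radius, length, remanence,
                         n_r = 80, n_th = 256) {
  gl <- gauss_legendre(n_r, 0, radius)
  th <- 2 * pi * (seq_len(n_th) - 0.5) / n_th
  dth <- 2 * pi / n_th
  src <- function(z0) {
    cbind(x = as.vector(outer(gl$nodes, cos(th))),
          y = as.vector(outer(gl$nodes, sin(th))),
          z = z0,
          w = as.vector(outer(gl$nodes * gl$weights, rep(dth, n_th))))
  }
  faces <- list(list(s = +1, pts = src(0)), list(s = -1, pts = src(-length)))
  t(apply(points, 1, function(p) {
    B <- c(0, 0, 0)
    for (f in faces) {
      d <- cbind(p[1] - f$pts[, 1], p[2] - f$pts[, 2], p[3] - f$pts[, 3])
      r3 <- (rowSums(d^2))^(1.5)
      B <- B + f$s * colSums(d * f$pts[, "w"] / r3)
    }
    remanence / (4 * pi) * B
  }))
}

# Closed-form slab capture fraction: uniform transverse drift u, mean axial
# velocity v, tube length L, gap H, uniform inlet heights.
slab_capture_fraction <- function(u, v, L, H) {
  min(1, (u * L / v) / H)
}

# Pooled two-sample t from raw replicates, written out longhand
oracle_pooled_t <- function(x, y) {
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
}
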