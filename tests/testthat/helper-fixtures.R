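# Small fixtures shared across test files; everything is generated in code.

# flat patch with a mildly perturbed z coordinate: non-planar but far from
# degenerate, suitable for geometry oracles
random_bumpy_mesh <- function(nx, ny, spacing, bump_sd = 0.2 * spacing) {
  m <- make_flat_patch_mesh(nx, ny, spacing)
  m$vertices[, 3] <- rnorm(nrow(m$vertices), 0, bump_sd)
  m
}

# deterministic trace: alternating +/-c baseline (population SD exactly c)
# and a two-sample deflection of peak-to-peak `p2p` inside the response window
constructed_trace <- function(p2p, baseline_c = 5, rate_hz = 2000,
                              t0_s = -0.25, n = 700) {
  x <- rep(c(baseline_c, -baseline_c), length.out = n)
  t <- t0_s + (seq_len(n) - 1) / rate_hz
  i <- which(t >= 0.020)[1]
  x[i] <- p2p / 2
  x[i + 1L] <- -p2p / 2
  emg_trace(x, rate_hz, t0_s)
}

# unit right triangle in the z = 0 plane as a tri_surface
right_triangle_surface <- function() {
  tri_surface(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
              matrix(c(1, 2, 3), nrow = 1))
}

# balanced long-format data with iid Gaussian values plus subject offsets
random_long <- function(n, a, b, subject_sd = 1) {
  d <- expand.grid(subject = seq_len(n), factor_a = paste0("a", seq_len(a)),
                   factor_b = paste0("b", seq_len(b)),
                   stringsAsFactors = FALSE)
  d$value <- rnorm(nrow(d)) + rep(rnorm(n, 0, subject_sd), a * b)
  d
}

# n x p matrix whose sample covariance is exactly the identity
whitened_scores <- function(n, p) {
  z <- matrix(rnorm(n * p), n, p)
  z <- scale(z, center = TRUE, scale = FALSE)
  s <- crossprod(z) / (n - 1)
  e <- eigen(s, symmetric = TRUE)
  z %*% e$vectors %*% diag(1 / sqrt(e$values), p) %*% t(e$vectors)
}

# one-way long table whose factor_a contrast scores are exactly `scores %*% C`
# for the package's orthonormal contrasts (k = ncol(scores) + 1 levels)
long_from_scores <- function(scores) {
  k <- ncol(scores) + 1L
  h <- stats::contr.helmert(k)
  C <- t(sweep(h, 2, sqrt(colSums(h^2)), "/")) # (k-1) x k orthonormal
  Y <- scores %*% C
  n <- nrow(Y)
  data.frame(subject = rep(seq_len(n), k),
             factor_a = rep(paste0("a", seq_len(k)), each = n),
             factor_b = "b1",
             value = as.vector(Y))
}
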