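# Independent oracles used across the suite. Each is a deliberately naive
# implementation of the quantity it checks, kept separate from the package's
# own computational path.

# mass-action equilibrium by root-finding on the complex concentration:
# (P - x)(L - x) = K x, x in [0, min(P, L)]; bound fraction = x / P
oracle_bound_fraction <- function(P, L, K) {
  if (L == 0) return(0)
  g <- function(x) (P - x) * (L - x) - K * x
  x <- uniroot(g, c(0, min(P, L)), tol = 1e-15)$root
  x / P
}

# two-site exchange evolution matrix built independently of the package
oracle_exchange_matrix <- function(delta_nu, r2_free, r2_bound, p_bound,
                                   k_off) {
  k_fb <- k_off * p_bound / (1 - p_bound)
  matrix(c(1i * 2 * pi * 0 - r2_free - k_fb, k_fb,
           k_off, 1i * 2 * pi * delta_nu - r2_bound - k_off),
         nrow = 2)
}

# peak positions (Hz) from the imaginary parts of the eigenvalues
oracle_peak_positions <- function(delta_nu, r2_free, r2_bound, p_bound,
                                  k_off) {
  A <- oracle_exchange_matrix(delta_nu, r2_free, r2_bound, p_bound, k_off)
  sort(Im(eigen(A)$values) / (2 * pi))
}

# brute-force 3x3 mean by explicit loops
oracle_nine_point <- function(mat, i, j) {
  s <- 0
  for (di in -1:1) for (dj in -1:1) s <- s + mat[i + di, j + dj]
  s / 9
}

# two-pass mean/sd
oracle_mean_sd <- function(x) {
  m <- sum(x) / length(x)
  list(mean = m, sd = sqrt(sum((x - m)^2) / (length(x) - 1)))
}

# random rigid rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# apply a rigid transform to a model data frame
transform_model <- function(model, rot = diag(3), shift = c(0, 0, 0)) {
  xyz <- as.matrix(model[, c("x", "y", "z")]) %*% t(rot)
  model$x <- xyz[, 1] + shift[1]
  model$y <- xyz[, 2] + shift[2]
  model$z <- xyz[, 3] + shift[3]
  model
}
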