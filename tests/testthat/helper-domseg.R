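# fixtures built in code: ideal geometries, random soft adjacencies and
# rigid-body transforms used across test files

make_line_chain <- function(L, spacing = 3.8) {
  protein_chain(cbind(spacing * (seq_len(L) - 1), 0, 0))
}

make_helix_chain <- function(L, rise = 1.5, radius = 2.3, turn_deg = 100) {
  t <- (seq_len(L) - 1) * turn_deg * pi / 180
  protein_chain(cbind(radius * cos(t), radius * sin(t),
                      rise * (seq_len(L) - 1)))
}

# random rotation (via QR of a Gaussian matrix), optional reflection
random_rigid_transform <- function(coords, reflect = FALSE) {
  qr_dec <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_dec)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  if (reflect) R[, 1] <- -R[, 1]
  shift <- matrix(runif(3, -50, 50), nrow(coords), 3, byrow = TRUE)
  coords %*% R + shift
}

# symmetric matrix of probabilities, uniform in [eps, 1 - eps]
random_soft_adjacency <- function(L, eps = 1e-4) {
  U <- matrix(runif(L * L, eps, 1 - eps), L, L)
  U <- (U + t(U)) / 2
  diag(U) <- 1 - eps
  U
}

clipped_adjacency <- function(labels, eps = 1e-4) {
  domseg:::clip_prob(assignment_to_adjacency(labels), eps)
}
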