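# Independent oracles used across the suite. These deliberately share no
# code with the package: the RMSD oracle uses Horn's quaternion method
# (largest eigenvalue of the 4x4 key matrix) instead of the SVD-based
# Kabsch solution, and the geometry oracle carries its own ideal-value
# table.

# Minimal RMSD via Horn's quaternion method.
oracle_rmsd <- function(a, b) {
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  S <- crossprod(a, b)
  K <- matrix(c(
    S[1, 1] + S[2, 2] + S[3, 3], S[2, 3] - S[3, 2],
    S[3, 1] - S[1, 3], S[1, 2] - S[2, 1],
    S[2, 3] - S[3, 2], S[1, 1] - S[2, 2] - S[3, 3],
    S[1, 2] + S[2, 1], S[3, 1] + S[1, 3],
    S[3, 1] - S[1, 3], S[1, 2] + S[2, 1],
    -S[1, 1] + S[2, 2] - S[3, 3], S[2, 3] + S[3, 2],
    S[1, 2] - S[2, 1], S[3, 1] + S[1, 3],
    S[2, 3] + S[3, 2], -S[1, 1] - S[2, 2] + S[3, 3]),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(a^2) + sum(b^2) - 2 * lam) / nrow(a)
  sqrt(max(msd, 0))
}

# Uniformly random proper rotation matrix.
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Closed-form KL divergence between two multivariate Gaussians.
oracle_gaussian_kl <- function(mu_p, sig_p, mu_q, sig_q) {
  n <- length(mu_p)
  iq <- solve(sig_q)
  dm <- mu_q - mu_p
  0.5 * (sum(diag(iq %*% sig_p)) + drop(t(dm) %*% iq %*% dm) - n +
           log(det(sig_q) / det(sig_p)))
}

# Bond-only geometry scan with its own ideal table (GLN chains with
# ACE/NME caps), counting bonds outside the fractional tolerance.
oracle_bond_violations <- function(conf, atoms, bond_tol = 0.15) {
  ideal <- list(GLN = list(c("N", "CA", 1.458), c("CA", "C", 1.525),
                           c("C", "O", 1.231), c("CA", "CB", 1.530),
                           c("CB", "CG", 1.530), c("CG", "CD", 1.516),
                           c("CD", "OE1", 1.231), c("CD", "NE2", 1.328)),
                ACE = list(c("CH3", "C", 1.508), c("C", "O", 1.231)),
                NME = list(c("N", "CH3", 1.449)))
  find <- function(rn, nm) {
    i <- which(atoms$resno == rn & atoms$elety == nm)
    if (length(i)) i[1] else NA_integer_
  }
  count <- 0L
  resnos <- unique(atoms$resno)
  for (rn in resnos) {
    resid <- atoms$resid[match(rn, atoms$resno)]
    for (b in ideal[[resid]]) {
      i <- find(rn, b[1]); j <- find(rn, b[2])
      if (is.na(i) || is.na(j)) next
      l <- sqrt(sum((conf[i, ] - conf[j, ])^2))
      if (abs(l - as.numeric(b[3])) > bond_tol * as.numeric(b[3]))
        count <- count + 1L
    }
  }
  for (p in seq_len(length(resnos) - 1L)) {
    i <- find(resnos[p], "C")
    j <- find(resnos[p + 1L], "N")
    if (is.na(i) || is.na(j)) next
    l <- sqrt(sum((conf[i, ] - conf[j, ])^2))
    if (abs(l - 1.329) > bond_tol * 1.329) count <- count + 1L
  }
  count
}
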