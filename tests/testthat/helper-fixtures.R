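# Fixture builders and independent oracles used across test files.

# A hand-written PDB ATOM line with full control over fields.
atom_line <- function(serial, name, resname, chain, resseq, x, y, z,
                      altloc = " ", icode = " ", occ = 1, element = "C",
                      record = "ATOM  ") {
  sprintf("%-6s%5d %-4s%s%3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, paste0(" ", name), altloc, resname, chain,
          resseq, icode, x, y, z, occ, 0, element)
}

pdb_text <- function(...) paste(c(..., "END"), collapse = "\n")

# Random charged point set: n points in a 30 A box, charges -1/0/+1.
random_cps <- function(n) {
  xyz <- matrix(stats::runif(3 * n, -15, 15), n, 3)
  q <- sample(c(-1, 0, 1), n, replace = TRUE)
  list(xyz = xyz, charge = q,
       cps = rbpmoments:::charged_point_set(xyz, q))
}

# --- independent literal-summation oracles (scalar loops, no linear
# --- algebra shared with the implementation) -------------------------

oracle_center <- function(xyz) {
  s <- c(0, 0, 0)
  for (i in seq_len(nrow(xyz))) s <- s + xyz[i, ]
  s / nrow(xyz)
}

oracle_dipole <- function(xyz, q, ref) {
  p <- c(0, 0, 0)
  for (i in seq_len(nrow(xyz))) p <- p + q[i] * (xyz[i, ] - ref)
  p
}

oracle_tensor <- function(xyz, q, ref) {
  m <- matrix(0, 3, 3)
  for (i in seq_len(nrow(xyz))) {
    r <- xyz[i, ] - ref
    r2 <- sum(r * r)
    for (a in 1:3) for (b in 1:3) {
      m[a, b] <- m[a, b] + 0.5 * q[i] * (3 * r[a] * r[b] - (a == b) * r2)
    }
  }
  m
}

# Eigenvalues of a symmetric 3x3 matrix via the characteristic cubic
# det(M - lambda I) = 0, solved with polyroot().
oracle_eigs <- function(m) {
  c2 <- -(m[1, 1] + m[2, 2] + m[3, 3])
  c1 <- m[1, 1] * m[2, 2] + m[1, 1] * m[3, 3] + m[2, 2] * m[3, 3] -
    m[1, 2]^2 - m[1, 3]^2 - m[2, 3]^2
  c0 <- -det(m)
  # lambda^3 + c2 lambda^2 + c1 lambda + c0 = 0
  roots <- polyroot(c(c0, c1, c2, 1))
  sort(Re(roots), decreasing = TRUE)
}

# Random 3D rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  r <- qr.Q(qr_)
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

# Welch t-test p-value from the textbook formula.
oracle_welch_p <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * stats::pt(-abs(t), df)
}
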