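#' @title Synthetic fixtures with known ground truth
#' @name synth
#' @description
#' Generators for testing the whole stack end to end: point-charge
#' configurations written as valid Calpha-only PDB files whose moments
#' are known analytically (computed here by a literal term-by-term
#' summation, independent of the vectorised implementation in the
#' moments module), perturbed bound/unbound structure pairs, and
#' two-class Gaussian feature tables with closed-form separability.
NULL

#' Specify a point-charge configuration
#'
#' Charges are restricted to -1, 0, +1 so each point can be encoded as
#' a residue in a PDB file: +1 -> LYS, -1 -> GLU, 0 -> GLY.
#'
#' @param charge Integer vector with values in {-1, 0, 1}.
#' @param xyz Numeric n x 3 coordinate matrix, Angstrom.
#' @return A `point_charge_spec`.
#' @export
point_charge_spec <- function(charge, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  charge <- as.numeric(charge)
  if (!length(charge) || length(charge) != nrow(xyz)) {
    stop_rbp("charge and xyz must describe >= 1 point each",
             "rbp_compute_error")
  }
  if (!all(charge %in% c(-1, 0, 1))) {
    stop_rbp("charges must be in {-1, 0, +1}", "rbp_compute_error")
  }
  if (any(!is.finite(xyz))) {
    stop_rbp("coordinates must be finite", "rbp_compute_error")
  }
  structure(list(charge = charge, xyz = xyz), class = "point_charge_spec")
}

charge_to_resname <- function(charge) {
  c("GLU", "GLY", "LYS")[charge + 2L]
}

# Literal term-by-term evaluation of the moment sums: scalar loops, no
# matrix algebra. This is the oracle the fixtures are checked against.
oracle_profile <- function(charge, xyz, source_id = "oracle") {
  n <- length(charge)
  ref <- c(0, 0, 0)
  for (i in seq_len(n)) ref <- ref + xyz[i, ]
  ref <- ref / n
  p <- c(0, 0, 0)
  for (i in seq_len(n)) p <- p + charge[i] * (xyz[i, ] - ref)
  m <- matrix(0, 3, 3)
  for (i in seq_len(n)) {
    r <- xyz[i, ] - ref
    r2 <- r[1]^2 + r[2]^2 + r[3]^2
    for (a in 1:3) for (b in 1:3) {
      m[a, b] <- m[a, b] + 0.5 * charge[i] * (3 * r[a] * r[b] - (a == b) * r2)
    }
  }
  ev <- sort(eigen((m + t(m)) / 2, symmetric = TRUE)$values, decreasing = TRUE)
  list(q = sum(charge) / n,
       p = sqrt(sum(p^2)) / n * DEBYE_PER_E_ANGSTROM,
       q_eigs = stats::setNames(ev / n, c("Q1", "Q2", "Q3")),
       raw = list(dipole = p, quadrupole = m, reference = ref),
       n_residues = n, source_id = source_id)
}

#' Build a synthetic point-charge structure with known moments
#'
#' Writes the configuration as a minimal valid PDB file and returns the
#' analytically expected moment profile, computed by a literal
#' summation oracle rather than by [moment_profile()] — so the pair
#' (PDB text, expected profile) exercises the full read/charge/moment
#' stack independently.
#'
#' @param spec A [point_charge_spec()].
#' @return List with `pdb` (PDB text), `expected` (oracle profile with
#'   `q`, `p`, `q_eigs`, `raw`, `n_residues`) and `spec`.
#' @export
make_structure <- function(spec) {
  stopifnot(inherits(spec, "point_charge_spec"))
  # quantise to the PDB coordinate grid (1e-3 A) so the analytic
  # expectation refers to exactly the coordinates the file carries
  xyz <- round(spec$xyz, 3)
  df <- data.frame(resname = charge_to_resname(spec$charge),
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  list(pdb = write_minimal_pdb(list(A = df)),
       expected = oracle_profile(spec$charge, xyz, "synthetic_A"),
       spec = spec)
}

#' Generate bound/unbound pairs by coordinate jitter
#'
#' Each pair has a bound member with the exact base coordinates and a
#' free member with isotropic Gaussian jitter of standard deviation
#' `jitter_sd` added to every coordinate. With zero jitter the
#' bound/unbound distance is exactly zero; it grows monotonically with
#' `jitter_sd` in expectation.
#'
#' @param base A [point_charge_spec()].
#' @param jitter_sd Coordinate noise, Angstrom (>= 0).
#' @param n_pairs Number of pairs.
#' @param seed Integer seed (mandatory; the generator never touches the
#'   caller's RNG state).
#' @return A [pair_set()] of `n_pairs` rows, class label `"synthetic"`.
#' @export
make_pairs <- function(base, jitter_sd, n_pairs, seed) {
  stopifnot(inherits(base, "point_charge_spec"), jitter_sd >= 0, n_pairs >= 1)
  n <- length(base$charge)
  bound_profile <- moment_profile(charged_point_set(base$xyz, base$charge,
                                                    "bound"))
  with_seed(seed, {
    bound <- vector("list", n_pairs)
    free <- vector("list", n_pairs)
    for (k in seq_len(n_pairs)) {
      bound[[k]] <- bound_profile
      jit <- matrix(stats::rnorm(3 * n, sd = jitter_sd), n, 3)
      free[[k]] <- moment_profile(charged_point_set(base$xyz + jit,
                                                    base$charge,
                                                    paste0("free_", k)))
    }
    pair_set(bound, free, labels = "synthetic",
             proteins = paste0("pair_", seq_len(n_pairs)))
  })
}

#' Generate a two-class Gaussian feature table
#'
#' Negative-class samples are drawn from N(0, s^2 I) over the five
#' descriptors (q, p, Q1, Q2, Q3); positive-class samples from
#' N(mean_shift, s^2 I). For a single informative dimension with unit
#' variance and mean separation delta, the theoretical AUC of the
#' optimal scorer is Phi(delta / sqrt(2)).
#'
#' @param n_pos,n_neg Sample counts per class (>= 1).
#' @param mean_shift Length-5 vector of class-mean differences.
#' @param cov_scale Common within-class standard deviation s (default 1).
#' @param seed Integer seed (mandatory).
#' @return Data frame with columns `q`, `p`, `Q1`, `Q2`, `Q3`, `label`
#'   (1 positive, 0 negative).
#' @export
make_features <- function(n_pos, n_neg, mean_shift = rep(0, 5),
                          cov_scale = 1, seed) {
  stopifnot(n_pos >= 1, n_neg >= 1, length(mean_shift) == 5, cov_scale > 0)
  with_seed(seed, {
    pos <- matrix(stats::rnorm(n_pos * 5, sd = cov_scale), n_pos, 5)
    pos <- sweep(pos, 2L, mean_shift, "+")
    neg <- matrix(stats::rnorm(n_neg * 5, sd = cov_scale), n_neg, 5)
    x <- rbind(pos, neg)
    colnames(x) <- c("q", "p", "Q1", "Q2", "Q3")
    df <- as.data.frame(x)
    df$label <- rep(c(1, 0), c(n_pos, n_neg))
    df
  })
}

#' Lay out points along a plausible Calpha-like path
#'
#' Helper producing coordinates spaced 3.8 Angstrom apart along a
#' gently curving path, so synthetic structures resemble a chain trace.
#' Purely cosmetic: moments depend only on the coordinates given.
#'
#' @param n Number of points.
#' @param seed Integer seed.
#' @return n x 3 coordinate matrix.
#' @export
calpha_layout <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  with_seed(seed, {
    xyz <- matrix(0, n, 3)
    dir <- c(1, 0, 0)
    for (i in seq_len(n)[-1]) {
      dir <- dir + stats::rnorm(3, sd = 0.35)
      dir <- dir / sqrt(sum(dir^2))
      xyz[i, ] <- xyz[i - 1, ] + 3.8 * dir
    }
    xyz
  })
}
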