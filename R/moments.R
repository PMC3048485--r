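#' @title Electric moments from a charged point set
#' @name moments
#' @description
#' The multipole expansion of the residue-level charge distribution:
#' monopole (net charge), dipole vector P = sum_i q_i (R_i - R_o) about
#' the geometric centre R_o of all Calpha positions, and the traceless
#' symmetric quadrupole tensor
#' M_ab = 1/2 sum_i q_i (3 r_ia r_ib - r_i^2 delta_ab).
#' Magnitudes and eigenvalues are normalised by the number of residues
#' N; dipole moments are converted to Debye (1 e*A = 4.80321 D).
NULL

#' Geometric centre of a charged point set
#'
#' Componentwise mean of all Calpha positions, charged and neutral
#' alike; this is the reference point R_o of the dipole and quadrupole
#' sums.
#'
#' @param cps A `charged_point_set`.
#' @return Numeric length-3 vector, Angstrom.
#' @export
geometric_center <- function(cps) {
  stopifnot(inherits(cps, "charged_point_set"), cps$n_residues >= 1)
  colMeans(cps$xyz)
}

#' Dipole moment vector
#'
#' P = sum_i q_i (R_i - R_o) in e*Angstrom. For a net-neutral point set
#' the result does not depend on the reference point.
#'
#' @param cps A `charged_point_set`.
#' @param reference Reference point R_o, default the geometric centre.
#' @return Numeric length-3 vector with attribute `reference`.
#' @export
dipole_vector <- function(cps, reference = geometric_center(cps)) {
  stopifnot(inherits(cps, "charged_point_set"),
            length(reference) == 3L, all(is.finite(reference)))
  r <- sweep(cps$xyz, 2L, reference)
  p <- as.numeric(crossprod(r, cps$charge))
  names(p) <- c("x", "y", "z")
  attr(p, "reference") <- as.numeric(reference)
  p
}

#' Dipole magnitude per residue, in Debye
#'
#' `||P|| / N` converted from e*Angstrom to Debye.
#'
#' @param mv Dipole vector from [dipole_vector()].
#' @param n_residues Residue count N used for normalisation.
#' @return Nonnegative scalar, Debye per residue.
#' @export
dipole_per_residue_debye <- function(mv, n_residues) {
  stopifnot(n_residues >= 1)
  sqrt(sum(as.numeric(mv)^2)) / n_residues * DEBYE_PER_E_ANGSTROM
}

#' Quadrupole moment tensor
#'
#' M_ab = 1/2 sum_i q_i (3 r_ia r_ib - r_i^2 delta_ab), with r_i taken
#' relative to the same reference as the dipole. Symmetric and traceless
#' by construction; eigenvalues are stored sorted by signed value in
#' decreasing order (Q1 >= Q2 >= Q3, summing to zero).
#'
#' @inheritParams dipole_vector
#' @return A `quadrupole_tensor`: list with `m` (3x3 matrix, e*A^2) and
#'   `eigenvalues` (length 3, decreasing).
#' @export
quadrupole_tensor <- function(cps, reference = geometric_center(cps)) {
  stopifnot(inherits(cps, "charged_point_set"),
            length(reference) == 3L, all(is.finite(reference)))
  r <- sweep(cps$xyz, 2L, reference)
  q <- cps$charge
  m <- 1.5 * crossprod(r, r * q) - 0.5 * sum(q * rowSums(r^2)) * diag(3)
  m <- (m + t(m)) / 2  # enforce exact symmetry
  dimnames(m) <- list(c("x", "y", "z"), c("x", "y", "z"))
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  structure(list(m = m, eigenvalues = sort(ev, decreasing = TRUE)),
            class = "quadrupole_tensor")
}

#' Quadrupole eigenvalues per residue
#'
#' Signed eigenvalues of the quadrupole tensor divided by N, sorted in
#' decreasing order. Tracelessness guarantees Q1 >= 0.
#'
#' @param tensor A `quadrupole_tensor`, or a symmetric 3x3 matrix.
#' @param n_residues Residue count N.
#' @return Named numeric vector `c(Q1, Q2, Q3)`, e*A^2 per residue.
#' @export
quadrupole_eigs_per_residue <- function(tensor, n_residues) {
  stopifnot(n_residues >= 1)
  if (inherits(tensor, "quadrupole_tensor")) {
    ev <- tensor$eigenvalues
  } else {
    m <- as.matrix(tensor)
    if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
      stop_rbp("quadrupole tensor must be symmetric", "rbp_compute_error")
    }
    ev <- sort(eigen((m + t(m)) / 2, symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
  }
  stats::setNames(ev / n_residues, c("Q1", "Q2", "Q3"))
}

#' Full five-descriptor moment profile of a protein chain
#'
#' Computes net charge per residue (q, signed), dipole magnitude per
#' residue (p, Debye) and the three quadrupole eigenvalues per residue
#' (Q1 >= Q2 >= Q3, e*A^2), all about the geometric centre of the
#' Calpha trace. These five numbers are the feature vector used for
#' RNA-binding class discrimination.
#'
#' @param chain A `chain_structure` from [read_pdb_calpha()].
#' @param scheme A [charge_scheme()].
#' @return A `moment_profile`: list with `q`, `p`, `q_eigs` (Q1, Q2,
#'   Q3), `raw` (dipole vector and quadrupole tensor, unnormalised),
#'   `n_residues`, `source_id`.
#' @examples
#' pdb <- write_minimal_pdb(list(A = data.frame(
#'   resname = c("LYS", "GLU"), x = c(1, -1), y = 0, z = 0)))
#' ch <- read_pdb_calpha(pdb)[[1]]
#' moment_profile(ch)  # p = 4.80321 D per residue
#' @export
moment_profile <- function(chain, scheme = charge_scheme()) {
  cps <- if (inherits(chain, "charged_point_set")) chain
         else assign_charges(chain, scheme)
  ref <- geometric_center(cps)
  mv <- dipole_vector(cps, ref)
  qt <- quadrupole_tensor(cps, ref)
  structure(list(
    q = net_charge_per_residue(cps),
    p = dipole_per_residue_debye(mv, cps$n_residues),
    q_eigs = quadrupole_eigs_per_residue(qt, cps$n_residues),
    raw = list(dipole = mv, quadrupole = qt, reference = ref),
    n_residues = cps$n_residues,
    source_id = cps$source_id
  ), class = "moment_profile")
}

#' @export
print.moment_profile <- function(x, ...) {
  cat(sprintf("Moment profile of %s (N = %d residues)\n", x$source_id,
              x$n_residues))
  cat(sprintf("  q  = %+.4f e/residue\n", x$q))
  cat(sprintf("  p  = %.4f D/residue\n", x$p))
  cat(sprintf("  Q  = (%.4f, %.4f, %.4f) e*A^2/residue\n",
              x$q_eigs[1], x$q_eigs[2], x$q_eigs[3]))
  invisible(x)
}

# Collect a list of moment_profile objects into a feature data frame.
profiles_to_features <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  data.frame(
    source_id = vapply(profiles, function(p) p$source_id, character(1)),
    n_residues = vapply(profiles, function(p) p$n_residues, numeric(1)),
    q  = vapply(profiles, function(p) p$q, numeric(1)),
    p  = vapply(profiles, function(p) p$p, numeric(1)),
    Q1 = vapply(profiles, function(p) unname(p$q_eigs[1]), numeric(1)),
    Q2 = vapply(profiles, function(p) unname(p$q_eigs[2]), numeric(1)),
    Q3 = vapply(profiles, function(p) unname(p$q_eigs[3]), numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Sensitivity of moments to the His protonation state
#'
#' Pearson correlations between descriptor values computed under the
#' His-neutral and His-positive charge schemes, across a set of chains:
#' one for net charge, one for dipole magnitude, and for the quadrupole
#' the best-correlated same-rank eigenvalue pair. Correlations near 1
#' justify treating His as neutral.
#'
#' @param profiles_neutral,profiles_positive Equal-length lists of
#'   `moment_profile` objects for the same chains in the same order.
#' @return Named numeric vector `c(q, p, Q)` of correlations in [-1, 1].
#' @export
his_sensitivity <- function(profiles_neutral, profiles_positive) {
  if (length(profiles_neutral) != length(profiles_positive)) {
    stop_rbp("profile lists must have equal length", "rbp_compute_error")
  }
  a <- profiles_to_features(profiles_neutral)
  b <- profiles_to_features(profiles_positive)
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 && stats::sd(y) == 0 && all(x == y)) return(1)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }
  qq <- vapply(c("Q1", "Q2", "Q3"), function(k) safe_cor(a[[k]], b[[k]]),
               numeric(1))
  c(q = safe_cor(a$q, b$q), p = safe_cor(a$p, b$p),
    Q = if (all(is.na(qq))) NA_real_ else max(qq, na.rm = TRUE))
}
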