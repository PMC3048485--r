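#' @title Bound/unbound pair statistics and conservation measures
#' @name pairstats
#' @description
#' Tools for asking how robust the residue-level electric moments are:
#' a root-mean-square Euclidean distance between bound (RNA-complexed)
#' and unbound (monomeric) values of a descriptor across structure
#' pairs, bound-vs-free Pearson correlation, a within-cluster
#' noise-to-signal ratio for evolutionary conservation, and a two-sample
#' t-test for group differences.
NULL

#' Build a pair set of bound/unbound moment profiles
#'
#' @param bound,free Equal-length lists of `moment_profile` objects, or
#'   a data frame already holding columns `p_bound`, `p_free`,
#'   `Q1_bound`, `Q1_free` (then `free` is omitted). Bound and free
#'   entries must refer to the same protein, in the same order.
#' @param labels Optional functional-class label per pair (e.g.
#'   `"rRNA"`); recycled if length 1.
#' @param proteins Optional protein names.
#' @return A `pair_set` data frame with one row per pair.
#' @export
pair_set <- function(bound, free = NULL, labels = NULL, proteins = NULL) {
  if (is.data.frame(bound) && is.null(free)) {
    df <- bound
    need <- c("p_bound", "p_free", "Q1_bound", "Q1_free")
    if (!all(need %in% names(df))) {
      stop_rbp(paste("pair data frame needs columns:",
                     paste(need, collapse = ", ")), "rbp_parse_error")
    }
  } else {
    if (length(bound) != length(free) || !length(bound)) {
      stop_rbp("bound and free must be non-empty lists of equal length",
               "rbp_compute_error")
    }
    fb <- profiles_to_features(bound)
    ff <- profiles_to_features(free)
    df <- data.frame(
      protein = if (is.null(proteins)) fb$source_id else proteins,
      q_bound = fb$q,  q_free = ff$q,
      p_bound = fb$p,  p_free = ff$p,
      Q1_bound = fb$Q1, Q1_free = ff$Q1,
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(labels)) df$class <- rep_len(labels, nrow(df))
  if (is.null(df$class)) df$class <- "all"
  class(df) <- c("pair_set", "data.frame")
  df
}

pair_columns <- function(ps, property = c("p", "Q1", "q")) {
  property <- match.arg(property)
  list(bound = ps[[paste0(property, "_bound")]],
       free  = ps[[paste0(property, "_free")]])
}

#' Root-mean-square bound/unbound distance of a descriptor
#'
#' `ED(X) = sqrt( (1/N) * sum_pairs (X_bound - X_free)^2 )` over the N
#' structure pairs of the set — the per-pair RMS change of the
#' descriptor on complex formation.
#'
#' @param ps A [pair_set()].
#' @param property `"p"` (dipole, Debye/residue), `"Q1"` (largest
#'   quadrupole eigenvalue) or `"q"` (net charge).
#' @return Nonnegative scalar in the descriptor's units.
#' @export
euclidean_distance <- function(ps, property = c("p", "Q1", "q")) {
  if (!NROW(ps)) stop_rbp("empty pair set", "rbp_compute_error")
  v <- pair_columns(ps, property)
  d <- v$bound - v$free
  sqrt(mean(d^2))
}

#' Bound-vs-free Pearson correlation of a descriptor
#'
#' @inheritParams euclidean_distance
#' @return Pearson r in [-1, 1].
#' @export
pair_correlation <- function(ps, property = c("p", "Q1", "q")) {
  if (NROW(ps) < 2) stop_rbp("need at least 2 pairs", "rbp_compute_error")
  v <- pair_columns(ps, property)
  if (stats::sd(v$bound) == 0 || stats::sd(v$free) == 0) {
    stop_rbp("correlation undefined: zero variance", "rbp_compute_error")
  }
  stats::cor(v$bound, v$free)
}

#' Within-cluster noise-to-signal ratio
#'
#' Sample standard deviation of a descriptor across the members of a
#' sequence cluster, divided by the cluster mean (absolute value). Small
#' values mean the descriptor is conserved among homologues.
#'
#' @param values Numeric vector of one descriptor across the cluster
#'   members (length >= 2).
#' @return Nonnegative scalar.
#' @export
conservation_ns <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop_rbp("cluster needs >= 2 members", "rbp_compute_error")
  m <- mean(values)
  if (m == 0) stop_rbp("N/S undefined: cluster mean is zero", "rbp_compute_error")
  abs(stats::sd(values) / m)
}

#' Two-sample test for a group difference in a descriptor
#'
#' Two-tailed two-sample t-test; Welch (unequal variance) by default,
#' pooled-variance Student's test with `pooled = TRUE`.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param pooled Use the pooled-variance (classical Student) form.
#' @return Two-tailed p-value in (0, 1].
#' @export
group_difference_test <- function(group_a, group_b, pooled = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop_rbp("each group needs >= 2 values", "rbp_compute_error")
  }
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    stop_rbp("t-test undefined: both groups have zero variance",
             "rbp_compute_error")
  }
  stats::t.test(group_a, group_b, var.equal = pooled,
                alternative = "two.sided")$p.value
}

#' Per-class bound/unbound distance summary
#'
#' Computes ED for dipole and Q1 within each functional class of a pair
#' set, mirroring the per-class summaries of a bound/unbound comparison
#' table.
#'
#' @param ps A [pair_set()] with a `class` column.
#' @return Data frame with columns `class`, `n`, `ED_p`, `ED_Q1`.
#' @export
pair_distance_by_class <- function(ps) {
  cls <- unique(ps$class)
  out <- lapply(cls, function(k) {
    sub <- ps[ps$class == k, , drop = FALSE]
    data.frame(class = k, n = nrow(sub),
               ED_p = euclidean_distance(sub, "p"),
               ED_Q1 = euclidean_distance(sub, "Q1"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
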