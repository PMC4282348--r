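# Rigid-body superposition and the GDT superposition search.

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of point set `P` onto `Q` using the SVD of
#' the cross-covariance matrix, constrained to a proper rotation (no
#' reflection).  The returned transform maps `P` as
#' `P %*% rotation + translation` (row vectors).
#'
#' @param P,Q Numeric n x 3 matrices of paired points, n >= 3.
#' @return Object of class `superposition`: list with `rotation` (3 x 3),
#'   `translation` (length 3), `rmsd` (Angstrom) and `n_points`.
#' @examples
#' P <- matrix(rnorm(12), 4, 3)
#' sp <- kabsch(P, P)
#' sp$rmsd  # 0
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q)) || ncol(P) != 3L)
    stop("P and Q must be n x 3 matrices of equal size")
  if (nrow(P) < 3L) stop("need at least 3 points")
  res <- kabsch_cpp(P, Q)
  res$translation <- as.numeric(res$translation)
  class(res) <- "superposition"
  res
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> %d points, rmsd %.4f A\n", x$n_points, x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates
#' @param X n x 3 coordinate matrix.
#' @param sp A `superposition` from [kabsch()].
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(X, sp) {
  sweep(as.matrix(X) %*% sp$rotation, 2L, -sp$translation)
}

#' GDT inlier fraction at one distance cutoff
#'
#' The largest percentage of paired Calpha atoms that a superposition
#' found by the search can bring within `cutoff` Angstrom of their target
#' positions.  For up to `exact_max_n` pairs the search seeds a
#' superposition from every subset of three or more pairs; above that it
#' enumerates contiguous sequence windows (lengths 3, 5, 7 and n) and
#' iteratively refits on the current inlier set until a fixed point
#' (at most `max_iter` rounds).  Equal inlier counts are broken towards
#' the lower inlier RMSD.
#'
#' @param model_ca,target_ca Paired Calpha coordinate matrices (n x 3),
#'   same row order.
#' @param cutoff Distance cutoff in Angstrom (> 0; membership inclusive).
#' @param exact_max_n Largest n for which all subsets are enumerated.
#' @param max_iter Cap on refit rounds per seed.
#' @return Percentage in \[0, 100\] of `nrow(target_ca)`.
#' @export
gdt_fraction <- function(model_ca, target_ca, cutoff,
                         exact_max_n = 12L, max_iter = 20L) {
  gdt_fractions(model_ca, target_ca, cutoff, exact_max_n, max_iter)
}

#' GDT inlier fractions at several cutoffs in one search
#'
#' Same search as [gdt_fraction()], but every candidate superposition is
#' scored against every cutoff and the per-cutoff maxima are returned
#' together; sharing the candidate pool makes the result non-decreasing
#' in the cutoff by construction.
#'
#' @inheritParams gdt_fraction
#' @param cutoffs Vector of positive distance cutoffs, Angstrom.
#' @return Numeric vector of percentages, one per cutoff.
#' @export
gdt_fractions <- function(model_ca, target_ca, cutoffs,
                          exact_max_n = 12L, max_iter = 20L) {
  P <- as.matrix(model_ca); Q <- as.matrix(target_ca)
  if (!all(dim(P) == dim(Q)) || ncol(P) != 3L)
    stop("model and target Calpha sets must be n x 3 matrices of equal size")
  if (nrow(P) < 3L) stop("need at least 3 paired residues")
  100 * gdt_counts_cpp(P, Q, as.numeric(cutoffs), exact_max_n, max_iter) /
    nrow(P)
}

#' GDT fraction on a reduced residue selection
#'
#' Identical computation to [gdt_fraction()] after removing an excluded
#' set of rows (e.g. residues flagged as flexible or involved in crystal
#' contacts), as used for masked Calpha-only re-evaluation.
#'
#' @inheritParams gdt_fraction
#' @param exclude Integer or logical row selection to drop from the
#'   correspondence.
#' @export
masked_gdt_fraction <- function(model_ca, target_ca, cutoff, exclude,
                                exact_max_n = 12L, max_iter = 20L) {
  P <- as.matrix(model_ca); Q <- as.matrix(target_ca)
  keep <- setdiff(seq_len(nrow(P)),
                  if (is.logical(exclude)) which(exclude) else as.integer(exclude))
  if (length(keep) == 0L) stop("exclusion mask removes every residue")
  if (length(keep) < 3L) stop("fewer than 3 residues remain after masking")
  gdt_fraction(P[keep, , drop = FALSE], Q[keep, , drop = FALSE],
               cutoff, exact_max_n, max_iter)
}
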