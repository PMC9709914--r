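#' Raw (unfitted) coordinate RMSD between two configurations
#'
#' Root-mean-squared difference of the Cartesian coordinates of two
#' configurations, without any superposition:
#' `sqrt( (1 / n_atoms) * sum of squared per-atom displacements )`.
#'
#' @param a,b configurations with the same number of atoms, as flat
#'   atom-major coordinate vectors or `n_atoms x 3` matrices.
#' @return Nonnegative RMSD (same length units as the input, nm by
#'   convention).
#' @examples
#' rmsd_raw(c(0, 0, 0), c(3, 4, 0)) # 5: one atom, 3-4-5 triangle
#' @export
rmsd_raw <- function(a, b) {
  a <- as_coord_vec(a)
  b <- as_coord_vec(b)
  if (length(a) != length(b))
    stop("configurations have different atom counts (", length(a) / 3,
         " vs ", length(b) / 3, ")")
  sqrt(sum((a - b)^2) / (length(a) / 3))
}

#' Optimal least-squares superposition of one configuration onto another
#'
#' Finds the proper rotation and translation minimizing the RMSD of `mobile`
#' onto `reference` (Kabsch procedure via singular value decomposition, with
#' the determinant sign corrected so that reflections are never returned).
#' Degenerate inputs (single atom, collinear atoms) are handled: some valid
#' minimizer is always returned.
#'
#' @param mobile,reference configurations with the same number of atoms
#'   (vectors or `n_atoms x 3` matrices).
#' @return An object of class `superposition`: list with `rotation` (3 x 3,
#'   determinant +1), `translation` (length-3), `rmsd`, and `fitted` (the
#'   transformed mobile coordinates, `n_atoms x 3`). Row coordinate
#'   convention: `fitted = mobile %*% rotation + translation` (rows are
#'   atoms).
#' @examples
#' x <- matrix(rnorm(12), ncol = 3)
#' s <- superpose(x + 5, x)
#' s$rmsd # ~0: pure translation is removed
#' @export
superpose <- function(mobile, reference) {
  M <- to_xyz_mat(mobile)
  R <- to_xyz_mat(reference)
  if (nrow(M) != nrow(R))
    stop("configurations have different atom counts")
  cm <- colMeans(M)
  cr <- colMeans(R)
  A <- sweep(M, 2L, cm)
  B <- sweep(R, 2L, cr)
  H <- crossprod(A, B) # 3x3
  sv <- svd(H)
  d <- sign(det(sv$u) * det(sv$v))
  if (d == 0) d <- 1 # rank-deficient H: either sign attains the optimum
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- A %*% rot + matrix(cr, nrow(M), 3L, byrow = TRUE)
  trans <- as.numeric(cr - cm %*% rot)
  structure(list(rotation = rot, translation = trans,
                 rmsd = rmsd_raw(fitted, R), fitted = fitted),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: rmsd = %.6g\n", x$rmsd))
  invisible(x)
}

to_xyz_mat <- function(x) {
  if (is.matrix(x) && ncol(x) == 3L) {
    storage.mode(x) <- "double"
    if (!all(is.finite(x))) stop("coordinates contain non-finite values")
    return(unname(x))
  }
  matrix(as_coord_vec(x), ncol = 3L, byrow = TRUE)
}

#' Least-squares fit every frame of an ensemble onto a reference frame
#'
#' Each frame is replaced by its optimal superposition onto the chosen
#' reference frame; the reference frame itself is returned unchanged.
#'
#' @param ensemble a [conf_ensemble()].
#' @param ref_frame 1-based index of the reference frame.
#' @return A [conf_ensemble()] with fitted coordinates.
#' @export
fit_all_to_reference <- function(ensemble, ref_frame) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  ref_frame <- as.integer(ref_frame)
  if (ref_frame < 1L || ref_frame > n_frames(ensemble))
    stop("ref_frame out of range")
  ref <- frame_coords(ensemble, ref_frame)
  out <- ensemble$xyz
  for (i in seq_len(n_frames(ensemble))) {
    if (i == ref_frame) next
    out[i, ] <- as_coord_vec(superpose(frame_coords(ensemble, i), ref)$fitted)
  }
  conf_ensemble(out, ensemble$n_atoms, frame_ids = ensemble$frame_ids,
                atom_labels = ensemble$atom_labels)
}

#' Pairwise RMSD matrix of an ensemble
#'
#' Builds the symmetric N x N matrix of RMSDs between all frame pairs,
#' either with per-pair optimal superposition (`mode = "pairwise_fit"`,
#' the default) or directly on the stored coordinates
#' (`mode = "prealigned"`, appropriate when the trajectory was already
#' least-squares aligned, or for abstract point-cloud data).
#'
#' @param ensemble a [conf_ensemble()].
#' @param mode `"pairwise_fit"` or `"prealigned"`.
#' @return An `rmsd_matrix`: a numeric matrix with attributes `mode` and
#'   `n_atoms`. Entries are nonnegative with a zero diagonal, and
#'   `pairwise_fit` entries never exceed the corresponding `prealigned`
#'   ones.
#' @examples
#' ens <- conf_ensemble(matrix(rnorm(5 * 9), nrow = 5), n_atoms = 3)
#' m <- pairwise_rmsd_matrix(ens)
#' all(m == t(m))
#' @export
pairwise_rmsd_matrix <- function(ensemble,
                                 mode = c("pairwise_fit", "prealigned")) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  mode <- match.arg(mode)
  if (!all(is.finite(ensemble$xyz))) stop("coords contain non-finite values")
  values <- if (mode == "prealigned") {
    as.matrix(stats::dist(ensemble$xyz)) / sqrt(ensemble$n_atoms)
  } else {
    pairwise_rmsd_fit_cpp(ensemble$xyz, ensemble$n_atoms)
  }
  rmsd_matrix(values, mode = mode, n_atoms = ensemble$n_atoms)
}

#' Construct (or validate) an RMSD matrix object
#'
#' @param values symmetric nonnegative numeric matrix with zero diagonal.
#' @param mode how the entries were obtained: `"pairwise_fit"` or
#'   `"prealigned"`.
#' @param n_atoms number of atoms behind each RMSD value (optional metadata).
#' @param tol tolerance for the symmetry/diagonal checks.
#' @return The matrix with class `rmsd_matrix` and attributes `mode`,
#'   `n_atoms`; the diagonal is forced to exact zero and the matrix to exact
#'   symmetry (upper triangle is authoritative).
#' @export
rmsd_matrix <- function(values, mode = c("pairwise_fit", "prealigned"),
                        n_atoms = NA_integer_, tol = 1e-8) {
  mode <- match.arg(mode)
  values <- unname(as.matrix(values))
  storage.mode(values) <- "double"
  if (nrow(values) != ncol(values)) stop("rmsd matrix must be square")
  if (any(!is.finite(values))) stop("rmsd matrix contains non-finite values")
  if (any(values < -tol)) stop("rmsd matrix contains negative entries")
  if (max(abs(values - t(values))) > tol) stop("rmsd matrix is not symmetric")
  if (max(abs(diag(values))) > tol) stop("rmsd matrix diagonal is not zero")
  values[lower.tri(values)] <- t(values)[lower.tri(values)]
  diag(values) <- 0
  values[values < 0] <- 0
  structure(values, mode = mode, n_atoms = as.integer(n_atoms),
            class = c("rmsd_matrix", "matrix", "array"))
}

#' @export
print.rmsd_matrix <- function(x, ...) {
  cat(sprintf("rmsd_matrix: %d x %d, mode = %s\n", nrow(x), ncol(x),
              attr(x, "mode")))
  if (nrow(x) <= 10L) {
    print(matrix(as.numeric(x), nrow(x)))
  } else {
    cat("  range:", format(range(x[upper.tri(x)])), "\n")
  }
  invisible(x)
}
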