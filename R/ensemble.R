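#' Configuration ensemble
#'
#' Container for N molecular configurations described by the Cartesian
#' coordinates of `n_atoms` atoms each (so every frame is a vector of
#' `3 * n_atoms` coordinates, atom-major: x1, y1, z1, x2, ...). Coordinates
#' are in nanometres.
#'
#' @param coords numeric matrix, one frame per row, `3 * n_atoms` columns.
#'   A single frame may be given as a vector or an `n_atoms x 3` matrix.
#' @param n_atoms number of atoms per frame; defaults to `ncol(coords) / 3`.
#' @param frame_ids integer frame labels, 0-based by convention; defaults to
#'   `0:(N - 1)`.
#' @param atom_labels optional data frame with one row per atom (columns such
#'   as `resno` and `elety`), carried along for reporting.
#'
#' @return An object of class `conf_ensemble`: a list with elements `xyz`
#'   (the N x 3n coordinate matrix), `n_atoms`, `frame_ids` and `atom_labels`.
#' @examples
#' ens <- conf_ensemble(matrix(rnorm(10 * 9), nrow = 10), n_atoms = 3)
#' n_frames(ens)
#' @export
conf_ensemble <- function(coords, n_atoms = NULL, frame_ids = NULL,
                          atom_labels = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (is.null(n_atoms)) {
    if (ncol(coords) %% 3L != 0L)
      stop("cannot infer n_atoms: number of coordinates is not a multiple of 3")
    n_atoms <- ncol(coords) %/% 3L
  }
  n_atoms <- as.integer(n_atoms)
  if (n_atoms < 1L) stop("n_atoms must be >= 1")
  if (ncol(coords) != 3L * n_atoms)
    stop("coords must have 3 * n_atoms = ", 3L * n_atoms, " columns, got ",
         ncol(coords))
  if (nrow(coords) < 1L) stop("ensemble must contain at least one frame")
  if (!all(is.finite(coords))) stop("coords contain non-finite values")
  if (is.null(frame_ids)) frame_ids <- seq_len(nrow(coords)) - 1L
  if (length(frame_ids) != nrow(coords))
    stop("frame_ids length must equal the number of frames")
  if (!is.null(atom_labels) && nrow(atom_labels) != n_atoms)
    stop("atom_labels must have one row per atom")
  structure(list(xyz = unname(coords), n_atoms = n_atoms,
                 frame_ids = as.integer(frame_ids), atom_labels = atom_labels),
            class = "conf_ensemble")
}

#' Number of frames in an ensemble
#' @param ensemble a [conf_ensemble()].
#' @return Integer frame count.
#' @export
n_frames <- function(ensemble) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  nrow(ensemble$xyz)
}

#' Extract one frame as an n_atoms x 3 coordinate matrix
#' @param ensemble a [conf_ensemble()].
#' @param i frame index (1-based).
#' @return `n_atoms` x 3 numeric matrix.
#' @export
frame_coords <- function(ensemble, i) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  if (i < 1L || i > n_frames(ensemble)) stop("frame index out of range")
  matrix(ensemble$xyz[i, ], ncol = 3L, byrow = TRUE)
}

#' Subset an ensemble by frame
#' @param ensemble a [conf_ensemble()].
#' @param frames 1-based frame indices to keep, in the requested order.
#' @return A [conf_ensemble()] with the selected frames.
#' @export
subset_frames <- function(ensemble, frames) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  frames <- as.integer(frames)
  if (length(frames) < 1L || any(frames < 1L | frames > n_frames(ensemble)))
    stop("frame indices out of range")
  conf_ensemble(ensemble$xyz[frames, , drop = FALSE], ensemble$n_atoms,
                frame_ids = ensemble$frame_ids[frames],
                atom_labels = ensemble$atom_labels)
}

#' @export
print.conf_ensemble <- function(x, ...) {
  cat(sprintf("conf_ensemble: %d frames, %d atoms (%d coordinates), nm\n",
              n_frames(x), x$n_atoms, ncol(x$xyz)))
  invisible(x)
}

# Accepts a frame given as a coordinate vector, a 1-row slice of an ensemble
# matrix, or an n_atoms x 3 matrix; returns the flat atom-major vector.
as_coord_vec <- function(x) {
  if (is.matrix(x) && ncol(x) == 3L) x <- t(x)
  x <- as.numeric(x)
  if (length(x) %% 3L != 0L)
    stop("coordinate length must be a multiple of 3")
  if (!all(is.finite(x))) stop("coordinates contain non-finite values")
  x
}
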