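#' Superpose trajectory frames on the iterative C-alpha mean structure
#'
#' Least-squares fits every frame onto a reference built iteratively: frames
#' are first fitted on the C-alpha coordinates of frame 1, the C-alpha mean
#' structure is recomputed, and fitting repeats until the mean structure moves
#' by less than `tol` (RMSD) or `max_iter` is reached.  Rigid-body drift must
#' be removed before fluctuation correlations are computed, otherwise global
#' rotation/translation shows up as spurious long-range correlation.
#'
#' @param traj A trajectory with at least 3 C-alpha atoms.
#' @param max_iter Maximum mean-refinement iterations.
#' @param tol Convergence threshold on the mean-structure RMSD change, in
#'   Angstrom.
#' @return The superposed trajectory (flagged `superposed = TRUE`).
#' @export
superpose <- function(traj, max_iter = 10L, tol = 1e-4) {
  stopifnot(inherits(traj, "traj"))
  assert_scalar_number(max_iter, "max_iter", min = 1)
  assert_scalar_number(tol, "tol", min = 0)
  ca <- traj$residues$calpha
  if (length(ca) < 3L) {
    abort_allopath(
      "Superposition needs at least 3 C-alpha atoms (rotation otherwise underdetermined).",
      "fit_error"
    )
  }
  arr <- xyz_to_array(traj$xyz)
  ref <- arr[1L, ca, , drop = TRUE]
  ref <- sweep(ref, 2L, colMeans(ref))
  for (iter in seq_len(max_iter)) {
    arr <- kabsch_fit_frames(arr, ca, ref)
    new_ref <- apply(arr[, ca, , drop = FALSE], c(2L, 3L), mean)
    delta <- sqrt(mean(rowSums((new_ref - ref)^2)))
    ref <- new_ref
    if (delta < tol) break
  }
  out <- traj
  out$xyz <- array_to_xyz(arr)
  out$superposed <- TRUE
  out
}

# Fit every frame of arr [frame, atom, axis] onto ref (n_ca x 3, centred),
# rotating/translating all atoms using the C-alpha subset for the fit.
kabsch_fit_frames <- function(arr, ca, ref) {
  nf <- dim(arr)[1L]
  cent <- apply(arr[, ca, , drop = FALSE], c(1L, 3L), mean) # nf x 3
  for (a in 1:3) arr[, , a] <- arr[, , a] - cent[, a]
  m <- array(0, c(nf, 3L, 3L))
  for (a in 1:3) m[, a, ] <- arr[, ca, a] %*% ref
  for (f in seq_len(nf)) {
    s <- svd(matrix(m[f, , ], 3L, 3L))
    d <- sign(det(s$v %*% t(s$u)))
    if (d == 0) d <- 1
    rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    arr[f, , ] <- arr[f, , ] %*% t(rot)
  }
  arr
}

# Total C-alpha variance about the mean structure; superposition must never
# increase it (tested property).
total_ca_variance <- function(traj) {
  ca <- traj$residues$calpha
  x <- traj$xyz[, atom_cols(ca), drop = FALSE]
  sum(apply(x, 2L, stats::var))
}
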