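#' Define a spherical source/sink region around an anchor residue
#'
#' A sphere of radius `radius` is centred on the anchor's C-alpha in every
#' frame; residues whose C-alpha stays inside the sphere (strictly closer than
#' `radius`) for at least `occupancy` of the trajectory are members.  The
#' anchor is always a member.
#'
#' @param traj A trajectory.
#' @param anchor Residue key ("chain:resno").
#' @param radius Sphere radius in Angstrom (default 6.0).
#' @param occupancy Minimum fraction of frames inside the sphere (default
#'   0.75, inclusive).
#' @return An object of class `region` with `anchor`, `members`, `radius`,
#'   `occupancy` and the anchor's subunit label.
#' @export
define_region <- function(traj, anchor, radius = 6.0, occupancy = 0.75) {
  stopifnot(inherits(traj, "traj"))
  assert_scalar_number(radius, "radius", min = 1e-8)
  assert_scalar_number(occupancy, "occupancy", min = 0, max = 1)
  res <- traj$residues
  ai <- match(anchor, res$key)
  if (is.na(ai)) {
    abort_allopath(sprintf("Unknown anchor residue: %s", anchor), "lookup_error")
  }
  frac <- vapply(seq_len(nrow(res)), function(r) {
    mean(atom_pair_distance(traj$xyz, res$calpha[ai], res$calpha[r]) < radius)
  }, numeric(1L))
  members <- res$key[frac >= occupancy]
  members <- union(anchor, members)
  new_region(anchor, members, radius, occupancy, res$subunit[ai])
}

new_region <- function(anchor, members, radius, occupancy, subunit = NA_character_) {
  structure(
    list(anchor = anchor, members = members, radius = radius,
         occupancy = occupancy, subunit = subunit),
    class = "region"
  )
}

region_members <- function(x) {
  if (inherits(x, "region")) x$members else as.character(x)
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf(
    "<region> anchor %s, radius %.1f A, %d member(s): %s\n",
    x$anchor, x$radius, length(x$members), paste(x$members, collapse = ", ")
  ))
  invisible(x)
}
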