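#' Define the subunit map of an oligomer
#'
#' In a domain-swapped tetramer each subunit's voltage-sensor domain packs
#' against the pore domain of the *neighboring* subunit, so pathway searches
#' need to know both the cyclic order of subunits and the neighbor relation
#' (which subunit's selectivity filter a given subunit's sensor talks to).
#'
#' @param chains Named character vector mapping chain identifiers to subunit
#'   labels, e.g. `c(A = "A", B = "B", C = "C", D = "D")`.
#' @param neighbor Named character vector giving, for each subunit label, the
#'   subunit whose pore domain it contacts, e.g. `c(A = "B", B = "C", C = "D",
#'   D = "A")`.  Must be a bijection with no fixed points.
#' @param order Cyclic order of the subunit labels; defaults to the order of
#'   `neighbor`.
#' @return An object of class `subunit_map`.
#' @export
subunit_map <- function(chains, neighbor, order = names(neighbor)) {
  if (is.null(names(chains)) || any(names(chains) == "")) {
    abort_allopath("`chains` must be a named vector (chain -> subunit label).", "config_error")
  }
  labels <- unique(unname(chains))
  if (is.null(names(neighbor)) || !setequal(names(neighbor), labels) ||
      !setequal(unname(neighbor), labels)) {
    abort_allopath(
      "`neighbor` must map every subunit label onto the set of subunit labels.",
      "config_error"
    )
  }
  if (anyDuplicated(unname(neighbor)) > 0L) {
    abort_allopath("Neighbor relation is not a bijection (duplicate targets).", "config_error")
  }
  if (length(labels) > 1L && any(neighbor[names(neighbor)] == names(neighbor))) {
    abort_allopath("Neighbor relation has fixed points (a subunit cannot neighbor itself).", "config_error")
  }
  if (!setequal(order, labels)) {
    abort_allopath("`order` must be a permutation of the subunit labels.", "config_error")
  }
  structure(
    list(chains = chains, neighbor = neighbor, order = order),
    class = "subunit_map"
  )
}

#' Assign subunit labels to trajectory residues
#'
#' @param traj A trajectory.
#' @param smap A [subunit_map()]; every chain in the residue table must appear
#'   in its `chains` mapping.
#' @return The trajectory with the residue table's `subunit` column filled and
#'   the map stored as `traj$subunits`.
#' @export
assign_subunits <- function(traj, smap) {
  stopifnot(inherits(traj, "traj"), inherits(smap, "subunit_map"))
  chains <- unique(traj$residues$chain)
  unmapped <- setdiff(chains, names(smap$chains))
  if (length(unmapped) > 0L) {
    abort_allopath(
      paste0("Chains not present in the subunit map: ", paste(unmapped, collapse = ", ")),
      "config_error"
    )
  }
  traj$residues$subunit <- unname(smap$chains[traj$residues$chain])
  traj$subunits <- smap
  traj
}

# Chain id carrying a given subunit label (inverse of smap$chains).
subunit_chain <- function(smap, label) {
  ch <- names(smap$chains)[smap$chains == label]
  if (length(ch) != 1L) {
    abort_allopath(sprintf("Subunit label %s maps to %d chains.", label, length(ch)), "config_error")
  }
  ch
}

#' @export
print.subunit_map <- function(x, ...) {
  cat("<subunit_map>", length(x$order), "subunits:",
      paste(x$order, collapse = " -> "), "\n")
  cat("  neighbor:", paste(sprintf("%s->%s", names(x$neighbor), x$neighbor), collapse = ", "), "\n")
  invisible(x)
}
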