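#' Contact probability of a residue pair
#'
#' Two residues are in contact in a frame when any pair of their side-chain
#' heavy atoms lies closer than `cutoff` (strictly); glycine, having no
#' side-chain heavy atoms, is represented by its C-alpha.  The probability is
#' the fraction of frames in contact.
#'
#' @param traj A trajectory.
#' @param res_i,res_j Residue keys ("chain:resno").
#' @param cutoff Distance cutoff in Angstrom (default 5.0).
#' @return A fraction in \[0, 1\].
#' @export
contact_probability <- function(traj, res_i, res_j, cutoff = 5.0) {
  stopifnot(inherits(traj, "traj"))
  assert_scalar_number(cutoff, "cutoff", min = 1e-8)
  idx <- match(c(res_i, res_j), traj$residues$key)
  if (anyNA(idx)) {
    abort_allopath(
      paste0("Unknown residue key(s): ", paste(c(res_i, res_j)[is.na(idx)], collapse = ", ")),
      "lookup_error"
    )
  }
  ai <- traj$residues$contact_atoms[[idx[1L]]]
  aj <- traj$residues$contact_atoms[[idx[2L]]]
  mean(min_pair_distance(traj$xyz, ai, aj) < cutoff)
}

# Per-frame minimum distance between two atom sets.
min_pair_distance <- function(xyz, atoms_i, atoms_j) {
  mind <- rep(Inf, nrow(xyz))
  for (a in atoms_i) {
    for (b in atoms_j) {
      mind <- pmin(mind, atom_pair_distance(xyz, a, b))
    }
  }
  mind
}

#' Persistent-contact map of a trajectory
#'
#' Computes, for every residue pair, the fraction of frames in which the
#' side-chain heavy atoms approach within `cutoff`, and marks pairs that stay
#' in contact for at least `occupancy` of the trajectory (inclusive
#' threshold).  A C-alpha distance bound prunes pairs that can never touch, so
#' only nearby pairs pay the atom-level scan; the result is identical to the
#' exhaustive all-pairs computation.
#'
#' @param traj A trajectory.
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 5.0).
#' @param occupancy Minimum in-contact fraction of frames (default 0.75).  A
#'   pair never observed in contact is never marked, so `occupancy = 0` marks
#'   exactly the pairs that ever touch.
#' @return An object of class `contact_map` with elements `probability`
#'   (symmetric matrix), `contact` (logical matrix, diagonal `FALSE`),
#'   `cutoff`, `occupancy` and the residue table.
#' @export
contact_map <- function(traj, cutoff = 5.0, occupancy = 0.75) {
  stopifnot(inherits(traj, "traj"))
  assert_scalar_number(cutoff, "cutoff", min = 1e-8)
  assert_scalar_number(occupancy, "occupancy", min = 0, max = 1)
  res <- traj$residues
  n <- nrow(res)
  keys <- res$key
  # Per-residue, per-frame radius of the contact-atom set about the C-alpha;
  # d_CA - r_i - r_j lower-bounds the minimum atom-pair distance.
  radius <- matrix(0, traj$n_frames, n)
  for (r in seq_len(n)) {
    extra <- setdiff(res$contact_atoms[[r]], res$calpha[r])
    if (length(extra) > 0L) {
      radius[, r] <- min_pair_distance_max(traj$xyz, res$calpha[r], extra)
    }
  }
  prob <- matrix(0, n, n, dimnames = list(keys, keys))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      dca <- atom_pair_distance(traj$xyz, res$calpha[i], res$calpha[j])
      bound <- dca - radius[, i] - radius[, j]
      candidate <- bound < cutoff
      if (!any(candidate)) next
      if (all(radius[, i] == 0) && all(radius[, j] == 0)) {
        p <- mean(dca < cutoff)
      } else {
        hits <- candidate
        sub <- which(candidate)
        mind <- min_pair_distance(
          traj$xyz[sub, , drop = FALSE],
          res$contact_atoms[[i]], res$contact_atoms[[j]]
        )
        hits[sub] <- mind < cutoff
        hits[!candidate] <- FALSE
        p <- mean(hits)
      }
      prob[i, j] <- p
      prob[j, i] <- p
    }
  }
  structure(
    list(
      probability = prob,
      contact = prob >= occupancy & prob > 0 & !diag(TRUE, n),
      cutoff = cutoff,
      occupancy = occupancy,
      atom_rule = "side-chain heavy atoms (C-alpha surrogate for glycine)",
      residues = res
    ),
    class = "contact_map"
  )
}

# Per-frame maximum distance from one atom to a set (used for the radius bound).
min_pair_distance_max <- function(xyz, atom, atoms) {
  maxd <- rep(0, nrow(xyz))
  for (b in atoms) maxd <- pmax(maxd, atom_pair_distance(xyz, atom, b))
  maxd
}

#' Single-subunit consensus contact map
#'
#' Folds a whole-protein contact map onto one subunit's residue coordinates:
#' a pair of residue positions is a consensus contact when the corresponding
#' pair is a contact in at least `min_subunits` subunits.  Intra-subunit pairs
#' are compared directly; inter-subunit pairs are mapped through the
#' domain-swap neighbor relation, so swap-interface contacts appear in the
#' single-subunit map.
#'
#' @param cmap A [contact_map()] whose residues carry subunit labels.
#' @param smap The [subunit_map()].
#' @param min_subunits Minimum number of subunits in which the contact must be
#'   formed (default 3, i.e. 3 of 4 for a tetramer).
#' @return An object of class `consensus_map` with the consensus logical
#'   matrix, the per-pair subunit counts, and the within-subunit residue
#'   numbering.
#' @export
subunit_consensus <- function(cmap, smap, min_subunits = 3L) {
  stopifnot(inherits(cmap, "contact_map"), inherits(smap, "subunit_map"))
  min_subunits <- as.integer(assert_scalar_number(min_subunits, "min_subunits", min = 1))
  res <- cmap$residues
  res$subunit <- unname(smap$chains[res$chain])
  labs <- smap$order
  resno_sets <- lapply(labs, function(s) sort(res$resno[res$subunit == s]))
  ref <- resno_sets[[1L]]
  same <- vapply(resno_sets, function(x) identical(x, ref), logical(1L))
  if (!all(same) || length(ref) == 0L) {
    abort_allopath(
      "Subunits do not share a common residue numbering; cannot build a consensus map.",
      "mapping_error"
    )
  }
  m <- length(ref)
  counts <- matrix(0L, m, m, dimnames = list(ref, ref))
  cm <- cmap$contact
  key_of <- function(lab, resno) residue_key(subunit_chain(smap, lab), resno)
  for (lab in labs) {
    nbr <- smap$neighbor[[lab]]
    own <- key_of(lab, ref)
    nb <- key_of(nbr, ref)
    hit <- cm[own, own, drop = FALSE] |
      cm[own, nb, drop = FALSE] |
      t(cm[own, nb, drop = FALSE])
    counts <- counts + (hit | t(hit))
  }
  consensus <- counts >= min_subunits
  diag(consensus) <- FALSE
  structure(
    list(
      consensus = consensus,
      counts = counts,
      min_subunits = min_subunits,
      n_subunits = length(labs),
      resno = ref,
      cutoff = cmap$cutoff,
      occupancy = cmap$occupancy
    ),
    class = "consensus_map"
  )
}

#' @export
print.contact_map <- function(x, ...) {
  n <- nrow(x$probability)
  cat(sprintf(
    "<contact_map> %d residues, %d contacts (cutoff %.1f A, occupancy >= %.2f)\n",
    n, sum(x$contact[upper.tri(x$contact)]), x$cutoff, x$occupancy
  ))
  invisible(x)
}

#' @export
print.consensus_map <- function(x, ...) {
  cat(sprintf(
    "<consensus_map> %d positions, %d consensus contacts (>= %d of %d subunits)\n",
    length(x$resno), sum(x$consensus[upper.tri(x$consensus)]),
    x$min_subunits, x$n_subunits
  ))
  invisible(x)
}
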