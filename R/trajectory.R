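#' Construct a trajectory object
#'
#' A trajectory holds per-frame coordinates (in Angstrom) for a fixed set of
#' heavy atoms together with a residue table mapping each residue to its
#' C-alpha atom and its side-chain heavy atoms.  Most users will obtain one
#' from [read_trajectory()] or [sample_frames()]; this constructor is exposed
#' so fixtures can be built programmatically.
#'
#' @param xyz Numeric matrix, one frame per row, columns `x1,y1,z1,x2,...`
#'   (bio3d layout), coordinates in Angstrom.
#' @param atoms A data frame with one row per atom and columns `elety` (atom
#'   name, e.g. "CA"), `chain`, `resno`, `resname` (3-letter code).
#' @param superposed Logical flag; set by [superpose()].
#' @return An object of class `traj` with elements `xyz`, `atoms`, `residues`
#'   (see [residue_table()]), `n_frames`, `superposed`.
#' @export
new_trajectory <- function(xyz, atoms, superposed = FALSE) {
  atoms <- tibble::as_tibble(atoms)
  required <- c("elety", "chain", "resno", "resname")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0L) {
    abort_allopath(
      paste0("`atoms` is missing columns: ", paste(missing, collapse = ", ")),
      "argument_error"
    )
  }
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  storage.mode(xyz) <- "double"
  if (nrow(xyz) < 2L) {
    abort_allopath(
      "A trajectory needs at least 2 frames (single structures carry no fluctuations).",
      "input_error"
    )
  }
  if (ncol(xyz) != 3L * nrow(atoms)) {
    abort_allopath(
      sprintf(
        "Coordinate columns (%d) do not match 3 x atom count (%d).",
        ncol(xyz), 3L * nrow(atoms)
      ),
      "consistency_error"
    )
  }
  if (!all(is.finite(xyz))) {
    abort_allopath("Trajectory coordinates contain non-finite values.", "input_error")
  }
  traj <- structure(
    list(
      xyz = unname(xyz),
      atoms = atoms,
      residues = build_residue_table(atoms),
      n_frames = nrow(xyz),
      superposed = isTRUE(superposed),
      subunits = NULL
    ),
    class = "traj"
  )
  check_units(traj)
  traj
}

# Backbone heavy atoms excluded from the side-chain set; glycine (no side
# chain) falls back to its C-alpha so the contact rule stays defined.
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

build_residue_table <- function(atoms) {
  atoms$.idx <- seq_len(nrow(atoms))
  res <- atoms |>
    dplyr::group_by(.data$chain, .data$resno) |>
    dplyr::summarise(
      resname = .data$resname[1L],
      calpha = list(.data$.idx[.data$elety == "CA"]),
      sidechain = list(.data$.idx[!(.data$elety %in% BACKBONE_ATOMS)]),
      .groups = "drop"
    ) |>
    dplyr::mutate(key = residue_key(.data$chain, .data$resno), .before = 1L)
  n_ca <- lengths(res$calpha)
  if (any(n_ca != 1L)) {
    bad <- res$key[n_ca != 1L]
    abort_allopath(
      paste0(
        "Each residue must have exactly one C-alpha atom; offending residues: ",
        paste(utils::head(bad, 5L), collapse = ", ")
      ),
      "consistency_error"
    )
  }
  if (anyDuplicated(res$key) > 0L) {
    abort_allopath("Residue keys (chain:resno) are not unique.", "consistency_error")
  }
  res$calpha <- as.integer(unlist(res$calpha))
  # Glycine surrogate: residues with no side-chain heavy atoms use C-alpha.
  res$contact_atoms <- purrr::map2(res$sidechain, res$calpha, function(sc, ca) {
    if (length(sc) == 0L) ca else sc
  })
  res$subunit <- NA_character_
  res[, c("key", "chain", "resno", "resname", "calpha", "sidechain",
          "contact_atoms", "subunit")]
}

# Coordinates in nm would make consecutive C-alpha spacings ~0.38 instead of
# ~3.8 Angstrom; reject such inputs with a clear message.
check_units <- function(traj) {
  res <- traj$residues
  d <- c()
  for (ch in unique(res$chain)) {
    sub <- res[res$chain == ch, ]
    sub <- sub[order(sub$resno), ]
    consec <- which(diff(sub$resno) == 1L)
    for (k in consec) {
      d <- c(d, atom_pair_distance(
        traj$xyz[1L, , drop = FALSE],
        sub$calpha[k], sub$calpha[k + 1L]
      ))
    }
  }
  if (length(d) >= 3L && stats::median(d) < 1.0) {
    abort_allopath(
      "Consecutive C-alpha spacing < 1; coordinates look like nm, but Angstrom is required.",
      "input_error"
    )
  }
  invisible(traj)
}

#' Read a molecular trajectory
#'
#' Reads a multi-model PDB, or a DCD trajectory together with a PDB topology,
#' keeps protein heavy atoms, and builds the residue table used by all
#' downstream analyses.  Coordinates are taken as Angstrom; inputs that look
#' like nm are rejected.
#'
#' @param file Path to a multi-model PDB or a DCD file.
#' @param topology Path to a PDB topology; required for DCD input.
#' @param stride Keep every `stride`-th frame (default 1, all frames).
#' @return A [new_trajectory()] object.
#' @examples
#' topo <- build_toy_tetramer(10)
#' traj <- sample_frames(topo, n_frames = 10, seed = 1)
#' f <- tempfile(fileext = ".pdb")
#' write_trajectory_pdb(traj, f)
#' read_trajectory(f)
#' @export
read_trajectory <- function(file, topology = NULL, stride = 1L) {
  if (!file.exists(file)) {
    abort_allopath(sprintf("File not found: %s", file), "input_error")
  }
  stride <- as.integer(assert_scalar_number(stride, "stride", min = 1))
  ext <- tolower(tools::file_ext(file))
  if (ext == "xtc") {
    abort_allopath(
      "XTC input is not supported; convert to DCD or multi-model PDB first.",
      "format_error"
    )
  }
  if (ext == "dcd") {
    if (is.null(topology)) {
      abort_allopath("DCD input requires a PDB `topology`.", "input_error")
    }
    pdb <- read_pdb_checked(topology)
    xyz <- tryCatch(
      bio3d::read.dcd(file, verbose = FALSE),
      error = function(e) abort_allopath(
        sprintf("Could not read DCD file %s: %s", file, conditionMessage(e)),
        "format_error"
      )
    )
    xyz <- unclass(xyz)
    if (ncol(xyz) != 3L * nrow(pdb$atom)) {
      abort_allopath(
        sprintf(
          "DCD atom count (%d) does not match topology atom count (%d).",
          ncol(xyz) / 3L, nrow(pdb$atom)
        ),
        "consistency_error"
      )
    }
  } else {
    pdb <- read_pdb_checked(file, multi = TRUE)
    xyz <- unclass(pdb$xyz)
    if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  }
  sel <- select_protein_heavy(pdb)
  if (length(sel) == 0L) {
    abort_allopath("Atom selection matched zero atoms.", "selection_error")
  }
  xyz <- xyz[seq(1L, nrow(xyz), by = stride), atom_cols(sel), drop = FALSE]
  atoms <- tibble::as_tibble(pdb$atom[sel, c("elety", "chain", "resno", "resid")])
  names(atoms)[names(atoms) == "resid"] <- "resname"
  atoms$chain[is.na(atoms$chain)] <- "A"
  new_trajectory(xyz, atoms)
}

read_pdb_checked <- function(file, multi = FALSE) {
  tryCatch(
    bio3d::read.pdb(file, multi = multi, verbose = FALSE),
    error = function(e) abort_allopath(
      sprintf("Could not read PDB file %s: %s", file, conditionMessage(e)),
      "format_error"
    )
  )
}

select_protein_heavy <- function(pdb) {
  prot <- bio3d::atom.select(pdb, "protein", verbose = FALSE)
  noh <- bio3d::atom.select(pdb, "noh", verbose = FALSE)
  intersect(prot$atom, noh$atom)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj A trajectory.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, file) {
  bio3d::write.pdb(
    file = file,
    xyz = traj$xyz,
    elety = traj$atoms$elety,
    chain = traj$atoms$chain,
    resno = traj$atoms$resno,
    resid = traj$atoms$resname
  )
  invisible(file)
}

#' Residue table of a trajectory
#'
#' One row per residue: `key` ("chain:resno"), `chain`, `resno`, `resname`,
#' C-alpha atom index, side-chain heavy-atom indices (empty for glycine, which
#' uses its C-alpha as contact surrogate), and the `subunit` label once
#' [assign_subunits()] has run.
#'
#' @param traj A trajectory.
#' @return A tibble.
#' @export
residue_table <- function(traj) {
  stopifnot(inherits(traj, "traj"))
  traj$residues
}

#' @export
print.traj <- function(x, ...) {
  cat(sprintf(
    "<trajectory> %d frames, %d atoms, %d residues, %d chain(s)%s%s\n",
    x$n_frames, nrow(x$atoms), nrow(x$residues),
    length(unique(x$residues$chain)),
    if (x$superposed) ", superposed" else "",
    if (!is.null(x$subunits)) ", subunits assigned" else ""
  ))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A trajectory.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) traj$n_frames

# C-alpha coordinates of one frame as an n_res x 3 matrix.
ca_frame <- function(traj, frame) {
  matrix(traj$xyz[frame, atom_cols(traj$residues$calpha)], ncol = 3L, byrow = TRUE)
}

# Per-frame coordinates of one atom across the trajectory, n_frames x 3.
atom_track <- function(traj, atom) traj$xyz[, atom_cols(atom), drop = FALSE]
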