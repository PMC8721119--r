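#' Build a four-fold symmetric bead-spring toy tetramer
#'
#' Constructs a coarse bead model that mimics the architecture of a
#' domain-swapped voltage-gated channel: four identical subunits (chains
#' A-D) arranged with exact C4 symmetry about the z axis, each carrying an
#' "S4" sensor segment, an "S5" and an "S6" pore segment, and an "SF"
#' filter segment near the axis.  The S4 segment of each subunit leans
#' toward, and only touches, the S5 segment of the *neighboring* subunit
#' (A's sensor contacts B's pore, and so on), reproducing the swap
#' interface that inter-subunit pathways must cross.  Beads within
#' `spring_cutoff` of one another are joined by harmonic springs of
#' constant `spring_k`, defining a Gaussian-network model whose
#' displacement covariance - and hence every pairwise correlation - is
#' known analytically (see [analytic_correlations()]).
#'
#' Geometry constants (bead spacing 3.5-4.3 A, cutoff 7 A) are chosen so
#' that consecutive beads and the designed interfaces sit well inside the
#' 5 A contact cutoff while all other inter-segment distances stay well
#' outside it, and so that the default 6 A source sphere around the S4
#' anchor contains only sensor beads.
#'
#' @param n_res_per_subunit Beads per subunit (>= 8; default 12).
#' @param spring_cutoff Spring (Kirchhoff) cutoff in Angstrom.
#' @param spring_k Baseline spring constant (arbitrary units).
#' @return An object of class `bead_topology`: reference coordinates `xyz`
#'   (n x 3), a residue tibble (`key`, `chain`, `resno`, `segment`), the
#'   spring table (`i`, `j`, `k`), anchor residue numbers (`anchors$s4`,
#'   `$sf`, `$s6`), and the chain/neighbor maps of the tetramer.
#' @export
build_toy_tetramer <- function(n_res_per_subunit = 12L, spring_cutoff = 7.0,
                               spring_k = 1.0) {
  n <- as.integer(assert_scalar_number(n_res_per_subunit, "n_res_per_subunit", min = 8))
  assert_scalar_number(spring_cutoff, "spring_cutoff", min = 1e-8)
  assert_scalar_number(spring_k, "spring_k", min = 1e-12)
  n4 <- max(2L, as.integer(round(0.25 * n)))
  n5 <- n4
  nsf <- max(2L, as.integer(round(0.15 * n)))
  n6 <- n - n4 - n5 - nsf
  if (n6 < 2L) {
    abort_allopath("n_res_per_subunit too small to allocate all four segments.", "argument_error")
  }
  z_top5 <- 3.5 * (n5 - 1L)
  segment_xyz <- function(theta) {
    deg <- pi / 180
    cyl <- function(r, ang, z) c(r * cos(ang), r * sin(ang), z)
    rows <- list()
    for (i in seq_len(n4)) {                      # S4: tilted, outer, swap-leaning
      rows <- c(rows, list(cyl(13 + 2.5 * (n4 - i), theta + 90 * deg, 3.5 * (i - 1L))))
    }
    for (i in seq_len(n5)) {                      # S5: outer pore helix
      rows <- c(rows, list(cyl(9, theta, 3.5 * (i - 1L))))
    }
    for (i in seq_len(nsf)) {                     # SF: filter, near axis, top
      rows <- c(rows, list(cyl(6, theta, z_top5 + 3 + 3.8 * (i - 1L))))
    }
    for (i in seq_len(n6)) {                      # S6: inner ring, descending;
      # radius 4.9 puts adjacent subunits' S6 beads within the spring cutoff
      # (joining the four pore domains) but beyond the 5 A contact cutoff
      rows <- c(rows, list(cyl(4.9, theta + 45 * deg, z_top5 + 1 - 4 * (i - 1L))))
    }
    do.call(rbind, rows)
  }
  chains <- c("A", "B", "C", "D")
  xyz <- do.call(rbind, lapply(0:3, function(s) segment_xyz(s * pi / 2)))
  segments <- rep(c(rep("S4", n4), rep("S5", n5), rep("SF", nsf), rep("S6", n6)), 4L)
  residues <- tibble::tibble(
    chain = rep(chains, each = n),
    resno = rep(seq_len(n), 4L),
    segment = segments
  )
  residues$key <- residue_key(residues$chain, residues$resno)
  d <- as.matrix(stats::dist(xyz))
  sel <- which(d <= spring_cutoff & upper.tri(d), arr.ind = TRUE)
  springs <- tibble::tibble(i = sel[, 1L], j = sel[, 2L], k = spring_k)
  topo <- structure(
    list(
      xyz = xyz,
      residues = residues[, c("key", "chain", "resno", "segment")],
      springs = springs,
      spring_cutoff = spring_cutoff,
      spring_k = spring_k,
      n_per_subunit = n,
      segment_sizes = c(S4 = n4, S5 = n5, SF = nsf, S6 = n6),
      anchors = list(s4 = 1L, sf = n4 + n5 + 1L, s6 = n),
      chains = stats::setNames(chains, chains),
      neighbor = c(A = "B", B = "C", C = "D", D = "A"),
      planted = NULL
    ),
    class = "bead_topology"
  )
  check_spring_connectivity(topo)
  topo
}

check_spring_connectivity <- function(topo) {
  g <- igraph::graph_from_edgelist(as.matrix(topo$springs[, c("i", "j")]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(topo$xyz) - igraph::vcount(g)))
  if (igraph::components(g)$no != 1L) {
    abort_allopath(
      "Spring graph is disconnected; the displacement covariance would be block-degenerate.",
      "degenerate_error"
    )
  }
  invisible(topo)
}

#' Plant (or re-tune) a high-correlation inter-subunit pathway
#'
#' Scales the spring constants along the canonical sensor-to-filter chain of
#' every subunit - up its S4 beads, across the swap interface to the
#' neighboring subunit's S5 top bead, and on to that subunit's first SF
#' bead - by `boost`.  Boosting (`boost > 1`) raises the correlations along
#' the chain, planting it as the dominant communication route; values below
#' the current boost weaken it, emulating a mutation that degrades the
#' coupling.
#'
#' @param topo A [build_toy_tetramer()] topology.
#' @param boost Multiplier applied to the baseline spring constant along the
#'   planted chain (default 8).
#' @return The topology with boosted springs and the planted chains recorded
#'   in `topo$planted`.
#' @export
plant_pathway <- function(topo, boost = 8) {
  stopifnot(inherits(topo, "bead_topology"))
  assert_scalar_number(boost, "boost", min = 1e-12)
  n4 <- topo$segment_sizes[["S4"]]
  n5 <- topo$segment_sizes[["S5"]]
  chains <- names(topo$chains)
  idx_of <- function(chain, resno) {
    which(topo$residues$chain == chain & topo$residues$resno == resno)
  }
  chains_list <- list()
  springs <- topo$springs
  for (s in seq_along(chains)) {
    ch <- chains[s]
    nbr <- topo$neighbor[[ch]]
    beads <- c(
      vapply(seq_len(n4), function(i) idx_of(ch, i), integer(1L)),
      idx_of(nbr, n4 + n5),       # neighbor S5 top bead (swap interface)
      idx_of(nbr, n4 + n5 + 1L)   # neighbor first SF bead
    )
    for (e in seq_len(length(beads) - 1L)) {
      a <- min(beads[e], beads[e + 1L])
      b <- max(beads[e], beads[e + 1L])
      hit <- springs$i == a & springs$j == b
      if (!any(hit)) {
        abort_allopath(
          "Planted chain is not connected in the spring graph; increase spring_cutoff.",
          "construction_error"
        )
      }
      springs$k[hit] <- topo$spring_k * boost
    }
    chains_list[[ch]] <- topo$residues$key[beads]
  }
  topo$springs <- springs
  topo$planted <- list(boost = boost, chains = chains_list)
  topo
}

#' Expected pathway segment recovered between the default toy regions
#'
#' With the default 6 A region spheres, the source region around the S4
#' anchor contains the two lowest S4 beads, and the sink region around the
#' neighbor's first SF bead reaches back to that subunit's S5 top bead; the
#' minimum-weight route between the regions is therefore the planted chain
#' from the second S4 bead up and across the swap interface, ending at the
#' neighbor's S5 top bead.  Exposed so tests and examples can state the
#' expected result of a planted-path recovery run without re-deriving the
#' geometry.
#'
#' @param topo A toy topology.
#' @param subunit Subunit label whose sensor starts the path.
#' @return Character vector of residue keys.
#' @export
toy_expected_vsd_path <- function(topo, subunit) {
  stopifnot(inherits(topo, "bead_topology"))
  n4 <- topo$segment_sizes[["S4"]]
  n5 <- topo$segment_sizes[["S5"]]
  ch <- subunit_chain_topo(topo, subunit)
  nbr <- topo$neighbor[[ch]]
  c(residue_key(ch, seq(2L, n4)), residue_key(nbr, n4 + n5))
}

subunit_chain_topo <- function(topo, label) {
  ch <- names(topo$chains)[topo$chains == label]
  if (length(ch) != 1L) abort_allopath("Unknown subunit label.", "argument_error")
  ch
}

# Kirchhoff (connectivity) matrix with per-pair spring constants.
kirchhoff_matrix <- function(topo) {
  n <- nrow(topo$xyz)
  g <- matrix(0, n, n)
  for (r in seq_len(nrow(topo$springs))) {
    i <- topo$springs$i[r]
    j <- topo$springs$j[r]
    k <- topo$springs$k[r]
    g[i, j] <- g[i, j] - k
    g[j, i] <- g[j, i] - k
  }
  diag(g) <- -rowSums(g)
  g
}

# Pseudo-inverse of the Kirchhoff matrix (zero translational mode dropped),
# with the rigid-body subspace projected out and the result averaged over the
# cyclic subunit permutations that are exact symmetries of the spring network.
#
# The projection removes the per-axis span of {1, x_ref, y_ref, z_ref}: with
# isotropic per-axis sampling this zeroes the linearised net translation and
# rotation of every frame, so the covariance describes internal fluctuations
# exactly as a superposed trajectory exposes them.  Without it, the soft
# (rotation-like) modes of the spring network would be partially absorbed by
# the least-squares fit and the estimated correlations would be biased away
# from the analytic ones.
gnm_covariance <- function(topo) {
  gamma <- kirchhoff_matrix(topo)
  check_spring_connectivity(topo)
  e <- eigen(gamma, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-10
  if (sum(!keep) != 1L) {
    abort_allopath(
      "Kirchhoff matrix has unexpected null space; spring graph may be degenerate.",
      "degenerate_error"
    )
  }
  ginv <- e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
  rigid <- cbind(1, sweep(topo$xyz, 2L, colMeans(topo$xyz)))
  q <- qr.Q(qr(rigid))
  ginv <- ginv - q %*% crossprod(q, ginv)
  ginv <- ginv - ginv %*% q %*% t(q)
  ginv <- (ginv + t(ginv)) / 2
  perm <- cyclic_subunit_permutation(topo)
  if (!is.null(perm)) {
    perms <- list(seq_len(nrow(gamma)))
    p <- perm
    for (step in 1:3) {
      if (max(abs(gamma - gamma[p, p])) < 1e-9) perms <- c(perms, list(p))
      p <- perm[p]
    }
    ginv <- Reduce(`+`, lapply(perms, function(q) ginv[q, q])) / length(perms)
  }
  ginv
}

# Permutation sending each bead to its image in the next subunit, or NULL if
# the chains do not share a residue numbering.
cyclic_subunit_permutation <- function(topo) {
  res <- topo$residues
  chains <- names(topo$chains)
  if (length(chains) != 4L) return(NULL)
  nxt <- topo$neighbor
  perm <- integer(nrow(res))
  for (r in seq_len(nrow(res))) {
    target <- which(res$chain == nxt[[res$chain[r]]] & res$resno == res$resno[r])
    if (length(target) != 1L) return(NULL)
    perm[r] <- target
  }
  perm
}

#' Analytic correlation matrix of a bead-spring topology
#'
#' In a Gaussian-network model the displacement covariance is proportional to
#' the pseudo-inverse of the Kirchhoff matrix, so the position correlation of
#' beads i and j is \eqn{\Gamma^+_{ij} / \sqrt{\Gamma^+_{ii}\Gamma^+_{jj}}},
#' independent of temperature.  This is the exact value that
#' [correlation_matrix()] estimates from sampled frames, making the topology
#' an oracle for the whole correlation pipeline.
#'
#' @param topo A [build_toy_tetramer()] topology (possibly with a planted
#'   pathway).
#' @return A `correlation_matrix` over the bead residue keys.
#' @export
analytic_correlations <- function(topo) {
  stopifnot(inherits(topo, "bead_topology"))
  ginv <- gnm_covariance(topo)
  v <- diag(ginv)
  corr <- ginv / sqrt(outer(v, v))
  corr <- (corr + t(corr)) / 2
  corr[corr > 1] <- 1
  corr[corr < -1] <- -1
  diag(corr) <- 1
  dimnames(corr) <- list(topo$residues$key, topo$residues$key)
  class(corr) <- c("correlation_matrix", class(corr))
  corr
}

#' Sample Gaussian equilibrium frames from a bead-spring topology
#'
#' Draws `n_frames` independent displacement vectors with per-axis covariance
#' `temperature` x the Kirchhoff pseudo-inverse (isotropic on x, y, z, the
#' Gaussian-network convention), adds them to the reference structure, and
#' optionally injects random rigid-body rotations and translations to emulate
#' un-aligned raw trajectories.  Each bead doubles as its own side-chain
#' contact atom (the beads are written as glycine C-alphas), so the side-chain
#' contact rule is exercised without an all-atom model.  Fully reproducible
#' from `seed`.
#'
#' @param topo A bead topology.
#' @param n_frames Number of frames (>= 2).
#' @param seed Integer RNG seed; recorded on the returned trajectory.
#' @param temperature Temperature factor scaling the covariance; the default
#'   0.04 keeps bonded-pair relative fluctuations near 0.2 A so that designed
#'   contacts persist and designed separations stay open.
#' @param rigid_motion Inject per-frame random rigid-body motion (default
#'   FALSE).
#' @return A trajectory with subunits assigned; `superposed` is TRUE unless
#'   rigid motion was injected.
#' @export
sample_frames <- function(topo, n_frames, seed, temperature = 0.04,
                          rigid_motion = FALSE) {
  stopifnot(inherits(topo, "bead_topology"))
  n_frames <- as.integer(assert_scalar_number(n_frames, "n_frames", min = 2))
  assert_scalar_number(seed, "seed")
  assert_scalar_number(temperature, "temperature", min = 1e-300)
  ginv <- gnm_covariance(topo)
  e <- eigen(ginv, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  if (min(e$values) < -1e-8 * max(vals)) {
    abort_allopath("Covariance is not positive semi-definite.", "numerical_error")
  }
  amp <- e$vectors %*% diag(sqrt(temperature * vals))
  n <- nrow(topo$xyz)
  arr <- array(0, c(n_frames, n, 3L))
  withr::with_seed(as.integer(seed), {
    for (a in 1:3) {
      z <- matrix(stats::rnorm(n_frames * n), n_frames, n)
      arr[, , a] <- z %*% t(amp)
    }
    for (a in 1:3) arr[, , a] <- arr[, , a] + matrix(topo$xyz[, a], n_frames, n, byrow = TRUE)
    if (rigid_motion) {
      for (f in seq_len(n_frames)) {
        rot <- random_rotation()
        shift <- stats::rnorm(3L, sd = 5)
        arr[f, , ] <- sweep(arr[f, , ] %*% t(rot), 2L, -shift)
      }
    }
  })
  atoms <- tibble::tibble(
    elety = "CA",
    chain = topo$residues$chain,
    resno = topo$residues$resno,
    resname = "GLY"
  )
  traj <- new_trajectory(array_to_xyz(arr), atoms, superposed = !rigid_motion)
  traj$seed <- as.integer(seed)
  assign_subunits(traj, subunit_map(topo$chains, topo$neighbor))
}

random_rotation <- function() {
  qr_res <- qr(matrix(stats::rnorm(9L), 3L, 3L))
  q <- qr.Q(qr_res)
  q * sign(det(q))
}

#' Reference-geometry contact map of a bead topology
#'
#' The deterministic analogue of [contact_map()]: a pair of beads is a
#' contact when their reference positions lie closer than `cutoff`.  Used for
#' noise-free analytic pipelines where no frames are sampled.
#'
#' @param topo A bead topology.
#' @param cutoff Contact cutoff in Angstrom (default 5.0).
#' @param occupancy Recorded threshold metadata (probabilities are 0/1).
#' @return A `contact_map`.
#' @export
reference_contact_map <- function(topo, cutoff = 5.0, occupancy = 0.75) {
  stopifnot(inherits(topo, "bead_topology"))
  assert_scalar_number(cutoff, "cutoff", min = 1e-8)
  d <- as.matrix(stats::dist(topo$xyz))
  keys <- topo$residues$key
  prob <- (d < cutoff) * 1
  diag(prob) <- 0
  dimnames(prob) <- list(keys, keys)
  res <- topo$residues
  res$resname <- "GLY"
  res$calpha <- seq_len(nrow(res))
  res$sidechain <- replicate(nrow(res), integer(0L), simplify = FALSE)
  res$contact_atoms <- as.list(seq_len(nrow(res)))
  res$subunit <- unname(stats::setNames(topo$chains, names(topo$chains))[res$chain])
  structure(
    list(
      probability = prob,
      contact = prob >= occupancy & prob > 0 & !diag(TRUE, nrow(prob)),
      cutoff = cutoff,
      occupancy = occupancy,
      atom_rule = "reference bead positions",
      residues = res[, c("key", "chain", "resno", "resname", "calpha",
                         "sidechain", "contact_atoms", "subunit")]
    ),
    class = "contact_map"
  )
}

#' Scripted contact fixture with exact in-contact fractions
#'
#' Builds a trajectory in which each scripted bead pair is placed below the
#' cutoff (at cutoff - 2) in exactly `round(fraction * n_frames)` frames and
#' above it (at cutoff + 3) otherwise, so requested occupancies are realised
#' to within 1/n_frames.  Pairs live on separate lanes 30 A apart; their
#' schedules cannot conflict geometrically.
#'
#' @param fractions Numeric vector of target in-contact fractions in \[0, 1\],
#'   one scripted pair per element.
#' @param n_frames Number of frames (default 1000).
#' @param cutoff Contact cutoff the schedule is built against (default 5.0).
#' @param seed Seed used to shuffle which frames are in contact (default 1).
#' @return A trajectory of glycine beads; pair p uses residues
#'   `A:(2p-1)` and `A:(2p)`.
#' @export
scripted_contact_fixture <- function(fractions, n_frames = 1000L, cutoff = 5.0,
                                     seed = 1L) {
  if (!is.numeric(fractions) || length(fractions) == 0L ||
      any(!is.finite(fractions)) || any(fractions < 0 | fractions > 1)) {
    abort_allopath("`fractions` must be numbers in [0, 1].", "construction_error")
  }
  n_frames <- as.integer(assert_scalar_number(n_frames, "n_frames", min = 2))
  assert_scalar_number(cutoff, "cutoff", min = 2.5)
  npair <- length(fractions)
  arr <- array(0, c(n_frames, 2L * npair, 3L))
  withr::with_seed(as.integer(seed), {
    for (p in seq_len(npair)) {
      m <- round(fractions[p] * n_frames)
      frames_in <- sample.int(n_frames, m)
      x <- rep(cutoff + 3, n_frames)
      x[frames_in] <- cutoff - 2
      arr[, 2L * p - 1L, 2L] <- 30 * p
      arr[, 2L * p, 1L] <- x
      arr[, 2L * p, 2L] <- 30 * p
    }
  })
  atoms <- tibble::tibble(
    elety = "CA",
    chain = "A",
    resno = seq_len(2L * npair),
    resname = "GLY"
  )
  traj <- new_trajectory(array_to_xyz(arr), atoms, superposed = TRUE)
  traj$seed <- as.integer(seed)
  traj
}

#' Write a synthetic fixture to disk
#'
#' Saves a trajectory as a multi-model PDB together with a JSON manifest
#' (frame count, seed, settings) and, when the generating topology is given,
#' the analytic correlation matrix as TSV.
#'
#' @param traj A trajectory from [sample_frames()] or
#'   [scripted_contact_fixture()].
#' @param prefix Output path prefix; writes `<prefix>.pdb`,
#'   `<prefix>_manifest.json` and optionally `<prefix>_analytic_corr.tsv`.
#' @param topo Optional generating topology.
#' @return `prefix`, invisibly.
#' @export
write_synthetic_fixture <- function(traj, prefix, topo = NULL) {
  write_trajectory_pdb(traj, paste0(prefix, ".pdb"))
  manifest <- list(
    n_frames = traj$n_frames,
    n_atoms = nrow(traj$atoms),
    seed = traj$seed,
    superposed = traj$superposed
  )
  if (!is.null(topo)) {
    manifest$spring_cutoff <- topo$spring_cutoff
    manifest$planted_boost <- if (is.null(topo$planted)) NULL else topo$planted$boost
    corr <- analytic_correlations(topo)
    readr::write_tsv(
      tibble::as_tibble(as.data.frame(unclass(corr)), rownames = "residue"),
      paste0(prefix, "_analytic_corr.tsv")
    )
    manifest$analytic_correlations <- paste0(prefix, "_analytic_corr.tsv")
  }
  jsonlite::write_json(manifest, paste0(prefix, "_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(prefix)
}

#' @export
print.bead_topology <- function(x, ...) {
  cat(sprintf(
    "<bead_topology> %d beads (4 x %d), %d springs (cutoff %.1f A)%s\n",
    nrow(x$xyz), x$n_per_subunit, nrow(x$springs), x$spring_cutoff,
    if (is.null(x$planted)) "" else sprintf(", planted pathway (boost %.1f)", x$planted$boost)
  ))
  invisible(x)
}
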