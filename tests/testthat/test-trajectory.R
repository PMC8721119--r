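test_that("multi-model PDB reading counts models and residues", {
  f <- withr::local_tempfile(fileext = ".pdb")
  ref <- matrix(c(0, 0, 0, 3.8, 0, 0, 7.6, 0, 0, 11.4, 0, 0, 15.2, 0, 0),
                ncol = 3, byrow = TRUE)
  models <- lapply(1:3, function(m) ref + m * 0.1)
  write_mini_pdb(f, models, resnames = rep("GLY", 5))
  traj <- read_trajectory(f)
  expect_equal(n_frames(traj), 3L)
  expect_equal(nrow(residue_table(traj)), 5L)
  expect_equal(residue_table(traj)$key, paste0("A:", 1:5))
})

test_that("single-model input and unreadable files are rejected", {
  f <- withr::local_tempfile(fileext = ".pdb")
  ref <- matrix(c(0, 0, 0, 3.8, 0, 0, 7.6, 0, 0), ncol = 3, byrow = TRUE)
  write_mini_pdb(f, list(ref), resnames = rep("ALA", 3))
  expect_error(read_trajectory(f), class = "allopath_input_error")
  expect_error(read_trajectory("no/such/file.pdb"), class = "allopath_input_error")
  g <- withr::local_tempfile(fileext = ".xtc")
  writeLines("x", g)
  expect_error(read_trajectory(g), class = "allopath_format_error")
})

test_that("trajectories round-trip through multi-model PDB within format precision", {
  topo <- build_toy_tetramer()
  traj <- sample_frames(topo, n_frames = 4, seed = 42)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory_pdb(traj, f)
  back <- read_trajectory(f)
  expect_equal(back$n_frames, traj$n_frames)
  expect_equal(back$residues$key, traj$residues$key)
  expect_lt(max(abs(back$xyz - traj$xyz)), 1e-3)
})

test_that("nm-scale coordinates are rejected with a units error", {
  f <- withr::local_tempfile(fileext = ".pdb")
  ref <- matrix(c(0, 0, 0, 0.38, 0, 0, 0.76, 0, 0, 1.14, 0, 0), ncol = 3, byrow = TRUE)
  write_mini_pdb(f, list(ref, ref + 0.01), resnames = rep("GLY", 4))
  expect_error(read_trajectory(f), class = "allopath_input_error")
})

test_that("glycine uses its C-alpha as the side-chain surrogate", {
  topo <- build_toy_tetramer()
  traj <- sample_frames(topo, n_frames = 3, seed = 1)
  rt <- residue_table(traj)
  expect_true(all(lengths(rt$sidechain) == 0))
  expect_true(all(mapply(identical, rt$contact_atoms,
                         lapply(rt$calpha, identity))))
})

test_that("superposition exactly removes pure rigid-body motion and is idempotent", {
  topo <- build_toy_tetramer()
  traj <- sample_frames(topo, n_frames = 8, seed = 9, temperature = 1e-16,
                        rigid_motion = TRUE)
  fit <- superpose(traj, max_iter = 50, tol = 1e-9)
  spread <- max(apply(fit$xyz, 2, function(x) diff(range(x))))
  expect_lt(spread, 1e-6)
  again <- superpose(fit, max_iter = 50, tol = 1e-9)
  expect_lt(max(abs(again$xyz - fit$xyz)), 1e-6)
})

test_that("superposition never increases total C-alpha variance", {
  topo <- build_toy_tetramer()
  for (seed in 1:3) {
    traj <- sample_frames(topo, n_frames = 60, seed = seed, rigid_motion = TRUE)
    fit <- superpose(traj)
    expect_lte(allopath:::total_ca_variance(fit),
               allopath:::total_ca_variance(traj) + 1e-8)
  }
})

test_that("post-superposition per-atom variance matches the injected noise", {
  # reference + isotropic iid noise + random rigid motions
  set.seed(4)
  ref <- matrix(rnorm(30 * 3, sd = 8), 30, 3)
  sd_true <- 0.3
  frames <- lapply(1:400, function(f) {
    q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    q <- q * sign(det(q))
    (ref + matrix(rnorm(90, sd = sd_true), 30, 3)) %*% t(q) +
      matrix(rnorm(3, sd = 10), 30, 3, byrow = TRUE)
  })
  traj <- bead_traj(frames, superposed = FALSE)
  fit <- superpose(traj)
  per_atom_var <- colMeans(matrix(apply(fit$xyz, 2, stats::var), nrow = 3))
  expect_equal(mean(per_atom_var), sd_true^2, tolerance = 0.08)
})

test_that("superposition requires at least three C-alpha atoms", {
  frames <- lapply(1:3, function(f) matrix(c(0, 0, 0, 4, 0, 0), 2, 3, byrow = TRUE))
  traj <- bead_traj(frames)
  expect_error(superpose(traj), class = "allopath_fit_error")
})

test_that("subunit maps validate their invariants", {
  chains <- c(A = "A", B = "B", C = "C", D = "D")
  good <- subunit_map(chains, c(A = "B", B = "C", C = "D", D = "A"))
  expect_s3_class(good, "subunit_map")
  # not a bijection
  expect_error(
    subunit_map(chains, c(A = "B", B = "B", C = "D", D = "A")),
    class = "allopath_config_error"
  )
  # fixed point
  expect_error(
    subunit_map(chains, c(A = "A", B = "C", C = "D", D = "B")),
    class = "allopath_config_error"
  )
  # order must be a permutation of the labels
  expect_error(
    subunit_map(chains, c(A = "B", B = "C", C = "D", D = "A"), order = c("A", "B")),
    class = "allopath_config_error"
  )
})

test_that("assign_subunits labels residues and rejects unmapped chains", {
  topo <- build_toy_tetramer()
  traj <- sample_frames(topo, n_frames = 3, seed = 1)
  expect_equal(unique(residue_table(traj)$subunit), c("A", "B", "C", "D"))
  partial <- subunit_map(c(A = "A", B = "B"), c(A = "B", B = "A"))
  expect_error(assign_subunits(traj, partial), class = "allopath_config_error")
})
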