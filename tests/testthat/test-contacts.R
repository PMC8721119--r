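test_that("contact probability counts frames below the cutoff", {
  frames <- lapply(1:10, function(f) rbind(c(0, 0, 0), c(3, 0, 0), c(40, 0, 0)))
  traj <- bead_traj(frames)
  expect_equal(contact_probability(traj, "A:1", "A:2"), 1)
  expect_equal(contact_probability(traj, "A:1", "A:3"), 0)
  expect_error(contact_probability(traj, "A:1", "B:9"),
               class = "allopath_lookup_error")
})

test_that("the 75% occupancy rule is inclusive at the boundary", {
  traj <- scripted_contact_fixture(c(0.75, 0.749), n_frames = 1000, seed = 2)
  cmap <- contact_map(traj)
  expect_equal(cmap$probability["A:1", "A:2"], 0.75)
  expect_true(cmap$contact["A:1", "A:2"])
  expect_equal(cmap$probability["A:3", "A:4"], 0.749)
  expect_false(cmap$contact["A:3", "A:4"])
})

test_that("a rigid three-residue fixture with distances {2, 6, 7} has one contact", {
  frames <- lapply(1:5, function(f) rbind(c(0, 0, 0), c(2, 0, 0), c(2, 6, 0)))
  cmap <- contact_map(bead_traj(frames))
  expect_equal(sum(cmap$contact) / 2, 1)
  expect_true(cmap$contact["A:1", "A:2"])
})

test_that("occupancy zero marks every pair that is ever within the cutoff", {
  traj <- scripted_contact_fixture(c(0.001, 0), n_frames = 1000, seed = 3)
  cmap <- contact_map(traj, occupancy = 0)
  expect_true(cmap$contact["A:1", "A:2"])   # in contact in a single frame
  expect_false(cmap$contact["A:3", "A:4"])  # never within the cutoff
})

test_that("the accelerated contact map equals the brute-force all-pairs scan", {
  topo <- build_toy_tetramer()
  traj <- sample_frames(topo, n_frames = 40, seed = 8)
  cmap <- contact_map(traj)
  res <- residue_table(traj)
  n <- nrow(res)
  brute <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d <- allopath:::min_pair_distance(traj$xyz, res$contact_atoms[[i]],
                                        res$contact_atoms[[j]])
      brute[i, j] <- brute[j, i] <- mean(d < 5)
    }
  }
  expect_equal(unname(cmap$probability), brute)
})

test_that("side-chain atoms, not C-alphas, define contacts when present", {
  # two residues whose CA-CA distance exceeds the cutoff but whose side-chain
  # atoms touch
  atoms <- tibble::tibble(
    elety = c("CA", "CB", "CA", "CB"),
    chain = "A",
    resno = c(1L, 1L, 2L, 2L),
    resname = "ALA"
  )
  frame <- c(0, 0, 0, 3, 0, 0, 7, 0, 0, 4, 0, 0)
  traj <- new_trajectory(rbind(frame, frame), atoms, superposed = TRUE)
  expect_equal(contact_probability(traj, "A:1", "A:2"), 1) # CB-CB at 1 A
  cmap <- contact_map(traj)
  expect_true(cmap$contact["A:1", "A:2"])
})

test_that("contact probabilities are invariant under frame reordering", {
  traj <- scripted_contact_fixture(c(0.4, 0.8), n_frames = 200, seed = 5)
  perm <- sample(traj$n_frames)
  shuffled <- traj
  shuffled$xyz <- traj$xyz[perm, , drop = FALSE]
  expect_equal(contact_map(traj)$probability, contact_map(shuffled)$probability)
})

test_that("the boolean map is monotone in occupancy and cutoff", {
  topo <- build_toy_tetramer()
  traj <- sample_frames(topo, n_frames = 50, seed = 6)
  base <- contact_map(traj, cutoff = 5, occupancy = 0.75)
  stricter <- contact_map(traj, cutoff = 5, occupancy = 0.9)
  wider <- contact_map(traj, cutoff = 6, occupancy = 0.75)
  expect_true(all(base$contact[stricter$contact]))   # raising occupancy adds nothing
  expect_true(all(wider$contact[base$contact]))      # raising cutoff removes nothing
})

test_that("subunit consensus requires the contact in at least min_subunits subunits", {
  smap <- subunit_map(c(A = "A", B = "B", C = "C", D = "D"),
                      c(A = "B", B = "C", C = "D", D = "A"))
  three <- subunit_consensus(contact_map(consensus_fixture(c("A", "B", "C"))), smap)
  expect_true(three$consensus["1", "2"])
  two <- subunit_consensus(contact_map(consensus_fixture(c("A", "B"))), smap)
  expect_false(two$consensus["1", "2"])
})

test_that("consensus with min_subunits 1 is the union and 4 the intersection", {
  topo <- build_toy_tetramer()
  traj <- sample_frames(topo, n_frames = 50, seed = 10)
  cmap <- contact_map(traj)
  smap <- subunit_map(topo$chains, topo$neighbor)
  cons1 <- subunit_consensus(cmap, smap, min_subunits = 1)
  cons4 <- subunit_consensus(cmap, smap, min_subunits = 4)
  expect_identical(cons1$consensus, cons1$counts >= 1 & !diag(TRUE, nrow(cons1$counts)))
  expect_identical(cons4$consensus, cons4$counts == 4 & !diag(TRUE, nrow(cons4$counts)))
  expect_true(all(cons4$consensus <= cons1$consensus))
})

test_that("a perfectly symmetric tetramer's consensus equals any single subunit map", {
  topo <- build_toy_tetramer()
  cmap <- reference_contact_map(topo)
  smap <- subunit_map(topo$chains, topo$neighbor)
  cons <- subunit_consensus(cmap, smap, min_subunits = 4)
  # single-subunit view of chain A, including its swap interface with B
  keysA <- paste0("A:", cons$resno)
  keysB <- paste0("B:", cons$resno)
  single <- cmap$contact[keysA, keysA] |
    cmap$contact[keysA, keysB] | t(cmap$contact[keysA, keysB])
  single <- single | t(single)
  diag(single) <- FALSE
  dimnames(single) <- dimnames(cons$consensus)
  expect_identical(cons$consensus, single)
})

test_that("mismatched subunit numbering is a mapping error", {
  traj <- consensus_fixture("A")
  traj$atoms$resno[traj$atoms$chain == "D"] <- c(5L, 6L)
  traj <- new_trajectory(traj$xyz, traj$atoms, superposed = TRUE)
  smap <- subunit_map(c(A = "A", B = "B", C = "C", D = "D"),
                      c(A = "B", B = "C", C = "D", D = "A"))
  expect_error(subunit_consensus(contact_map(traj), smap),
               class = "allopath_mapping_error")
})
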