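test_that("a hand-built PDB parses into residues with verbatim numbering", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_tiny_pdb(path)
  rec <- read_receptor_pdb(path)
  expect_s3_class(rec, "receptor_structure")
  expect_equal(nrow(rec$atoms), 6)
  expect_equal(sort(unique(rec$atoms$residue_number)), c(10, 11, 12))
  expect_equal(rec$atoms$element[rec$atoms$atom_name == "OH"], "O")
})

test_that("PDB edge cases: models, HETATM, altlocs, empty files", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("MODEL        1",
               pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0, element = "C"),
               "ENDMDL", "MODEL        2",
               pdb_line(2, "CA", "GLY", "A", 1, 9, 9, 9, element = "C"),
               pdb_line(3, "CA", "ALA", "A", 2, 9, 9, 9, element = "C"),
               "ENDMDL", "END"), path)
  rec <- read_receptor_pdb(path)
  expect_equal(nrow(rec$atoms), 1)   # first MODEL only
  expect_equal(rec$atoms$x, 0)

  writeLines(c(pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0, element = "C"),
               pdb_line(2, "O", "HOH", "A", 99, 5, 5, 5, type = "HETATM"),
               "END"), path)
  expect_equal(nrow(read_receptor_pdb(path)$atoms), 1)
  expect_equal(nrow(read_receptor_pdb(path, include_hetatm = TRUE)$atoms), 2)

  # altloc B listed first must lose to altloc A
  writeLines(c(pdb_line(1, "CA", "GLY", "A", 1, 9, 9, 9, alt = "B",
                        occupancy = 0.7, element = "C"),
               pdb_line(2, "CA", "GLY", "A", 1, 0, 0, 0, alt = "A",
                        occupancy = 0.3, element = "C"),
               "END"), path)
  rec <- read_receptor_pdb(path)
  expect_equal(nrow(rec$atoms), 1)
  expect_equal(rec$atoms$x, 0)

  writeLines(character(0), path)
  expect_error(read_receptor_pdb(path))
})

test_that("SDF files yield poses ranked in file order", {
  fx <- simulate_pose_fixture(seed = 10)
  one <- read_ligand_poses(fx$pose_path)
  expect_length(one, 1)
  expect_equal(one[[1]]$pose_rank, 1L)

  # nine-record file, as a docking run writes
  nine <- withr::local_tempfile(fileext = ".sdf")
  rec <- readLines(fx$pose_path)
  writeLines(rep(rec, 9), nine)
  poses <- read_ligand_poses(nine)
  expect_length(poses, 9)
  expect_equal(vapply(poses, function(p) p$pose_rank, integer(1)), 1:9)

  # a record whose counts line promises more atoms than it has
  bad <- withr::local_tempfile(fileext = ".sdf")
  lines <- readLines(fx$pose_path)
  counts <- grep("V2000", lines)
  writeLines(c(lines[seq_len(counts)], lines[(counts + 2):length(lines)]), bad)
  expect_error(suppressWarnings(read_ligand_poses(bad)))
})

test_that("minimum distances match hand geometry and the exhaustive oracle", {
  rec <- make_receptor("TYR", 251, "OH", "O", cbind(3, 4, 0))
  pose <- make_pose("C", cbind(0, 0, 0))
  rep1 <- min_ligand_residue_distance(pose, rec)
  expect_equal(rep1$min_distance, 5.0)
  expect_equal(rep1$nearest_residue$number, 251L)

  # tie at 2 A: the lower residue number wins
  rec2 <- make_receptor(c("ALA", "GLY"), c(30, 7), c("CA", "CA"), c("C", "C"),
                        rbind(c(2, 0, 0), c(0, 2, 0)))
  rep2 <- min_ligand_residue_distance(pose, rec2)
  expect_equal(rep2$min_distance, 2.0)
  expect_equal(rep2$nearest_residue$number, 7L)
  expect_equal(rep2$nearest_residue$name, "GLY")

  set.seed(99)
  for (k in 1:10) {
    L <- matrix(rnorm(60, sd = 3), ncol = 3)
    R <- matrix(rnorm(150, sd = 3), ncol = 3)
    rec3 <- make_receptor("ALA", rep(1:10, each = 5), "CA", "C", R)
    pose3 <- make_pose(rep("C", 20), L)
    expect_equal(min_ligand_residue_distance(pose3, rec3)$min_distance,
                 oracle_min_dist(L, R), tolerance = 1e-12)
  }
})

test_that("distances are invariant under joint rigid motion", {
  set.seed(17)
  L <- matrix(rnorm(30), ncol = 3)
  R <- matrix(rnorm(60, mean = 4), ncol = 3)
  base <- min_ligand_residue_distance(
    make_pose(rep("C", 10), L),
    make_receptor("ALA", rep(1:5, each = 4), "CA", "C", R))$min_distance
  for (k in 1:10) {
    Q <- random_rotation()
    shift <- rnorm(3, sd = 10)
    Lr <- sweep(L %*% Q, 2, shift, "+")
    Rr <- sweep(R %*% Q, 2, shift, "+")
    moved <- min_ligand_residue_distance(
      make_pose(rep("C", 10), Lr),
      make_receptor("ALA", rep(1:5, each = 4), "CA", "C", Rr))$min_distance
    expect_equal(moved, base, tolerance = 1e-9)
  }
})

test_that("hydrogen filtering only removes candidate pairs", {
  set.seed(4)
  L <- matrix(rnorm(30), ncol = 3)
  R <- matrix(rnorm(30, mean = 3), ncol = 3)
  elemL <- c(rep("C", 7), rep("H", 3))
  pose <- make_pose(elemL, L)
  rec <- make_receptor("ALA", rep(1:2, each = 5), "CA",
                       c(rep("C", 8), "H", "H"), R)
  heavy <- min_ligand_residue_distance(pose, rec)$min_distance
  all_atoms <- min_ligand_residue_distance(pose, rec,
                                           include_hydrogens = TRUE)$min_distance
  expect_lte(all_atoms, heavy)
  # a pose of hydrogens only cannot be measured under the default filter
  expect_error(min_ligand_residue_distance(make_pose("H", cbind(0, 0, 0)), rec),
               "hydrogen")
})

test_that("named atom pairs measure the published contact geometry", {
  rec <- make_receptor("TYR", 251, c("CA", "OH"), c("C", "O"),
                       rbind(c(0, 0, 5), c(0, 0, 3.26)))
  pose <- make_pose("O", cbind(0, 0, 0))
  expect_equal(atom_pair_distance(pose, 1, rec, 251, atom_name = "OH"), 3.26)
  # convenience mode: nearest oxygen within the residue
  expect_equal(atom_pair_distance(pose, 1, rec, 251, element = "O"), 3.26)
  expect_equal(atom_pair_distance(make_pose("O", cbind(0, 0, 3.26)), 1, rec,
                                  251, atom_name = "OH"), 0)
  expect_error(atom_pair_distance(pose, 1, rec, 999), "no residue")
  expect_error(atom_pair_distance(pose, 1, rec, 251, atom_name = "NZ"),
               "no atom named")
  expect_error(atom_pair_distance(pose, 1, rec, 251, element = "S"), "atom in")
  set.seed(12)
  a <- rnorm(3)
  b <- rnorm(3)
  rec2 <- make_receptor("ALA", 1, "CA", "C", rbind(b))
  expect_equal(atom_pair_distance(make_pose("C", rbind(a)), 1, rec2, 1),
               sqrt(sum((a - b)^2)))
})

test_that("panel contact tables select poses and average to 3 decimals", {
  expect_equal(mean_nearest_distance(3.26), 3.26)
  expect_equal(mean_nearest_distance(c(3.5, 3.7)), 3.6)
  expect_error(mean_nearest_distance(numeric(0)), "no distance")

  rec <- make_receptor("TYR", 251, "OH", "O", cbind(0, 0, 0))
  near <- make_pose("C", cbind(0, 0, 2), "ligA", pose_rank = 2L)
  far <- make_pose("C", cbind(0, 0, 4), "ligA", pose_rank = 1L)
  other <- make_pose("C", cbind(0, 0, 3), "ligB", pose_rank = 1L)
  tab_rank <- pose_distance_table(rec, list(near, far, other))
  expect_equal(tab_rank$distance[tab_rank$ligand == "ligA"], 4)
  tab_min <- pose_distance_table(rec, list(near, far, other),
                                 pose_selection = "min_distance")
  expect_equal(tab_min$distance[tab_min$ligand == "ligA"], 2)
  expect_equal(attr(tab_min, "mean_distance"), round(mean(c(2, 3)), 3))
})
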