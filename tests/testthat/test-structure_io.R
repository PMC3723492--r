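test_that("PDB round trip preserves atoms, order, names, res_ids and coords", {
  h <- build_helix("ACDEFGHIKLMNPQRSTVWY", resid_start = 100L)
  p <- file.path(tempdir(), "rt.pdb")
  write_structure(h, p)
  h2 <- read_structure(p)
  expect_identical(n_atoms(h2), n_atoms(h))
  expect_identical(h2$atoms$name, h$atoms$name)
  expect_identical(h2$atoms$res_id, h$atoms$res_id)
  expect_identical(h2$atoms$res_name, h$atoms$res_name)
  expect_lt(max(abs(h2$xyz - h$xyz)), 1e-3)
  # atom count equals an independent text scan of ATOM/HETATM records
  lines <- readLines(p)
  expect_identical(n_atoms(h2),
                   sum(grepl("^ATOM  ", lines) | grepl("^HETATM", lines)))
})

test_that("GRO files read in Angstrom with the nm box converted", {
  h <- build_helix("AAAA")
  h$box <- c(140, 140, 140, 90, 90, 90)
  p <- file.path(tempdir(), "rt.gro")
  write_structure(h, p)
  # the box line is written in nm
  expect_match(readLines(p)[length(readLines(p))], "14.0")
  h2 <- read_structure(p)
  expect_equal(h2$box[1:3], c(140, 140, 140))
  expect_lt(max(abs(h2$xyz - h$xyz)), 1e-2)  # GRO stores 0.001 nm
})

test_that("a hand-written GRO box line of 14.0 nm becomes a 140 A box", {
  p <- file.path(tempdir(), "box.gro")
  writeLines(c("toy", "    1",
               "    1W        W    1   0.500   0.500   0.500",
               "  14.0 14.0 14.0"), p)
  s <- read_structure(p)
  expect_equal(s$box[1:3], c(140, 140, 140))
  expect_equal(s$xyz[1, ], c(5, 5, 5))
})

test_that("PDB reads agree with bio3d on a fixture", {
  skip_if_not_installed("bio3d")
  h <- build_helix(anchor_sequence(), resid_start = 710L)
  p <- file.path(tempdir(), "x.pdb")
  write_structure(h, p)
  ref <- bio3d::read.pdb(p)
  s <- read_structure(p)
  expect_equal(unname(cbind(ref$atom$x, ref$atom$y, ref$atom$z)),
               unname(s$xyz), tolerance = 1e-8)
  expect_identical(as.integer(ref$atom$resno), s$atoms$res_id)
  expect_identical(trimws(ref$atom$elety), s$atoms$name)
})

test_that("malformed records raise parse errors naming the line", {
  p <- file.path(tempdir(), "bad.pdb")
  writeLines(c("TITLE     bad",
               "ATOM      1  CA  ALA A   1      xx.xxx   0.000   0.000  1.00  0.00           C"),
             p)
  expect_error(read_structure(p), "line 2")
  p2 <- file.path(tempdir(), "bad.gro")
  writeLines(c("t", "    1", "    1TOY    HD    1   aaaa   0.000   0.000",
               "  3.0 3.0 3.0"), p2)
  expect_error(read_structure(p2, format = "gro"), "line 3")
  expect_error(read_structure("noext.xyz"), "format")
})

test_that("selection grammar: ranges, names, boolean logic", {
  h <- build_helix(paste(rep("A", 332), collapse = ""), resid_start = 1L)
  # 332-residue chain: an anchor-sized range selects 15 CAs
  h$atoms$res_id <- h$atoms$res_id + 709L
  expect_length(select_atoms(h, "resid 710-724 and name CA"), 15)
  expect_length(select_atoms(h, "resid 724-750 and name CA"), 27)
  expect_length(select_atoms(h, "name XX"), 0)
  both <- select_atoms(h, "resid 710-711 or resid 713")
  expect_setequal(both, which(h$atoms$res_id %in% c(710, 711, 713)))
  expect_error(select_atoms(h, "resid and"), "syntax")
  expect_error(select_atoms(h, "frooble 3"), "syntax")
})

test_that("selection is idempotent and monotone on subsets", {
  h <- build_helix(anchor_sequence(), resid_start = 710L)
  idx <- select_atoms(h, "resid 712-720")
  sub <- subset_structure(h, idx)
  idx2 <- select_atoms(sub, "resid 712-720")
  expect_identical(idx2, seq_along(idx))
  # selecting on the subset can only return atoms inside it
  idx3 <- select_atoms(sub, "resid 710-724 and name CA")
  expect_true(all(sub$atoms$res_id[idx3] %in% 712:720))
})

test_that("trajectory round trip through native and PDB formats", {
  h <- build_helix("AKLV")
  h$box <- c(30, 30, 30, 90, 90, 90)
  coords <- list(h$xyz, h$xyz + 0.5, h$xyz + 1)
  traj <- trajectory(h, coords, times = c(0, 25, 50))
  p <- file.path(tempdir(), "t.traj")
  write_trajectory(traj, p)
  t2 <- read_trajectory(p, topology = h)
  expect_equal(n_frames(t2), 3)
  expect_equal(t2$times, c(0, 25, 50))
  expect_lt(max(abs(t2$coords[[3]] - coords[[3]])), 1e-5)
  p2 <- file.path(tempdir(), "t.pdb")
  write_trajectory(traj, p2)
  t3 <- read_trajectory(p2)
  expect_equal(n_frames(t3), 3)
  expect_lt(max(abs(t3$coords[[2]] - coords[[2]])), 1e-3)
  expect_error(trajectory(h, coords, times = c(2, 1, 0)), "non-decreasing")
})
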