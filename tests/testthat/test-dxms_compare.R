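toy_complex_traj <- function(pose, head_offset = 12) {
  bil <- build_bilayer(nx = 6, ny = 6, head_offset = head_offset,
                       box_z = 72, jitter = 0)
  center_z <- 36
  prot <- toy_protein(pose, phosphate_z = center_z + head_offset,
                      center_xy = bil$box[1:2] / 2)
  sys <- combine_structures(prot, bil, box = bil$box)
  lip <- which(sys$atoms$res_name == "TOY")
  pho <- which(sys$atoms$name == "HD")
  traj <- trajectory(sys, list(sys$xyz))
  mf <- membrane_frame(sys, lip, pho)
  list(traj = traj, mf = mf)
}

test_that("fragment classification follows the published thresholds", {
  fr <- synth_dxms(list(
    list(range = c(1, 5), decrement_pct = 70, incubation_s = 300),
    list(range = c(10, 15), decrement_pct = 0, incubation_s = 300),
    list(range = c(20, 25), decrement_pct = 55, incubation_s = 300),
    list(range = c(30, 35), decrement_pct = 39.9, incubation_s = 300)))
  cl <- classify_fragments(fr)$class
  expect_identical(cl, c("strong", "none", "intermediate", "weak"))
})

test_that("burial profiles separate membrane-bound from solution poses", {
  mem <- toy_complex_traj("membrane")
  sol <- toy_complex_traj("solution")
  bp_mem <- burial_profile(mem$traj, mem$mf)
  bp_sol <- burial_profile(sol$traj, sol$mf)
  # solution pose: everything exposed
  expect_true(all(bp_sol$fraction == 0))
  # membrane pose: hydrophobic anchor residues buried
  anchor_hyd <- c(711, 714, 715, 717, 721, 722)
  expect_true(all(bp_mem$fraction[bp_mem$res_id %in% anchor_hyd] > 0.5))
})

test_that("single buried residue yields fraction 1, others 0", {
  b <- build_bilayer(nx = 4, ny = 4, center_z = 24, box_z = 48, jitter = 0)
  helix <- build_helix("LS", resid_start = 1L)
  # residue 1 side chain below the upper phosphate plane, residue 2 above
  helix$xyz[helix$atoms$res_id == 1, 3] <- 30
  helix$xyz[helix$atoms$res_id == 2, 3] <- 45
  helix$xyz[, 1:2] <- 13
  sys <- combine_structures(helix, b, box = b$box)
  lip <- which(sys$atoms$res_name == "TOY")
  pho <- which(sys$atoms$name == "HD")
  mf <- membrane_frame(sys, lip, pho)
  bp <- burial_profile(trajectory(sys, list(sys$xyz)), mf)
  expect_equal(bp$fraction[bp$res_id == 1], 1)
  expect_equal(bp$fraction[bp$res_id == 2], 0)
})

test_that("SASA mode distinguishes exposed from occluded residues", {
  helix <- build_helix("AAAA")
  s_alone <- helix
  sasa_open <- residue_sasa(s_alone, 2)
  # bury residue 2 inside a dense shell of atoms
  set.seed(1)
  ctr <- colMeans(helix$xyz[helix$atoms$res_id == 2, , drop = FALSE])
  shell_pts <- matrix(rnorm(3 * 200), 200, 3)
  shell_pts <- ctr + 4.5 * shell_pts / sqrt(rowSums(shell_pts^2))
  shell <- structure3d(data.frame(name = rep("C", 200), element = "C",
                                  res_name = "SHL", res_id = 999),
                       shell_pts)
  occluded <- combine_structures(helix, shell)
  expect_gt(sasa_open, 50)
  expect_lt(residue_sasa(occluded, 2), sasa_open / 3)
  traj <- trajectory(helix, list(helix$xyz))
  traj$topology$atoms$is_bead <- TRUE
  expect_error(burial_profile(traj, res_ids = 1, mode = "sasa"), "depth")
})

test_that("consistency score rewards matching burial patterns", {
  # fully exposed model, all-none fragments: perfect score
  bp <- structure(data.frame(res_id = 1:100, fraction = 0),
                  class = c("burial_profile", "data.frame"))
  fr <- classify_fragments(data.frame(res_start = c(1, 50),
                                      res_end = c(20, 70),
                                      decrement_pct = 0,
                                      incubation_s = 300))
  expect_equal(consistency_score(bp, fr)$score, 1)
  # buried anchor + exposed body against (strong, none)
  bp2 <- structure(data.frame(res_id = c(1:100, 710:724),
                              fraction = c(rep(0, 100), rep(1, 15))),
                   class = c("burial_profile", "data.frame"))
  fr2 <- classify_fragments(data.frame(res_start = c(710, 1),
                                       res_end = c(724, 100),
                                       decrement_pct = c(90, 0),
                                       incubation_s = 300))
  expect_equal(consistency_score(bp2, fr2)$score, 1)
  # swapped labels fail completely
  fr3 <- fr2; fr3$decrement_pct <- rev(fr3$decrement_pct)
  fr3 <- classify_fragments(fr3[c("res_start", "res_end", "decrement_pct",
                                  "incubation_s")])
  expect_equal(consistency_score(bp2, fr3)$score, 0)
  # fragments outside the model are reported unscored
  fr4 <- classify_fragments(data.frame(res_start = 2000, res_end = 2010,
                                       decrement_pct = 80,
                                       incubation_s = 300))
  out <- consistency_score(bp2, fr4)
  expect_false(out$table$scored)
  expect_true(is.na(out$score))
})

test_that("score is invariant to fragment order and consistent id shifts", {
  bp <- structure(data.frame(res_id = 1:50,
                             fraction = c(rep(1, 20), rep(0, 30))),
                  class = c("burial_profile", "data.frame"))
  fr <- classify_fragments(data.frame(res_start = c(1, 30), res_end = c(15, 45),
                                      decrement_pct = c(85, 0),
                                      incubation_s = 300))
  s1 <- consistency_score(bp, fr)$score
  s2 <- consistency_score(bp, fr[2:1, ])$score
  expect_identical(s1, s2)
  bp_shift <- bp; bp_shift$res_id <- bp_shift$res_id + 500
  fr_shift <- fr; fr_shift$res_start <- fr_shift$res_start + 500
  fr_shift$res_end <- fr_shift$res_end + 500
  expect_identical(consistency_score(bp_shift, fr_shift)$score, s1)
})

test_that("deepening a buried anchor never lowers the strong-fragment match", {
  fr <- classify_fragments(synth_dxms(preset = "ipla2"))
  scores <- vapply(c(0, 2, 4, 6), function(extra) {
    bil <- build_bilayer(nx = 6, ny = 6, box_z = 72, jitter = 0)
    prot <- toy_protein("membrane", phosphate_z = 48,
                        center_xy = bil$box[1:2] / 2,
                        anchor_depth = 4 + extra)
    sys <- combine_structures(prot, bil, box = bil$box)
    lip <- which(sys$atoms$res_name == "TOY")
    pho <- which(sys$atoms$name == "HD")
    mf <- membrane_frame(sys, lip, pho)
    bp <- burial_profile(trajectory(sys, list(sys$xyz)), mf)
    tab <- consistency_score(bp, fr)$table
    tab$match[tab$class == "strong" & tab$scored]
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))
})
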