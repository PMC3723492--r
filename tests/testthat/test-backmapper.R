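random_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

test_that("Kabsch self-fit is the identity with zero residual", {
  set.seed(1)
  pts <- matrix(rnorm(30), 10, 3)
  tr <- kabsch_fit(pts, pts)
  expect_equal(tr$rotation, diag(3), tolerance = 1e-10)
  expect_equal(tr$translation, c(0, 0, 0), tolerance = 1e-10)
  expect_lt(tr$rmsd_after, 1e-10)
  expect_error(kabsch_fit(pts, pts[1:5, ]), "same number")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_fit(line, line), "collinear")
})

test_that("Kabsch recovers a random rigid transform", {
  for (seed in 1:8) {
    set.seed(seed + 100)
    pts <- matrix(rnorm(45), 15, 3)
    R <- random_rotation(seed)
    moved <- sweep(pts %*% t(R), 2, c(3, -7, 2), "+")
    tr <- kabsch_fit(pts, moved)
    expect_lt(tr$rmsd_after, 1e-8)
    expect_equal(det(tr$rotation), 1, tolerance = 1e-10)
    expect_equal(apply_transform(pts, tr), moved, tolerance = 1e-8)
  }
})

test_that("Kabsch residual on noisy data matches an independent optimizer", {
  set.seed(5)
  pts <- matrix(rnorm(60), 20, 3)
  target <- sweep(pts %*% t(random_rotation(3)), 2, c(1, 2, 3), "+") +
    matrix(rnorm(60, 0, 0.5), 20, 3)
  tr <- kabsch_fit(pts, target)
  # independent oracle: direct minimization over quaternion + translation
  obj <- function(par) {
    q <- par[1:4] / sqrt(sum(par[1:4]^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                  2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                  2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
                3, 3, byrow = TRUE)
    moved <- sweep(pts %*% t(R), 2, par[5:7], "+")
    sqrt(mean(rowSums((moved - target)^2)))
  }
  best <- Inf
  for (s in 1:12) {
    set.seed(s)
    o <- optim(c(rnorm(4), 0, 0, 0), obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, o$value)
  }
  expect_equal(tr$rmsd_after, best, tolerance = 1e-6)
})

test_that("Kabsch agrees with bio3d superposition", {
  skip_if_not_installed("bio3d")
  set.seed(11)
  pts <- matrix(rnorm(36), 12, 3)
  target <- sweep(pts %*% t(random_rotation(9)), 2, c(2, 0, -4), "+") +
    matrix(rnorm(36, 0, 0.3), 12, 3)
  tr <- kabsch_fit(pts, target)
  fitted <- suppressWarnings(bio3d::fit.xyz(fixed = as.numeric(t(target)),
                                            mobile = as.numeric(t(pts))))
  ref_rmsd <- sqrt(mean(rowSums((matrix(fitted, ncol = 3, byrow = TRUE) -
                                   target)^2)))
  expect_equal(tr$rmsd_after, ref_rmsd, tolerance = 1e-6)
})

test_that("protein fit moves rigidly onto CG backbone beads", {
  aa <- build_helix(anchor_sequence(), resid_start = 710L)
  cg <- map_protein(aa)
  # displace the CG model: fit must recover the pose
  R <- random_rotation(2)
  cg$beads$xyz <- sweep(cg$beads$xyz %*% t(R), 2, c(10, -4, 6), "+")
  fitted <- fit_protein_to_cg(aa, cg)
  ca <- select_atoms(fitted, "name CA")
  rmsd <- sqrt(mean(rowSums((fitted$xyz[ca, ] -
                               cg$beads$xyz[cg$backbone, ])^2)))
  expect_lt(rmsd, 1)  # CA vs backbone-bead discretization offset
  # internal geometry untouched
  d0 <- dist(aa$xyz); d1 <- dist(fitted$xyz)
  expect_lt(max(abs(d0 - d1)), 1e-6)
  # already-aligned reference gives the identity transform
  cg2 <- map_protein(aa)
  tr <- attr(fit_protein_to_cg(aa, cg2), "transform")
  expect_equal(tr$rotation, diag(3), tolerance = 1e-6)
  bad <- aa; bad$atoms$res_id <- bad$atoms$res_id + 1L
  expect_error(fit_protein_to_cg(bad, cg2), "mapping error")
})

test_that("membrane patch alignment matches midplanes and centers", {
  patch <- build_bilayer(nx = 4, ny = 4, center_z = 0, box_z = 48)
  pho <- select_atoms(patch, "name HD")
  cg_phos <- patch$xyz[pho, ]
  cg_phos[, 3] <- cg_phos[, 3] + 30
  moved <- fit_membrane_to_cg(patch, cg_phos)
  expect_equal(attr(moved, "translation"), c(0, 0, 30), tolerance = 1e-9)
  # leaflet spacing preserved
  z0 <- sort(unique(round(patch$xyz[pho, 3], 3)))
  z1 <- sort(unique(round(moved$xyz[pho, 3], 3)))
  expect_equal(diff(range(z1)), diff(range(z0)), tolerance = 1e-9)
  # coincident patch: zero translation
  same <- fit_membrane_to_cg(patch, patch$xyz[pho, ])
  expect_equal(attr(same, "translation"), c(0, 0, 0), tolerance = 1e-9)
  flat <- patch; flat$xyz[, 3] <- 0
  expect_error(fit_membrane_to_cg(flat, cg_phos), "bilayer")
})

test_that("lipid pruning removes whole lipids strictly within the cutoff", {
  bil <- build_bilayer(nx = 3, ny = 3, jitter = 0)
  prot <- structure3d(data.frame(name = "CA", element = "C",
                                 res_name = "ALA", res_id = 1, chain = "P",
                                 mass = 12, charge = 0, is_bead = FALSE),
                      matrix(c(100, 100, 100), 1, 3))
  none <- prune_lipids(bil, prot)
  expect_identical(attr(none, "removed"), 0L)
  expect_identical(n_atoms(none), n_atoms(bil))
  # construct a clash at 0.5 A from lipid 1's head
  prot$xyz <- matrix(bil$xyz[1, ] + c(0.5, 0, 0), 1, 3)
  pruned <- prune_lipids(bil, prot)
  expect_identical(attr(pruned, "removed"), 1L)
  expect_false(1 %in% pruned$atoms$res_id[pruned$atoms$res_name == "TOY"])
  # contact at exactly 0.7 A is kept (strict inequality at 0.6)
  prot$xyz <- matrix(bil$xyz[1, ] + c(0.7, 0, 0), 1, 3)
  expect_identical(attr(prune_lipids(bil, prot), "removed"), 0L)
})

test_that("pruning counts match the brute-force all-pairs scan", {
  for (seed in 1:10) {
    set.seed(seed)
    bil <- build_bilayer(nx = 3, ny = 3, seed = seed)
    prot <- build_helix("LKV")
    prot$xyz <- sweep(prot$xyz, 2,
                      runif(3, c(0, 0, 10), c(26, 26, 30)), "+")
    cutoff <- runif(1, 0.5, 6)
    got <- attr(prune_lipids(bil, prot, cutoff = cutoff), "removed")
    want <- brute_prune_count(bil, prot, cutoff, "TOY")
    expect_identical(got, as.integer(want))
  }
})

test_that("solvation fills the box, ionizes to target, and neutralizes", {
  empty <- structure3d(
    data.frame(name = character(0), element = character(0),
               res_name = character(0), res_id = integer(0),
               chain = character(0), mass = numeric(0), charge = numeric(0),
               is_bead = logical(0)),
    matrix(0, 0, 3), box = c(40, 40, 40))
  out <- solvate_and_ionize(empty, target_conc = 0.1, seed = 2)
  nions <- attr(out, "n_ions")
  expect_identical(nions[["NA."]], nions[["CL"]])
  # count follows n = round(conc * N_A * V_solvent)
  nw <- attr(out, "n_waters") + sum(nions)
  v <- nw * 1e27 / (55.34 * 6.02214076e23)
  expect_identical(nions[["NA."]],
                   as.integer(round(0.1 * 6.02214076e23 * v * 1e-27)))
  # conc 0, neutral: no ions at all
  none <- solvate_and_ionize(empty, target_conc = 0)
  expect_identical(sum(attr(none, "n_ions")), 0L)
  # charged solute at conc 0: counter-ions only
  solute <- structure3d(
    data.frame(name = "Q", element = "X", res_name = "ION", res_id = 1:5,
               chain = "Q", mass = 10, charge = -1, is_bead = FALSE),
    cbind(20, 20, 16 + 2 * (1:5)), box = c(40, 40, 40))
  charged <- solvate_and_ionize(solute, target_conc = 0, seed = 3)
  expect_identical(attr(charged, "n_ions")[["NA."]], 5L)
  expect_identical(attr(charged, "n_ions")[["CL"]], 0L)
  expect_equal(sum(charged$atoms$charge), 0)
  # no water within the exclusion radius of any solute atom
  wat <- which(charged$atoms$res_name == "HOH")
  for (i in which(charged$atoms$res_name == "ION")) {
    d <- sqrt(rowSums(sweep(charged$xyz[wat, ], 2, charged$xyz[i, ])^2))
    expect_gt(min(d), 2.4 - 1e-9)
  }
})

test_that("water exclusion region spans the protein-membrane gap", {
  bil <- build_bilayer(nx = 4, ny = 4, center_z = 0, box_z = 60)
  prot <- build_helix("LKVE")
  prot$xyz <- sweep(prot$xyz, 2, c(13, 13, 25) - colMeans(prot$xyz), "+")
  reg <- water_exclusion_region(prot, bil)
  expect_false(reg$empty)
  expect_equal(reg$z_bottom, 12, tolerance = 0.2)
  expect_equal(reg$z_top, min(prot$xyz[, 3]), tolerance = 1e-9)
  # touching protein: empty region with a warning
  prot2 <- prot
  prot2$xyz[, 3] <- prot2$xyz[, 3] - 20
  expect_warning(reg2 <- water_exclusion_region(prot2, bil), "empty")
  expect_true(reg2$empty)
  p <- file.path(tempdir(), "region.yaml")
  write_region(reg, p)
  expect_true(file.exists(p))
  y <- yaml::read_yaml(p)
  expect_equal(y$z_bottom, reg$z_bottom)
})
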