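# Independent brute-force oracles used across the suite.  These
# deliberately re-derive quantities in plain R (no calls into the
# compiled engine) so that engine results are checked against a second,
# independent code path.

# minimum-image displacement of b relative to a
mi_disp <- function(a, b, box) {
  d <- b - a
  d - box * round(d / box)
}

# all-pairs nonbonded energy/forces oracle built on the R-level
# lj_shifted()/coulomb_shifted() functions with minimum-image PBC,
# honoring 1-2 bond and 1-3 angle exclusions
brute_nonbonded <- function(coords, box, classes, charges, ff, excl = NULL) {
  n <- nrow(coords)
  excl_key <- character(0)
  if (!is.null(excl) && nrow(excl))
    excl_key <- paste(pmin(excl[, 1], excl[, 2]), pmax(excl[, 1], excl[, 2]))
  energy <- 0
  forces <- matrix(0, n, 3)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (paste(i, j) %in% excl_key) next
      d <- mi_disp(coords[i, ], coords[j, ], box)
      r <- sqrt(sum(d^2))
      if (r >= max(ff$lj_window[2], ff$coul_window[2])) next
      lj <- lj_shifted(r, ff$epsilon[classes[i], classes[j]],
                       ff$sigma[classes[i], classes[j]], ff$lj_window)
      e <- lj$energy; fs <- lj$force
      if (charges[i] != 0 && charges[j] != 0) {
        cc <- coulomb_shifted(r, charges[i], charges[j], ff$eps_r,
                              ff$coul_window)
        e <- e + cc$energy; fs <- fs + cc$force
      }
      energy <- energy + e
      fv <- fs * (-d) / r   # force on i points away from j for repulsion
      forces[i, ] <- forces[i, ] + fv
      forces[j, ] <- forces[j, ] - fv
    }
  }
  list(energy = energy, forces = forces)
}

# O(n^2) elastic-network oracle
brute_enm <- function(xyz, backbone, bonds, cutoff, k) {
  out <- NULL
  bonded <- character(0)
  if (nrow(bonds))
    bonded <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
  for (a in seq_along(backbone)) {
    for (b in seq_along(backbone)) {
      if (b <= a) next
      i <- backbone[a]; j <- backbone[b]
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (r <= cutoff && !(paste(min(i, j), max(i, j)) %in% bonded))
        out <- rbind(out, data.frame(i = min(i, j), j = max(i, j),
                                     r0 = r, k = k))
    }
  }
  if (is.null(out)) return(empty_bonds())
  out[order(out$i, out$j), ]
}

# brute-force lipid clash count (any atom within cutoff, strict)
brute_prune_count <- function(system, protein, cutoff, lipid_resnames) {
  is_lip <- system$atoms$res_name %in% lipid_resnames
  keys <- unique(paste(system$atoms$chain, system$atoms$res_id)[is_lip])
  removed <- 0
  for (key in keys) {
    idx <- which(paste(system$atoms$chain, system$atoms$res_id) == key & is_lip)
    clash <- FALSE
    for (a in idx) {
      for (b in seq_len(n_atoms(protein))) {
        if (sqrt(sum((system$xyz[a, ] - protein$xyz[b, ])^2)) < cutoff) {
          clash <- TRUE; break
        }
      }
      if (clash) break
    }
    if (clash) removed <- removed + 1
  }
  removed
}

# brute-force triple-loop hydrogen-bond count
brute_hbond <- function(s, donors, acceptors, dist_cutoff = 3.5,
                        angle_min = 150) {
  count <- 0L
  for (r in seq_len(nrow(donors))) {
    d <- donors[r, 1]; h <- donors[r, 2]
    for (a in acceptors) {
      dist <- sqrt(sum((s$xyz[d, ] - s$xyz[a, ])^2))
      if (dist > dist_cutoff || dist == 0) next
      v1 <- s$xyz[d, ] - s$xyz[h, ]
      v2 <- s$xyz[a, ] - s$xyz[h, ]
      ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang >= angle_min) count <- count + 1L
    }
  }
  count
}

# numeric central-difference gradient of a scalar function of coordinates
num_grad <- function(f, x, h = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# small random CG system (neutral or charged) for engine oracles
random_cg_instance <- function(n, box_len, seed, charged = FALSE) {
  set.seed(seed)
  classes <- sample(c("P", "N", "C", "Q"), n, replace = TRUE)
  charge <- rep(0, n)
  if (charged) {
    q_idx <- which(classes == "Q")
    if (length(q_idx) >= 2) {
      half <- seq_len(length(q_idx) %/% 2 * 2)
      charge[q_idx[half]] <- rep(c(1, -1), length.out = length(half))
    }
  }
  beads <- structure3d(
    data.frame(name = "B", element = "X", res_name = "TST",
               res_id = seq_len(n), chain = "A", mass = 72,
               charge = charge, is_bead = TRUE, stringsAsFactors = FALSE),
    matrix(runif(3 * n) * box_len, n, 3),
    box = c(box_len, box_len, box_len))
  cg_model(beads, classes)
}
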