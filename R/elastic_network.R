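# elastic_network: harmonic restraints between backbone beads that
# preserve protein secondary/tertiary structure during CG simulation.
# Convention: E = 1/2 k (r - r0)^2 with the default force constant
# k = 10 kJ mol^-1 A^-2 and a 7 A cutoff between backbone beads.

#' Build the elastic network for a coarse-grained protein
#'
#' One harmonic restraint for every unordered pair of backbone beads whose
#' reference distance is at most `cutoff`, excluding pairs already joined
#' by a backbone bond (those are restrained by the bond term; set
#' `include_bonded = TRUE` to keep them).  Side-chain beads never
#' participate.  The returned list is ordered by `(i, j)` and `r0` is the
#' reference distance, making the network independent of input atom
#' ordering.
#'
#' @param cg a [cg_model()] with non-empty `backbone` and reference
#'   coordinates
#' @param cutoff network cutoff in Angstrom (default 7)
#' @param k force constant in kJ mol^-1 A^-2 (default 10)
#' @param include_bonded also restrain sequence-adjacent (bonded) backbone
#'   pairs (default `FALSE`)
#' @return data.frame with columns `i, j, r0, k` (i < j, ascending)
#' @export
build_elastic_network <- function(cg, cutoff = 7, k = 10,
                                  include_bonded = FALSE) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  bb <- cg$backbone
  if (length(bb) == 0) stop("model has no backbone beads")
  x <- cg$beads$xyz[bb, , drop = FALSE]
  d <- as.matrix(stats::dist(x))
  pair <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  i <- bb[pair[, 1]]; j <- bb[pair[, 2]]
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  if (!include_bonded && nrow(cg$bonds) > 0) {
    bonded <- paste(pmin(cg$bonds$i, cg$bonds$j),
                    pmax(cg$bonds$i, cg$bonds$j))
    keep <- !(paste(i, j) %in% bonded)
    i <- i[keep]; j <- j[keep]; pair <- pair[keep, , drop = FALSE]
  }
  r0 <- d[pair]
  ord <- order(i, j)
  if (length(i) == 0) return(empty_bonds())
  data.frame(i = i[ord], j = j[ord], r0 = r0[ord], k = k)
}

#' Attach an elastic network to a model
#'
#' Convenience wrapper that stores the result of
#' [build_elastic_network()] in the model's `elastic` slot.
#'
#' @inheritParams build_elastic_network
#' @return the model, with `elastic` filled
#' @export
with_elastic_network <- function(cg, cutoff = 7, k = 10,
                                 include_bonded = FALSE) {
  cg$elastic <- build_elastic_network(cg, cutoff, k, include_bonded)
  cg
}

#' Harmonic restraint energy and forces
#'
#' `E = sum 1/2 k (r - r0)^2` over the bond list, with exact analytic
#' gradients.  At the reference geometry the energy and every force vanish;
#' forces obey Newton's third law for any configuration.
#'
#' @param bonds data.frame `i, j, r0, k` as returned by
#'   [build_elastic_network()] (also works for ordinary harmonic bonds)
#' @param coords `n x 3` coordinate matrix covering all bond indices
#' @return list with `energy` (kJ mol^-1) and `forces` (`n x 3`,
#'   kJ mol^-1 A^-1)
#' @export
elastic_energy_forces <- function(bonds, coords) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  forces <- matrix(0, n, 3)
  if (nrow(bonds) == 0) return(list(energy = 0, forces = forces))
  if (max(bonds$i, bonds$j) > n) stop("bond index exceeds coordinate count")
  dvec <- coords[bonds$j, , drop = FALSE] - coords[bonds$i, , drop = FALSE]
  r <- sqrt(rowSums(dvec^2))
  dr <- r - bonds$r0
  energy <- sum(0.5 * bonds$k * dr^2)
  # F_j = -k (r - r0) * unit(j - i); F_i = -F_j
  fscal <- ifelse(r > 0, -bonds$k * dr / r, 0)
  fj <- dvec * fscal
  for (col in 1:3) {
    forces[, col] <- forces[, col] +
      tapply_add(bonds$j, fj[, col], n) - tapply_add(bonds$i, fj[, col], n)
  }
  list(energy = energy, forces = forces)
}

# sum values into an accumulator of length n by index (fast, no tapply)
tapply_add <- function(idx, val, n) {
  out <- numeric(n)
  agg <- rowsum(val, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}
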