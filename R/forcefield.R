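# ForceField: per-class-pair 12-6 LJ parameters plus screened Coulomb,
# both smoothly shifted to zero at the cutoff.  The packaged table
# (inst/extdata/forcefield.yaml) is a deliberately reduced 4-class toy
# parameter set (epsilon 2-5 kJ/mol, sigma 4.7 A) chosen so that the toy
# lipid of the fixtures module self-assembles into a bilayer; it is data,
# not code, and can be swapped for any other class table.

#' Load a coarse-grained force field
#'
#' @param path YAML file with keys `classes`, `epsilon` (upper-triangular
#'   map of class-pair well depths, kJ mol^-1), `sigma` (single value or
#'   map, A), `eps_r` (relative dielectric, default 15), `lj_window` and
#'   `coul_window` (shift windows in A).  Defaults to the packaged table.
#' @return an object of class `mem_forcefield`: list with `classes`,
#'   `epsilon` and `sigma` matrices, `eps_r`, `lj_window`, `coul_window`.
#' @export
read_forcefield <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata/forcefield.yaml", package = "memscale")
  y <- yaml::read_yaml(path)
  classes <- unlist(y$classes)
  k <- length(classes)
  eps <- matrix(NA_real_, k, k, dimnames = list(classes, classes))
  for (a in names(y$epsilon)) {
    for (b in names(y$epsilon[[a]])) {
      eps[a, b] <- y$epsilon[[a]][[b]]
      eps[b, a] <- y$epsilon[[a]][[b]]
    }
  }
  if (anyNA(eps)) stop("force field epsilon table is incomplete")
  if (any(eps < 0)) stop("epsilon must be >= 0")
  sig <- y$sigma
  if (length(sig) == 1) {
    sig <- matrix(as.numeric(sig), k, k, dimnames = list(classes, classes))
  } else stop("per-pair sigma maps not supported; give a single sigma")
  if (any(sig <= 0)) stop("sigma must be > 0")
  lw <- as.numeric(unlist(y$lj_window)); cw <- as.numeric(unlist(y$coul_window))
  if (lw[1] >= lw[2] || cw[1] >= cw[2]) stop("shift window lower must be < upper")
  if (y$eps_r <= 0) stop("eps_r must be > 0")
  structure(list(classes = classes, epsilon = eps, sigma = sig,
                 eps_r = y$eps_r, lj_window = lw, coul_window = cw),
            class = "mem_forcefield")
}

#' @rdname read_forcefield
#' @export
default_forcefield <- function() read_forcefield()

#' @export
print.mem_forcefield <- function(x, ...) {
  cat("<mem_forcefield> classes:", paste(x$classes, collapse = " "),
      sprintf("| eps_r = %g | LJ shift %g-%g A | Coulomb shift %g-%g A\n",
              x$eps_r, x$lj_window[1], x$lj_window[2],
              x$coul_window[1], x$coul_window[2]))
  invisible(x)
}

# shifted 1/r^p term (R reference implementation of the same polynomial
# the compiled engine uses): force F(r) = p/r^(p+1) + A(r-r1)^2 + B(r-r1)^3
# for r1 < r < rc, zero at and beyond rc with zero slope; energy is the
# integral, offset to vanish at rc.
.shifted_term <- function(r, p, r1, rc) {
  if (any(r <= 0)) stop("r must be > 0")
  d <- rc - r1
  A <- -p * ((p + 4) * rc - (p + 1) * r1) / (rc^(p + 2) * d^2)
  B <- p * ((p + 3) * rc - (p + 1) * r1) / (rc^(p + 2) * d^3)
  C <- 1 / rc^p - A / 3 * d^3 - B / 4 * d^4
  phi <- 1 / r^p - C
  f <- p / r^(p + 1)
  inwin <- r > r1 & r < rc
  s <- (r - r1)[inwin]
  phi[inwin] <- phi[inwin] - A / 3 * s^3 - B / 4 * s^4
  f[inwin] <- f[inwin] + A * s^2 + B * s^3
  phi[r >= rc] <- 0
  f[r >= rc] <- 0
  list(phi = phi, f = f)
}

#' Shifted 12-6 Lennard-Jones interaction
#'
#' Standard 12-6 LJ with both the r^-12 and r^-6 terms taken through the
#' shift polynomial over `window`, so the energy and the force go smoothly
#' (continuously, with continuous force) to exactly zero at the outer
#' cutoff.  Below the inner window edge the force is plain LJ and only the
#' energy offset applies.
#'
#' @param r distance(s), A (> 0)
#' @param epsilon well depth, kJ mol^-1
#' @param sigma contact distance, A
#' @param window shift window `c(lower, upper)` in A (default `c(9, 12)`)
#' @return list with `energy` (kJ mol^-1) and `force` (kJ mol^-1 A^-1,
#'   the scalar radial force `-dE/dr`)
#' @export
#' @examples
#' lj_shifted(12.5, 4, 4.7)   # beyond the cutoff: exactly zero
lj_shifted <- function(r, epsilon, sigma, window = c(9, 12)) {
  t12 <- .shifted_term(r, 12, window[1], window[2])
  t6 <- .shifted_term(r, 6, window[1], window[2])
  c12 <- 4 * epsilon * sigma^12
  c6 <- 4 * epsilon * sigma^6
  list(energy = c12 * t12$phi - c6 * t6$phi,
       force = c12 * t12$f - c6 * t6$f)
}

#' Shifted, dielectric-screened Coulomb interaction
#'
#' Coulomb energy `k_e q_i q_j / (eps_r r)` with the shift applied over
#' the whole `window` (default 0-12 A) so that energy and force vanish at
#' the outer cutoff.  The uniform relative dielectric (default 15)
#' implicitly screens electrostatics for a chargeless CG water model.
#'
#' @param r distance(s), A (> 0)
#' @param q_i,q_j charges in elementary charge units
#' @param eps_r relative dielectric constant (default 15)
#' @param window shift window in A (default `c(0, 12)`)
#' @return list with `energy` (kJ mol^-1) and `force` (kJ mol^-1 A^-1)
#' @export
coulomb_shifted <- function(r, q_i, q_j, eps_r = 15, window = c(0, 12)) {
  if (any(r <= 0)) stop("r must be > 0")
  if (q_i == 0 || q_j == 0)
    return(list(energy = rep(0, length(r)), force = rep(0, length(r))))
  t1 <- .shifted_term(r, 1, window[1], window[2])
  qq <- .COULOMB_K / eps_r * q_i * q_j
  list(energy = qq * t1$phi, force = qq * t1$f)
}
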