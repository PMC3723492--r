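# Central unit system: length in Angstrom, time in fs, mass in amu,
# energy in kJ/mol.  Derived units: velocity A/fs, force kJ/mol/A.
# 1 amu (A/fs)^2 == 1e4 kJ/mol exactly (amu * N_A = 1 g/mol).

#' Physical constants and unit conversions used throughout memscale
#'
#' All internal quantities use Angstrom / femtosecond / amu / kJ mol^-1.
#' `kB` is Boltzmann's constant in kJ mol^-1 K^-1; `KE_UNIT` converts
#' amu (A/fs)^2 to kJ mol^-1; `PRESSURE_UNIT` converts kJ mol^-1 A^-3 to
#' bar; `COULOMB_K` is the electrostatic constant in kJ mol^-1 A e^-2.
#'
#' @return A named list of constants.
#' @export
#' @examples
#' mem_constants()$kB
mem_constants <- function() {
  list(
    kB = 8.3144621e-3,        # kJ/mol/K
    KE_UNIT = 1e4,            # kJ/mol per amu*(A/fs)^2
    PRESSURE_UNIT = 16605.39, # bar per kJ/mol/A^3
    COULOMB_K = 1389.35458,   # kJ/mol * A / e^2
    AVOGADRO = 6.02214076e23
  )
}

.kB <- 8.3144621e-3
.KE_UNIT <- 1e4
.PRESSURE_UNIT <- 16605.39
.COULOMB_K <- 1389.35458

# atomic masses (amu) for elements that occur in protein/lipid/water systems
.ELEMENT_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, NA. = 22.990, CL = 35.45, K = 39.098, MG = 24.305,
  CA = 40.078, F = 18.998, FE = 55.845, ZN = 65.38, X = 0
)

.element_mass <- function(element) {
  el <- toupper(element)
  el[el == "NA"] <- "NA."
  m <- .ELEMENT_MASS[el]
  m[is.na(m)] <- 0
  unname(m)
}

# guess an element symbol from a PDB-style atom name
.guess_element <- function(name) {
  vapply(name, function(nm) {
    nm <- gsub("[0-9'\"*]", "", trimws(nm))
    if (nchar(nm) == 0) return("X")
    two <- toupper(substr(nm, 1, 2))
    if (two %in% c("NA", "CL", "MG", "FE", "ZN", "BR")) return(two)
    toupper(substr(nm, 1, 1))
  }, character(1), USE.NAMES = FALSE)
}
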