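# Physical constants (CODATA 2018; the SI-defining ones are exact) and the
# element table used for bond perception and RRHO thermochemistry.
#
# Unit policy: coordinates are always angstrom, energies always kcal/mol,
# entropies cal/(mol K), temperatures K. Conversions happen only at the I/O
# boundary (e.g. hartree input tables, cm^-1 frequencies).

.k_B      <- 1.380649e-23      # J K^-1
.h_planck <- 6.62607015e-34    # J s
.N_A      <- 6.02214076e23     # mol^-1
.c_light  <- 29979245800       # cm s^-1
.atm_Pa   <- 101325            # Pa
.cal_J    <- 4.184             # J cal^-1

.R_J    <- .k_B * .N_A                       # 8.31446261815324 J mol^-1 K^-1
.R_kcal <- .R_J / (1000 * .cal_J)            # 1.987204259e-3 kcal mol^-1 K^-1

# 1 cm^-1 of a harmonic mode as molar energy: h*c*N_A -> 2.85914e-3 kcal/mol
.cm1_kcal <- .h_planck * .c_light * .N_A / (1000 * .cal_J)

# 1 hartree = 4.3597447222071e-18 J (CODATA 2018)
.hartree_kcal <- 4.3597447222071e-18 * .N_A / (1000 * .cal_J)

#' Physical constants used throughout the package
#'
#' Returns the embedded CODATA 2018 constant set, mainly so that scripts and
#' tests can use exactly the same values as the package internals.
#'
#' @return Named list: `k_B` (J/K), `h` (J s), `N_A` (1/mol), `c` (cm/s),
#'   `R_J` (J/mol/K), `R_kcal` (kcal/mol/K), `cm1_kcal` (kcal/mol per
#'   cm^-1), `hartree_kcal` (kcal/mol per hartree), `atm_Pa` (Pa).
#' @examples
#' physical_constants()$R_kcal
#' @export
physical_constants <- function() {
  list(k_B = .k_B, h = .h_planck, N_A = .N_A, c = .c_light,
       R_J = .R_J, R_kcal = .R_kcal, cm1_kcal = .cm1_kcal,
       hartree_kcal = .hartree_kcal, atm_Pa = .atm_Pa)
}

# Covalent radii (angstrom, Cordero-type single-bond values) and standard
# atomic masses (g/mol). Enough main-group coverage for nucleic-acid /
# ester work plus the common heteroatoms.
.element_table <- data.frame(
  symbol = c("H",  "He", "Li", "Be", "B",  "C",  "N",  "O",  "F",  "Ne",
             "Na", "Mg", "Al", "Si", "P",  "S",  "Cl", "Ar", "K",  "Ca",
             "Fe", "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br",
             "Kr", "I"),
  r_cov  = c(0.31, 0.28, 1.28, 0.96, 0.84, 0.76, 0.71, 0.66, 0.57, 0.58,
             1.66, 1.41, 1.21, 1.11, 1.07, 1.05, 1.02, 1.06, 2.03, 1.76,
             1.32, 1.26, 1.24, 1.32, 1.22, 1.22, 1.20, 1.19, 1.20, 1.20,
             1.16, 1.39),
  mass   = c(1.008, 4.0026, 6.94, 9.0122, 10.81, 12.011, 14.007, 15.999,
             18.998403163, 20.180, 22.98976928, 24.305, 26.982, 28.085,
             30.973761998, 32.06, 35.45, 39.948, 39.098, 40.078,
             55.845, 58.933, 58.693, 63.546, 65.38, 69.723, 72.630,
             74.921595, 78.971, 79.904, 83.798, 126.90447),
  stringsAsFactors = FALSE
)

.normalize_element <- function(x) {
  x <- trimws(x)
  bad <- !nzchar(x)
  x <- paste0(toupper(substring(x, 1, 1)), tolower(substring(x, 2)))
  x[bad] <- NA_character_
  x
}

.known_element <- function(symbol) {
  .normalize_element(symbol) %in% .element_table$symbol
}

#' Covalent radius of an element
#'
#' @param symbol Character vector of element symbols (case-insensitive).
#' @return Numeric vector of covalent radii in angstrom.
#' @examples
#' covalent_radius(c("O", "H"))  # sums to ~0.97: the O-H bond criterion
#' @export
covalent_radius <- function(symbol) {
  s <- .normalize_element(symbol)
  i <- match(s, .element_table$symbol)
  if (anyNA(i)) {
    stop("no tabulated covalent radius for element(s): ",
         paste(unique(symbol[is.na(i)]), collapse = ", "))
  }
  .element_table$r_cov[i]
}

#' Standard atomic mass of an element
#'
#' @param symbol Character vector of element symbols (case-insensitive).
#' @return Numeric vector of masses in g/mol.
#' @export
atomic_mass <- function(symbol) {
  s <- .normalize_element(symbol)
  i <- match(s, .element_table$symbol)
  if (anyNA(i)) {
    stop("no tabulated atomic mass for element(s): ",
         paste(unique(symbol[is.na(i)]), collapse = ", "))
  }
  .element_table$mass[i]
}

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards, so generators are pure in (args, seed).
.with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
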