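# Ideal-gas rigid-rotor harmonic-oscillator (RRHO) thermochemistry:
# zero-point energies and thermal corrections that turn electronic energies
# plus harmonic frequencies into Gibbs free energies of activation.
#
# Standard state for the statistical-mechanics terms is the ideal gas at
# 1 atm. No quasi-harmonic raising/flooring of low frequencies is applied.

#' Construct a set of harmonic frequencies
#'
#' Wavenumbers in cm^-1; a negative entry encodes an imaginary mode. A
#' transition-state set must contain exactly one imaginary mode, a minimum
#' none.
#'
#' @param wavenumbers Numeric vector, cm^-1.
#' @param is_ts Is this a transition-state frequency set?
#' @return Object of class `"frequency_set"`.
#' @export
frequency_set <- function(wavenumbers, is_ts = FALSE) {
  wavenumbers <- as.numeric(wavenumbers)
  if (anyNA(wavenumbers)) stop("wavenumbers must be finite")
  n_imag <- sum(wavenumbers < 0)
  if (is_ts && n_imag != 1L) {
    stop("invalid TS frequency set: expected exactly 1 imaginary mode, got ",
         n_imag)
  }
  if (!is_ts && n_imag > 0L) {
    stop("minimum frequency set must not contain imaginary modes (got ",
         n_imag, "); pass is_ts = TRUE for a transition state")
  }
  structure(list(wavenumbers = wavenumbers, is_ts = is_ts),
            class = "frequency_set")
}

.as_frequency_set <- function(freqs) {
  if (inherits(freqs, "frequency_set")) return(freqs)
  frequency_set(as.numeric(freqs), is_ts = any(freqs < 0))
}

#' Harmonic zero-point energy
#'
#' `0.5 * h * c * sum(nu)` over the real (positive) modes only; the
#' imaginary mode of a transition state is excluded from the sum.
#'
#' @param freqs A [frequency_set()] or numeric wavenumber vector (cm^-1).
#' @return ZPE in kcal/mol.
#' @examples
#' zero_point_energy(1000)  # 1.4296 kcal/mol
#' @export
zero_point_energy <- function(freqs) {
  fs <- .as_frequency_set(freqs)
  nu <- fs$wavenumbers[fs$wavenumbers > 0]
  0.5 * .cm1_kcal * sum(nu)
}

#' RRHO thermal corrections
#'
#' Translational (Sackur-Tetrode, ideal gas at `pressure_atm`), rotational
#' (classical rigid rotor from the principal moments of inertia; monatomic
#' and linear cases handled) and vibrational (harmonic oscillator)
#' contributions to the enthalpy and entropy, combined into the Gibbs
#' correction that is added to an electronic energy.
#'
#' For a transition state the single imaginary mode is excluded from every
#' statistical sum. The thermal enthalpy includes the ZPE and the ideal-gas
#' `RT` term (H = U + RT).
#'
#' @param geom A `geometry` (element masses and coordinates are used).
#' @param freqs A [frequency_set()] or numeric wavenumber vector (cm^-1).
#' @param temperature Temperature in K (> 0); default 298.
#' @param pressure_atm Standard-state pressure in atm (default 1).
#' @param symmetry_number Rotational symmetry number (default 1).
#' @return Object of class `"thermo_result"`: `temperature`, `zpe`,
#'   `thermal_enthalpy` (kcal/mol), `entropy` (cal/mol/K),
#'   `gibbs_correction` (kcal/mol, `= thermal_enthalpy -
#'   temperature * entropy / 1000` exactly) and a per-term `breakdown`.
#' @export
rrho_corrections <- function(geom, freqs, temperature = 298,
                             pressure_atm = 1, symmetry_number = 1) {
  stopifnot(inherits(geom, "geometry"))
  if (!is.numeric(temperature) || temperature <= 0) {
    stop("temperature must be positive")
  }
  fs <- .as_frequency_set(freqs)
  T <- temperature
  n <- n_atoms(geom)
  m_amu <- atomic_mass(geom$elements)
  m_kg <- sum(m_amu) * 1e-3 / .N_A

  # translational: Sackur-Tetrode at the stated standard state
  p_Pa <- pressure_atm * .atm_Pa
  q_t <- (2 * pi * m_kg * .k_B * T / .h_planck^2)^1.5 * (.k_B * T / p_Pa)
  S_trans <- .R_J * (log(q_t) + 2.5)
  E_trans <- 1.5 * .R_J * T

  # rotational: from principal moments of inertia (kg m^2)
  if (n == 1L) {
    S_rot <- 0; E_rot <- 0; shape <- "atom"
  } else {
    mi <- m_amu * 1e-3 / .N_A
    xyz <- geom$coords * 1e-10
    com <- colSums(xyz * mi) / sum(mi)
    xc <- sweep(xyz, 2, com)
    Ixx <- sum(mi * (xc[, 2]^2 + xc[, 3]^2))
    Iyy <- sum(mi * (xc[, 1]^2 + xc[, 3]^2))
    Izz <- sum(mi * (xc[, 1]^2 + xc[, 2]^2))
    Ixy <- -sum(mi * xc[, 1] * xc[, 2])
    Ixz <- -sum(mi * xc[, 1] * xc[, 3])
    Iyz <- -sum(mi * xc[, 2] * xc[, 3])
    I <- matrix(c(Ixx, Ixy, Ixz, Ixy, Iyy, Iyz, Ixz, Iyz, Izz), 3, 3)
    ev <- sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values)
    if (ev[1] < 1e-6 * ev[3]) {  # linear molecule
      q_r <- 8 * pi^2 * ev[3] * .k_B * T / (symmetry_number * .h_planck^2)
      S_rot <- .R_J * (log(q_r) + 1)
      E_rot <- .R_J * T
      shape <- "linear"
    } else {
      q_r <- sqrt(pi * prod(ev)) / symmetry_number *
        (8 * pi^2 * .k_B * T / .h_planck^2)^1.5
      S_rot <- .R_J * (log(q_r) + 1.5)
      E_rot <- 1.5 * .R_J * T
      shape <- "nonlinear"
    }
  }

  # vibrational: harmonic oscillator over real modes, ZPE included in E
  nu <- fs$wavenumbers[fs$wavenumbers > 0]
  theta <- .h_planck * .c_light * nu / .k_B     # K
  x <- theta / T
  E_vib <- .R_J * sum(theta * (0.5 + 1 / expm1(x)))
  S_vib <- .R_J * sum(x / expm1(x) - log1p(-exp(-x)))

  zpe <- zero_point_energy(fs)
  H_kcal <- (E_trans + E_rot + E_vib + .R_J * T) / (1000 * .cal_J)
  S_cal <- (S_trans + S_rot + S_vib) / .cal_J
  structure(list(
    temperature = T,
    zpe = zpe,
    thermal_enthalpy = H_kcal,
    entropy = S_cal,
    gibbs_correction = H_kcal - T * S_cal / 1000,
    breakdown = list(
      shape = shape,
      n_imaginary_dropped = sum(fs$wavenumbers < 0),
      energy_kcal = c(translational = E_trans, rotational = E_rot,
                      vibrational = E_vib, pv = .R_J * T) / (1000 * .cal_J),
      entropy_cal = c(translational = S_trans, rotational = S_rot,
                      vibrational = S_vib) / .cal_J)
  ), class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat("<thermo_result> T =", x$temperature, "K\n")
  cat(sprintf("  ZPE %.4f  H_corr %.4f kcal/mol  S %.4f cal/mol/K  G_corr %.4f kcal/mol\n",
              x$zpe, x$thermal_enthalpy, x$entropy, x$gibbs_correction))
  invisible(x)
}

#' Gibbs free energy of a species
#'
#' @param electronic_energy Electronic (+ solvation, if any) energy in
#'   kcal/mol.
#' @param thermo A `thermo_result` for the species.
#' @return G in kcal/mol.
#' @export
gibbs_free_energy <- function(electronic_energy, thermo) {
  stopifnot(inherits(thermo, "thermo_result"), is.finite(electronic_energy))
  electronic_energy + thermo$gibbs_correction
}

#' Activation free energy
#'
#' `dG_act = G(TS) - G(reactants)`. The sign is preserved; a negative
#' barrier triggers a warning, not an error.
#'
#' @param g_reactants,g_ts Gibbs free energies in kcal/mol.
#' @return dG_act in kcal/mol.
#' @export
activation_free_energy <- function(g_reactants, g_ts) {
  if (!is.finite(g_reactants) || !is.finite(g_ts)) {
    stop("free energies must be finite")
  }
  dg <- g_ts - g_reactants
  if (dg < 0) warning("negative activation free energy (", signif(dg, 4),
                      " kcal/mol)")
  dg
}
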