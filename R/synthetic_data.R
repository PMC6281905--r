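# Seeded synthetic-fixture generators. These stand in for the outputs of
# electronic-structure calculations (optimized geometries, harmonic
# frequencies, single-point energy sets) with machine-readable ground truth,
# so that every pipeline stage is testable without any external download.
# All generators are pure functions of (parameters, seed).
#
# The reactant/TS internal coordinates embedded in the ester generators are
# the published tetrahedral-ester and trigonal-bipyramidal-TS values for
# each class and central atom (angstrom, degrees); the generated structures
# are synthetic stand-ins that reproduce exactly those asserted parameters,
# with 0.01-angstrom uniform jitter on every non-asserted coordinate.

# class -> central -> named reactant ("r") and TS ("ts") parameters.
# dOL: center to bridging/leaving oxygen (O1' for class 1B, O3' for 2);
# dO5: second bridging oxygen (class 2 only); dOp: proton-capturing oxygen;
# ang: O_L-E-O_p (classes 1A/1B) or O3'-E-O5' (class 2); dW: forming
# bond to the water oxygen in the TS.
.ester_params <- list(
  "1A" = list(
    P  = list(r = c(dOL = 1.64, dOp = 1.48, ang = 108.27),
              ts = c(dOL = 1.68, dOp = 1.58, ang = 93.39, dW = 1.90)),
    As = list(r = c(dOL = 1.76, dOp = 1.63, ang = 109.65),
              ts = c(dOL = 1.77, dOp = 1.70, ang = 99.13, dW = 2.05))),
  "1B" = list(
    P  = list(r = c(dOL = 1.63, dOp = 1.48, ang = 106.08),
              ts = c(dOL = 1.67, dOp = 1.57, ang = 94.10, dW = 1.90)),
    As = list(r = c(dOL = 1.76, dOp = 1.62, ang = 106.59),
              ts = c(dOL = 1.79, dOp = 1.69, ang = 95.64, dW = 2.05))),
  "2" = list(
    P  = list(r = c(dOL = 1.64, dO5 = 1.63, dOp = 1.48, ang = 101.00),
              ts = c(dOL = 1.67, dO5 = 1.62, dOp = 1.59, ang = 97.33,
                     dW = 1.90)),
    As = list(r = c(dOL = 1.77, dO5 = 1.76, dOp = 1.63, ang = 100.47),
              ts = c(dOL = 1.78, dO5 = 1.75, dOp = 1.71, ang = 97.23,
                     dW = 2.05)))
)

.deg <- pi / 180

# three unit vectors at the tetrahedral angle from `axis`, splayed 120
# degrees apart around it
.tetra_dirs <- function(axis) {
  a <- axis / sqrt(sum(axis^2))
  p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- p - sum(p * a) * a
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(a[2] * e1[3] - a[3] * e1[2],
          a[3] * e1[1] - a[1] * e1[3],
          a[1] * e1[2] - a[2] * e1[1])
  th <- (180 - 109.47) * .deg
  t(vapply(c(0, 2 * pi / 3, 4 * pi / 3), function(phi) {
    cos(th) * a + sin(th) * (cos(phi) * e1 + sin(phi) * e2)
  }, numeric(3)))
}

# unit vector at ~115 degrees from the reverse of bond_dir: direction in
# which a chain continues past an atom reached along bond_dir
.continue_dir <- function(bond_dir) {
  a <- bond_dir / sqrt(sum(bond_dir^2))
  p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- p - sum(p * a) * a
  e1 <- e1 / sqrt(sum(e1^2))
  cos(65 * .deg) * a + sin(65 * .deg) * e1
}

.jitter <- function(coords, rows, amount = 0.01) {
  if (length(rows)) {
    coords[rows, ] <- coords[rows, ] +
      matrix(stats::runif(3 * length(rows), -amount, amount),
             length(rows), 3)
  }
  coords
}

# shared construction of the ester skeleton; state = "r" or "ts"
.build_ester <- function(central, ester_class, anionic, state) {
  par <- .ester_params[[ester_class]][[central]][[state]]
  ang <- par[["ang"]] * .deg
  el <- central; nm <- if (central == "P") "P" else "AS"
  xyz <- matrix(0, 1, 3)
  add <- function(e, n, p) {
    el <<- c(el, e); nm <<- c(nm, n); xyz <<- rbind(xyz, p)
  }
  if (ester_class == "2") {
    # bridging O3' along +z, bridging O5' at the table angle, then O_p
    add("O", "O3'", c(0, 0, par[["dOL"]]))
    add("O", "O5'", par[["dO5"]] * c(sin(ang), 0, cos(ang)))
    b <- 109.47 * .deg
    add("O", "OP", par[["dOp"]] *
          c(sin(b) * cos(3 * pi / 4), sin(b) * sin(3 * pi / 4), cos(b)))
    add("O", "OX1", par[["dOp"]] *
          c(sin(b) * cos(5 * pi / 4), sin(b) * sin(5 * pi / 4), cos(b)))
    asserted <- 1:4
    # methyl scaffolds beyond both bridging oxygens
    for (ob in 2:3) {
      v <- .continue_dir(xyz[ob, ])
      ci <- nrow(xyz) + 1L
      add("C", paste0("C", ob), xyz[ob, ] + 1.43 * v)
      hd <- .tetra_dirs(v)
      for (k in 1:3) add("H", paste0("H", ob, k), xyz[ci, ] + 1.09 * hd[k, ])
    }
  } else {
    add("O", if (ester_class == "1A") "OL" else "O1'", c(0, 0, par[["dOL"]]))
    add("O", "OP", par[["dOp"]] * c(sin(ang), 0, cos(ang)))
    b <- 109.47 * .deg
    add("O", "OX1", par[["dOp"]] *
          c(sin(b) * cos(2 * pi / 3), sin(b) * sin(2 * pi / 3), cos(b)))
    add("O", "OX2", par[["dOp"]] *
          c(sin(b) * cos(4 * pi / 3), sin(b) * sin(4 * pi / 3), cos(b)))
    asserted <- 1:3
    v <- .continue_dir(xyz[2, ])
    if (ester_class == "1A") {
      p2 <- nrow(xyz) + 1L
      add("P", "P2", xyz[2, ] + 1.64 * v)
      hd <- .tetra_dirs(v)
      for (k in 1:3) add("O", paste0("OT", k), xyz[p2, ] + 1.52 * hd[k, ])
    } else {
      c1 <- nrow(xyz) + 1L
      add("C", "C1", xyz[2, ] + 1.43 * v)
      hd <- .tetra_dirs(v)
      for (k in 1:3) add("H", paste0("H1", k), xyz[c1, ] + 1.09 * hd[k, ])
    }
  }
  if (state == "ts") {
    # attacking water opposite the first bridging oxygen (in-line axial)
    ow <- nrow(xyz) + 1L
    add("O", "OW", c(0, 0, -par[["dW"]]))
    for (k in 1:2) {
      phi <- c(0, 2 * pi / 3)[k]
      add("H", paste0("HW", k),
          xyz[ow, ] + 0.96 * c(sin(110 * .deg) * cos(phi),
                               sin(110 * .deg) * sin(phi),
                               -cos(70 * .deg)))
    }
    asserted <- c(asserted, ow)
  }
  list(elements = el, names = nm, coords = xyz, asserted = asserted,
       par = par)
}

#' Print method for fixture bundles
#' @param x A `fixture_bundle`.
#' @param ... Ignored.
#' @export
print.fixture_bundle <- function(x, ...) {
  cat("<fixture_bundle>", x$kind, " seed", x$seed, "\n")
  cat("  ground truth:", paste(names(x$ground_truth), collapse = ", "),
      "\n")
  invisible(x)
}

#' Generate an idealized tetrahedral ester reactant
#'
#' Builds a synthetic monoester or diester with the published
#' class-specific bond lengths and valence angle around the central As/P
#' atom, a class-appropriate leaving-group scaffold (a second phosphate
#' group for class 1A, a carbon scaffold for 1B and 2), and 0.01-angstrom
#' jitter on all non-asserted coordinates.
#'
#' @param central `"P"` or `"As"`.
#' @param ester_class `"1A"`, `"1B"` or `"2"`.
#' @param anionic `"mono"` (charge -1) or `"di"` (charge -2). Class 2
#'   diesters exist only in monoanionic form.
#' @param seed Integer seed.
#' @return A `fixture_bundle` with elements `geometry`, `ground_truth`
#'   (classification fields plus the asserted internal coordinates and
#'   their atom indices), `seed`.
#' @export
make_ideal_ester <- function(central = c("P", "As"),
                             ester_class = c("1A", "1B", "2"),
                             anionic = c("di", "mono"), seed = 1) {
  central <- match.arg(central)
  ester_class <- match.arg(ester_class)
  anionic <- match.arg(anionic)
  if (ester_class == "2" && anionic == "di") {
    stop("class 2 diesters have a single ionizable oxygen and exist only ",
         "in monoanionic form")
  }
  .with_seed(seed, {
    b <- .build_ester(central, ester_class, anionic, "r")
    co <- .jitter(b$coords, setdiff(seq_len(nrow(b$coords)), b$asserted))
    geom <- geometry(b$elements, co, name = b$names,
                     charge = if (anionic == "mono") -1L else -2L,
                     label = sprintf("%s ester class %s (%sanionic)",
                                     central, ester_class, anionic),
                     role = "reactant")
    gt <- list(
      ester_class = ester_class,
      ester_type = if (ester_class == "2") "diester" else "monoester",
      leaving_group_pattern = if (ester_class == "1A") "O-P-R" else "O-C-R",
      central_atom = central, anionic_state = anionic,
      charge = geom$charge, center_index = 1L,
      d_E_OL = unname(b$par[["dOL"]]), d_E_Op = unname(b$par[["dOp"]]),
      angle = unname(b$par[["ang"]]),
      indices = list(E = 1L, OL = 2L,
                     Op = if (ester_class == "2") 4L else 3L))
    if (ester_class == "2") {
      gt$d_E_O5 <- unname(b$par[["dO5"]])
      gt$indices$O5 <- 3L
      a <- b$par[["ang"]] * .deg
      gt$d_O3_O5 <- sqrt(b$par[["dOL"]]^2 + b$par[["dO5"]]^2 -
                           2 * b$par[["dOL"]] * b$par[["dO5"]] * cos(a))
    }
    structure(list(kind = "ideal_ester", geometry = geom,
                   ground_truth = gt, seed = seed),
              class = "fixture_bundle")
  })
}

#' Generate a paired reactant / trigonal-bipyramidal TS fixture
#'
#' The transition-state analogue of [make_ideal_ester()]: a
#' five-coordinate center with the attacking water oxygen axial (in line
#' with the first bridging oxygen) and the published TS bond lengths and
#' angle, paired with the matching reactant. The reactant-to-TS changes of
#' the asserted parameters are stored as ground truth, and a harmonic
#' frequency set with exactly one imaginary mode is attached to the TS.
#'
#' @inheritParams make_ideal_ester
#' @return A `fixture_bundle` with `reactant`, `ts` (geometries),
#'   `frequencies` (list with `reactant` and `ts` [frequency_set()]s) and
#'   `ground_truth` (per-parameter reactant/ts/delta plus atom indices).
#' @export
make_ts_like <- function(central = c("P", "As"),
                         ester_class = c("1A", "1B", "2"),
                         anionic = c("di", "mono"), seed = 1) {
  central <- match.arg(central)
  ester_class <- match.arg(ester_class)
  anionic <- match.arg(anionic)
  if (ester_class == "2" && anionic == "di") {
    stop("class 2 diesters have a single ionizable oxygen and exist only ",
         "in monoanionic form")
  }
  .with_seed(seed, {
    br <- .build_ester(central, ester_class, anionic, "r")
    bt <- .build_ester(central, ester_class, anionic, "ts")
    cr <- .jitter(br$coords, setdiff(seq_len(nrow(br$coords)), br$asserted))
    ct <- .jitter(bt$coords, setdiff(seq_len(nrow(bt$coords)), bt$asserted))
    chg <- if (anionic == "mono") -1L else -2L
    lab <- sprintf("%s ester class %s (%sanionic)", central, ester_class,
                   anionic)
    reac <- geometry(br$elements, cr, name = br$names, charge = chg,
                     label = lab, role = "reactant")
    ts <- geometry(bt$elements, ct, name = bt$names, charge = chg,
                   label = paste(lab, "TS"), role = "transition_state")
    nr <- nrow(cr); nt <- nrow(ct)
    f_r <- frequency_set(sort(stats::runif(3 * nr - 6, 100, 3500)))
    f_t <- frequency_set(c(-stats::runif(1, 300, 600),
                           sort(stats::runif(3 * nt - 7, 100, 3500))),
                         is_ts = TRUE)
    pr <- br$par; pt <- bt$par
    param <- data.frame(
      name = c("d_E_OL", "d_E_Op", "angle"),
      reactant = unname(c(pr[["dOL"]], pr[["dOp"]], pr[["ang"]])),
      ts = unname(c(pt[["dOL"]], pt[["dOp"]], pt[["ang"]])),
      stringsAsFactors = FALSE)
    if (ester_class == "2") {
      param <- rbind(param, data.frame(
        name = "d_E_O5", reactant = unname(pr[["dO5"]]),
        ts = unname(pt[["dO5"]]), stringsAsFactors = FALSE))
    }
    param$delta <- param$ts - param$reactant
    gt <- list(params = param,
               indices = list(E = 1L, OL = 2L,
                              Op = if (ester_class == "2") 4L else 3L,
                              O5 = if (ester_class == "2") 3L else NULL,
                              OW_ts = which(bt$names == "OW")),
               central_atom = central, ester_class = ester_class,
               anionic_state = anionic)
    structure(list(kind = "ts_pair", reactant = reac, ts = ts,
                   frequencies = list(reactant = f_r, ts = f_t),
                   ground_truth = gt, seed = seed),
              class = "fixture_bundle")
  })
}

#' Generate a fragment-energy set with prescribed strain decomposition
#'
#' Draws random fragment equilibrium energies and splits the prescribed
#' distortion across fragments (non-negative shares), then fixes the
#' supersystem TS energy so that the interaction term matches. The
#' decomposition recovers the targets to floating-point rounding.
#'
#' @param target_distortion Total distortion energy, kcal/mol (>= 0).
#' @param target_interaction Interaction energy, kcal/mol.
#' @param n_fragments Number of fragments (>= 2; default 2, ester +
#'   water).
#' @param seed Integer seed.
#' @return A `fixture_bundle` with `fragment_energies` and `ground_truth`
#'   (`distortion`, `interaction`, `activation`, `per_fragment`).
#' @export
make_fragment_energies <- function(target_distortion, target_interaction,
                                   n_fragments = 2, seed = 1) {
  if (!is.finite(target_distortion) || target_distortion < 0) {
    stop("target_distortion must be finite and non-negative")
  }
  if (!is.finite(target_interaction)) {
    stop("target_interaction must be finite")
  }
  n_fragments <- as.integer(n_fragments)
  if (n_fragments < 2L) stop("at least two fragments required")
  .with_seed(seed, {
    e_eq <- stats::runif(n_fragments, -120, -40)
    if (target_distortion == 0) {
      d <- rep(0, n_fragments)
    } else {
      cuts <- sort(stats::runif(n_fragments - 1))
      d <- diff(c(0, cuts, 1)) * target_distortion
      d[n_fragments] <- target_distortion - sum(d[-n_fragments])
    }
    e_ts <- e_eq + d
    labels <- if (n_fragments == 2L) c("ester", "water")
    else paste0("fragment_", seq_len(n_fragments))
    fe <- fragment_energies(
      e_supersystem_ts = sum(e_ts) + target_interaction,
      fragments = data.frame(label = labels, e_ts_geometry = e_ts,
                             e_equilibrium = e_eq,
                             stringsAsFactors = FALSE))
    structure(list(kind = "fragment_energies", fragment_energies = fe,
                   ground_truth = list(
                     distortion = target_distortion,
                     interaction = target_interaction,
                     activation = target_distortion + target_interaction,
                     per_fragment = stats::setNames(d, labels)),
                   seed = seed),
              class = "fixture_bundle")
  })
}

# Independent closed-form RRHO Gibbs correction (kcal/mol) used by the
# thermo-species generator to solve for the TS electronic energy; written
# separately from rrho_corrections() so the generator does not depend on
# the code path it is meant to test.
.rrho_reference <- function(masses_amu, coords, wavenumbers, temperature,
                            pressure_atm = 1, sigma = 1) {
  T <- temperature
  kB <- 1.380649e-23; h <- 6.62607015e-34; NA_ <- 6.02214076e23
  c_cm <- 29979245800; R <- kB * NA_
  M <- sum(masses_amu) * 1e-3 / NA_
  p <- pressure_atm * 101325
  S <- R * (1.5 * log(2 * pi * M * kB * T) - 3 * log(h) +
              log(kB * T / p) + 2.5)
  E <- 1.5 * R * T
  if (length(masses_amu) > 1L) {
    mi <- masses_amu * 1e-3 / NA_
    x <- sweep(coords * 1e-10, 2, colSums(coords * 1e-10 * mi) / sum(mi))
    Imat <- matrix(0, 3, 3)
    for (k in seq_along(mi)) {
      r2 <- sum(x[k, ]^2)
      Imat <- Imat + mi[k] * (diag(rep(r2, 3)) - outer(x[k, ], x[k, ]))
    }
    ev <- sort(eigen(Imat, symmetric = TRUE, only.values = TRUE)$values)
    if (ev[1] < 1e-6 * ev[3]) {
      S <- S + R * (log(8 * pi^2 * ev[3] * kB * T / (sigma * h^2)) + 1)
      E <- E + R * T
    } else {
      S <- S + R * (log(sqrt(pi * prod(ev)) / sigma) +
                      1.5 * log(8 * pi^2 * kB * T / h^2) + 1.5)
      E <- E + 1.5 * R * T
    }
  }
  nu <- wavenumbers[wavenumbers > 0]
  u <- h * c_cm * nu / (kB * T)
  E <- E + R * T * sum(u * (0.5 + 1 / (exp(u) - 1)))
  S <- S + R * sum(u / (exp(u) - 1) - log(1 - exp(-u)))
  H <- E + R * T
  (H - T * S) / 4184
}

#' Generate reactant/TS species with a prescribed activation free energy
#'
#' Draws small rigid reactant and TS geometries with random harmonic
#' frequency sets (one imaginary mode for the TS), computes both RRHO
#' Gibbs corrections with an internal closed-form evaluation, and solves
#' for the TS electronic energy such that the full
#' frequencies-to-free-energy pipeline reproduces `target_dg_act`.
#'
#' @param target_dg_act Prescribed activation free energy, kcal/mol.
#' @param temperature Temperature in K (default 298).
#' @param seed Integer seed.
#' @return A `fixture_bundle` with `reactant` and `ts` sublists
#'   (`geometry`, `frequencies`, `electronic_energy` in kcal/mol) and
#'   `ground_truth` (`dg_act`, `temperature`).
#' @export
make_thermo_species <- function(target_dg_act, temperature = 298,
                                seed = 1) {
  if (!is.finite(target_dg_act)) stop("target_dg_act must be finite")
  .with_seed(seed, {
    base_r <- rbind(c(0, 0, 0), c(1.6, 0, 0), c(-0.5, 1.5, 0),
                    c(-0.5, -0.7, 1.4))
    base_t <- rbind(base_r, c(-0.5, -0.7, -1.4))
    co_r <- .jitter(base_r, seq_len(nrow(base_r)))
    co_t <- .jitter(base_t, seq_len(nrow(base_t)))
    g_r <- geometry(c("P", "O", "O", "O"), co_r, charge = -1L,
                    label = "thermo fixture reactant", role = "reactant")
    g_t <- geometry(c("P", "O", "O", "O", "O"), co_t, charge = -1L,
                    label = "thermo fixture TS", role = "transition_state")
    f_r <- frequency_set(sort(stats::runif(3 * 4 - 6, 200, 3200)))
    f_t <- frequency_set(c(-stats::runif(1, 300, 600),
                           sort(stats::runif(3 * 5 - 7, 200, 3200))),
                         is_ts = TRUE)
    gc_r <- .rrho_reference(atomic_mass(g_r$elements), g_r$coords,
                            f_r$wavenumbers, temperature)
    gc_t <- .rrho_reference(atomic_mass(g_t$elements), g_t$coords,
                            f_t$wavenumbers, temperature)
    e_r <- stats::runif(1, -500, -400)
    e_t <- e_r + target_dg_act - (gc_t - gc_r)
    structure(list(kind = "thermo_species",
                   reactant = list(geometry = g_r, frequencies = f_r,
                                   electronic_energy = e_r),
                   ts = list(geometry = g_t, frequencies = f_t,
                             electronic_energy = e_t),
                   ground_truth = list(dg_act = target_dg_act,
                                       temperature = temperature),
                   seed = seed),
              class = "fixture_bundle")
  })
}

#' Generate a simplified single-stranded sugar-phosphate model
#'
#' Builds an n-residue single strand with a simplified three-carbon sugar
#' (C5'-C4'-C3', all sp3), O5'/O3' bridging oxygens, a placeholder base
#' nitrogen on C4', and a tetrahedral P or As center with two terminal
#' oxygens between consecutive residues, following PDB naming and residue
#' numbering (the bridging center belongs to the following residue). The
#' backbone is laid out as an extended zigzag so that covalent-radius bond
#' perception recovers exactly the intended connectivity.
#'
#' @param n_residues Number of residues (>= 2).
#' @param central_elements Character vector (length `n_residues - 1`) of
#'   bridging centers, `"P"` or `"As"`; default all `"P"`.
#' @param bases Residue names, recycled; default `c("DT", "DT", "DA",
#'   "DA")`, giving the d(TpTpApA)-style strand for `n_residues = 4`.
#' @param seed Integer seed (0.01-angstrom coordinate jitter).
#' @return A `fixture_bundle` with `geometry` and `ground_truth`
#'   (`residue_atom_counts`, `center_indices`, `n_linkages`,
#'   `central_elements`, `residue_names`).
#' @export
make_mock_strand <- function(n_residues = 4, central_elements = NULL,
                             bases = c("DT", "DT", "DA", "DA"), seed = 1) {
  n_residues <- as.integer(n_residues)
  if (n_residues < 2L) stop("a strand needs at least 2 residues")
  if (is.null(central_elements)) {
    central_elements <- rep("P", n_residues - 1L)
  }
  central_elements <- .normalize_element(central_elements)
  if (length(central_elements) != n_residues - 1L ||
      !all(central_elements %in% c("P", "As"))) {
    stop("central_elements must be length n_residues - 1, each 'P' or 'As'")
  }
  bases <- rep_len(bases, n_residues)
  .with_seed(seed, {
    # backbone heavy-atom chain: O5' C5' C4' C3' O3' [E] per residue
    kinds <- character(0)
    for (i in seq_len(n_residues)) {
      kinds <- c(kinds, "O5'", "C5'", "C4'", "C3'", "O3'",
                 if (i < n_residues) "E")
    }
    blen <- function(a, b) {
      if (a == "E" || b == "E") 1.60
      else if ((a == "O5'" && b == "C5'") || (a == "C3'" && b == "O3'"))
        1.43
      else 1.53
    }
    nb <- length(kinds)
    pos <- matrix(0, nb, 3)
    alpha <- 35 * .deg
    dirs <- matrix(0, nb, 3)  # step direction used to reach atom k
    for (k in 2:nb) {
      u <- c(cos(alpha), ifelse(k %% 2 == 0, sin(alpha), -sin(alpha)), 0)
      pos[k, ] <- pos[k - 1, ] + blen(kinds[k - 1], kinds[k]) * u
      dirs[k, ] <- u
    }
    # assemble atoms residue by residue
    el <- character(0); nm <- character(0); rs <- integer(0)
    xyz <- matrix(0, 0, 3)
    add <- function(e, n, resno, p) {
      el <<- c(el, e); nm <<- c(nm, n); rs <<- c(rs, resno)
      xyz <<- rbind(xyz, p)
    }
    bb_index <- function(res, kind) {
      which(kinds == kind)[res]
    }
    center_pos <- which(kinds == "E")
    for (i in seq_len(n_residues)) {
      if (i > 1L) {
        e_i <- center_pos[i - 1L]
        pe <- pos[e_i, ]
        ce <- central_elements[i - 1L]
        # terminal oxygens on the side opposite the backbone neighbours
        q <- sign(dirs[e_i, 2])
        if (q == 0) q <- 1
        add(ce, if (ce == "P") "P" else "AS", i, pe)
        add("O", "OP1", i, pe + c(0, q * 0.9, 1.32))
        add("O", "OP2", i, pe + c(0, q * 0.9, -1.32))
      }
      p5 <- pos[bb_index(i, "O5'"), ]
      add("O", "O5'", i, p5)
      if (i == 1L) {
        add("H", "HO5'", i, p5 + 0.96 * c(-cos(alpha), sin(alpha), 0))
      }
      pc5 <- pos[bb_index(i, "C5'"), ]
      add("C", "C5'", i, pc5)
      add("H", "H5'", i, pc5 + c(0, 0, 1.09))
      add("H", "H5''", i, pc5 + c(0, 0, -1.09))
      pc4 <- pos[bb_index(i, "C4'"), ]
      add("C", "C4'", i, pc4)
      add("H", "H4'", i, pc4 + c(0, 0, 1.09))
      pn <- pc4 + c(0, 0, -1.45)
      add("N", "N1", i, pn)
      add("H", "HN1", i, pn + c(0.95, 0, -0.35))
      add("H", "HN2", i, pn + c(-0.95, 0, -0.35))
      pc3 <- pos[bb_index(i, "C3'"), ]
      add("C", "C3'", i, pc3)
      add("H", "H3'", i, pc3 + c(0, 0, 1.09))
      add("H", "H3''", i, pc3 + c(0, 0, -1.09))
      p3 <- pos[bb_index(i, "O3'"), ]
      add("O", "O3'", i, p3)
      if (i == n_residues) {
        add("H", "HO3'", i, p3 + 0.96 * c(cos(alpha),
                                          ifelse(nb %% 2 == 0,
                                                 -sin(alpha), sin(alpha)),
                                          0))
      }
    }
    xyz <- .jitter(xyz, seq_len(nrow(xyz)))
    geom <- geometry(el, xyz, name = nm,
                     residue_name = bases[rs], residue_number = rs,
                     chain_id = "A", charge = -(n_residues - 1L),
                     label = sprintf("mock %d-residue strand", n_residues),
                     role = "reference")
    centers <- which(nm %in% c("P", "AS"))
    gt <- list(residue_atom_counts = as.integer(table(rs)),
               center_indices = centers,
               n_linkages = n_residues - 1L,
               central_elements = central_elements,
               residue_names = bases)
    structure(list(kind = "mock_strand", geometry = geom,
                   ground_truth = gt, seed = seed),
              class = "fixture_bundle")
  })
}
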