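# Independent oracles and small constructors shared by the test files.
# Each oracle is a separate implementation of the quantity it checks and
# never calls the code path under test.

# random proper rotation matrix (det +1)
rand_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# random plausible geometry for IO round-trips
rand_geometry <- function(n = 8, elements = c("H", "C", "N", "O", "P", "As")) {
  geometry(sample(elements, n, replace = TRUE),
           matrix(runif(3 * n, -12, 12), n, 3),
           label = "random fixture")
}

# second, independent dihedral implementation: Gram-Schmidt projection of
# the outer bonds onto the plane normal to the axis, atan2 of the planar
# components (IUPAC sign convention)
dihedral_oracle <- function(p1, p2, p3, p4) {
  a1 <- p1 - p2   # from the axis toward the front substituent
  axis <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  b3 <- p4 - p3   # from the axis toward the rear substituent
  v <- a1 - sum(a1 * axis) * axis
  w <- b3 - sum(b3 * axis) * axis
  cross_av <- c(axis[2] * v[3] - axis[3] * v[2],
                axis[3] * v[1] - axis[1] * v[3],
                axis[1] * v[2] - axis[2] * v[1])
  ang <- atan2(sum(cross_av * w), sum(v * w)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# independent brute-force ester classifier: builds its own adjacency from
# raw coordinates with its own radius table and matches the O-bridge
# patterns directly
classify_oracle <- function(geom) {
  radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, P = 1.07, As = 1.19)
  n <- n_atoms(geom)
  adj <- vector("list", n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((geom$coords[i, ] - geom$coords[j, ])^2))
      if (d <= 1.15 * (radii[[geom$elements[i]]] +
                       radii[[geom$elements[j]]])) {
        adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
      }
    }
  }
  centers <- which(geom$elements %in% c("As", "P"))
  n_o <- sapply(centers, function(i) sum(geom$elements[adj[[i]]] == "O"))
  ctr <- centers[n_o == max(n_o)][1]
  bridge_to <- character(0)
  for (o in adj[[ctr]]) {
    if (geom$elements[o] != "O") next
    nbr <- setdiff(adj[[o]], ctr)
    nbr <- nbr[!geom$elements[nbr] %in% "H"]
    if (length(nbr)) bridge_to <- c(bridge_to, geom$elements[nbr[1]])
  }
  if (length(bridge_to) == 1L) {
    list(ester_class = if (bridge_to == "P") "1A" else "1B",
         ester_type = "monoester", center = ctr)
  } else if (length(bridge_to) == 2L && all(bridge_to == "C")) {
    list(ester_class = "2", ester_type = "diester", center = ctr)
  } else {
    stop("oracle: unsupported pattern")
  }
}

# closed-form RRHO for a diatomic at 1 atm (translational Sackur-Tetrode,
# classical linear rotor, one harmonic mode); all outputs kcal/cal units
rrho_diatomic_oracle <- function(m1_amu, m2_amu, d_angstrom, nu_cm,
                                 temperature, sigma = 1) {
  cst <- physical_constants()
  T <- temperature
  M <- (m1_amu + m2_amu) * 1e-3 / cst$N_A
  S_t <- cst$R_J * (log((2 * pi * M * cst$k_B * T / cst$h^2)^1.5 *
                          cst$k_B * T / cst$atm_Pa) + 2.5)
  mu <- (m1_amu * m2_amu / (m1_amu + m2_amu)) * 1e-3 / cst$N_A
  I <- mu * (d_angstrom * 1e-10)^2
  S_r <- cst$R_J * (log(8 * pi^2 * I * cst$k_B * T /
                          (sigma * cst$h^2)) + 1)
  u <- cst$h * cst$c * nu_cm / (cst$k_B * T)
  S_v <- cst$R_J * (u / (exp(u) - 1) - log(1 - exp(-u)))
  E <- 1.5 * cst$R_J * T + cst$R_J * T +
    cst$R_J * T * u * (0.5 + 1 / (exp(u) - 1))
  H <- (E + cst$R_J * T) / 4184
  S <- (S_t + S_r + S_v) / 4.184
  list(zpe = 0.5 * nu_cm * cst$cm1_kcal, thermal_enthalpy = H,
       entropy = S, gibbs_correction = H - T * S / 1000)
}

# 20-atom phosphate-capped pentyl chain used for brute-force cut-set
# enumeration: P(-O_t)2-O-C1H2-C2H2-C3H2-C4H2-C5H3
chain_fixture <- function() {
  el <- c("P", "O", "O", "O", rep(c("C", "H", "H"), 4), "C", "H", "H", "H")
  xyz <- rbind(
    c(0.0, 0.0, 0.0),     # P
    c(1.60, 0.0, 0.0),    # bridging O
    c(-0.5, 1.40, 0.0),   # terminal O
    c(-0.5, -0.9, 1.1),   # terminal O
    NULL)
  for (i in 1:4) {
    cx <- 1.60 + 1.43 + 1.5 * (i - 1)
    xyz <- rbind(xyz, c(cx, 0, 0), c(cx, 0.9, 0.6), c(cx, -0.9, 0.6))
  }
  c5 <- 1.60 + 1.43 + 1.5 * 4
  xyz <- rbind(xyz, c(c5, 0, 0), c(c5, 0.9, 0.6), c(c5, -0.9, 0.6),
               c(c5 + 1.08, 0, 0))
  geometry(el, xyz, charge = -2L, label = "pentyl phosphate chain")
}

# brute-force minimal admissible QM region: enumerates every subset of
# eligible sp3 C-C cut bonds and keeps the smallest center component whose
# boundary uses only eligible bonds
oniom_bruteforce <- function(geom, bonds, center, min_graph_distance = 4) {
  n <- bonds$n
  deg <- lengths(bonds$adjacency)
  dist_c <- local({
    d <- rep(Inf, n); d[center] <- 0; fr <- center
    while (length(fr)) {
      nx <- integer(0)
      for (v in fr) for (w in bonds$adjacency[[v]])
        if (is.infinite(d[w])) { d[w] <- d[v] + 1; nx <- c(nx, w) }
      fr <- nx
    }
    d
  })
  sp3c <- geom$elements == "C" & deg == 4L
  cand <- NULL
  for (i in which(sp3c)) for (j in bonds$adjacency[[i]]) {
    if (j > i && sp3c[j] && dist_c[i] > min_graph_distance &&
        dist_c[j] > min_graph_distance) cand <- rbind(cand, c(i, j))
  }
  comp <- function(cut_rows) {
    blocked <- if (length(cut_rows)) cand[cut_rows, , drop = FALSE]
    else matrix(0L, 0, 2)
    key <- c(paste(blocked[, 1], blocked[, 2]),
             paste(blocked[, 2], blocked[, 1]))
    seen <- rep(FALSE, n); seen[center] <- TRUE; fr <- center
    while (length(fr)) {
      nx <- integer(0)
      for (v in fr) for (w in bonds$adjacency[[v]]) {
        if (!seen[w] && !(paste(v, w) %in% key)) {
          seen[w] <- TRUE; nx <- c(nx, w)
        }
      }
      fr <- nx
    }
    which(seen)
  }
  if (is.null(cand)) return(list(best_size = n, qm = seq_len(n)))
  nc <- nrow(cand)
  best <- NULL
  for (mask in 0:(2^nc - 1)) {
    rows <- which(bitwAnd(mask, 2^(seq_len(nc) - 1)) > 0)
    qm <- comp(rows)
    # admissibility: every bond leaving the region must be an eligible cut
    ok <- TRUE
    for (v in qm) for (w in bonds$adjacency[[v]]) {
      if (!(w %in% qm)) {
        is_cand <- any((cand[, 1] == v & cand[, 2] == w) |
                         (cand[, 1] == w & cand[, 2] == v))
        if (!is_cand) { ok <- FALSE; break }
      }
    }
    if (ok && (is.null(best) || length(qm) < length(best))) best <- qm
  }
  list(best_size = length(best), qm = best)
}

# the ten reported first-order hydrolysis rate constants (s^-1) at 298 K
# with their printed significant figures
reported_rates <- function() {
  data.frame(
    label = c("pyro_As_mono", "pyro_P_mono", "ribose1_As_mono",
              "ribose1_P_mono", "As_DNA_mono", "P_DNA_mono",
              "pyro_As_di", "pyro_P_di", "ribose1_As_di", "ribose1_P_di"),
    k = c(0.0003, 5.49e-16, 0.0007, 1.58e-16, 1.23e-6, 5.74e-20,
          0.08, 3.17e-15, 0.07, 8.53e-14),
    sig_figs = c(1, 3, 1, 3, 3, 3, 1, 3, 1, 3),
    stringsAsFactors = FALSE)
}
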