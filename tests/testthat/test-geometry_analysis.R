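test_that("distances match coordinate arithmetic and reject bad indices", {
  g <- geometry(c("O", "O"), rbind(c(0, 0, 0), c(0, 0, 1)))
  expect_equal(atom_distance(g, 1, 2), 1.0)
  expect_error(atom_distance(g, 1, 1), "distinct")
  expect_error(atom_distance(g, 1, 3), "out of range")

  set.seed(101)
  gr <- rand_geometry(n = 25)
  for (rep in 1:100) {
    ij <- sample(25, 2)
    d_oracle <- unname(sqrt((gr$coords[ij[1], 1] - gr$coords[ij[2], 1])^2 +
                              (gr$coords[ij[1], 2] - gr$coords[ij[2], 2])^2 +
                              (gr$coords[ij[1], 3] - gr$coords[ij[2], 3])^2))
    expect_equal(atom_distance(gr, ij[1], ij[2]), d_oracle,
                 tolerance = 1e-12)
  }
})

test_that("angles cover orthogonal, collinear and degenerate cases", {
  g <- geometry(c("O", "P", "O"),
                rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)))
  expect_equal(atom_angle(g, 1, 2, 3), 90.0)
  lin <- geometry(c("O", "P", "O"),
                  rbind(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0)))
  expect_equal(atom_angle(lin, 1, 2, 3), 180.0)
  expect_equal(atom_angle(lin, 3, 2, 1), atom_angle(lin, 1, 2, 3))
  degen <- geometry(c("O", "P", "O"),
                    rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)))
  expect_error(atom_angle(degen, 1, 2, 3), "zero-length")
})

test_that("dihedrals match an independent atan2 implementation", {
  cis <- geometry(rep("C", 4),
                  rbind(c(1, 1, 0), c(1, 0, 0), c(-1, 0, 0), c(-1, 1, 0)))
  expect_equal(atom_dihedral(cis, 1, 2, 3, 4), 0.0)
  trans <- geometry(rep("C", 4),
                    rbind(c(1, 1, 0), c(1, 0, 0), c(-1, 0, 0),
                          c(-1, -1, 0)))
  expect_equal(abs(atom_dihedral(trans, 1, 2, 3, 4)), 180.0)

  set.seed(55)
  for (rep in 1:200) {
    p <- matrix(rnorm(12, sd = 3), 4, 3)
    g <- geometry(rep("C", 4), p)
    expect_equal(atom_dihedral(g, 1, 2, 3, 4),
                 dihedral_oracle(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-9)
    # a torsion has the same sign viewed from either end
    expect_equal(atom_dihedral(g, 4, 3, 2, 1),
                 atom_dihedral(g, 1, 2, 3, 4), tolerance = 1e-9)
  }
  coll <- geometry(rep("C", 4),
                   rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)))
  expect_error(atom_dihedral(coll, 1, 2, 3, 4), "collinear")
})

test_that("all internal coordinates are invariant under rigid motion", {
  set.seed(77)
  g <- rand_geometry(n = 10)
  d0 <- atom_distance(g, 1, 2)
  a0 <- atom_angle(g, 1, 2, 3)
  t0 <- atom_dihedral(g, 1, 2, 3, 4)
  for (rep in 1:10) {
    g2 <- g
    g2$coords <- sweep(g$coords %*% t(rand_rotation()), 2,
                       runif(3, -50, 50), "+")
    expect_equal(atom_distance(g2, 1, 2), d0, tolerance = 1e-9)
    expect_equal(atom_angle(g2, 1, 2, 3), a0, tolerance = 1e-9)
    expect_equal(abs(atom_dihedral(g2, 1, 2, 3, 4)), abs(t0),
                 tolerance = 1e-9)
  }
})

test_that("parameter tables carry exact deltas and constructed changes", {
  g <- make_ideal_ester("P", "1A", "di", seed = 21)$geometry
  sp <- list(param_spec("distance", c("E", "O_L"), c(1, 2)),
             param_spec("angle", c("O_L", "E", "O_p"), c(2, 1, 3)))
  same <- parameter_table(g, g, sp)
  expect_equal(same$delta, c(0, 0))
  expect_identical(same$unit, c("angstrom", "degrees"))

  pair <- make_ts_like("As", "2", "mono", seed = 8)
  idx <- pair$ground_truth$indices
  specs <- list(
    param_spec("distance", c("E", "O3'"), c(1, idx$OL)),
    param_spec("distance", c("E", "O_p"), c(1, idx$Op)),
    param_spec("angle", c("O3'", "E", "O5'"), c(idx$OL, 1, idx$O5)))
  tab <- parameter_table(pair$reactant, pair$ts, specs)
  gt <- pair$ground_truth$params
  expect_equal(tab$reactant,
               gt[match(c("d_E_OL", "d_E_Op", "angle"), gt$name),
                  "reactant"], tolerance = 1e-9)
  expect_equal(tab$ts,
               gt[match(c("d_E_OL", "d_E_Op", "angle"), gt$name), "ts"],
               tolerance = 1e-9)
  expect_equal(tab$delta, tab$ts - tab$reactant)

  expect_error(param_spec("angle", c("a", "b"), c(1, 2)), "3 roles")
  expect_error(parameter_table(g, g, list()), "at least one")
  # offending spec named when measurement fails
  bad <- param_spec("distance", c("E", "far"), c(1, 99))
  expect_error(parameter_table(g, g, list(bad)), "d\\(E-far\\)")
})

test_that("geometry tables export as TSV and JSON", {
  pair <- make_ts_like("P", "1A", "di", seed = 4)
  tab <- parameter_table(pair$reactant, pair$ts,
                         list(param_spec("distance", c("E", "O_p"),
                                         c(1, 3))))
  tsv <- write_geometry_table(tab, format = "tsv")
  expect_match(tsv, "^parameter\tkind\tunit\treactant\tts\tdelta\n")
  js <- jsonlite::fromJSON(write_geometry_table(tab, format = "json"))
  expect_equal(js$delta, tab$delta, tolerance = 1e-12)
})

test_that("kabsch recovers applied rigid transforms", {
  set.seed(31)
  P <- matrix(rnorm(45), 15, 3)
  ident <- kabsch_superpose(P, P)
  expect_equal(ident$rmsd, 0, tolerance = 1e-12)
  expect_equal(ident$rotation, diag(3), tolerance = 1e-9)
  expect_equal(det(ident$rotation), 1, tolerance = 1e-8)

  for (rep in 1:20) {
    R <- rand_rotation(); tr <- runif(3, -10, 10)
    M <- sweep(P %*% t(R), 2, tr, "+")
    s <- kabsch_superpose(P, M)
    expect_lt(s$rmsd, 1e-9)
    # recovered rotation inverts the applied one
    expect_equal(s$rotation %*% R, diag(3), tolerance = 1e-8)
    expect_equal(det(s$rotation), 1, tolerance = 1e-8)
    expect_equal(crossprod(s$rotation), diag(3), tolerance = 1e-8)
  }
})

test_that("kabsch rmsd is never beaten by explicit rigid transforms", {
  set.seed(61)
  P <- matrix(rnorm(30), 10, 3)
  M <- P + matrix(rnorm(30, sd = 0.4), 10, 3)  # noisy copy
  best <- kabsch_superpose(P, M)$rmsd
  for (rep in 1:500) {
    R <- rand_rotation(); tr <- runif(3, -3, 3)
    fit <- sweep(M %*% t(R), 2, tr, "+")
    expect_gte(sqrt(mean(rowSums((fit - P)^2))), best - 1e-12)
  }
})

test_that("torsions and fitted RMSDs agree with bio3d", {
  set.seed(83)
  for (rep in 1:20) {
    p <- matrix(rnorm(12, sd = 2), 4, 3)
    g <- geometry(rep("C", 4), p)
    b3d <- suppressWarnings(bio3d::torsion.xyz(as.numeric(t(p)),
                                               atm.inc = 4))
    expect_equal(atom_dihedral(g, 1, 2, 3, 4), as.numeric(b3d)[1],
                 tolerance = 1e-6)
  }
  P <- matrix(rnorm(30), 10, 3)
  M <- P + matrix(rnorm(30, sd = 0.3), 10, 3)
  expect_equal(kabsch_superpose(P, M)$rmsd,
               as.numeric(bio3d::rmsd(as.numeric(t(P)), as.numeric(t(M)),
                                      fit = TRUE)),
               tolerance = 1e-3)
})

test_that("kabsch degenerate inputs error and pairing helper works", {
  expect_error(kabsch_superpose(matrix(rnorm(6), 2, 3),
                                matrix(rnorm(6), 2, 3)),
               "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line + 1), "collinear")

  b <- make_mock_strand(3, seed = 17)
  g <- b$geometry
  g2 <- g
  g2$coords <- sweep(g$coords %*% t(rand_rotation()), 2, c(4, -2, 9), "+")
  pr <- pair_atoms(g, g2)
  expect_equal(nrow(pr), sum(g$elements != "H"))
  s <- kabsch_superpose(g, g2)
  expect_lt(s$rmsd, 1e-9)
  moved <- apply_superposition(s, g2)
  expect_equal(moved$coords, g$coords, tolerance = 1e-9)
  js <- jsonlite::fromJSON(write_superposition(s))
  expect_equal(js$n_pairs, s$n_pairs)
})
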