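test_that("representative esters classify as expected", {
  pyro_as <- make_ideal_ester("As", "1A", "di", seed = 1)
  c1 <- classify_ester(pyro_as$geometry)
  expect_equal(c1$ester_class, "1A")
  expect_equal(c1$ester_type, "monoester")
  expect_equal(c1$leaving_group_pattern, "O-P-R")
  expect_equal(c1$central_atom, "As")
  expect_equal(c1$anionic_state, "di")

  rib_as <- make_ideal_ester("As", "1B", "mono", seed = 2)
  c2 <- classify_ester(rib_as$geometry)
  expect_equal(c2$ester_class, "1B")
  expect_equal(c2$anionic_state, "mono")

  dna_as <- make_ideal_ester("As", "2", "mono", seed = 3)
  c3 <- classify_ester(dna_as$geometry)
  expect_equal(c3$ester_class, "2")
  expect_equal(c3$ester_type, "diester")
  expect_equal(c3$leaving_group_pattern, "O-C-R")
})

test_that("classifier agrees with the independent pattern-matching oracle", {
  seeds <- 1:5
  for (ce in c("P", "As")) {
    for (cl in c("1A", "1B", "2")) {
      for (an in if (cl == "2") "mono" else c("mono", "di")) {
        for (s in seeds) {
          g <- make_ideal_ester(ce, cl, an, seed = s)$geometry
          got <- classify_ester(g)
          want <- classify_oracle(g)
          expect_equal(got$ester_class, want$ester_class)
          expect_equal(got$ester_type, want$ester_type)
          expect_equal(got$center, want$center)
        }
      }
    }
  }
})

test_that("unclassifiable inputs raise the documented errors", {
  # no bridging oxygen at all: bare orthophosphate-like fragment
  iso <- geometry(c("P", "O", "O", "O", "O"),
                  rbind(c(0, 0, 0), c(1.55, 0, 0), c(-0.5, 1.45, 0),
                        c(-0.5, -0.75, 1.25), c(-0.5, -0.75, -1.25)),
                  charge = -2L)
  expect_error(classify_ester(iso), "unsupported ester")
  g <- make_ideal_ester("P", "1A", "di", seed = 1)$geometry
  g$charge <- -5L
  expect_warning(cls <- classify_ester(g), "charge")
  expect_true(is.na(cls$anionic_state))
})

test_that("As-for-P substitution preserves everything it should", {
  b <- make_mock_strand(4, c("P", "P", "P"), seed = 6)
  g <- b$geometry
  ctrs <- b$ground_truth$center_indices
  expect_identical(substitute_central_atoms(g, integer(0)), g)

  g2 <- substitute_central_atoms(g, ctrs[1:2])
  expect_equal(n_atoms(g2), n_atoms(g))
  expect_equal(sum(g2$elements == "As"), 2L)
  expect_identical(g2$elements[ctrs[3]], "P")
  # bit-exact coordinates when adjust_bonds is off
  expect_identical(g2$coords, g$coords)
  expect_identical(g2$serial, g$serial)
  expect_error(substitute_central_atoms(g, 1), "not phosphorus")
})

test_that("bond adjustment lengthens each As-O bond by the radius gap", {
  b <- make_ideal_ester("P", "1A", "di", seed = 4)
  g <- b$geometry
  bonds <- perceive_bonds(g)
  oxy <- bonds$adjacency[[1]]
  before <- vapply(oxy, function(o) atom_distance(g, 1, o), numeric(1))
  g2 <- substitute_central_atoms(g, 1, adjust_bonds = TRUE)
  after <- vapply(oxy, function(o) atom_distance(g2, 1, o), numeric(1))
  dr <- covalent_radius("As") - covalent_radius("P")
  expect_equal(dr, 0.12, tolerance = 1e-12)
  expect_equal(after - before, rep(dr, length(oxy)), tolerance = 1e-6)
  # atoms outside the ester group untouched (the second P's terminal O)
  p2 <- which(g$name == "P2")
  ot <- which(g$name == "OT1")
  expect_identical(g2$coords[c(p2, ot), ], g$coords[c(p2, ot), ])
})

test_that("partition invariants hold on strand fixtures", {
  for (s in 1:3) {
    ce <- list(c("P", "P", "P"), c("P", "As", "P"), c("As", "As", "As"))[[s]]
    b <- make_mock_strand(4, ce, seed = s)
    g <- b$geometry
    bonds <- perceive_bonds(g)
    for (ctr in b$ground_truth$center_indices) {
      p <- partition_oniom(g, bonds, center = ctr)
      # disjoint and exhaustive layers
      expect_length(intersect(p$qm_atoms, p$mm_atoms), 0)
      expect_setequal(union(p$qm_atoms, p$mm_atoms), seq_len(n_atoms(g)))
      expect_true(ctr %in% p$qm_atoms)
      # QM connectivity
      qm_set <- p$qm_atoms
      seen <- ctr
      repeat {
        grow <- unique(unlist(bonds$adjacency[seen]))
        grow <- intersect(grow, qm_set)
        if (all(grow %in% seen)) break
        seen <- union(seen, grow)
      }
      expect_setequal(seen, qm_set)
      # cut bonds: sp3 C-C, both ends more than 4 bonds from the center
      d <- esterkin:::.graph_distances(bonds, ctr)
      deg <- lengths(bonds$adjacency)
      for (r in seq_len(nrow(p$cut_bonds))) {
        i <- p$cut_bonds[r, 1]; j <- p$cut_bonds[r, 2]
        expect_true(all(g$elements[c(i, j)] == "C"))
        expect_true(all(deg[c(i, j)] == 4L))
        expect_true(all(d[c(i, j)] > 4))
        expect_true(i %in% p$qm_atoms && j %in% p$mm_atoms)
      }
      # one hydrogen link atom per cut bond, on the bond axis at 1.09
      expect_equal(nrow(p$link_atoms), nrow(p$cut_bonds))
      for (r in seq_len(nrow(p$link_atoms))) {
        la <- p$link_atoms[r, ]
        axis <- g$coords[la$replaced, ] - g$coords[la$host, ]
        pos <- unlist(la[c("x", "y", "z")])
        v <- pos - g$coords[la$host, ]
        expect_equal(sqrt(sum(v^2)), 1.09, tolerance = 1e-9)
        cosang <- sum(v * axis) / sqrt(sum(v^2) * sum(axis^2))
        expect_equal(cosang, 1, tolerance = 1e-9)
      }
    }
  }
})

test_that("partition QM size matches brute-force cut-set enumeration", {
  # 20-atom capped chain: single eligible cut, enumerable by hand
  g <- chain_fixture()
  bonds <- perceive_bonds(g)
  p <- partition_oniom(g, bonds, center = 1)
  bf <- oniom_bruteforce(g, bonds, center = 1)
  expect_equal(length(p$qm_atoms), bf$best_size)
  expect_setequal(p$qm_atoms, bf$qm)
  expect_equal(nrow(p$cut_bonds), 1L)

  # and on a 3-residue strand around its first bridging center
  b <- make_mock_strand(3, c("P", "As"), seed = 12)
  bonds2 <- perceive_bonds(b$geometry)
  for (ctr in b$ground_truth$center_indices) {
    p2 <- partition_oniom(b$geometry, bonds2, center = ctr)
    bf2 <- oniom_bruteforce(b$geometry, bonds2, center = ctr)
    expect_equal(length(p2$qm_atoms), bf2$best_size)
    expect_setequal(p2$qm_atoms, bf2$qm)
  }
})

test_that("molecules without eligible cuts become all-QM with a warning", {
  ts <- make_ts_like("As", "1A", "di", seed = 2)$ts  # pyroarsenate + water
  expect_warning(p <- partition_oniom(ts, perceive_bonds(ts)),
                 "no eligible")
  expect_setequal(p$qm_atoms, seq_len(n_atoms(ts)))
  expect_length(p$mm_atoms, 0)
  expect_equal(nrow(p$cut_bonds), 0L)
  expect_equal(nrow(p$link_atoms), 0L)
})

test_that("layered PDB and JSON manifest serialize the partition", {
  b <- make_mock_strand(4, seed = 3)
  bonds <- perceive_bonds(b$geometry)
  p <- partition_oniom(b$geometry, bonds,
                       center = b$ground_truth$center_indices[2])
  out <- write_oniom_partition(b$geometry, p)
  back <- read_pdb_subset(text = out$pdb)
  expect_equal(n_atoms(back), n_atoms(b$geometry))
  js <- jsonlite::fromJSON(out$json)
  expect_setequal(js$qm_atoms, p$qm_atoms)
  expect_equal(nrow(js$link_atoms), nrow(p$link_atoms))
  # the B-factor layer tags in the PDB match the QM set
  bf_col <- as.numeric(substr(strsplit(out$pdb, "\n")[[1]][p$qm_atoms[1]],
                              61, 66))
  expect_equal(bf_col, 1)
})

test_that("strand extraction respects residues, chains and capping", {
  b <- make_mock_strand(4, seed = 8)
  g <- b$geometry
  whole <- extract_strand(g, "A", 1:4)
  expect_equal(n_atoms(whole), n_atoms(g))

  first2 <- extract_strand(g, "A", 1:2)
  expect_equal(n_atoms(first2),
               sum(b$ground_truth$residue_atom_counts[1:2]))
  expect_true(all(first2$residue_number %in% 1:2))
  expect_error(extract_strand(g, "A", 3:6), "chain break")
  expect_error(extract_strand(g, "B", 1:2), "chain break")

  # capping adds one hydroxyl hydrogen at the severed O3'-P bond
  capped <- extract_strand(g, "A", 1:2, cap = TRUE)
  expect_equal(n_atoms(capped), n_atoms(first2) + 1L)
  newH <- n_atoms(capped)
  expect_equal(capped$elements[newH], "H")
  o3 <- which(capped$name == "O3'" & capped$residue_number == 2L)
  expect_equal(sqrt(sum((capped$coords[newH, ] -
                           capped$coords[o3, ])^2)), 0.96,
               tolerance = 1e-9)
})

test_that("single-residue extraction is the identity on that residue", {
  b <- make_mock_strand(2, seed = 14)
  g <- b$geometry
  one <- extract_strand(g, "A", 1)
  expect_true(all(one$residue_number == 1L))
  sel <- which(g$residue_number == 1L)
  expect_identical(one$coords, g$coords[sel, , drop = FALSE])
  expect_identical(one$name, g$name[sel])
})
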