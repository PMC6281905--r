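test_that("generators are pure functions of their seed", {
  for (gen in list(
    function(s) make_ideal_ester("As", "1B", "di", seed = s),
    function(s) make_ts_like("P", "2", "mono", seed = s),
    function(s) make_fragment_energies(12.5, -4.25, 3, seed = s),
    function(s) make_thermo_species(21.7, seed = s),
    function(s) make_mock_strand(3, c("P", "As"), seed = s))) {
    expect_identical(gen(7), gen(7))
    expect_false(identical(gen(7), gen(8)))
  }
  # and the global RNG stream is left untouched
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(make_ideal_ester(seed = 5)); after <- runif(3)
  expect_identical(before, after)
})

test_that("ideal esters measure back their construction table", {
  for (ce in c("P", "As")) {
    for (cl in c("1A", "1B", "2")) {
      b <- make_ideal_ester(ce, cl, if (cl == "2") "mono" else "di",
                            seed = 31)
      g <- b$geometry; gt <- b$ground_truth; ix <- gt$indices
      expect_equal(atom_distance(g, ix$E, ix$OL), gt$d_E_OL,
                   tolerance = 1e-9)
      expect_equal(atom_distance(g, ix$E, ix$Op), gt$d_E_Op,
                   tolerance = 1e-9)
      if (cl == "2") {
        expect_equal(atom_angle(g, ix$OL, ix$E, ix$O5), gt$angle,
                     tolerance = 1e-9)
        expect_equal(atom_distance(g, ix$OL, ix$O5), gt$d_O3_O5,
                     tolerance = 1e-9)
      } else {
        expect_equal(atom_angle(g, ix$OL, ix$E, ix$Op), gt$angle,
                     tolerance = 1e-9)
      }
      # classification ground truth reproduced by the pipeline operation
      cls <- classify_ester(g)
      expect_equal(cls$ester_class, gt$ester_class)
      expect_equal(cls$anionic_state, gt$anionic_state)
    }
  }
  expect_error(make_ideal_ester("P", "2", "di"), "monoanionic")
})

test_that("TS pairs elongate the forming bond and carry one imaginary mode", {
  for (ce in c("P", "As")) {
    for (cl in c("1A", "1B", "2")) {
      b <- make_ts_like(ce, cl, if (cl == "2") "mono" else "di", seed = 41)
      ix <- b$ground_truth$indices
      d_r <- atom_distance(b$reactant, ix$E, ix$Op)
      d_t <- atom_distance(b$ts, ix$E, ix$Op)
      expect_gt(d_t, d_r)
      expect_equal(sum(b$frequencies$ts$wavenumbers < 0), 1L)
      expect_true(b$frequencies$ts$is_ts)
      expect_equal(sum(b$frequencies$reactant$wavenumbers < 0), 0L)
      # parameter-table deltas reproduce the stored ground truth
      gt <- b$ground_truth$params
      specs <- list(param_spec("distance", c("E", "OL"), c(ix$E, ix$OL)),
                    param_spec("distance", c("E", "Op"), c(ix$E, ix$Op)))
      tab <- parameter_table(b$reactant, b$ts, specs)
      expect_equal(tab$delta,
                   gt$delta[match(c("d_E_OL", "d_E_Op"), gt$name)],
                   tolerance = 1e-9)
      # the TS is five-coordinate at the center
      bb <- perceive_bonds(b$ts)
      expect_length(bb$adjacency[[ix$E]], 5L)
    }
  }
})

test_that("fragment-energy bundles prescribe their decomposition", {
  b0 <- make_fragment_energies(0, 0, 2, seed = 1)
  r0 <- asm_decompose(b0$fragment_energies)
  expect_equal(r0$distortion, 0)
  expect_equal(r0$interaction, 0)
  expect_equal(r0$activation, 0)
  b1 <- make_fragment_energies(7, -7, 2, seed = 2)
  expect_equal(asm_decompose(b1$fragment_energies)$activation, 0,
               tolerance = 1e-10)
  expect_error(make_fragment_energies(-3, 0), "non-negative")
  expect_error(make_fragment_energies(5, 2, n_fragments = 1), "two")
})

test_that("thermo-species bundles hit their target through the full path", {
  set.seed(6)
  for (rep in 1:10) {
    tgt <- runif(1, 5, 45)
    T <- sample(c(280, 298, 320), 1)
    b <- make_thermo_species(tgt, temperature = T, seed = rep)
    g_r <- gibbs_free_energy(
      b$reactant$electronic_energy,
      rrho_corrections(b$reactant$geometry, b$reactant$frequencies,
                       temperature = T))
    g_t <- gibbs_free_energy(
      b$ts$electronic_energy,
      rrho_corrections(b$ts$geometry, b$ts$frequencies, temperature = T))
    expect_equal(activation_free_energy(g_r, g_t), tgt, tolerance = 1e-9)
  }
})

test_that("mock strands keep their declared bookkeeping", {
  b <- make_mock_strand(4, c("P", "As", "P"), seed = 19)
  g <- b$geometry; gt <- b$ground_truth
  expect_equal(gt$n_linkages, 3L)
  expect_equal(length(gt$center_indices), 3L)
  expect_identical(g$elements[gt$center_indices], c("P", "As", "P"))
  expect_equal(sum(gt$residue_atom_counts), n_atoms(g))
  expect_equal(as.integer(table(g$residue_number)),
               gt$residue_atom_counts)
  expect_equal(g$charge, -3L)
  expect_identical(unique(g$residue_name),
                   unique(gt$residue_names))
  # bridging centers connect O3' of residue i to O5' of residue i+1
  bonds <- perceive_bonds(g)
  for (k in seq_along(gt$center_indices)) {
    ctr <- gt$center_indices[k]
    nbr <- bonds$adjacency[[ctr]]
    expect_length(nbr, 4L)
    expect_setequal(unique(g$elements[nbr]), "O")
    bridge_names <- sort(g$name[intersect(nbr, which(g$name %in%
                                                       c("O3'", "O5'")))])
    expect_identical(bridge_names, c("O3'", "O5'"))
  }
  # substitution gives the two-arsenic composition
  b2 <- make_mock_strand(4, seed = 20)
  gs <- substitute_central_atoms(b2$geometry,
                                 b2$ground_truth$center_indices[1:2])
  expect_equal(sum(gs$elements == "As"), 2L)
  expect_equal(n_atoms(gs), n_atoms(b2$geometry))
  # PDB serialization is valid and re-readable
  back <- read_pdb_subset(text = write_pdb(gs))
  expect_equal(sum(back$elements == "As"), 2L)
})

test_that("strand fixtures admit partitions around any bridge center", {
  b <- make_mock_strand(5, c("P", "P", "As", "P"), seed = 23)
  bonds <- perceive_bonds(b$geometry)
  for (ctr in b$ground_truth$center_indices) {
    p <- partition_oniom(b$geometry, bonds, center = ctr)
    expect_length(intersect(p$qm_atoms, p$mm_atoms), 0)
    expect_setequal(union(p$qm_atoms, p$mm_atoms),
                    seq_len(n_atoms(b$geometry)))
    expect_true(ctr %in% p$qm_atoms)
    expect_equal(nrow(p$link_atoms), nrow(p$cut_bonds))
    expect_gt(length(p$mm_atoms), 0)  # a 5-mer always has eligible cuts
  }
})
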