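ref_pot <- load_reference_potential()

test_that("Q is the mean tetrahedron score", {
  # a single all-carbon tetrahedron scores exactly the CCCC entry
  s4 <- regular_tetrahedron(edge = 2)
  tess <- filter_tetrahedra(tessellate(s4), s4, 8)
  q <- topological_score(tess, rep("C", 4), ref_pot)
  expect_equal(q$Q, -0.140244)
  expect_equal(q$N, 1)
  expect_equal(q$n_undefined, 0)

  # two face-sharing tetrahedra: Q = (s1 + s2) / 2
  bipyr <- rbind(regular_tetrahedron(edge = 3),
                 c(1.5, sqrt(3) / 2 * 3 / 3, -sqrt(6) / 3 * 3))
  cls <- c("C", "C", "N", "O", "C")
  tess <- filter_tetrahedra(tessellate(bipyr), bipyr, 8)
  expect_equal(tess$n_retained, 2)
  q <- topological_score(tess, cls, ref_pot)
  keys <- canonical_quadruplet(matrix(cls[tess$simplices], ncol = 4))
  s12 <- ref_pot$s[match(keys, ref_pot$quad)]
  expect_equal(q$Q, mean(s12))
})

test_that("Q matches an independent sum/divide recomputation", {
  s <- random_structure(fixture_spec(
    300, composition = c(C = 0.6, N = 0.2, O = 0.15, S = 0.05),
    box = 40, seed = 17))
  cls <- classify_atom(s$element)
  tess <- tessellate_structure(s)
  q <- topological_score(tess, cls, ref_pot)
  brute <- vapply(seq_len(nrow(tess$simplices)), function(i) {
    key <- paste(sort(cls[tess$simplices[i, ]]), collapse = "")
    ref_pot$s[ref_pot$quad == key]
  }, numeric(1))
  expect_equal(q$Q, sum(brute) / tess$n_retained, tolerance = 1e-12)
  expect_equal(q$N, tess$n_retained)
})

test_that("Q is invariant under rigid-body motion", {
  s <- random_structure(protein_spec(n = 100, seed = 29, box = 22))
  cls <- classify_atom(s$element)
  q1 <- topological_score(tessellate_structure(s), cls, ref_pot)$Q
  set.seed(4)
  rot <- random_rotation()
  moved <- s
  xyz <- atom_coords(s) %*% t(rot) +
    matrix(c(31, -8, 12), nrow(s), 3, byrow = TRUE)
  moved$x <- xyz[, 1]; moved$y <- xyz[, 2]; moved$z <- xyz[, 3]
  q2 <- topological_score(tessellate_structure(moved), cls, ref_pot)$Q
  expect_equal(q1, q2, tolerance = 1e-9)
})

test_that("undefined-score tetrahedra follow the missing policy", {
  # potential trained on C/N/O only: sulfur quadruplets are undefined
  corpus <- lapply(1:3, function(i) random_structure(protein_spec(seed = i)))
  pot <- derive_potential(corpus)
  s <- random_structure(fixture_spec(
    60, composition = c(C = 0.5, S = 0.5), box = 16, seed = 41))
  cls <- classify_atom(s$element)
  tess <- tessellate_structure(s)
  expect_error(topological_score(tess, cls, pot, "error"), "undefined")
  expect_warning(qz <- topological_score(tess, cls, pot, "zero"),
                 "undefined")
  qs <- topological_score(tess, cls, pot, "skip")
  expect_gt(qz$n_undefined, 0)
  expect_equal(qz$n_undefined, qs$n_undefined)
  # zero policy: undefined tetrahedra enter only through the denominator
  defined_sum <- qs$Q * qs$N
  expect_equal(qz$Q, defined_sum / tess$n_retained)
  expect_equal(qs$N, tess$n_retained - qs$n_undefined)
})

test_that("score differences and provenance checks behave", {
  s4 <- regular_tetrahedron(edge = 2)
  tess <- filter_tetrahedra(tessellate(s4), s4, 8)
  q <- topological_score(tess, rep("C", 4), ref_pot)
  expect_equal(delta_q(q, q), 0)
  corpus <- lapply(1:2, function(i) random_structure(protein_spec(seed = i)))
  other <- derive_potential(corpus)
  q2 <- topological_score(tess, rep("C", 4), other)
  expect_error(delta_q(q, q2), "different potentials")
})

test_that("the linear binding-energy model is applied exactly", {
  expect_equal(predict_binding_energy(0), -10.49)
  expect_equal(predict_binding_energy(-0.003), -20.49)
  expect_equal(predict_binding_energy(0.003147), 0)
  # affine: differences scale by 1/0.0003 exactly
  dq <- c(-0.01, 0, 0.002, 0.03)
  pred <- predict_binding_energy(dq)
  expect_equal(diff(pred), diff(dq) / 0.0003)
  expect_error(predict_binding_energy(NA_real_), "finite")
})

test_that("thermodynamic conversions reproduce the published table", {
  expect_equal(free_energy_from_constant(1), 0)
  expect_equal(free_energy_from_constant(10^-6.52), -8.887610045,
               tolerance = 1e-6)
  expect_equal(free_energy_from_constant(10^-9.22), -12.56806206,
               tolerance = 1e-6)
  expect_error(free_energy_from_constant(0), "positive")
  expect_error(free_energy_from_constant(-1e-6), "positive")
  # negative free energy iff k < 1 molar
  k <- 10^seq(-9, 2, by = 0.5)
  expect_equal(free_energy_from_constant(k) < 0, k < 1)

  expect_equal(pk_to_free_energy(0), 0)
  expect_equal(pk_to_free_energy(6.52), -8.887610045, tolerance = 1e-6)
  expect_equal(pk_to_free_energy(4.68), -6.379450155, tolerance = 1e-6)
  expect_equal(pk_to_free_energy(9.22), free_energy_from_constant(10^-9.22))
})

test_that("score_complex is internally consistent end to end", {
  tc <- toy_complex(fixture_spec(
    80, composition = c(C = 0.6, N = 0.2, O = 0.2), box = 20, seed = 11,
    ligand = list(n_atoms = 14, offset = c(6, 6, 6), box = 6)))
  aff <- score_complex(tc$structure, tc$selector, pot = ref_pot)
  expect_equal(aff$delta_q, aff$q_complex$Q - aff$q_protein$Q)
  expect_equal(aff$dg_calc, aff$delta_q / 0.0003 - 10.49)
  expect_equal(aff$ligand_atom_count, 14)
  expect_equal(tidy(aff)$dg_calc, aff$dg_calc)
  expect_error(score_complex(tc$structure, ligand_selector("ZZZ"),
                             pot = ref_pot), "matches no atoms")
})

test_that("a ligand beyond the cutoff leaves the score unchanged", {
  # ligand block 150 A away, its atoms mutually > 8 A apart: no retained
  # tetrahedron can involve a ligand atom, so the retained simplex sets of
  # complex and protein coincide and the prediction is the intercept
  tc <- toy_complex(fixture_spec(
    60, composition = c(C = 0.7, O = 0.3), box = 18, seed = 37,
    ligand = list(n_atoms = 5, offset = c(150, 150, 150), box = 40,
                  min_sep = 9)))
  s <- filter_structure(tc$structure)
  tess_c <- tessellate_structure(s)
  prot <- strip_ligand(s, tc$selector)$protein
  tess_p <- tessellate_structure(prot)
  expect_equal(simplex_set(tess_c$simplices), simplex_set(tess_p$simplices))
  aff <- score_complex(tc$structure, tc$selector, pot = ref_pot)
  expect_identical(aff$delta_q, 0)
  expect_identical(aff$dg_calc, -10.49)
})
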