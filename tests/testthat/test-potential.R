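table1_composition <- function() {
  composition(c(C = 3612988, N = 969253, O = 1088410, S = 28502,
                M = 2529, X = 4299))
}

test_that("quadruplet keys are canonical, permutation-invariant and 126-fold", {
  expect_equal(canonical_quadruplet(c("O", "C", "N", "C")), "CCNO")
  perms <- matrix(unlist(combinat_perms(c("C", "M", "S", "X"))),
                  ncol = 4, byrow = TRUE)
  expect_equal(unique(canonical_quadruplet(perms)), "CMSX")
  expect_error(canonical_quadruplet(c("C", "C")), "exactly 4")
  expect_error(canonical_quadruplet(c("C", "C", "C", "Z")), "invalid")
  keys <- quadruplet_keys()
  expect_equal(length(keys), 126)
  expect_equal(length(keys), choose(6 + 4 - 1, 4))
  expect_equal(anyDuplicated(keys), 0)
  expect_equal(canonical_quadruplet(do.call(rbind, strsplit(keys, ""))),
               keys)
})

test_that("expected probabilities reproduce the published table", {
  comp <- table1_composition()
  expect_equal(expected_probability("CCCC", comp), 0.160748,
               tolerance = 1e-5)
  expect_equal(expected_probability("CCCN", comp), 0.172495,
               tolerance = 2e-5)
  expect_equal(expected_probability("MMMM", comp), 3.86e-14,
               tolerance = 2e-3)
  # single-class alphabet: certainty
  expect_equal(expected_probability("CCCC", composition(c(C = 10))), 1)
  expect_error(expected_probability("CCNO", comp[1:3, ]), "normalized")
  expect_error(expected_probability("OCNC", comp), "not canonical")
})

test_that("multinomial background is complete over the 126 keys", {
  keys <- quadruplet_keys()
  expect_equal(sum(expected_probability(keys, table1_composition())), 1,
               tolerance = 1e-9)
  set.seed(99)
  for (i in 1:20) {
    counts <- setNames(sample(1:1e5, 6), atom_classes())
    expect_equal(sum(expected_probability(keys, composition(counts))), 1,
                 tolerance = 1e-9)
  }
})

test_that("log-odds scores match the published spot values", {
  expect_equal(quadruplet_score(0.116386, 0.160748), -0.140244,
               tolerance = 1e-4)
  expect_equal(quadruplet_score(0.25, 0.25), 0)
  comp <- table1_composition()
  a_m4 <- expected_probability("MMMM", comp)
  expect_equal(quadruplet_score(83 / 34504737, a_m4), 7.794725,
               tolerance = 1e-4)
  expect_true(is.na(quadruplet_score(0, 0.5)))
  expect_error(quadruplet_score(0.1, 0), "p must be")
})

test_that("quadruplet counting matches a brute-force tally", {
  # one tetrahedron of four carbons
  s4 <- regular_tetrahedron(edge = 2)
  tess <- filter_tetrahedra(tessellate(s4), s4, 8)
  counts <- count_quadruplets(list(tessellation = tess,
                                   classes = rep("C", 4)))
  expect_equal(counts$count[counts$quad == "CCCC"], 1)
  expect_equal(attr(counts, "total"), 1)
  expect_equal(sum(counts$count), 1)

  # larger seeded fixture against an independent per-simplex tally
  s <- random_structure(fixture_spec(
    300, composition = c(C = 0.6, N = 0.2, O = 0.15, S = 0.05),
    box = 40, seed = 11))
  cls <- classify_atom(s$element)
  tess <- tessellate_structure(s)
  counts <- count_quadruplets(list(tessellation = tess, classes = cls))
  brute <- brute_quad_tally(tess$simplices, cls)
  expect_equal(attr(counts, "total"), tess$n_retained)
  for (k in names(brute)) {
    expect_equal(counts$count[counts$quad == k], as.integer(brute[[k]]))
  }
  expect_equal(sum(counts$count), sum(brute))

  # additivity over structures
  s2 <- random_structure(protein_spec(seed = 12))
  cls2 <- classify_atom(s2$element)
  tess2 <- tessellate_structure(s2)
  both <- count_quadruplets(list(
    list(tessellation = tess, classes = cls),
    list(tessellation = tess2, classes = cls2)))
  single2 <- count_quadruplets(list(tessellation = tess2, classes = cls2))
  expect_equal(both$count, counts$count + single2$count)

  expect_error(
    count_quadruplets(list(tessellation = tess, classes = cls[1:10])),
    "labels")
})

test_that("derive_potential composes the pipeline consistently", {
  corpus <- lapply(1:5, function(i) random_structure(fixture_spec(
    80, composition = c(C = 0.6, N = 0.2, O = 0.2), box = 20, seed = i)))
  pot <- derive_potential(corpus)
  expect_s3_class(pot, "fb_potential")
  expect_equal(nrow(pot), 126)
  expect_equal(sum(pot$f), 1, tolerance = 1e-9)
  expect_equal(sum(pot$p), 1, tolerance = 1e-9)
  # corpus with no S/M/X: those keys unobserved, score undefined
  smx <- grepl("[SMX]", pot$quad)
  expect_true(all(pot$count[smx] == 0))
  expect_true(all(is.na(pot$s[smx])))
  # observed proportions equal brute-force count/total
  tally <- setNames(numeric(126), pot$quad)
  for (s in corpus) {
    tess <- tessellate_structure(s)
    b <- brute_quad_tally(tess$simplices, classify_atom(s$element))
    tally[names(b)] <- tally[names(b)] + as.numeric(b)
  }
  expect_equal(pot$f, unname(tally) / sum(tally))
  expect_equal(pot$count, as.integer(unname(tally)))
  expect_error(derive_potential(list()), "empty")
})

test_that("the bundled reference potential loads exactly as published", {
  pot <- load_reference_potential()
  expect_equal(nrow(pot), 126)
  expect_equal(attr(pot, "total_tetrahedra"), 34504737)
  cccc <- pot[pot$quad == "CCCC", ]
  expect_equal(cccc$count, 4015872)
  expect_equal(cccc$f, 0.116386)
  expect_equal(cccc$p, 0.160748)
  expect_equal(cccc$s, -0.140244)
  # undefined scores exactly where the corpus never observed the quadruplet
  expect_equal(sum(is.na(pot$s)), sum(pot$count == 0))
  expect_equal(sum(is.na(pot$s)), 11)
  # published composition is attached with unrounded frequencies
  comp <- attr(pot, "composition")
  expect_equal(attr(comp, "total"), 5705981)
  expect_equal(comp$a[comp$class == "C"], 3612988 / 5705981)
})

test_that("printed scores are consistent with printed f and p", {
  # agreement is limited by the rounding of the printed proportions, so the
  # tolerance per row is the log-propagated half-ulp of f and p
  pot <- load_reference_potential()
  obs <- pot[pot$count > 0, ]
  ulp <- function(v) ifelse(v >= 1e-4, 1e-6, 10^(floor(log10(v)) - 2))
  tol <- (0.5 * ulp(obs$f) / obs$f + 0.5 * ulp(obs$p) / obs$p) / log(10)
  ds <- abs(log10(obs$f / obs$p) - obs$s)
  expect_true(all(ds <= tol + 1e-6))
})

test_that("potential tables round-trip through TSV", {
  corpus <- lapply(1:2, function(i) random_structure(protein_spec(seed = i)))
  pot <- derive_potential(corpus)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_potential(pot, tf)
  back <- read_potential(tf)
  expect_equal(back$quad, pot$quad)
  expect_equal(back$count, pot$count)
  expect_equal(back$f, signif(pot$f, 6))
  expect_equal(is.na(back$s), is.na(pot$s))
  expect_equal(back$s[!is.na(back$s)], round(pot$s[!is.na(pot$s)], 6))
  expect_error(read_potential(withr::local_tempfile(lines = "quad\tcount")),
               "potential table")
})
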