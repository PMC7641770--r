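test_that("elemental masses match textbook values", {
  expect_equal(average_mass("H2O"), 18.015, tolerance = 1e-3)
  expect_equal(average_mass("C10H14N5O7P"), 347.22, tolerance = 0.01)
  expect_equal(average_mass(c(H = 2, O = 1)), average_mass("H2O"))
  expect_error(average_mass("Xx3"), "malformed|unknown")
  expect_error(average_mass(c(Zz = 1)), "unknown element")
  expect_error(average_mass(character(0)), "empty composition")
  expect_error(average_mass(c(H = 0)), "empty composition")
})

test_that("protein masses follow residue + water arithmetic", {
  expect_equal(protein_average_mass("G"), 75.07, tolerance = 0.01)
  expect_equal(protein_average_mass("GG"), 132.12, tolerance = 0.01)
  expect_error(protein_average_mass(""), "empty")
  expect_error(protein_average_mass("GXG"), "non-canonical")
})

test_that("appending any residue adds exactly its residue mass", {
  base <- protein_average_mass("AG")
  for (x in AA_ALPHABET) {
    delta <- protein_average_mass(paste0("AG", x)) - base
    ref <- protein_average_mass(paste0("G", x)) - protein_average_mass("G")
    expect_equal(delta, ref, tolerance = 1e-9, info = x)
  }
})

test_that("the AMP residue mass rounds to 329 Da", {
  expect_equal(amp_residue_mass("avg"), 329.21, tolerance = 0.01)
  expect_equal(round(amp_residue_mass("avg")), 329)
  expect_equal(amp_residue_mass("mono"), 329.05, tolerance = 0.01)
  # free AMP minus water
  expect_equal(amp_residue_mass("avg"),
               average_mass("C10H14N5O7P") - average_mass("H2O"),
               tolerance = 1e-9)
  expect_equal(3 * amp_residue_mass("avg"), 987.63, tolerance = 0.01)
})

test_that("small-molecule identification is unique, absent, or ambiguous", {
  id <- identify_small_molecule(347.6, tolerance = 0.5)
  expect_equal(id$status, "match")
  expect_equal(id$matches$name, "5'-AMP")

  expect_equal(identify_small_molecule(500.0, tolerance = 0.5)$status,
               "no_match")

  id_cmp <- identify_small_molecule(323.5, tolerance = 0.5)
  expect_equal(id_cmp$status, "match")
  expect_equal(id_cmp$matches$name, "5'-CMP")

  # CMP (323.198) and UMP (324.182) both within 0.6 of 323.7: must be
  # flagged ambiguous, never silently resolved
  amb <- identify_small_molecule(323.7, tolerance = 0.6)
  expect_equal(amb$status, "ambiguous")
  expect_setequal(amb$matches$name, c("5'-CMP", "5'-UMP"))

  expect_error(identify_small_molecule(100, candidates = NULL), "empty")
})

test_that("the 987.45 Da intact-mass shift is explained by three AMPs", {
  sol <- infer_stoichiometry(987.45, tolerance = 1.5, max_total = 10)
  expect_equal(sol$counts, c(AMP = 3L))
  # shipped table masses are rounded to 4 dp, hence the loose tolerance
  expect_equal(sol$residual, 987.45 - 3 * amp_residue_mass("avg"),
               tolerance = 1e-3)
  expect_equal(abs(sol$residual), 0.18, tolerance = 0.03)
})

test_that("stoichiometry handles the zero shift and mixed adducts", {
  z <- infer_stoichiometry(0)
  expect_length(z$counts, 0)
  expect_equal(z$residual, 0)

  cand <- data.frame(name = c("AMP", "phospho"),
                     residue_mass_avg = c(329.21, 79.97))
  mix <- infer_stoichiometry(409.18, cand, tolerance = 0.1, max_total = 10)
  expect_equal(mix$counts, c(AMP = 1L, phospho = 1L))

  expect_null(infer_stoichiometry(100.0, tolerance = 0.01))
})

test_that("stoichiometry is exact on constructed integer combinations", {
  cand <- mod_candidate_table()
  ms <- setNames(cand$residue_mass_avg, cand$name)
  combos <- expand.grid(0:6, 0:6, 0:6)
  combos <- combos[rowSums(combos) <= 6 & rowSums(combos) > 0, ]
  for (i in seq_len(nrow(combos))) {
    cnt <- setNames(as.integer(combos[i, ]), cand$name)
    shift <- sum(cnt * ms)
    sol <- infer_stoichiometry(shift, cand, tolerance = 1e-6, max_total = 6)
    expect_false(is.null(sol))
    expect_equal(sol$counts, cnt[cnt > 0])
    expect_equal(sol$residual, 0, tolerance = 1e-9)
  }
})

test_that("parsimony prefers fewer moieties before smaller residuals", {
  # 2 x A (100) fits 200 exactly but 1 x B (199.9) is within tolerance:
  # the single addition wins despite the larger residual
  cand <- data.frame(name = c("A", "B"), residue_mass_avg = c(100, 199.9))
  sol <- infer_stoichiometry(200, cand, tolerance = 0.5, max_total = 5)
  expect_equal(sol$counts, c(B = 1L))
})
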