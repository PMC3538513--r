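test_that("the registry holds exactly 98 uniquely named descriptors in 4 classes", {
  reg <- descriptor_registry()
  expect_equal(nrow(reg), 98L)
  expect_equal(as.integer(table(reg$class)[c("simple", "chemical",
                                             "connectivity_shape", "estate")]),
               c(18L, 3L, 35L, 42L))
  expect_false(anyDuplicated(reg$name) > 0)
  expect_equal(reg$index, 0:97)
})

test_that("simple properties match independently computed golden values", {
  golden <- fixture_golden_values()
  mols <- fixture_graphs()
  for (k in seq_len(nrow(golden))) {
    sp <- simple_properties(mols[[golden$name[k]]])
    expect_equal(unname(sp["nC"]), golden$nC[k], info = golden$name[k])
    expect_equal(unname(sp["nN"]), golden$nN[k], info = golden$name[k])
    expect_equal(unname(sp["nO"]), golden$nO[k], info = golden$name[k])
    expect_equal(unname(sp["nS"]), golden$nS[k], info = golden$name[k])
    expect_equal(unname(sp["nAtoms"]), golden$nAtoms[k], info = golden$name[k])
    expect_equal(unname(sp["nRings"]), golden$nRings[k], info = golden$name[k])
    expect_equal(unname(sp["MW"]), golden$MW[k], tolerance = 1e-3,
                 info = golden$name[k])
    expect_equal(unname(sp["nHBDon"]), golden$nHBDon[k], info = golden$name[k])
  }
})

test_that("worked descriptor examples hold", {
  eth <- simple_properties(parse_smiles("CCO"))
  expect_equal(unname(eth[c("nC", "nO", "nRings", "nHBDon")]), c(2, 1, 0, 1))
  expect_equal(unname(eth["MW"]), 46.07, tolerance = 1e-2)

  benz <- simple_properties(parse_smiles("c1ccccc1"))
  expect_equal(unname(benz[c("nRings", "nAromRing6", "nRingN")]), c(1, 1, 0))

  pyr <- simple_properties(parse_smiles("c1ccncc1"))
  expect_equal(unname(pyr[c("nRingN", "nN")]), c(1, 1))
})

test_that("chemical properties follow the atomic-contribution contracts", {
  # methane polarizability = contribution(C) + 4 contribution(H)
  meth <- chemical_properties(parse_smiles("C"))
  expect_equal(unname(meth["Polarizability"]), 1.76 + 4 * 0.666793,
               tolerance = 1e-6)
  # ALogP monotone in hydrophobic carbon count
  expect_gt(chemical_properties(parse_smiles("CC"))["ALogP"],
            chemical_properties(parse_smiles("C"))["ALogP"])
  expect_gt(chemical_properties(parse_smiles("CCCC"))["ALogP"],
            chemical_properties(parse_smiles("CC"))["ALogP"])
  # unparameterized element: finite value plus warning
  expect_warning(se <- chemical_properties(parse_smiles("C[Se]C")),
                 "Se")
  expect_true(all(is.finite(se)))
})

test_that("distance-based indices agree with brute-force oracles on small fixtures", {
  mols <- fixture_graphs()
  small <- mols[vapply(mols, function(m) nrow(m$atoms) <= 8L, TRUE)]
  expect_gte(length(small), 15L)
  for (m in small) {
    cs <- connectivity_shape(m)
    if (nrow(m$atoms) > 1L) {
      expect_equal(unname(cs["Wiener"]), oracle_wiener(m), info = m$id)
      expect_equal(unname(cs["Harary"]), oracle_harary(m), info = m$id)
      ecc <- oracle_eccentricities(m)
      expect_equal(unname(cs["TopoRadius"]), min(ecc), info = m$id)
      expect_equal(unname(cs["Eccentricity"]), sum(ecc), info = m$id)
    }
    pc <- oracle_path_counts(m, 6L)
    expect_equal(unname(cs[paste0("PathCount", 1:6)]), pc, info = m$id)
  }
})

test_that("golden Wiener/Harary values from independent tooling reproduce", {
  golden <- fixture_golden_values()
  mols <- fixture_graphs()
  for (k in seq_len(nrow(golden))) {
    cs <- connectivity_shape(mols[[golden$name[k]]])
    expect_equal(unname(cs["Wiener"]), golden$Wiener[k], info = golden$name[k])
    expect_equal(unname(cs["Harary"]), golden$Harary[k], tolerance = 1e-5,
                 info = golden$name[k])
  }
})

test_that("connectivity and kappa worked examples evaluate exactly", {
  # n-butane Wiener = 10 (4-path: 1+2+3+1+2+1)
  expect_equal(unname(connectivity_shape(parse_smiles("CCCC"))["Wiener"]), 10)
  # ethane: 1st-order chi = (1*1)^(-1/2) = 1; deltav(CH3) = 1 so chi1v = 1 too
  e <- connectivity_shape(parse_smiles("CC"))
  expect_equal(unname(e["Chiv1"]), 1.0)
  expect_equal(unname(e["DeltaChi1"]), 0.0)
  # propane kappa1 = A(A-1)^2/P1^2 = 3*4/4 = 3
  expect_equal(unname(connectivity_shape(parse_smiles("CCC"))["Kappa1"]), 3.0)
  # cyclohexane: vertex-transitive, centralization 0, shape coefficient 0
  ch <- connectivity_shape(parse_smiles("C1CCCCC1"))
  expect_equal(unname(ch["Centralization"]), 0)
  expect_equal(unname(ch["ShapeCoef"]), 0)
})

test_that("single-atom graphs emit finite degenerate values", {
  v <- connectivity_shape(parse_smiles("C"))
  expect_true(all(is.finite(v)))
  expect_equal(unname(v["Wiener"]), 0)
  expect_equal(unname(v["Kappa1"]), 0)   # P1 = 0 divides out to the convention
})

test_that("the full vector is 98 long, finite, deterministic and discriminating", {
  eth <- compute_descriptor_vector(parse_smiles("CCO"))
  expect_length(eth, 98L)
  expect_true(all(is.finite(eth)))
  expect_equal(names(eth), descriptor_registry()$name)
  expect_identical(eth, compute_descriptor_vector(parse_smiles("CCO")))
  benz <- compute_descriptor_vector(parse_smiles("c1ccccc1"))
  tol <- compute_descriptor_vector(parse_smiles("Cc1ccccc1"))
  expect_gte(sum(abs(benz - tol) > 1e-9), 5L)
})

test_that("descriptors are invariant under atom relabeling", {
  mols <- fixture_graphs()
  set.seed(42)
  for (m in mols[c("aspirin", "caffeine", "imidazole", "benzenesulfonamide",
                   "ibuprofen")]) {
    v0 <- compute_descriptor_vector(m)
    for (r in 1:3) {
      perm <- sample(nrow(m$atoms))
      vp <- compute_descriptor_vector(permute_molgraph(m, perm))
      expect_equal(unname(vp), unname(v0), tolerance = 1e-10, info = m$id)
    }
  }
})

test_that("featurize_library preserves order, drops failures, round-trips TSV", {
  mols <- fixture_graphs()[1:5]
  mat <- featurize_library(mols)
  expect_equal(dim(mat), c(5L, 98L))
  expect_equal(attr(mat, "n_failed"), 0L)
  # permuted input gives row-permuted output
  mat2 <- featurize_library(mols[c(3, 1, 2, 5, 4)])
  expect_equal(mat2, mat[c(3, 1, 2, 5, 4), ], ignore_attr = TRUE)
  # table round trip
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_descriptor_table(mat, tmp)
  back <- read_descriptor_table(tmp)
  expect_equal(back, mat, ignore_attr = TRUE, tolerance = 1e-12)
})
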