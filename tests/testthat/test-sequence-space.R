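test_that("residue classification follows the constraint table", {
  tab <- residue_classes()
  expect_equal(classify_residue("K", tab), "positive")
  expect_equal(classify_residue("C", tab), "excluded")
  expect_equal(classify_residue("V", tab), "hydrophobic")
  expect_equal(classify_residue("D", tab), "negative")
  expect_equal(classify_residue("N", tab), "polar")
  expect_error(classify_residue("Z", tab), "unknown residue")
  expect_error(residue_classes(hydrophobic = c("A", "V"),
                               polar = c("A", "T")), "disjoint")
  expect_error(residue_classes(excluded = c("C", "P")), "C, P and G")
})

test_that("validate_pair accepts the designed pairs and rejects malformed ones", {
  expect_true(validate_pair(peptide_pair("KKKVKVKVNTT", "TNTAEFEFEED"))$pass)
  v <- validate_pair(peptide_pair("QQKFKFKFKQQ", "EQEFEFEFEQE"))
  expect_false(v$pass)
  expect_true(any(grepl("chain A: 4 charged", v$violations)))
  expect_true(any(grepl("chain B: 6 charged", v$violations)))
  expect_true(any(grepl("chain A: 4 polar", v$violations)))
  expect_error(peptide_pair("KKKVKVKVNTC", "TNTAEFEFEED"), NA)
  v2 <- validate_pair(peptide_pair("KKKVKVKVNTC", "TNTAEFEFEED"))
  expect_false(v2$pass)
  expect_true(any(grepl("excluded residue", v2$violations)))
  expect_error(validate_pair(peptide_pair("KKKV", "TNTAEFEFEED")),
               "length")
})

test_that("validation is idempotent and charge signs are chain-specific", {
  p <- peptide_pair("KKKVKVKVNTT", "TNTAEFEFEED")
  v1 <- validate_pair(p)
  v2 <- validate_pair(p)
  expect_identical(v1, v2)
  # a negative residue on chain A is an illegal P-site occupant
  swapped <- peptide_pair("TNTAEFEFEED", "KKKVKVKVNTT")
  expect_false(validate_pair(swapped)$pass)
})

test_that("random pairs are deterministic per seed, diverse across seeds, and valid", {
  p1 <- random_pair(seed = 1)
  p2 <- random_pair(seed = 1)
  expect_identical(p1, p2)
  keys <- vapply(1:100, function(s) {
    p <- random_pair(seed = s)
    paste(p$seq_A, p$seq_B)
  }, character(1))
  expect_gte(length(unique(keys)), 99)
  set.seed(42)
  for (i in 1:2000) {
    expect_true(validate_pair(random_pair())$pass)
  }
})

test_that("infeasible constraints raise configuration errors", {
  pat <- sequence_pattern("HPH")
  comp <- composition_constraint(2, 0, 1, 1, -1)
  expect_error(random_pair(pat, composition_constraint(2, 0, 4, 4, -4)),
               "n_charged")
  expect_silent(random_pair(pat, comp, seed = 1))
  tab0 <- residue_classes(polar = character(0))
  expect_error(random_pair(sequence_pattern(), composition_constraint(),
                           tab0), "empty residue class|infeasible")
})

test_that("space size matches the closed form and brute-force enumeration", {
  n <- enumerate_space_size()
  expect_equal(n$per_chain_A, choose(8, 5) * 2^5 * 4^3 * 8^3)
  expect_equal(n$per_chain_B, n$per_chain_A)
  expect_equal(n$pairs, n$per_chain_A * n$per_chain_B)
  # doubling the polar set multiplies the per-chain count by 2^3
  n_base <- enumerate_space_size(table = residue_classes(
    polar = c("S", "T")))
  n_dbl <- enumerate_space_size(table = residue_classes(
    polar = c("S", "T", "N", "Q")))
  expect_equal(n_dbl$per_chain_A / n_base$per_chain_A, 2^3)
  # toy alphabets: exact agreement with exhaustive enumeration
  pat <- sequence_pattern("PHPP")
  comp <- composition_constraint(1, 1, 2, 2, -2)
  tab <- residue_classes(hydrophobic = c("V", "F"), polar = c("T", "N"),
                         positive = c("K", "R"), negative = c("D", "E"))
  counted <- enumerate_space_size(pat, comp, tab)
  expect_equal(counted$per_chain_A,
               brute_force_chain_count(pat, comp, tab, "A"))
  expect_equal(counted$per_chain_B,
               brute_force_chain_count(pat, comp, tab, "B"))
  # singleton space
  pat1 <- sequence_pattern("H")
  comp1 <- structure(list(n_hydrophobic = 1, n_polar = 0, n_charged = 0,
                          charge_A = 0, charge_B = 0),
                     class = "composition_constraint")
  tab1 <- residue_classes(hydrophobic = "V", polar = character(0))
  expect_equal(enumerate_space_size(pat1, comp1, tab1)$per_chain_A, 1)
})
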