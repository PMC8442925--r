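test_that("score combination is the exact linear form", {
  expect_equal(combine_score(0, 0, 3.0), 0)
  expect_equal(combine_score(-25.21, -0.18, 4.0), -25.93, tolerance = 1e-12)
  expect_equal(combine_score(-25.07, -0.11, 3.0), -25.40, tolerance = 1e-12)
  set.seed(11)
  for (i in 1:100) {
    dg <- rnorm(1, -20, 5); pa <- rnorm(1, 0, 0.3); l <- runif(1, 2, 5)
    expect_identical(combine_score(dg, pa, l), dg + l * pa)
  }
})

test_that("binding energy vanishes in the non-interacting limit", {
  # chains far apart, no charges, no hydrogen bonds
  geo <- scaffold_geometry(strand_spacing = 500, sheet_separation = 2000,
                           n_strands_per_sheet = 2)
  sc <- build_scaffold(geo)
  pair <- peptide_pair("TTTVTVTVTTT", "TTTVTVTVTTT")
  pz <- energy_params(hbond_energy = 0)
  be <- binding_energy(pair, sc, pz)
  expect_equal(be$dg, 0)
  expect_equal(unname(be$components), c(0, 0, 0, 0))
  # with the default hbond energy only the hbond term survives
  ph <- energy_params()
  be2 <- binding_energy(pair, sc, ph)
  expect_equal(be2$components[["contact"]], 0)
  expect_equal(be2$components[["electrostatic"]], 0)
  expect_equal(be2$total, be2$components[["hbond"]])
})

test_that("binding energy matches the brute-force all-pairs oracle", {
  set.seed(21)
  params <- energy_params()
  for (rep in 1:8) {
    geo <- scaffold_geometry(
      strand_spacing = runif(1, 4.5, 5.2),
      sheet_separation = runif(1, 9, 11),
      n_strands_per_sheet = sample(2:4, 1),
      n_sheets = sample(1:2, 1))
    sc <- build_scaffold(geo)
    pair <- random_pair()
    be <- binding_energy(pair, sc, params)
    oracle <- oracle_binding_energy(pair, sc, params)
    expect_equal(be$dg, oracle, tolerance = 1e-9)
  }
})

test_that("binding energy is invariant under rigid motion and slot relabeling", {
  set.seed(31)
  sc <- build_scaffold()
  pair <- random_pair()
  ref <- binding_energy(pair, sc)$dg
  for (rep in 1:3) {
    rot <- random_rotation()
    sc2 <- transform_scaffold(sc, rot, rnorm(3, 0, 20))
    expect_equal(binding_energy(pair, sc2)$dg, ref, tolerance = 1e-9)
  }
  perm <- sample(nrow(sc$slots))
  sc3 <- permute_scaffold(sc, perm)
  expect_equal(binding_energy(pair, sc3)$dg, ref, tolerance = 1e-12)
})

test_that("electrostatics penalize like charges and flip sign under charge negation", {
  sc <- build_scaffold()
  pair <- reference_pair("design4")
  e_compl <- binding_energy(pair, sc)$components[["electrostatic"]]
  # replace the cross-strand K...E partner with K...K at the same sites
  b_chars <- strsplit(pair$seq_B, "")[[1]]
  b_chars[b_chars == "E"] <- "K"
  b_chars[b_chars == "D"] <- "K"
  like <- peptide_pair(pair$seq_A, paste(b_chars, collapse = ""))
  e_like <- binding_energy(like, sc)$components[["electrostatic"]]
  expect_gt(e_like, e_compl)
  # with uniform centroid extents and a geometry where every inter-chain
  # pair is an A-B pair, negating the B-chain charges flips the
  # electrostatic term exactly
  uniform <- energy_params(sidechain_extent = setNames(
    rep(2.5, 20), names(coapep:::SIDECHAIN_EXTENT)))
  sc2 <- build_scaffold(scaffold_geometry(n_strands_per_sheet = 2,
                                          n_sheets = 1))
  e1 <- binding_energy(pair, sc2, uniform)$components[["electrostatic"]]
  b2 <- chartr("ED", "KK", pair$seq_B)
  e2 <- binding_energy(peptide_pair(pair$seq_A, b2), sc2,
                       uniform)$components[["electrostatic"]]
  expect_equal(e2, -e1, tolerance = 1e-9)
})

test_that("aggregation propensity behaves like a normalized profile mean", {
  ap <- aggregation_params()
  # constant sequence: windowing is a no-op
  p_const <- aggregation_propensity("VVVVVVVVVVV", ap)
  z_v <- ap$weight_hydropathy * coapep:::KD_HYDROPATHY[["V"]] +
    ap$weight_beta * coapep:::BETA_PROPENSITY[["V"]]
  expect_equal(p_const, ap$gain * z_v + ap$offset)
  # hydropathy monotonicity (beta term switched off)
  ap_h <- aggregation_params(weight_beta = 0)
  base <- aggregation_propensity("TTTVTVTVTTT", ap_h)
  more_hp <- aggregation_propensity("TTTVTVTVTTV", ap_h)
  expect_gte(more_hp, base)
  # T -> V raises both scales, so the default P_agg rises too
  expect_gte(aggregation_propensity("TTTVTVTVTTV"),
             aggregation_propensity("TTTVTVTVTTT"))
  # reversal invariance (symmetric windows, truncation symmetric)
  set.seed(41)
  for (i in 1:20) {
    s <- random_pair()$seq_A
    rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(aggregation_propensity(s), aggregation_propensity(rev_s))
  }
  expect_error(aggregation_propensity("KKKVKVKVNTT",
                                      aggregation_params(window = 12)),
               "window")
})

test_that("score_pair reports a consistent breakdown and stable ordering", {
  sc <- build_scaffold()
  set.seed(51)
  for (i in 1:20) {
    pair <- random_pair()
    l <- sample(c(3, 4), 1)
    br <- score_pair(pair, sc, lambda_weight = l)
    expect_identical(br$gamma,
                     combine_score(br$dg_binding, br$p_agg, br$lambda))
    expect_equal(br$p_agg, (br$p_agg_A + br$p_agg_B) / 2)
  }
  pair <- reference_pair("design4")
  br1 <- score_pair(pair, sc)
  br2 <- score_pair(pair, sc)
  expect_identical(br1, br2)
  # charge-complementary pair beats the like-charged A/A pairing
  like <- peptide_pair(pair$seq_A, pair$seq_A)
  expect_lt(br1$gamma, score_pair(like, sc)$gamma)
})
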