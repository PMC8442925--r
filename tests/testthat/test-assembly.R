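test_that("strand vectors are signed principal axes", {
  ca <- cbind(seq(0, 35, by = 3.5), 0, 0)
  expect_equal(strand_vector(ca), c(1, 0, 0))
  expect_equal(strand_vector(ca[rev(seq_len(nrow(ca))), ]), c(-1, 0, 0))
  expect_equal(sqrt(sum(strand_vector(ca + rnorm(33, 0, 0.1))^2)), 1,
               tolerance = 1e-9)
  expect_error(strand_vector(matrix(1, 5, 3)), "degenerate")
})

test_that("pair orientation classification has exact threshold behavior", {
  v <- c(1, 0, 0)
  expect_equal(classify_pair_orientation(v, v), "parallel")
  expect_equal(classify_pair_orientation(v, -v), "antiparallel")
  expect_equal(classify_pair_orientation(v, c(0, 1, 0)), "unclassified")
  at_thr <- c(0.5, sqrt(0.75), 0)
  expect_equal(classify_pair_orientation(v, at_thr), "parallel")
})

test_that("sheet partitioning recovers the built architecture and is noise-robust", {
  sc <- build_scaffold()
  fr <- scaffold_to_frame(sc)
  part <- partition_sheets(fr)
  expect_equal(length(unique(part)), 2)
  expect_equal(as.numeric(table(part)), c(6, 6))
  expect_equal(part, sc$slots$sheet)
  set.seed(81)
  for (i in 1:5) {
    expect_equal(partition_sheets(noisy_frame(fr, 0.3)), part)
  }
  # mutually distant chains form singleton sheets
  far <- fr
  for (k in seq_along(far$chains)) {
    far$chains[[k]]$ca <- far$chains[[k]]$ca + 1000 * k
  }
  expect_equal(partition_sheets(far), seq_along(far$chains))
})

test_that("neighbor statistics are exact on the ideal fixture", {
  fr <- scaffold_to_frame(build_scaffold())
  st <- neighbor_statistics(fr)
  expect_equal(nrow(st$within_nearest), 1)
  expect_equal(st$within_nearest$species_pair, "AB")
  expect_equal(st$within_nearest$orientation, "antiparallel")
  expect_true(all(st$within_next_nearest$species_pair %in% c("AA", "BB")))
  expect_true(all(st$within_next_nearest$orientation == "parallel"))
  expect_true(all(st$cross_nearest$orientation == "parallel"))
  expect_equal(sum(st$within_nearest$count), st$totals[["within_nearest"]])
  # single-sheet frame: no cross-sheet counts
  fr1 <- scaffold_to_frame(build_scaffold(scaffold_geometry(n_sheets = 1)))
  st1 <- neighbor_statistics(fr1)
  expect_equal(st1$totals[["cross_nearest"]], 0)
})

test_that("nearest-pair species fractions match the hypergeometric expectation under label shuffles", {
  fr <- scaffold_to_frame(build_scaffold())
  set.seed(82)
  fracs <- replicate(200, {
    labels <- sample(rep(c("A", "B"), 6))
    fr2 <- fr
    for (k in seq_along(fr2$chains)) fr2$chains[[k]]$species <- labels[k]
    st <- neighbor_statistics(fr2)
    tab <- st$within_nearest
    sum(tab$count[tab$species_pair == "AB"]) / sum(tab$count)
  })
  p_ab <- 6 * 6 / choose(12, 2)  # = 6/11 for 6A+6B labels
  se <- stats::sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - p_ab), 3 * se)
})

test_that("composition ratio counts aggregated chains only", {
  fr <- scaffold_to_frame(build_scaffold())
  expect_equal(composition_ratio(fr), 1.0)
  # 9A + 6B in one sheet
  sc15 <- build_scaffold(scaffold_geometry(n_strands_per_sheet = 15,
                                           n_sheets = 1))
  fr15 <- scaffold_to_frame(sc15)
  for (k in 1:15) fr15$chains[[k]]$species <- if (k <= 9) "A" else "B"
  expect_equal(composition_ratio(fr15), 1.5)
  # invariant under chain reordering
  perm <- sample(15)
  fr_p <- fr15; fr_p$chains <- fr15$chains[perm]
  expect_equal(composition_ratio(fr_p), 1.5)
  # dispersed chains are excluded; all-A aggregation is undefined
  for (k in 10:15) fr15$chains[[k]]$ca <- fr15$chains[[k]]$ca + 1000 * k
  expect_warning(r <- composition_ratio(fr15), "undefined")
  expect_true(is.na(r))
})

test_that("beta content is 1 on the fibril, 0 when dispersed, 0.5 when mixed", {
  fr <- scaffold_to_frame(build_scaffold())
  expect_equal(beta_content(fr)$beta_fraction, 1.0)
  far <- fr
  for (k in seq_along(far$chains)) {
    far$chains[[k]]$ca <- far$chains[[k]]$ca + 1000 * k
  }
  expect_equal(beta_content(far)$beta_fraction, 0.0)
  half <- fr
  for (k in 7:12) half$chains[[k]]$ca <- half$chains[[k]]$ca + 1000 * k
  expect_equal(beta_content(half)$beta_fraction, 0.5)
  # multi-frame series keeps the time axis
  series <- beta_content(list(fr, far))
  expect_equal(series$beta_fraction, c(1, 0))
  expect_equal(nrow(series), 2)
})

test_that("assembly statistics are invariant under global rigid motion", {
  set.seed(83)
  fr <- scaffold_to_frame(build_scaffold())
  rot <- random_rotation()
  fr2 <- fr
  for (k in seq_along(fr2$chains)) {
    fr2$chains[[k]]$ca <- sweep(fr2$chains[[k]]$ca %*% t(rot), 2,
                                c(7, -2, 30), "+")
  }
  expect_equal(partition_sheets(fr2), partition_sheets(fr))
  # exact distance ties may resolve differently after rotation, so
  # compare the category composition rather than raw pair counts
  st1 <- neighbor_statistics(fr)
  st2 <- neighbor_statistics(fr2)
  for (nm in c("within_nearest", "cross_nearest")) {
    expect_equal(unique(st2[[nm]][, c("species_pair", "orientation")]),
                 unique(st1[[nm]][, c("species_pair", "orientation")]))
  }
  expect_equal(beta_content(fr2)$beta_fraction,
               beta_content(fr)$beta_fraction)
})
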