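test_that("default fibril realizes the 18-chain DP-40 composition", {
  f <- build_cellulose_fibril()
  a <- f$atoms
  expect_equal(length(unique(a$chain_id)), 18)
  expect_equal(sum(a$atom_label == "C1"), 18 * 40) # one C1 per glucose
  expect_true(all(a$residue_type == "GLC"))
  expect_equal(nrow(a), 18 * 40 * 11) # 11 heavy atoms per glucose (incl O4)
  expect_error(fibril_spec(n_chains = 18, arrangement = c(2, 3, 4)),
               "sum to n_chains")
})

test_that("fibril geometry is chemically sane", {
  f <- build_cellulose_fibril(fibril_spec(dp = 6))
  cen <- pair_distance_census(f)
  expect_equal(cen$n_bad, 0)
  # glycosidic O4(i) -> C1(i+1) bonds within 1.3-1.5 A on every chain
  a <- f$atoms
  for (ch in c(1, 9, 18)) {
    ai <- a[a$chain_id == ch, ]
    for (j in 1:5) {
      o4 <- unlist(ai[ai$residue_index == j & ai$atom_label == "O4",
                      c("x", "y", "z")])
      c1 <- unlist(ai[ai$residue_index == j + 1 & ai$atom_label == "C1",
                      c("x", "y", "z")])
      d <- sqrt(sum((o4 - c1)^2))
      expect_gt(d, 1.3); expect_lt(d, 1.5)
    }
  }
  # chains continue across the dp * 5.19 periodic repeat: the image of C1 of
  # residue 1 bonds the terminal O4
  ai <- a[a$chain_id == 1, ]
  o4 <- unlist(ai[ai$residue_index == 6 & ai$atom_label == "O4",
                  c("x", "y", "z")])
  c1 <- unlist(ai[ai$residue_index == 1 & ai$atom_label == "C1",
                  c("x", "y", "z")])
  d <- sqrt(sum((o4 - (c1 - c(0, 0, 6 * 5.19)))^2))
  expect_gt(d, 1.3); expect_lt(d, 1.5)
})

test_that("single-residue degenerate fibril builds", {
  f <- build_cellulose_fibril(fibril_spec(n_chains = 1, arrangement = 1,
                                          dp = 1))
  expect_equal(sum(f$atoms$atom_label == "C1"), 1)
  expect_equal(length(unique(f$atoms$residue_index)), 1)
})

test_that("xylan decoration rules follow the even-residue pattern", {
  x <- build_xylan(xylan_spec(dp = 40))
  a <- x$atoms
  ace <- sort(unique(a$residue_index[a$residue_type == "ACE"]))
  expect_identical(ace, seq(2L, 40L, 2L)) # 20 acetylated residues
  glca <- sort(unique(a$residue_index[a$residue_type == "GLCA"]))
  expect_identical(glca, c(2L, 10L, 18L, 26L, 34L)) # 5 GlcA, phase 2

  # GlcA-bearing residues carry the acetyl on O3 (checked geometrically:
  # the acetyl carbonyl bonds the swung O3, not O2)
  for (j in glca) {
    acc <- a[a$residue_index == j & a$atom_label == "AcCO", ]
    o3 <- a[a$residue_index == j & a$atom_label == "O3" &
            a$residue_type == "XYL", ]
    expect_lt(sqrt(sum((unlist(acc[, c("x", "y", "z")]) -
                        unlist(o3[, c("x", "y", "z")]))^2)), 1.5)
  }

  for (phase in c(4L, 6L, 8L)) {
    xp <- build_xylan(xylan_spec(dp = 40, glca_phase = phase))
    g <- sort(unique(xp$atoms$residue_index[xp$atoms$residue_type == "GLCA"]))
    expect_identical(g, seq(phase, 40L, 8L))
  }

  x2 <- build_xylan(xylan_spec(dp = 2))
  expect_identical(unique(x2$atoms$residue_index[x2$atoms$residue_type == "ACE"]),
                   2L)
  expect_error(xylan_spec(glca_phase = 3), "even")
})

test_that("twofold xylan hits the 2_1 conformational anchors", {
  x <- build_xylan(xylan_spec(dp = 20))
  ps <- phi_psi_sum(x, 1)
  expect_true(all(abs(ps$values - 120) < 15))
  th <- theta_2f(x, 1)
  expect_true(all(abs(th$values) < 15))
  expect_lt(scwforge:::circular_sd(th$values), 20)
})

test_that("threefold xylan lands in the 3_1 torsion regime", {
  x <- build_xylan(xylan_spec(dp = 12, conformation = "threefold"))
  ps <- phi_psi_sum(x, 1)
  # near 50 or near 190 (= -170) degrees
  d50 <- abs(scwforge:::fold_angle(ps$values - 50))
  d190 <- abs(scwforge:::fold_angle(ps$values - 190))
  expect_true(all(pmin(d50, d190) < 25))
})

test_that("disordered xylan spreads theta2f widely", {
  x <- build_xylan(xylan_spec(dp = 40, conformation = "disordered"), seed = 7)
  th <- theta_2f(x, 1)
  expect_gt(scwforge:::circular_sd(th$values), 60)
})

test_that("lignin composition, linkages and shapes meet spec", {
  l <- build_lignin(lignin_spec(), seed = 3)
  a <- l$structure$atoms
  expect_equal(sum(a$atom_label == "S1"), 13)
  expect_equal(sum(a$atom_label == "G1"), 7)
  expect_equal(nrow(l$linkages), 19)
  expect_error(lignin_spec(n_syringyl = 10, n_guaiacyl = 7), "must equal")
  expect_error(lignin_spec(linkage_fractions = c("beta-O-4" = 0.5)),
               "sum to 1")

  # dimer with pure beta-O-4
  d <- build_lignin(lignin_spec(n_monomers = 2, n_syringyl = 1,
                                n_guaiacyl = 1,
                                linkage_fractions = c("beta-O-4" = 1)),
                    seed = 1)
  expect_identical(d$linkages$type, "beta-O-4")

  # extended shape: end-to-end > 0.8 x contour
  cents <- vapply(1:20, function(i)
    colMeans(a[a$residue_index == i, c("x", "y", "z")]), numeric(3))
  e2e <- sqrt(sum((cents[, 20] - cents[, 1])^2))
  contour <- 19 * scwforge:::lignin_step()
  expect_gt(e2e, 0.8 * contour)

  # globular: radius of gyration < 0.3 x extended end-to-end
  g <- build_lignin(lignin_spec(shape = "globular"), seed = 3)
  m <- as.matrix(g$structure$atoms[, c("x", "y", "z")])
  rg <- sqrt(mean(rowSums(sweep(m, 2, colMeans(m))^2)))
  expect_lt(rg, 0.3 * e2e)
  # self-avoidance: no cross-unit contacts under 1.7 A beyond bonds
  cen <- pair_distance_census(g$structure, floor = 1.7)
  expect_equal(cen$n_bad, 0)
})

test_that("lignin builds are bit-identical per seed", {
  a <- build_lignin(lignin_spec(shape = "globular"), seed = 42)
  b <- build_lignin(lignin_spec(shape = "globular"), seed = 42)
  expect_identical(a$structure$atoms, b$structure$atoms)
  expect_identical(a$linkages, b$linkages)
  c <- build_lignin(lignin_spec(shape = "globular"), seed = 43)
  expect_false(identical(a$structure$atoms, c$structure$atoms))
})

test_that("lignin ensembles hit the beta-O-4 fraction exactly", {
  ens <- build_lignin_ensemble(20, lignin_spec(), seed = 11)
  types <- unlist(lapply(ens, function(e) e$linkages$type))
  expect_equal(mean(types == "beta-O-4"), 0.80, tolerance = 1e-12)
  # and within 2 percentage points for a non-multiple-of-5 ensemble
  ens2 <- build_lignin_ensemble(23, lignin_spec(), seed = 11)
  types2 <- unlist(lapply(ens2, function(e) e$linkages$type))
  expect_lt(abs(mean(types2 == "beta-O-4") - 0.80), 0.02)
})
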