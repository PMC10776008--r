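test_that("scenario table maps both naming systems", {
  expect_equal(scenario_spec("a")$roman, "i")
  expect_equal(scenario_spec("ii")$scenario, "b")
  expect_equal(scenario_spec("b.8")$n_fibrils, 8)
  expect_equal(scenario_spec("x")$scenario, "d")
  expect_error(scenario_spec("z"), "unknown scenario")
})

test_that("toy assembly respects counts, fractions and steric floor", {
  toy <- toy_model("b", seed = 5)
  rep <- toy$report
  expect_equal(rep$n_chains$xylan, 6)
  expect_equal(rep$n_chains$lignin, 6)
  expect_equal(rep$n_chains$cellulose, 2 * 18)
  expect_equal(rep$n_xylan_bound, round(0.7 * 6))
  s <- toy$structure
  # no cross-chain heavy-atom pair under 1.8 A (periodic)
  m <- as.matrix(s$atoms[, c("x", "y", "z")])
  chain <- as.integer(factor(s$atoms$chain_id)) - 1L
  r <- scwforge:::chain_push_cpp(m, chain, 1.8, s$box, TRUE)
  expect_equal(r$n_clash, 0)
})

test_that("assembly is bit-identical for a fixed seed", {
  s1 <- assemble_scenario(scenario_spec("b", n_fibrils = 2, n_xylan = 4,
                                        n_lignin = 4, dp = 8, seed = 21))
  s2 <- assemble_scenario(scenario_spec("b", n_fibrils = 2, n_xylan = 4,
                                        n_lignin = 4, dp = 8, seed = 21))
  expect_identical(s1$structure$atoms, s2$structure$atoms)
  expect_identical(s1$structure$box, s2$structure$box)
})

test_that("xylan-free, lignin-free assembly is just the fibrils", {
  s <- assemble_scenario(scenario_spec("a", n_fibrils = 2, n_xylan = 0,
                                       n_lignin = 0, dp = 8, seed = 1))
  fib <- build_cellulose_fibril(fibril_spec(dp = 8))
  expect_equal(nrow(s$structure$atoms), 2 * nrow(fib$atoms))
})

test_that("adjacent fibrils sit at ~25 A center-to-center", {
  toy <- toy_model("a")
  a <- toy$structure$atoms
  cel <- a[a$polymer_class == "cellulose", ]
  # fibrils were placed first: chains 1..18 and 19..36
  f1 <- colMeans(cel[cel$chain_id <= 18, c("x", "y")])
  f2 <- colMeans(cel[cel$chain_id > 18, c("x", "y")])
  d <- sqrt(sum((f1 - f2)^2))
  expect_gt(d, 22); expect_lt(d, 28)
})

test_that("compression reaches the target density and conserves mass", {
  toy <- toy_model("a")
  s0 <- toy$structure
  m0 <- structure_mass(s0)
  s1 <- compress_to_density(s0, 1.0, seed = 5)
  expect_equal(structure_mass(s1), m0, tolerance = 1e-12)
  expect_equal(nrow(s1$atoms), nrow(s0$atoms))
  expect_lt(abs(structure_density(s1) - 1.0), 0.01)
  # already at target: unchanged
  s2 <- compress_to_density(s1, structure_density(s1))
  expect_identical(s2$atoms, s1$atoms)
  # shrinking to below current density errors
  expect_error(compress_to_density(s1, 0.5), "denser")
  # fiber-axis dimension is preserved
  expect_equal(s1$box[3], s0$box[3])
})

test_that("solvation matches the moisture formula and neutralizes charge", {
  toy <- toy_model("a")
  s <- toy$structure
  dry <- structure_mass(s)
  sol <- solvate_and_neutralize(s, 3, seed = 2)
  n_w <- sum(sol$atoms$residue_type == "WAT")
  expect_equal(n_w, round(0.03 * dry / (18.015 * 0.97)))
  ach <- 100 * n_w * 18.015 / structure_mass(sol)
  expect_lt(abs(ach - 3), 100 * 18.015 / dry * 1.5) # within ~one water
  n_na <- sum(sol$atoms$residue_type == "NA")
  n_glca <- sum(s$atoms$residue_type == "GLCA" & s$atoms$atom_label == "C1")
  expect_equal(n_na, n_glca) # one cation per carboxylate: net charge zero
  expect_gt(n_na, 0)
  # waters respect the 2.4 A clearance
  w <- sol$atoms[sol$atoms$residue_type == "WAT", c("x", "y", "z")]
  d <- scwforge:::min_dist_to_set_cpp(as.matrix(w),
                                      as.matrix(s$atoms[, c("x", "y", "z")]),
                                      2.4, sol$box, TRUE)
  expect_true(all(d >= 2.4 - 1e-6))
  # moisture 0 adds nothing but ions
  s0 <- solvate_and_neutralize(s, 0, seed = 2)
  expect_equal(sum(s0$atoms$residue_type == "WAT"), 0)
})

test_that("worked moisture example: 970 kDa dry mass at 3% needs 1665 waters", {
  n_w <- round(0.03 * 970000 / (18.015 * (1 - 0.03)))
  expect_lt(abs(n_w - 1665), 1.5)
})

test_that("scenario contrasts reproduce the negative-control orderings", {
  pa <- proximity_profile(toy_model("a")$structure)
  pd <- proximity_profile(toy_model("d")$structure)
  pe <- proximity_profile(toy_model("e")$structure)
  met <- function(p, i) p$percent[i]
  # d (lignin-coated cellulose) underpredicts xylan -> cellulose vs a
  expect_lt(met(pd, 2), met(pa, 2))
  # d and e (direct lignin deposition) overpredict lignin -> cellulose vs a
  expect_gt(met(pd, 4), met(pa, 4))
  # trapped-xylan toys isolate trapped chains from lignin
  b8 <- assemble_scenario(scenario_spec("b.8", n_xylan = 20, n_lignin = 20,
                                        dp = 10, seed = 3))
  s <- b8$structure
  lig_ids <- select_atoms(s, "lignin_ring")
  xyl_chains <- unique(s$atoms$chain_id[s$atoms$polymer_class == "xylan"])
  # chains were placed trapped-first within the xylan inventory
  trapped <- head(xyl_chains, b8$report$n_xylan_trapped)
  lig_contact <- function(ch) {
    ids <- s$atoms$atom_id[s$atoms$chain_id == ch & s$atoms$element == "C"]
    percent_within(s, lig_ids, ids, 10)$percent
  }
  trap_c <- vapply(trapped, lig_contact, numeric(1))
  other_c <- vapply(setdiff(xyl_chains, trapped), lig_contact, numeric(1))
  expect_lt(max(trap_c), mean(other_c) + 1e-9)
})
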