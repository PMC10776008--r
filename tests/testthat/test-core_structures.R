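test_that("structure containers validate their invariants", {
  s <- scw_structure()
  expect_equal(nrow(s$atoms), 0)
  expect_false(s$periodic)

  expect_error(scw_structure(box = c(10, -1, 10)), "positive")
  bad <- random_structure(5)
  bad$atoms$x[2] <- NaN
  expect_error(validate_structure(bad), "finite")
  bad2 <- random_structure(5)
  bad2$atoms$polymer_class[1] <- "lignin" # GLC typed as lignin
  expect_error(validate_structure(bad2), "inconsistent")
})

test_that("mass and density bookkeeping are residue-wise", {
  x <- build_xylan(xylan_spec(dp = 40))
  # 40 xylose + 20 acetyl + 5 GlcA
  expect_equal(structure_mass(x), 40 * 132.115 + 20 * 42.037 + 5 * 176.124,
               tolerance = 1e-9)
  s <- scw_structure(x$atoms, box = c(50, 50, 210))
  expect_equal(structure_density(s),
               structure_mass(x) * 1.66054 / (50 * 50 * 210), tolerance = 1e-12)
})

test_that("PDB round trip preserves atoms, labels, classes and coordinates", {
  x <- build_xylan(xylan_spec(dp = 8))
  s <- scw_structure(x$atoms, box = c(30, 40, 50))
  path <- tempfile(fileext = ".pdb")
  write_structure(s, path)
  r <- read_structure(path)
  expect_equal(nrow(r$atoms), nrow(s$atoms))
  expect_identical(r$atoms$atom_label, s$atoms$atom_label)
  expect_identical(r$atoms$residue_type, s$atoms$residue_type)
  expect_identical(r$atoms$polymer_class, s$atoms$polymer_class)
  expect_identical(r$atoms$residue_index, s$atoms$residue_index)
  expect_equal(r$box, s$box, tolerance = 1e-6)
  expect_lt(max(abs(r$atoms$x - s$atoms$x), abs(r$atoms$y - s$atoms$y),
                abs(r$atoms$z - s$atoms$z)), 1e-3)
})

test_that("XYZ round trip preserves coordinates and box", {
  s <- random_structure(20, box = c(25, 30, 35), seed = 4)
  path <- tempfile(fileext = ".xyz")
  write_structure(s, path)
  r <- read_structure(path)
  expect_equal(nrow(r$atoms), 20)
  expect_identical(r$atoms$element, s$atoms$element)
  expect_equal(r$box, s$box, tolerance = 1e-6)
  expect_lt(max(abs(r$atoms$x - s$atoms$x)), 1e-5)
})

test_that("degenerate and malformed files are handled explicitly", {
  # empty model round trip
  p <- tempfile(fileext = ".pdb")
  write_structure(scw_structure(box = c(20, 20, 20)), p)
  r <- read_structure(p)
  expect_equal(nrow(r$atoms), 0)
  expect_equal(r$box, c(20, 20, 20))

  # hand-written 3-atom PDB with CRYST1 box
  lines <- c(
    "CRYST1   20.000   20.000   20.000  90.00  90.00  90.00 P 1",
    "ATOM      1  C1  GLC C   1       1.000   2.000   3.000  1.00  0.00      C001 C",
    "ATOM      2  O2  GLC C   1       2.500   2.000   3.000  1.00  0.00      C001 O",
    "ATOM      3  C2  GLC C   1       3.100   3.300   3.000  1.00  0.00      C001 C",
    "END")
  p2 <- tempfile(fileext = ".pdb")
  writeLines(lines, p2)
  r2 <- read_structure(p2)
  expect_equal(r2$box, c(20, 20, 20))
  expect_equal(nrow(r2$atoms), 3)
  expect_identical(r2$atoms$polymer_class, rep("cellulose", 3))

  # malformed coordinate record names the offending line
  lines[3] <- sub("   2.500", "  bogus ", lines[3])
  writeLines(lines, p2)
  expect_error(read_structure(p2), "line 3")

  # truncated XYZ
  p3 <- tempfile(fileext = ".xyz")
  writeLines("5", p3)
  expect_error(read_structure(p3), "truncated")
})

test_that("multi-model PDB reads back as a trajectory", {
  s <- random_structure(10, seed = 2)
  tr <- jitter_structure(s, 0.2, n_frames = 3, seed = 9)
  p <- tempfile(fileext = ".pdb")
  write_structure(tr, p)
  r <- read_structure(p, multi = TRUE)
  expect_s3_class(r, "scw_trajectory")
  expect_length(r, 3)
  expect_equal(r[[2]]$atoms$x, tr[[2]]$atoms$x, tolerance = 1e-3)
  # single-model read takes the first frame
  r1 <- read_structure(p)
  expect_equal(r1$atoms$x, s$atoms$x, tolerance = 1e-3)
})

test_that("minimum-image distance matches the 27-image oracle", {
  expect_equal(min_image_distance(c(1, 1, 1), c(1, 1, 1), c(10, 10, 10)), 0)
  expect_equal(min_image_distance(c(0, 0, 0), c(19, 0, 0), c(20, 20, 20)), 1)
  expect_error(min_image_distance(c(0, 0, 0), c(1, 1, 1), c(0, 10, 10)),
               "positive")

  # the 27-image oracle is valid when points lie within one box image
  set.seed(11)
  box <- c(17, 23, 31)
  a <- sweep(matrix(runif(3000), ncol = 3), 2, box, "*")
  b <- sweep(matrix(runif(3000), ncol = 3), 2, box, "*")
  d <- min_image_distance(a, b, box)
  d27 <- vapply(seq_len(nrow(a)), function(i) min_image_27(a[i, ], b[i, ], box),
                numeric(1))
  expect_lt(max(abs(d - d27)), 1e-9)
  expect_true(all(d <= sqrt(sum((box / 2)^2)) + 1e-12))
})

test_that("wrapping leaves pairwise minimum-image distances unchanged", {
  s <- random_structure(60, box = c(18, 22, 26), seed = 7)
  shifted <- s
  shifted$atoms$x <- shifted$atoms$x + 53.7
  shifted$atoms$y <- shifted$atoms$y - 17.1
  shifted$atoms$z <- shifted$atoms$z + 5.5
  w <- wrap_structure(shifted)
  m1 <- as.matrix(s$atoms[, c("x", "y", "z")])
  m2 <- as.matrix(w$atoms[, c("x", "y", "z")])
  i <- rep(1:10, each = 6); j <- rep(11:16, times = 10)
  d1 <- min_image_distance(m1[i, ], m1[j, ], s$box)
  d2 <- min_image_distance(m2[i, ], m2[j, ], s$box)
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("selections resolve reproducibly and in order", {
  s <- toy_model("a")$structure
  sel <- scw_selection("xylan", labels = "AcMe")
  ids <- resolve_selection(s, sel)
  expect_identical(ids, sort(ids))
  expect_identical(ids, resolve_selection(s, sel))
  expect_true(all(s$atoms$atom_label[ids + 1] == "AcMe"))
})
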