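test_that("gen_spectrum is reproducible and peaks where it should", {
  pk <- peak_model(120, 4, 0.6, "solo", "lignin")
  g <- gen_spectrum(pk, 10, noise_sd = 0, seed = 1)
  sp <- g$spectrum
  expect_equal(sp$ppm[which.max(sp$intensity)], 120, tolerance = 0.2)

  g1 <- gen_spectrum(default_peak_table(), 50, noise_sd = 1, seed = 7)
  g2 <- gen_spectrum(default_peak_table(), 50, noise_sd = 1, seed = 7)
  expect_identical(g1$spectrum$intensity, g2$spectrum$intensity)
  g3 <- gen_spectrum(default_peak_table(), 50, noise_sd = 1, seed = 8)
  expect_false(identical(g1$spectrum$intensity, g3$spectrum$intensity))
})

test_that("noiseless spectra integrate to the closed-form areas", {
  peaks <- default_peak_table()
  amps <- seq(20, 80, length.out = nrow(peaks))
  g <- gen_spectrum(peaks, amps, noise_sd = 0, seed = 1, n = 16384,
                    ppm_range = c(1200, -1000)) # Lorentzian tails need room
  sp <- g$spectrum
  dx <- abs(mean(diff(sp$ppm)))
  total <- sum(sp$intensity) * dx
  expect_equal(total, sum(g$ground_truth$areas), tolerance = 1e-3)
})

test_that("recovery datasets hit their tau limits", {
  peaks <- default_peak_table()
  pairs <- data.frame(sink = c("L S3/5 G3/4", "C 1C4"), A = c(0.8, 0.4),
                      T_SD = c(300, 2000))
  ds <- gen_recovery_dataset(pairs, peaks, noise = 0, seed = 2,
                             tau_grid = c(1e-6, 10, 1e7))
  d0 <- deconvolve(ds$selective[[1]], peaks, shift_tol = 0)
  dI <- deconvolve(ds$selective[[3]], peaks, shift_tol = 0)
  dn <- deconvolve(ds$nonselective, peaks, shift_tol = 0)
  # tau -> 0: sink amplitudes zero; tau -> inf: A per sink
  expect_equal(unname(d0$areas["L S3/5 G3/4"] / dn$areas["L S3/5 G3/4"]), 0,
               tolerance = 1e-6)
  expect_equal(unname(dI$areas["L S3/5 G3/4"] / dn$areas["L S3/5 G3/4"]), 0.8,
               tolerance = 1e-3)
  expect_equal(unname(dI$areas["C 1C4"] / dn$areas["C 1C4"]), 0.4,
               tolerance = 1e-3)
  # the source assignment stays fully polarized
  expect_equal(unname(d0$areas["Xn AcMe"] / dn$areas["Xn AcMe"]), 1,
               tolerance = 1e-3)
})

test_that("pipeline round trip recovers (A, T_SD) at 2% noise", {
  peaks <- default_peak_table()
  # every lignin peak is a sink so the polymer-level asymptote equals A
  pairs <- data.frame(sink = c("L S3/5 G3/4", "L S1/G1", "L OMe"),
                      A = 0.8, T_SD = 300)
  ds <- gen_recovery_dataset(pairs, peaks, noise = 0.02, seed = 11)
  curves <- recovery_curves(ds$tau_m, ds$selective, ds$nonselective, ds$peaks,
                            source_label = "Xn AcMe")
  f <- fit_tsd(curves[["lignin"]])
  expect_lt(abs(f$T_SD / 300 - 1), 0.10)
  expect_lt(abs(f$asymptote / 0.8 - 1), 0.05)
})

test_that("jitter respects its seed, amplitude and chi-distributed norms", {
  s <- toy_model("a")$structure
  tr0 <- jitter_structure(s, 0, n_frames = 3, seed = 1)
  expect_identical(tr0[[1]]$atoms, tr0[[3]]$atoms) # amplitude 0: identical

  tr1 <- jitter_structure(s, 0.4, n_frames = 2, seed = 5)
  tr2 <- jitter_structure(s, 0.4, n_frames = 2, seed = 5)
  expect_identical(tr1[[2]]$atoms, tr2[[2]]$atoms)
  expect_identical(tr1[[1]]$atoms, s$atoms) # frame 1 is the input

  # displacement norms follow the 3D chi distribution: mean = a * 2 sqrt(2/pi)
  s_np <- s; s_np$periodic <- FALSE; s_np$box <- NULL # avoid wrap artifacts
  tr <- jitter_structure(s_np, 0.4, n_frames = 6, seed = 9)
  norms <- unlist(lapply(2:6, function(i) {
    sqrt((tr[[i]]$atoms$x - s$atoms$x)^2 + (tr[[i]]$atoms$y - s$atoms$y)^2 +
         (tr[[i]]$atoms$z - s$atoms$z)^2)
  }))
  expect_equal(mean(norms), 0.4 * 2 * sqrt(2 / pi), tolerance = 0.01)
})

test_that("proximity metrics are stable under small jitter", {
  s <- toy_model("a")$structure
  tr <- jitter_structure(s, 0.5, n_frames = 4, seed = 13)
  p0 <- proximity_profile(s)$percent
  for (i in 2:4) {
    pi_ <- proximity_profile(tr[[i]])$percent
    expect_lt(max(abs(pi_ - p0)), 2) # < 2 percentage points
  }
})
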