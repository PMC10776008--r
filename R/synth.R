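# Synthetic-data generators: every input the analysis stages need, with
# serialized ground truth, so the pipeline is testable without downloads.

# The 16 spin-diffusion mixing times (ms) of the experimental protocol.
TAU_GRID <- c(0.001, 2, 5, 10, 20, 50, 100, 200, 500, 750, 1000, 1500,
              2000, 3000, 4000, 5000)

# A representative assigned peak table for the three-polymer wall:
# cellulose C1/C4/C6 split into domain 1 (sharp) and domain 2 (broad)
# components, xylan backbone + acetyl methyl (22 ppm) and carbonyl
# (170 ppm), lignin aromatics (~150 ppm) and methoxy (56 ppm).
#' Default assigned peak table for synthetic wall spectra
#'
#' @return a [peak_model()] with 12 assigned pseudo-Voigt peaks.
#' @export
default_peak_table <- function() {
  peak_model(
    center = c(105, 89, 84, 65, 62, 75,
               102, 72, 22, 170,
               153, 135, 56),
    fwhm = c(2.0, 1.6, 3.2, 1.6, 3.0, 3.5,
             2.2, 3.0, 2.2, 2.5,
             4.0, 4.5, 2.4),
    gauss_fraction = rep(0.7, 13),
    assignment = c("C C1", "C 1C4", "C 2C4", "C 1C6", "C 2C6", "C C2/3/5",
                   "Xn C1", "Xn C2/3/4", "Xn AcMe", "Xn AcCO",
                   "L S3/5 G3/4", "L S1/G1", "L OMe"),
    polymer_class = c(rep("cellulose", 6), rep("xylan", 4),
                      rep("lignin", 3))
  )
}

#' Generate a synthetic 1D spectrum with known ground truth
#'
#' Sum of pseudo-Voigt lines on a uniform descending ppm grid plus seeded
#' Gaussian noise.
#'
#' @param peaks a [peak_model()].
#' @param amplitudes per-peak amplitudes (>= 0), recycled if length 1.
#' @param noise_sd absolute noise standard deviation (intensity units).
#' @param seed RNG seed.
#' @param ppm_range axis range (default 200..0 ppm).
#' @param n points (default 2048).
#' @return list: `spectrum` (a `spectrum1d` with `noise_sd` set) and
#'   `ground_truth` (amplitudes, areas, noise_sd, seed).
#' @export
gen_spectrum <- function(peaks, amplitudes, noise_sd = 0, seed = 1L,
                         ppm_range = c(200, 0), n = 2048L) {
  if (length(amplitudes) == 1) amplitudes <- rep(amplitudes, nrow(peaks))
  stopifnot(length(amplitudes) == nrow(peaks), all(amplitudes >= 0))
  x <- seq(max(ppm_range), min(ppm_range), length.out = n)
  y <- rep(0, n)
  for (i in seq_len(nrow(peaks)))
    y <- y + amplitudes[i] * pseudo_voigt(x, peaks$center[i], peaks$fwhm[i],
                                          peaks$gauss_fraction[i])
  if (noise_sd > 0) y <- y + with_seed(seed, rnorm(n, 0, noise_sd))
  gt <- list(amplitudes = setNames(amplitudes, peaks$assignment),
             areas = setNames(amplitudes * pv_area_unit(peaks$fwhm,
                                                        peaks$gauss_fraction),
                              peaks$assignment),
             noise_sd = noise_sd, seed = seed)
  list(spectrum = spectrum1d(x, y, noise_sd = if (noise_sd > 0) noise_sd
                                              else NULL),
       ground_truth = gt)
}

#' Generate a paired selective/nonselective mixing-time series
#'
#' The nonselective series is constant (every carbon fully polarized). In
#' the selective series each sink assignment's amplitude builds up as
#' `A * (1 - exp(-tau / T_SD))` while the source assignment stays at full
#' amplitude; assignments that are neither source nor sink stay dark.
#'
#' @param pairs data.frame with columns `sink` (assignment label), `A`
#'   (asymptotic recovered fraction) and `T_SD` (ms).
#' @param peaks a [peak_model()]; all `pairs$sink` and `source` must be in
#'   its assignments.
#' @param source source assignment label (kept fully polarized).
#' @param amplitudes nonselective per-peak amplitudes (recycled).
#' @param tau_grid mixing times, ms (default the 16-point protocol grid).
#' @param noise relative noise: sd = `noise` x max nonselective intensity.
#' @param seed RNG seed.
#' @return list: `tau_m`, `selective` (list of `spectrum1d`),
#'   `nonselective` (a `spectrum1d`), `peaks`, `ground_truth`.
#' @export
gen_recovery_dataset <- function(pairs, peaks = default_peak_table(),
                                 source = "Xn AcMe", amplitudes = 100,
                                 tau_grid = TAU_GRID, noise = 0.02,
                                 seed = 1L) {
  stopifnot(all(diff(tau_grid) > 0),
            all(pairs$sink %in% peaks$assignment),
            source %in% peaks$assignment)
  if (length(amplitudes) == 1) amplitudes <- rep(amplitudes, nrow(peaks))
  ref <- gen_spectrum(peaks, amplitudes, noise_sd = 0, seed = seed)
  noise_sd <- noise * max(ref$spectrum$intensity)
  nonsel <- gen_spectrum(peaks, amplitudes, noise_sd = noise_sd,
                         seed = seed * 1000L + 1L)
  sel <- lapply(seq_along(tau_grid), function(i) {
    amp <- numeric(nrow(peaks))
    amp[match(source, peaks$assignment)] <-
      amplitudes[match(source, peaks$assignment)]
    for (r in seq_len(nrow(pairs))) {
      j <- match(pairs$sink[r], peaks$assignment)
      amp[j] <- amplitudes[j] * pairs$A[r] *
        (1 - exp(-tau_grid[i] / pairs$T_SD[r]))
    }
    gen_spectrum(peaks, amp, noise_sd = noise_sd,
                 seed = seed * 1000L + 1L + i)$spectrum
  })
  list(tau_m = tau_grid, selective = sel, nonselective = nonsel$spectrum,
       peaks = peaks,
       ground_truth = list(pairs = pairs, source = source,
                           amplitudes = setNames(amplitudes,
                                                 peaks$assignment),
                           noise_sd = noise_sd, seed = seed))
}

#' Generate a noiseless recovery curve directly
#'
#' Convenience generator for estimator studies: evaluates the saturating
#' exponential on a mixing-time grid and attaches homoscedastic noise.
#'
#' @param A asymptote; `T_SD` time constant (ms).
#' @param T_SD time constant, ms.
#' @param tau_grid mixing times, ms.
#' @param noise_sd absolute per-point noise sd.
#' @param seed RNG seed.
#' @param source_label,sink_label labels.
#' @return a [recovery_curve()] plus ground truth attributes.
#' @export
gen_recovery_curve <- function(A, T_SD, tau_grid = TAU_GRID, noise_sd = 0.01,
                               seed = 1L, source_label = "source",
                               sink_label = "sink") {
  f <- A * (1 - exp(-tau_grid / T_SD))
  if (noise_sd > 0)
    f <- f + with_seed(seed, rnorm(length(tau_grid), 0, noise_sd))
  cu <- recovery_curve(source_label, sink_label, tau_grid, f,
                       rep(max(noise_sd, 1e-6), length(tau_grid)))
  attr(cu, "ground_truth") <- list(A = A, T_SD = T_SD, noise_sd = noise_sd,
                                   seed = seed)
  cu
}

#' Jitter a structure into pseudo-equilibrated snapshots
#'
#' Adds per-atom seeded Gaussian displacements (sd = `amplitude` per axis)
#' and wraps into the box; a cheap stand-in for equilibrated MD snapshots.
#' Frame 1 is the input structure unchanged.
#'
#' @param s an `scw_structure`.
#' @param amplitude displacement sd per axis, Angstrom (>= 0).
#' @param n_frames total frames including the unperturbed first one.
#' @param seed RNG seed.
#' @return an `scw_trajectory` (list of structures) with a `ground_truth`
#'   attribute.
#' @export
jitter_structure <- function(s, amplitude, n_frames = 2L, seed = 1L) {
  stopifnot(amplitude >= 0, n_frames >= 1)
  m0 <- coords_matrix(s)
  frames <- vector("list", n_frames)
  frames[[1]] <- s
  if (n_frames > 1) with_seed(seed, {
    for (i in 2:n_frames) {
      d <- matrix(rnorm(length(m0), 0, amplitude), nrow(m0))
      si <- set_coords(s, m0 + d)
      frames[[i]] <- if (s$periodic) wrap_structure(si) else si
    }
  })
  structure(frames, class = "scw_trajectory",
            ground_truth = list(amplitude = amplitude, seed = seed,
                                n_frames = n_frames))
}
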