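Package: scwforge
Title: Rule-Based Atomistic Models of the Hardwood Secondary Cell Wall and
    Their Comparison to Solid-State NMR Proximity Observables
Version: 0.1.0
Authors@R:
    person("scwforge", "developers", email = "scwforge@example.org",
           role = c("aut", "cre"))
Description: Constructs atomistic models of the lignified plant secondary
    cell wall from composition rules: 18-chain cellulose I-beta elementary
    fibrils, acetylated glucuronoxylan chains, and syringyl/guaiacyl lignin
    20-mers, assembled into periodic packing scenarios, compressed to a
    target density and solvated to a target moisture. Scores models against
    13C-13C spin-diffusion observables with a periodic proximity statistic
    (percentage of sink carbons within a cutoff of source carbons), computes
    xylan conformational metrics (glycosidic phi+psi sums and the
    acetate-orientation dihedral between consecutive acetylated xyloses),
    and quantifies selective/nonselective 1D spin-diffusion spectra through
    pseudo-Voigt deconvolution, magnetization-recovery curves, spin-diffusion
    time-constant fits, and distance-range classification. Ships synthetic
    generators for spectra, recovery series and coordinate snapshots with
    known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
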