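# scwforge

Rule-based atomistic models of the hardwood secondary cell wall (SCW),
scored against solid-state NMR spin-diffusion observables.

## What problem this solves, and for whom

The lignified secondary wall of hardwoods is a composite of cellulose
elementary fibrils, acetylated glucuronoxylan, and syringyl/guaiacyl (S/G)
lignin. Selective ¹³C–¹³C spin-diffusion ssNMR constrains how these
polymers are arranged: after selectively inverting a source carbon pool
(xylan acetyl methyls at 22 ppm, or lignin S3/5–G3/4 ring carbons near
150 ppm), the fraction of each sink pool that receives magnetization
within a mixing time τₘ reports how much of that polymer lies within
~1 nm of the source, and the transfer time constant T_SD maps to
internuclear distance. `scwforge` is for structural biologists and
molecular modelers who want to (i) build candidate atomistic SCW models
from composition rules, (ii) score them against those NMR observables,
and (iii) quantify the 1D spin-diffusion spectra themselves.

## The statistic at the core

For a periodic model with source atom set *S* and sink atom set *K* in an
orthorhombic box, the proximity statistic is

    P(S → K; r) = 100 · |{ k ∈ K : min_{s ∈ S} d_min(k, s) ≤ r }| / |K|

with `d_min` the minimum-image distance and r = 10 Å (1 nm). The four
canonical metrics — xylan→lignin, xylan→cellulose, lignin→xylan,
lignin→cellulose — are compared with the experimental asymptotes
(~80 / 40 / 60 / 20 %), and models are ranked by mean absolute mismatch.
On the NMR side, recovery curves f(τ) per sink polymer are ratios of
deconvolved selective/nonselective peak areas, fitted with
f(τ) = A·(1 − exp(−τ/T_SD)); T_SD maps to a distance range
(≤ 500 ms → 3–5 Å; ≤ 2.5 s → 5–10 Å; slower → 5 to >10 Å).

## Worked example

```r
library(scwforge)

# a small two-fibril model under packing hypothesis "a"
# (all xylan bound on cellulose, lignin random in the matrix)
toy <- assemble_scenario(scenario_spec("a", n_fibrils = 2, n_xylan = 6,
                                       n_lignin = 6, dp = 10, seed = 3))
toy$report
proximity_profile(toy$structure)

# conformational check of one bound xylan chain
xch <- unique(toy$structure$atoms$chain_id[
  toy$structure$atoms$polymer_class == "xylan"])[1]
summary(phi_psi_sum(toy$structure, xch)$values)
classify_bound(toy$structure, xch)

# NMR: synthesize a recovery series with known truth and re-fit it
pairs <- data.frame(sink = c("L S3/5 G3/4", "L S1/G1", "L OMe"),
                    A = 0.8, T_SD = 300)
ds <- gen_recovery_dataset(pairs, source = "Xn AcMe", noise = 0.02, seed = 1)
curves <- recovery_curves(ds$tau_m, ds$selective, ds$nonselective, ds$peaks,
                          source_label = "Xn AcMe")
fit <- fit_tsd(curves[["lignin"]])
fit
distance_class(fit)
```

Output (exactly reproduced by the code above):

```
<assembly report> scenario a (i), 2 fibrils, seed 3
  atoms 6522, mass 92934 Da, box 87.2 x 87.2 x 51.9 A
  density 0.391 g/cm^3, moisture 0.00%, counterions 0
  chains: cellulose=36, lignin=6, xylan=6
  xylan: 6 bound, 0 trapped, 0 matrix

       source      sink  percent sd n_sink reference
1  xylan_AcMe    lignin 14.94523 NA   1278        80
2  xylan_AcMe cellulose 18.24074 NA   2160        40
3 lignin_ring     xylan 13.48039 NA    408        60
4 lignin_ring cellulose  0.00000 NA   2160        20

   Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
  123.4   123.4   123.4   123.4   123.4   123.4
           bound contact_fraction           cutoff
             1.0              1.0              4.5

<spin_diffusion_fit> monoexponential: T_SD = 300.4 ms (sd 1.8), asymptote = 0.799 (sd 0.001)
[1] "3-5 A"
```

Reading it: the report says what was built (chain counts by class, how
much xylan is cellulose-bound vs trapped vs matrix, mass, box, density);
the profile gives the four proximity percentages next to their
experimental reference values (sparse un-compressed toys sit far below
the dense-wall references — the profile is used to *rank* packing
hypotheses, e.g. this "a"-like toy scores 0% lignin→cellulose while a
"d"-like negative control with lignin deposited on cellulose scores
~39%); the bound chain sits in the twofold conformation (φ+ψ = 123.4°,
inside the 2₁ anchor band 120 ± 15°) with every residue in cellulose
contact; and the fit recovers the generating T_SD = 300 ms and A = 0.8
within noise — 300 ms classifies as a 3–5 Å contact, the lignin↔xylan
regime.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "scwforge", package = "scwforge"))')
Rscript $CLI build --scenario b.8 --density 1.5 --moisture 3 --seed 42 \
        -o model.pdb --report report.json
Rscript $CLI proximity model.pdb --cutoff-nm 1.0 --out profile.json
Rscript $CLI torsions model.pdb --chain 145 --metric theta2f --hist theta.csv
Rscript $CLI synth recovery --seed 7 --out rec
Rscript $CLI nmr fit-recovery --selective rec_sel_0001.csv,... \
        --nonselective rec_nonsel.csv --peaks rec_peaks.csv \
        --tau 0.001,2,5,... --out curves.json
Rscript $CLI scorecard model_a.pdb model_b8.pdb --out scores.csv
```

All subcommands honor `--seed`; reports are JSON/CSV and stamp the package
version and seed.

## File conventions

PDB: `CRYST1` box; polymer class encoded in the chainID column and the
segid (C=cellulose, X=xylan, L=lignin, W=water, I=ion + chain number), so
models re-read bit-compatibly; resSeq is the 1-based residue index from
the reducing end. XYZ carries the box as a `box=a b c` comment token.
Atom serials above 99999 wrap (readers renumber).

## Scope notes

Molecular dynamics, force fields and pulse-sequence simulation are out of
scope: compression is a deterministic rigid-chain scale-and-relax loop,
"equilibrated snapshots" are jittered frames, and the experimental
percentages/T_SD values enter only as scorecard reference constants and
distance-class anchors. See `vignettes/scw-methods.Rmd` for the model
details, assumptions and limitations.
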