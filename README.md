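# stereoisa

Unsupervised learning of binocular complex-cell models from stereo image
patches, and measurement of their disparity selectivity.

`stereoisa` is for researchers in natural scene statistics and early
vision modelling who want to test whether ideal disparity detectors —
phase-invariant units tuned to interocular phase difference — emerge from
the statistics of binocular images under an efficient-coding objective.
The package learns the models by **Independent Subspace Analysis** (ISA)
and then characterizes each one the way a physiologist would: sine-grating
and bar response maps, a disparity tuning curve, the **Disparity
Discrimination Index** (DDI), and a tuned-excitatory / tuned-inhibitory /
near / far symmetry label.

## The model in brief

Binocular patches (left ∥ right, each eye centred and normalised, the
concatenation renormalised) are PCA-whitened to $z_i$.  ISA fits an
orthonormal component matrix $W$, rows grouped into two-subunit subspaces
$S$, by maximising the smoothed sparse-subspace likelihood

$$\frac1N\sum_i\sum_S -\sqrt{\sum_{j\in S}\langle w_j, z_i\rangle^2 +
\varepsilon},$$

gradient ascent with symmetric re-orthonormalisation, started from a
symmetric fixed-point ICA solution grouped by energy correlation.  Each
subspace becomes a complex cell: energy read-out
$\sum_j\langle x, w_j\rangle^2$ (or max-pooling $\max_j|\langle x,
w_j\rangle|$).  Probing with binocular gratings whose phases vary
independently gives a phase–phase response map; averaging along circular
diagonals gives the tuning curve over phase disparity $d=\phi_R-\phi_L$; a
closed-form sinusoid fit yields

$$\mathrm{DDI} = \frac{R_{\max}-R_{\min}}{(R_{\max}-R_{\min}) +
2\sqrt{SSE/(N-3)}}$$

with the residual taken over every map cell, and the peak location of the
fitted sinusoid determines the symmetry class.  A seeded synthetic stereo
generator (naturalistic edge structure with an exact $1/f$ amplitude
spectrum; right view warped by a smooth near-zero disparity field) makes
the whole analysis self-contained.

## Worked example

An ideal quadrature-pair detector built as a fixture is recovered
perfectly by the measurement chain:

```r
library(stereoisa)
det <- make_ideal_detector(25, frequency = 0.12, orientation = 0.4,
                           phase_disparity = 0)
ch <- characterize_model(det)
c(ddi = ch$ddi, symmetry = ch$symmetry)
#>   ddi symmetry
#> 0.995       TE
```

DDI close to 1 says virtually all response variation is explained by
disparity; `TE` says the tuning curve has an even-symmetric peak at zero
disparity (the cell prefers stimuli on the horopter).

A desk-scale end-to-end run (20 synthetic 512×512 pairs, 50,000 patches,
50 subspaces; a few minutes on one core):

```r
cfg <- run_config(source = "synthetic", n_pairs = 20, width = 512,
                  height = 512, n_patches = 50000, patch_px = 25,
                  n_subspaces = 50, seed = 101)
res <- run_pipeline(cfg, "run_desk")
s <- res$summaries$energy
c(frac_tuned = s$frac_above_threshold, p95 = s$ddi_p95, max = s$ddi_max)
#> frac_tuned        p95        max
#>      0.660      0.900      0.981
s$label_proportions
#>   label proportion      ci_lo     ci_hi
#> 1    TE 0.69696970 0.54545455 0.8181818
#> 2    TI 0.15151515 0.05984848 0.3030303
#> 3  NEAR 0.06060606 0.00000000 0.1515152
#> 4   FAR 0.09090909 0.02954545 0.2121212
```

Disparity-tuned models are dominated by TE and TI — detection is largely
confined to the horopter, with odd-symmetric (NEAR/FAR) classes rare —
and the max-pooling read-out of the same subunits tops out at a lower
maximum DDI (0.814 here) than the energy read-out, because its response
function is less smooth across phase.  On these synthetic scenes a
majority of subspaces are disparity-tuned; photographic stereo sets, with
their occlusions and wide disparity range, push the DDI distribution
bottom-heavy (see the methods vignette for the full discussion).

Each `run_pipeline` stage is persisted in the output directory and reruns
resume from the last completed stage; identical config and seed reproduce
byte-identical summaries.  A thin CLI wrapper is installed at
`inst/scripts/stereoisa-run.R` (`Rscript stereoisa-run.R config.yaml
outdir` with a YAML config read by `read_run_config()`).

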