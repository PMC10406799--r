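# compaudit

Task-oriented auditing of lossy compression for volumetric vessel
segmentation.

Preclinical volumetric imaging (high-resolution episcopic microscopy,
micro-CT, micro-MRI) produces 16-bit stacks of tens of gigabytes, and lossy
compression can shrink them a hundred-fold — but how much compression does a
*segmentation task* tolerate? `compaudit` answers this the way a study
team would: segment the compressed reconstructions, score them against the
uncompressed reference with the **Jaccard index**
(JI = |X∩Y| / |X∪Y|, per slice, averaged over the stack) and the
**average Hausdorff distance**
(HD = (mean<sub>x∈X</sub> min<sub>y</sub> d(x,y) +
mean<sub>y∈Y</sub> min<sub>x</sub> d(y,x)) / 2),
and normalize the result against human observer variability: a compression
level whose error stays below the *inter-observer* disagreement (mean JI at
least the baseline's, mean HD at most the baseline's) is a **valid
compression** — it perturbs the analysis less than swapping annotators
would.

The package is self-contained and fully synthetic-data-driven:

* **phantoms** — tubular-vessel volumes with ground truth, plus simulated
  observers (boundary jitter, small-structure dropout, timepoint drift);
* **reference codec** — slice-wise wavelet coding with PSNR-targeted
  bisection rate control (±0.5 dB), and grouped inter-slice predictive
  coding with quantization-level search matched to a reference PSNR;
  concrete byte counts from losslessly packed coefficient streams;
* **metrics** — per-slice/stack JI, exact average HD, per-pixel MS-SSIM
  maps;
* **variability** — valid-slice selection (JI ≥ t between an observer's two
  timepoints, default t = 0.7), intra-/inter-observer baselines (IaOV,
  IeOV);
* **texture** — weighted total-variation audit of annotation bounding
  boxes (ΔwTV% versus raw);
* **report** — Tukey multiple comparisons, the validity decision rule,
  rate-distortion curves, segmentation-complexity profiles, and
  storage-reduction arithmetic for study planning.

## Worked example

```r
library(compaudit)

ph <- generate_phantom(phantom_config(shape = c(64, 64, 32), seed = 7))
ladder <- make_fixture_ladder(ph$volume, c(45, 40, 35, 30))
for (r in ladder) print(r)
#> <compression_result> wavelet, control 45, CR 8.6, PSNR 45.25 dB, 30528 bytes
#> <compression_result> wavelet, control 40, CR 13.2, PSNR 40.20 dB, 19865 bytes
#> <compression_result> wavelet, control 35, CR 19.5, PSNR 35.24 dB, 13468 bytes
#> <compression_result> wavelet, control 30, CR 57.4, PSNR 29.66 dB, 4568 bytes

for (r in ladder) {
  rep_ <- jaccard_stack(otsu_segment(r$reconstructed), ph$mask)
  cat(sprintf("target %g dB: stack JI %.3f, avg HD %.4f voxels\n",
              r$control_param, rep_$stack_ji, rep_$avg_hd))
}
#> target 45 dB: stack JI 1.000, avg HD 0.0000 voxels
#> target 40 dB: stack JI 0.989, avg HD 0.0053 voxels
#> target 35 dB: stack JI 0.910, avg HD 0.0423 voxels
#> target 30 dB: stack JI 0.652, avg HD 0.2367 voxels
```

Each rung achieves its PSNR target within ±0.5 dB; compression ratio rises
as quality falls, and the automated segmentation degrades gradually — JI
drops from perfect overlap to 0.65 and the mean boundary error grows to a
quarter voxel at the strongest compression.

Observer baselines on the same phantom:

```r
omA <- observer_model(seed = 11); omB <- observer_model(seed = 23)
recA <- observer_record("A", simulate_observer(ph$mask, omA, 0),
                             simulate_observer(ph$mask, omA, 1))
recB <- observer_record("B", simulate_observer(ph$mask, omB, 0, "B"),
                             simulate_observer(ph$mask, omB, 1, "B"))
ia <- iaov(recA); ie <- ieov(recA, recB)
#> IaOV: JI 0.815 HD 0.127 (14 valid slices)
#> IeOV: JI 0.832 HD 0.119
```

(Single runs are stochastic; across replicate seeds intra-observer
agreement exceeds inter-observer agreement on average, as the test suite
verifies.) The 40 dB rung above scores JI 0.989 / HD 0.0053 — far better
than either baseline, hence a *valid compression* under the decision rule;
`run_audit()` assembles these decisions, the Tukey comparison, the ΔwTV
texture table and the CR-quality curve into one bundle.

Study-level planning arithmetic:

```r
storage_reduction(data.frame(
  modality = c("HREM", "MRI", "CT"), n_datasets = 10,
  raw_size_mb = c(51000, 36, 300), chosen_cr = c(274, 52, 34)))$display_total
#> [1] "510 GB -> 2 GB (262-fold)"
```

A command-line wrapper ships at `inst/cli/audit.R`
(`phantom` / `compress` / `segment` / `run` subcommands).

## Documentation

The methods vignette (`vignettes/compression-audit.Rmd`) describes the
model and assumptions, every tunable parameter with units and defaults,
what the phantom generator does and does not emulate, numerical choices
(tolerances, tie-breaks, degenerate inputs), and known limitations.
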