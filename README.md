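# metradsp

Treatment-response assessment of pelvic lymph nodes from 3D segmentation
masks, following the MET-RADS-P nodal criteria (the RECIST 1.1-style rules
used for nodal disease in metastatic prostate cancer), plus the statistical
battery for comparing two segmentation or assessment sources.

## Who this is for

Groups building or validating (semi)automated node-tracking pipelines on
pelvic MRI: you have label volumes (NIfTI) from some segmentation source —
a 3D U-Net, a human reader, a phantom generator — at baseline and one or
more follow-ups, and you want, reproducibly and auditable:

1. per-node **short/long axial diameters** (caliper-style, in mm);
2. MET-RADS-P **size categories** — target (short axis ≥ 15 mm),
   nontarget (10–15 mm), nonpathological (< 10 mm);
3. node **matching across timepoints** (automatic by centroid distance,
   manual override always wins — the "semiautomated" part);
4. per-category **CR / PR / SD / PD calls** with the evidence that
   justifies them;
5. **agreement statistics** between two sources: Dice similarity (DSC),
   volumetric similarity (VS), Bland–Altman limits of agreement on percent
   diameter differences, Cohen's kappa, and accuracy with exact CIs.

## The rules in brief

Let $S_t$ be the sum of short-axis diameters of the baseline-designated
target nodes at timepoint $t$, and nadir $= \min S$ over baseline and all
earlier timepoints. For target disease:

| Call | Condition |
|------|-----------|
| CR | every target node < 10 mm (precedence over PD) |
| PD | $S_t -$ nadir $\ge 20\%$ of nadir **and** $\ge 5$ mm |
| PR | $S_t \le 70\%$ of baseline |
| SD | otherwise |

Nontarget disease: CR when all baseline nontarget nodes fall below 10 mm
with no new pathological node; PD on any new pathological node or
unequivocal progression (≥ 15 mm with ≥ 20 % and ≥ 5 mm growth); else SD.
Nonpathological nodes: PD when any reaches 10 mm, else SD. All comparisons
inclusive; every threshold lives in `response_rules()`.

## Worked example

Build a one-patient phantom series — a 26 mm target, a 12.5 mm nontarget
and a 6 mm nonpathological node — where the target halves, the nontarget
is stable, and the small node more than doubles:

```r
library(metradsp)

spec <- phantom_spec(list(
  list(center_mm = c(120, 120, 48), semi_axes_mm = c(16, 13, 13)),   # target
  list(center_mm = c(280, 280, 48), semi_axes_mm = c(8, 6.25, 9.6)), # nontarget
  list(center_mm = c(120, 280, 48), semi_axes_mm = c(4, 3, 6.5))))   # nonpath.
traj <- trajectory_spec(matrix(c(0.5, 1.0, 2.2), nrow = 3, ncol = 1))
sim  <- simulate_series(spec, traj)

baseline <- measure_nodes(sim$volumes[[1]])
baseline[, c("node_id", "short_mm", "long_mm", "slice", "category")]
#>   node_id short_mm long_mm slice        category
#> 1       1    27.06  32.693    12          target
#> 2       2    10.50  15.652    12       nontarget
#> 3       3     7.00   7.826    12 nonpathological

series <- match_nodes("patient01",
  list(baseline = baseline, followup1 = measure_nodes(sim$volumes[[2]])))
assess_series(series)[, c("timepoint", "category", "call",
                          "baseline_sum_mm", "current_sum_mm",
                          "percent_change_from_baseline")]
#>   timepoint        category call baseline_sum_mm current_sum_mm
#> 1 followup1          target   PR           27.06          12.25
#> 2 followup1       nontarget   SD           10.50          10.50
#> 3 followup1 nonpathological   PD            7.00          14.45
#>   percent_change_from_baseline
#> 1                       -54.72
#> 2                         0.00
#> 3                       106.47
```

The target sum dropped 54.7 % from baseline → PR; the nontarget node is
unchanged → SD; the 7 mm node grew past the 10 mm pathological cut → PD.
All three calls equal the simulator's independent truth table
(`sim$truth`). Diameters are measured on the rasterized masks, so they
differ from the analytic ellipsoid axes by up to about one in-plane pixel
diagonal — e.g. the 26 mm target reads 27.06 mm.

On real data, replace the phantom volumes with
`read_label_volume("scan.nii.gz")` and drive batches through the manifest
interface: `cmd_measure()`, `cmd_assess()`, `cmd_agree()`, or the shell
wrapper `inst/cli/metradsp.R` (subcommands `measure`, `assess`, `agree`,
`simulate`; NIfTI in, audited TSV out).

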