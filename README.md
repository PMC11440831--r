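# bodycomp

Automated CT body-composition analysis at the third lumbar vertebra
(L3): select the L3 axial slice from an abdominal CT volume, segment it
into skeletal muscle (SM), visceral fat (VAT) and subcutaneous fat
(SAT), and derive the sarcopenia metrics used in oncology. The package
ships a synthetic abdominal-phantom generator with exact ground truth,
so the entire pipeline — preprocessing, two U-nets, post-processing and
metrics — trains and validates end-to-end without clinical data.

## Who this is for

Researchers building or validating automated sarcopenia pipelines:
muscle mass and quality at the L3 level predict survival and treatment
toxicity across cancers, but routine measurement is blocked by the
manual work of finding the slice and outlining tissues.

## Method

**L3 selection as 2-D segmentation.** The volume is body-masked
(threshold −200 HU, largest connected component, closing + dilation),
voxels outside the mask are zeroed, and a maximum-intensity projection
along the anteroposterior axis yields a coronal image (rows =
craniocaudal position at a fixed mm/row, padded to a fixed shape). A
U-net (depth 4, 64 base filters at full scale) is trained with the dice
loss to mark a 1 cm band at L3. At inference the band probability map is
averaged across columns into a 1-D signal, Gaussian-smoothed, and the
global maximum is mapped back to a slice index via the recorded
provenance (crop offset, row scale, padding). Long scans are first
cropped between the lung and pelvic centroids when they are more than
20 cm apart.

**Tissue segmentation.** A second U-net (depth 4, 32 base filters at
full scale, 5 classes) labels the selected 512 × 512 slice; pixels with
HU > 150 or < −500 are then forced to background (the classical
muscle/fat windows, muscle [−29, 150] HU and fat [−500, −30] HU, are
available as an optional strict filter).

**Metrics.** With A = muscle area (cm²), h = height (m) and SMD = mean
muscle attenuation in [−29, 150] HU:

    SMI = A / h²            (cm²/m²)
    SMG = SMI × SMD         (HU·cm²/m²)
    LBM = 0.3 × A + 6.06    (kg)

plus per-class DICE, MAE, MAPE and R² for cohort evaluation.

Training (Adam, learning rate 1e-4, batch 8, early stopping on the
validation loss, best-validation-DICE checkpointing), the dice loss and
its gradients, and the convolution primitives are implemented in the
package itself (R + Rcpp/Armadillo); the backward pass is verified
against finite differences in the test suite. Reduced "desk" profiles
(depth 3, 16 filters, smaller grids) make every experiment reproducible
on one CPU.

## Worked example

```r
library(bodycomp)

# a synthetic abdominal CT with known ground truth
ph <- generate_phantom(phantom_spec(seed = 1))
ph$volume
#> <ct_volume> 100 x 64 x 64 voxels (z, y, x), spacing 4 x 6 x 6 mm
#>   HU range [-1000, 700]
ph$truth$l3_slice_index
#> [1] 46

# ground-truth tissue map of the L3 slice -> sarcopenia report
rep <- build_report(ph$volume$voxels[ph$truth$l3_slice_index + 1, , ],
                    ph$truth$tissue_labels,
                    height_m = ph$truth$height_m)
rep
#> <sarcopenia_report>
#>   SM  area   116.64 cm^2    SMD   45.0 HU
#>   VAT area   134.64 cm^2    SAT area   116.64 cm^2
#>   LBM  41.05 kg    SMI  40.36 cm^2/m^2    SMG  1817.1 HU.cm^2/m^2
```

The muscle area of 116.6 cm² at 1.70 m gives a skeletal muscle index of
40.4 cm²/m²; SMD ≈ 45 HU reflects the phantom's muscle attenuation, and
LBM follows the linear L3 formula. Training and evaluating the reduced
pipeline end-to-end:

```r
l3 <- run_l3_experiment(n = 200, seed = 42)        # ~10 min on 1 CPU
l3$mae_mm; l3$correct_rate
bc <- run_bodycomp_experiment(n = 200, seed = 7)   # ~7 min on 1 CPU
bc$median_dice
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/bodycomp.R simulate --n 10 --out cohort --seed 1
Rscript inst/cli/bodycomp.R train --task l3 --data cohort --out l3.rds
Rscript inst/cli/bodycomp.R detect --in scan.nii.gz --l3-model l3.rds --out pred.json
```

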