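# PETsim

Analytic simulation and reconstruction of positron emission tomography (PET)
images in R.

PET simulators are the standard way to study how reconstruction settings,
scan duration and noise affect quantitative image metrics (recovery
coefficients, background variability, radiomics features) without acquiring
hundreds of physical phantom scans. Monte Carlo simulators are accurate but
slow; PETsim implements the fast analytic alternative: it converts a
noise-free activity image and a matched attenuation map (or CT image) into
realistic noisy PET images under user-chosen acquisition settings, and
evaluates them with the image-quality metrics used for scanner harmonisation.
It is written for imaging physicists and method developers who need many
statistically equivalent replicates at controlled noise levels.

## What it computes

For an activity image λ (kBq/mL) and attenuation map μ (cm⁻¹ at 511 keV),
expected projection data are

    trues_i = sens · t · a_i · [H λ_smoothed]_i ,   a_i = exp(−∫ μ dl),

where H is a slice-wise 128-angle Radon transform (with optional
time-of-flight binning: a 1D Gaussian of spatial FWHM c·Δt/2 along each
ray), λ_smoothed is λ convolved with the system PSF, `sens` is the
scanner-specific sensitivity factor and t the scan duration. Uniform randoms
and Gaussian-blurred scatter are added as fixed fractions of the trues,
Poisson noise is drawn per bin, and images are reconstructed with
ordinary-Poisson OSEM

    x ← x / H_Sᵀ(a) · H_Sᵀ[ a y / (a H_S x + s + r) ]

(4 iterations × 16 subsets by default), with optional resolution modelling
in H, Gaussian post-filtering and reblurred Van-Cittert deconvolution.
Noise is summarised as the background coefficient of variation
COV = SD/mean over six 30 mm background ROIs, with the closed-form checks

    COV_t2 = √(t1/t2) · COV_t1      and      SNR gain_TOF = √(2D / (c Δt)).

The package also generates the NEMA NU 2 image-quality phantom (six spheres
of 10–37 mm in a 9400 mL torso background) as a digital reference object
pair, including the DRO-modifier used to match measured activities and
grids.

## Worked example

Simulate ten statistically equivalent 120 s scans of the IQ phantom
(170 × 170 matrix, 3 × 3 × 2 mm, 23 kBq/mL spheres over 2.1 kBq/mL
background) and analyse them:

```r
library(PETsim)

spec <- phantomSpec(sphereActivity = 23, voxelSize = c(3, 3, 2),
                    matrixSize = c(170, 170, 15))
dro <- generateIQPhantom(spec)
dro
#> DROPair (mu/511keV attenuation)
#>   activity:    ActivityImage 170 x 170 x 15, voxel 3 x 3 x 2 mm, range [0, 23]
#>   attenuation: AttenuationMap 170 x 170 x 15, voxel 3 x 3 x 2 mm, range [0, 0.096]

sp <- simulationParams(sensitivityFactor = 0.002, scanDuration = 120,
                       systemFWHM = 7, seed = 1L, nReplicates = 10L)
stack <- simulateReplicates(dro, sp, reconParams())
result <- analyzeReplicates(stack, iqROISet(dro), expected = 23)
result
#> AnalysisResult
#>   background COV (mean over 10 replicates): 0.6841
#>   RC_mean: 0.378 0.614 0.712 0.516 0.765 0.811
#>   RC_max:  0.583 1.056 1.302 0.931 1.255 1.274
```

The background COV of 0.68 is the image noise at this sensitivity and
duration; the recovery coefficients rise with sphere diameter (printed in
ring order — 10, 17, 22, 13, 28, 37 mm — partial-volume losses are largest
for the 10 mm sphere). The theoretical predictors connect settings:

```r
round(expectedCOVScaling(result@covMean, 120, 300), 3)  # COV expected at 300 s
#> [1] 0.433
round(expectedTOFGain(450, 0.27), 2)   # SNR gain of 450 ps TOF on a 27 cm object
#> [1] 2
```

`calibrateSensitivity()` tunes `sensitivityFactor` until the simulated COV
matches a measured scanner value, after which any other duration or
reconstruction setting can be simulated. `runPipeline()` (and the CLI at
`inst/cli/petsim.R`) runs the whole chain from a YAML config and writes
replicate/mean/SD NIfTI images plus a COV/RC report.

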