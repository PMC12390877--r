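# pavmark

Hemodynamic marker mapping for peripheral arterio-venous malformations
(pAVMs) from time-resolved angiography.

Peripheral AVMs shunt blood directly from arteries into veins through a
tangle of abnormal vessels (the *nidus*). How fast, and along which
paths, a contrast-agent (CA) bolus traverses the lesion is the
information interventional radiologists use to type the lesion and plan
treatment. `pavmark` extracts that information from dynamic image
series — 2D+t digital subtraction angiography (DSA) or 3D+t
contrast-enhanced time-resolved MR angiography (CE-trMRA) — as
per-pixel/voxel maps of two markers derived from each time–intensity
curve c(i, t):

* **CA_ToA** — contrast time of arrival: the time from injection until
  the signal first reaches 10% of the voxel's own peak intensity.
* **CA_si** — maximum dispersive wash-in slope: the largest forward
  finite difference (ĉ(i, t + Δt) − ĉ(i, t)) / Δt of the
  dilution-corrected curve ĉ = c / I_max(i), where I_max(i) is the
  voxel's peak.

Their normalized variants,
CA_ToA^norm = (max_j CA_ToA(j) − CA_ToA(i)) / t_eff and
CA_si^norm = CA_si(i) / max_j CA_si(j), remove injection-timing,
acquisition-length and scale differences so lesions imaged under
different protocols (or modalities) can be compared. The package
provides the full chain around the markers: preprocessing (background
subtraction, cropping, temporal/spatial median filtering, global
normalization, noise thresholding), temporal-standard-deviation vessel
detection, histograms with moment summaries, a χ² histogram comparison,
2D/3D colour renderings, a reproducible pipeline runner with YAML
configuration, and a gamma-variate bolus phantom simulator with
closed-form ground truth that makes every stage testable without
clinical data.

The intended users are researchers in quantitative angiographic image
analysis; the tool outputs markers and distribution metrics, not
diagnoses.

## Worked example

A synthetic pAVM phantom (feeding artery → nidus → draining veins,
gamma-variate bolus, SNR 20) stands in for an acquisition:

```r
library(pavmark)

ph <- simulatePhantom(defaultPhantomSpec(noiseSd = 0.05, seed = 7))
ph$series
#> DynamicSeries: 18 frames x (10, 32, 32) [volumetric], dt = 1.1 s, spacing = (1.4, 1.35, 1.35) mm
#>   intensity range [0, 1.10203]; background subtracted: TRUE

pre  <- preprocessSeries(ph$series)          # median filters, normalize, threshold
mask <- detectVessels(temporalStdMap(pre))   # std >= 3 x robust noise scale
mask
#> VesselMask: 1390 / 10240 voxels (threshold 3 x noise scale, temporal_std)

toa <- computeToa(pre, mask)
toa
#> MarkerMap 'toa': 1390 present voxels of 10240, range [0, 17.6] s
#>   context: tEff = 18.7, fraction = 0.1

histogramMetrics(normalizeToa(toa))
#> HistogramMetrics (n = 1390): mean 0.7455, median 0.7647, skewness -3.728, kurtosis 30.47

histogramMetrics(normalizeSlope(computeSlope(pre, mask)))
#> HistogramMetrics (n = 1390): mean 0.6404, median 0.6235, skewness 0.8392, kurtosis 8.381
```

The 1390-voxel mask recovers the simulated vessel tree; arrival times
span the full bolus transit (artery ≈ 1 s after injection, veins
several seconds later, plus noise-limited voxels at the extremes). The
normalized-arrival mean of 0.75 says most masked voxels arrive early
relative to the latest voxel — an artery/nidus-dominated lesion — and
the strongly negative skewness flags the long late-arriving (venous)
tail. The slope metrics summarize how dispersed the bolus is across the
lesion.

`runPipeline()` wraps the same steps and writes every artifact (mask,
four marker maps as NIfTI + JSON sidecars, histograms as CSV, moment
metrics as JSON, colour renderings) into a run directory;
`compareRuns()` compares marker histograms of two runs with the
symmetric χ² statistic. A thin command-line front end with `simulate`,
`run` and `compare` subcommands is installed at `inst/cli/pavmark.R`.

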