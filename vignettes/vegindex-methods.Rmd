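---
title: "Vegetation index composites and anomaly products: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vegetation index composites and anomaly products: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vegindex)
```

# The product chain

`vegindex` implements a near-real-time vegetation-condition monitoring
chain of the kind run operationally over cropland from daily 250 m
satellite surface reflectance. The chain is:

1. **Daily NDVI.** From co-registered RED and NIR digital-number rasters
   (16-bit signed, valid range $[-100, 16000]$, i.e. reflectance scaled by
   $10^4$), compute per pixel
   $$\mathrm{NDVI} = \frac{\rho_{NIR} - \rho_{RED}}{\rho_{NIR} + \rho_{RED}}.$$
   Tiles of one acquisition are mosaicked (first valid observation in input
   order wins) and clipped to an area of interest before the quotient.
2. **Maximum-value composites (MVC).** Weekly and biweekly NDVI is the
   per-pixel *maximum* of the daily NDVI within the window. Clouds, fog and
   missing data bias NDVI low, so the within-window maximum is the
   least-contaminated observation; a pixel is masked only if no day saw it.
3. **Multi-year climatology.** For each week-of-year slot, the archive of
   yearly composites yields per-pixel reference fields: minimum, maximum,
   mean and median NDVI.
4. **Anomaly indices.** With the current composite $N_i$ and references for
   the same period of year:
   $$\mathrm{VCI} = \frac{N_i - N_{min}}{N_{max} - N_{min}}, \qquad
     \mathrm{MVCI} = \frac{N_i - N_{mean}}{N_{mean}}, \qquad
     \mathrm{RMVCI} = \frac{N_i - N_{med}}{N_{med}}, \qquad
     \mathrm{RVCI} = \frac{N_i - N_{i-1}}{N_{i-1}},$$
   where $N_{i-1}$ is last year's composite of the same slot. VCI positions
   the week inside its historical envelope (0 = driest on record, 1 =
   greenest); the three ratio indices are relative deviations from mean,
   median and previous year.
5. **8-bit encoding.** Every product is stored as unsigned bytes:
   NDVI maps $[-1,1]$ through $v \times 125 + 125$, VCI maps $[0,1]$
   through $v \times 250$, and the ratio indices map through
   $v \times 100 + 125$ after saturating at $|v| = 1.25$ (125 %). Valid
   bytes are $0..250$; 255 is the no-data sentinel; 251–254 are never
   produced and are rejected on read.

# Calendar

Weekly products follow the ISO-8601 week calendar: weeks run Monday to
Sunday and week 1 is the week containing January 4th, which matches the
operational products (week 1 of 2021 starts 2021-01-04; 2021-06-07 to
2021-06-13 is week 23). Years have 52 or 53 weeks; dates near the year
boundary belong to their ISO year, so "files per year" counts ISO weeks.
Biweekly slots pair consecutive ISO weeks $(1,2), (3,4), \dots$; in a
53-week year the orphan week 53 becomes a short 7-day final slot. Daily
products follow the calendar year. The multi-year reference archive always
exposes 53 weekly (27 biweekly) slots, regardless of the current year's
length.

Layer names reproduce the operational convention exactly, including the
legacy aliases `RNDVI` (for RVCI) and `RMNDVI` (for RMVCI), e.g.

```{r names}
p <- week_partition(2021)[[1]]
layer_name("VCI", p)
layer_name("RVCI", p)
layer_name("NDVI", p, method = "MEAN")
```

# Numerical choices

* **Rounding.** Float-to-byte conversion rounds to the nearest integer with
  ties away from zero, so each byte decodes to the unbiased centre of its
  bin. Decoding inverts the affine maps; saturated ratio bytes (0, 250)
  decode to $\mp 1.25$ and are not further recoverable.
* **Clamping before encoding.** NDVI is clamped to $[-1,1]$ (admissible
  negative reflectances can push the raw quotient slightly outside), VCI to
  $[0,1]$ (a near-real-time composite can exceed the archived extremes),
  and ratio indices to $[-1.25, 1.25]$, mirroring the piecewise encoding so
  index values and encodings saturate identically.
* **Degenerate denominators.** Where the historical envelope collapses
  ($N_{max} = N_{min}$) or a ratio reference is zero, the output is masked
  (byte 255) rather than forced to 0: no meaningful anomaly exists there.
* **Median with an even year count** is the mean of the two central values.
* **Mask algebra.** Every index output mask is the union of its input masks
  plus the degenerate cells; validation only ever shrinks a validity mask.
* **Exact incremental climatology.** The stack retains every per-year grid
  (running summaries cannot maintain exact medians); inserting a year
  recomputes that slot's derived fields with the same code path as a full
  rebuild, so the two are bitwise identical.
* **Reference policy.** The multi-year mean/median references by default
  exclude the current product year — an anomaly measured against a
  reference containing itself is damped — with `include_current = TRUE`
  exposing the alternative reading. For week 53 over a 52-week previous
  year, RVCI falls back to week 52.
* **In-memory vs. archived precision.** Within one pipeline run the
  climatology holds full-precision composites; only files are quantized to
  the 8-bit product form. References rebuilt from an archive directory are
  therefore quantized, exactly as when operating from the distributed
  products.

# The synthetic scene generator

Real scenes require satellite downloads, so every stage is exercised
against generated MOD09GQ-style scenes with known truth. The generator
(`make_truth_series()`, `to_reflectance()`, `add_clouds()`) emulates:

* a **seasonal sinusoid**: base NDVI 0.45, amplitude 0.25 and phase day 80
  by default, keeping the curve inside the 0.2–0.8 range typical of
  vegetated land with a peak around midsummer;
* a **spatial gradient** (±0.05 across columns) giving each pixel a
  distinct level;
* **interannual variability** as deterministic per-year offsets, by default
  evenly spaced over ±0.1 — a realistic year-to-year NDVI swing. Without
  it, a noise-free multi-year archive would repeat identically and the
  min–max envelope would be degenerate everywhere;
* **pixel noise** (Gaussian, sd 0.02 by default) and **cloud blobs**:
  a smooth Gaussian-bump random field thresholded at the requested coverage
  quantile, giving contiguous masked patches whose fraction matches the
  request almost exactly.

`to_reflectance()` realises a truth field $v$ as integer bands with
$\rho_{NIR} + \rho_{RED} = \texttt{total\_dn}$ (default 8000), so the NDVI
quotient recovers $v$ to within $1/\texttt{total\_dn}$.

What the generator does *not* emulate: radiative transfer, view-angle and
BRDF effects, sensor orbit geometry, spatially correlated noise, or
snow/water spectra. Passing tests therefore demonstrate the correctness of
the *production chain* — calendar, compositing, climatology, index math,
encoding, I/O — not the radiometric quality of any real product.

# Verification design

The test suite checks, among others:

* every printed encoding anchor (0 → 125, ±1 → {250, 0} for NDVI; 1 → 250
  for VCI; {−2, 0, 1.25} → {0, 125, 250} for ratios) and that bytes
  251–254 never occur;
* the week calendar against an independent day-of-week-arithmetic oracle,
  and all naming-convention examples byte-for-byte;
* MVC dominance, permutation invariance, mask shrinkage, and
  weekly→biweekly associativity against a brute-force maximum over 14
  synthetic dailies on a 128×128 grid;
* incremental climatology updates against a from-scratch rebuild, bitwise,
  over a five-year 128×128 weekly archive;
* end-to-end truth recovery: on a noise-free, cloud-free five-year archive
  the pipeline's decoded VCI matches the analytic VCI computed from the
  generator's truth within one byte-quantization step (1/250) at every
  pixel. This check digitises reflectance at
  $\texttt{total\_dn} = 16000$: the error budget
  (digitisation + reference propagation + byte rounding,
  $\approx 4\delta/(N_{max}-N_{min}) + 1/500$ with
  $\delta = 1/\texttt{total\_dn}$) stays below $1/250$ for all pixels at
  $1/16000$, whereas the default $1/8000$ would admit rare boundary pixels
  above it;
* composite error against truth decreasing monotonically as cloud cover
  drops through 0.8 → 0.4 → 0.1.

Problem sizes (128×128 grids, five-year archives, one to two weeks per
stage where a single slot suffices) were chosen so that a full suite run
completes in about two minutes while still exercising every code path at
operationally shaped data.

# File formats

Products are single-band 8-bit GeoTIFFs (no-data tag 255); reflectance
inputs are single-band 16-bit signed GeoTIFFs, any other sample type being
rejected. The package includes its own minimal baseline GeoTIFF
reader/writer (uncompressed, single band, ModelPixelScale/ModelTiepoint/
GeoKey directory plus the GDAL no-data convention); files round-trip
byte-exactly and are read by libtiff- and GDAL-based tools, which the test
suite cross-checks with an independent TIFF reader. The tool is
CRS-agnostic: the identifier carried by the inputs is preserved, never
reprojected.

# Known limitations

* Only NDVI-family indices are produced (no EVI/LAI), and no atmospheric or
  BRDF correction or cloud *detection* is attempted — the validity mask is
  taken as given.
* Mosaicking requires tiles on a common lattice in one CRS; reprojection is
  out of scope.
* The GeoTIFF writer emits exactly the layout described above (no tiling,
  compression or multi-band files).
* `run_pipeline()` idempotence is file-level: products whose outputs exist
  are skipped; products that errored (e.g. RVCI in the archive's first
  year) are re-attempted on rerun.
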