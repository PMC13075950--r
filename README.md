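# hxms

An R implementation of **HXMS v1.0**, a lightweight, human-readable flat-file
format for peptide-level hydrogen/deuterium-exchange mass spectrometry
(HX-MS) data, together with converters from the export tables of the common
HX-MS analysis programs.

## Who this is for

HX-MS measures how fast backbone amide hydrogens of a protein exchange for
deuterium in D₂O, reporting on conformation and local stability. Most
analysis software exports only the *mean deuteration* ("centroid") of each
peptide's isotopic envelope, in a vendor-specific table layout, which makes
data sharing and quantitative reanalysis painful. HXMS files keep everything
in one plain-text file per protein state: the experimental conditions, every
peptide × timepoint × replicate measurement, the **full isotopic mass
envelopes**, fully deuterated (FD) controls, multimodal populations, PTM
annotations, and optionally the raw matched m/z–intensity evidence behind
each envelope. This package is for practitioners who need to write, read,
validate, convert, or simulate such files from R or the shell.

## What it computes

The quantitative core is small and explicit:

* An **isotopic envelope** is a vector of relative intensities
  *p₀, p₁, …* of consecutive isotope peaks, normalized so Σᵢ pᵢ = 1.
* Its **centroid** (mean deuteration) is the intensity-weighted mean peak
  index, c = Σᵢ i·pᵢ / Σᵢ pᵢ, with adjacent peaks treated as 1 Da apart.
* **Deuterium uptake** at time *t* is referenced to the experiment's zero
  timepoint: u(t) = c(t) − c(0 s), in daltons, per peptide and replicate.
  When a replicate lacks its own 0 s point, the reference falls back to the
  mean of the 0 s centroids of the replicates that have one. Uptake is raw
  incorporation — no back-exchange or D₂O-saturation correction is applied
  (FD controls are stored so downstream tools can correct).
* The synthetic generator models per-residue exchange as first-order
  kinetics, dⱼ(t) = s·(1 − e^(−kⱼt)) toward D₂O saturation *s*, and builds
  envelopes as the **Poisson-binomial** distribution of the deuteron count,
  whose mean Σⱼ dⱼ is the ground-truth uptake.

Converters accept simplified, documented dialects of DynamX, HDX Workbench,
HDExaminer, BioPharma Finder exports, and a custom CSV. DynamX and BioPharma
Finder report uptake directly (used as-is); Workbench and HDExaminer report
centroids, from which uptake is recomputed by the zero-referencing rule
above. Workbench and HDExaminer spectra become ENVELOPE fields and (with the
fine-match option) MATCH records.

## Worked example

Convert a small custom table with envelopes, recompute uptake, and write an
HXMS file:

```r
library(hxms)
md <- hxmsMetadata("GSHMKTVEVNGADASDDN", temperatureK = 293.15,
                   pHRead = 6.0, d2oSaturation = 0.91,
                   proteinName = "Human PFK-1", proteinState = "APO")
tab <- data.frame(start = 1, end = 10, replicate = 0, mode = "A",
                  time_s = c(0, 30, 300),
                  envelope = c("527;298;116;36;0;23;0",
                               "113;288;345;188;49;14;3",
                               "21;96;219;287;229;114;34"))
ds <- recomputeUptake(parseCustomCSV(tab, md))
timepoints(ds)[, c("index", "start", "end", "time_s", "uptake")]
#>   index start end time_s uptake
#> 1     0     1  10      0  0.000
#> 2     1     1  10     30  1.073
#> 3     2     1  10    300  2.332
cat(writeHXMS(ds))
#> METADATA  PROTEIN_SEQUENCE    GSHMKTVEVNGADASDDN
#> ...
#> TP          0       A      1      10     0    0000    0.000000e+00    0.00     0.527,0.298,0.116,0.036,0.000,0.023,0.000
#> TP          1       A      1      10     0    0000    3.000000e+01    1.07     0.113,0.288,0.345,0.188,0.049,0.014,0.003
#> TP          2       A      1      10     0    0000    3.000000e+02    2.33     0.021,0.096,0.219,0.287,0.229,0.114,0.034
```

The uptake column says this peptide gained 1.07 Da of deuterium after 30 s
and 2.33 Da after 300 s relative to its 0 s control; the trailing field of
each `TP` row is the unit-sum envelope those numbers were derived from.
`validateDataset(ds)` returns an empty violation table for this file;
`readHXMS(writeHXMS(ds))` reproduces the dataset exactly.

A command-line interface wraps the same functions
(`inst/cli/hxms.R convert|validate|inspect|synth`); see `?hxmsCLI`.

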