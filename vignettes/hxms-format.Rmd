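---
title: "The HXMS format and its numerics"
author: "hxms package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The HXMS format and its numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hxms)
```

## The data model

An HX-MS experiment exposes a protein to D₂O and follows, peptide by
peptide, how much deuterium the backbone amides take up over time. One
`HXMSDataset` holds one protein state's experiment in four parts, mirroring
the sections of an HXMS v1.0 file:

* **Metadata** — the protein sequence (one-letter codes, required), optional
  name and state, labeling temperature in kelvin, pH(read) of the D₂O
  buffer, and the D₂O saturation (the deuterium fraction of the labeling
  buffer, in (0, 1]). Free-form REMARK entries are preserved, and the format
  version is emitted automatically as one of them.
* **Timepoints** — one record per peptide × incubation time × replicate ×
  mode. Peptide coordinates are 1-based and inclusive at both ends. `MOD`
  letters A–Z index coexisting envelope populations (e.g. the slow- and
  fast-exchanging subpopulations of EX1 kinetics); a unimodal measurement is
  always "A", and the validator requires an "A" record wherever higher
  letters occur. Replicates count from 0 and increment only for new
  experimental measurements. Fully deuterated (FD) controls are ordinary
  records whose time is the distinguished value `inf`.
* **PTM dictionary** — nonzero 4-digit IDs mapping to free-text
  modification descriptions with absolute positions. ID `0000` is reserved
  to mean "no PTM": the format's tables could be read as allowing a real
  modification under ID 0, but a reserved sentinel cannot double as a real
  entry, so this implementation forbids ID-0 dictionary entries and the
  validator flags them.
* **MATCH records** — optional raw spectral evidence per timepoint:
  assignment confidence in [0, 1], retention time, charge state,
  monoisotopic mass, and the hierarchical m/z–intensity structure (comma
  between envelope peak groups, semicolon between uncentroided
  fine-structure points within a group, colon between m/z and intensity).
  `TP_ID` is bound to the timepoint `INDEX`; the format leaves room to read
  it as an independent counter, but an independent counter would add a second
  key space with no lookup table to resolve it, so identity is the only
  self-consistent reading.

The per-record population fraction of multimodal measurements is *not*
modeled: the format has no field for it, so modes record shapes, not
abundances.

## Uptake numerics

The centroid of an envelope `p` is `sum(i * p[i]) / sum(p)` over 0-based
peak indices, and uptake is the centroid difference against the 0 s
timepoint of the same peptide and replicate. Numeric choices, each of which
was genuinely open:

* **Peak spacing.** Adjacent isotope peaks are treated as exactly 1 Da
  apart, so centroid units are daltons. The physical H→D increment
  (≈1.00628 Da) and the ¹³C spacing (≈1.00336 Da) differ from 1 only at the
  third decimal — below the 2-decimal precision at which UPTAKE is
  serialized — and `envelopeCentroid()` takes a `peakSpacingDa` override
  for users who care.
* **No isotope deconvolution.** Envelopes are used as stored; the natural
  isotope distribution is not divided out. Uptake is a *difference* of
  centroids, so a time-invariant natural envelope shape cancels exactly.
* **Zero referencing.** A replicate missing its own 0 s point is referenced
  against the arithmetic mean of the 0 s centroids of the replicates that
  have one (`zeroReferenceForReplicate()`); if no replicate has one, the
  conversion fails loudly with `MISSING_ZERO` rather than guessing.
* **Multimodal referencing.** Modes beyond "A" are referenced against the
  mode-"A" 0 s centroid, on the assumption that 0 s (undeuterated) samples
  are unimodal. `computeUptake()` accepts an explicit `zeroReference` to
  override this.
* **Saturation is stored, not applied.** UPTAKE is raw incorporation; no
  back-exchange or D₂O-saturation correction is performed. FD controls are
  carried so that downstream analysis can correct on its own terms.
* Mildly negative uptake is legitimate measurement noise; the validator
  only warns (never errors) below −1 Da.

## Serialization choices

Tabular rows are written fixed-width — each field left-justified and
space-padded to its documented character count, the trailing variable-length
field (ENVELOPE / CONTENT / M/Z) unpadded — which keeps files aligned and
greppable, in the spirit of the PDB. Because the pad character is a layout
choice rather than format semantics, the reader also accepts tab-separated
rows, detected per line, and tolerates sections in any order; the writer
always emits METADATA → TP → PTM → MATCH.

Precision is fixed per field: envelope peaks at 3 decimals (the documented
example values carry 3; a per-peak character budget in the documentation is
ambiguous between significant digits and total width, and 3 decimals
round-trips those examples exactly), UPTAKE at 2, CONF at 2, RT at 3,
MONO_M at 6, m/z and intensity at 4 (intensity with trailing zeros
trimmed, matching the documented example strings). Incubation times are
written in lowercase scientific notation with six fractional digits and a
two-digit exponent, `inf` for FD controls. In-memory values keep full
precision; quantization happens only at the writer. Files are UTF-8 with
`\n` line endings, and writing is byte-deterministic.

Validation is report-based: `validateDataset()` returns a table of coded
violations (severity `error` or `warning`) and never throws, so a broken
file can be inspected and repaired (`renumberIndices()` fixes INDEX gaps and
remaps MATCH links). The writer refuses datasets with error-severity
violations. A MATCH whose group count disagrees with its envelope is a
warning, not an error, because centroided-only exports may legitimately
store fewer groups.

## Vendor dialects

The vendor programs' exact export schemas are proprietary and variable, so
each converter defines a minimal documented schema (see the converter help
pages) that captures what that program can express; extra columns are
ignored, missing required ones raise `SCHEMA_ERROR`. The capability matrix
(`hxmsDialects()`): DynamX and BioPharma Finder report uptake directly and
their values are used as-is; HDX Workbench and HDExaminer report centroids,
from which uptake is recomputed by the zero-referencing rule above, and can
carry full spectra, which become ENVELOPE fields and — for HDExaminer, when
the fine-match option is enabled — MATCH records with the uncentroided fine
structure. PTM annotations are harvested from all dialects except
HDExaminer and BioPharma Finder, whose files need PTMs added manually.

Implementation-defined details the exports themselves do not pin down:

* **FD sentinels.** DynamX/Workbench/HDExaminer exposure columns accept the
  literal `FD` (or `inf`); BioPharma Finder uses `MAX`.
* **Replicates** come from an optional `Replicate` column, defaulting to 0.
* **Charge states.** Workbench rows differing only in charge are one
  measurement observed several times; they merge by intensity-weighted
  averaging of their normalized envelopes (weight = total spectrum
  intensity), overridable to "keep the strongest charge". Every charge row
  keeps its own MATCH record, so per-charge evidence stays traceable.
* **HDExaminer populations** map a `Population` column (letters, or
  numerals 1, 2, … read as A, B, …) onto MOD.

## The synthetic generator

`generateExperiment()` exists so that the whole stack — model, codec,
converters, CLI — is testable offline with known ground truth. It emulates:
a random protein with per-residue exchange rates drawn log-uniformly
(default 10⁻⁴–10⁰ s⁻¹, spanning the default 30 s–1 h time course at
293.15 K, pH(read) 6.0, D₂O saturation 0.91); a random peptide tiling;
first-order labeling kinetics; Poisson-binomial envelopes; replicate
measurements with independent lognormal multiplicative intensity noise
(renormalized, so envelopes stay valid; default SD 0.02); bimodal peptides
as a second, independently drawn rate set emitted as MOD "B" records at
every nonzero time; PTM annotations; FD controls; and a MATCH record per
timepoint with one m/z group per envelope peak on the ¹³C-spaced grid of a
random charge state. The first two residues of each peptide are treated as
non-exchanging, the usual fast-back-exchange convention for peptide-level
HX-MS. An optional natural-isotope flag convolves a carbon-isotope
distribution into the envelopes and emits three-point fine structure per
MATCH group.

Everything stored in the generated dataset is quantized to the
serialization grid (envelope peaks to 3 decimals with the rounding residue
folded into the largest peak, uptake to 2, and so on). That makes the
generator's output a fixed point of the codec — writing and re-reading it
is an exact identity — which is what the round-trip properties assert. The
exported vendor tables instead carry the *exact* noise-free centroids and
uptake at export precision, so converter recovery can be compared against
the closed-form Poisson-binomial mean Σⱼdⱼ(t).

What it does **not** emulate, and what passing tests therefore cannot show:
physically calibrated intrinsic rates (no sequence or pH/temperature
dependence of kⱼ), EX1/EX2 kinetic regimes behind the bimodality, real
back-exchange (FD rows are exactly saturated), chromatographic or m/z
calibration artifacts, and real vendor export quirks beyond the documented
dialect schemas. Tests demonstrate correctness of the format arithmetic and
plumbing, not fidelity to any particular instrument.

Test problem sizes: unit and property suites run on 2–3-peptide,
two-replicate experiments (tens of records each); the round-trip property
sweeps 100 seeds with bimodality, PTMs, FD controls and fine structure
toggled across seeds. These sizes were chosen to exercise every format
feature with fully enumerable expectations.

## Degenerate inputs and tie-breaks

All-zero or negative intensity vectors are rejected before normalization;
envelope sums are accepted within 5·10⁻³ of 1, absorbing worst-case
3-decimal rounding of long envelopes. Empty input to the reader (no
metadata section at all) and duplicated required metadata raise
`FORMAT_ERROR` with the line number; a *missing* individual required entry
parses and is reported by the validator instead, so incomplete files remain
inspectable. Unknown row tags warn and are skipped. When several 0 s points
exist in one series their centroid mean is the reference.

## Known limitations

No protection-factor or rate fitting, no bimodal deconvolution of raw
spectra, no back-exchange correction, no raw instrument file (e.g. mzML)
parsing, and no claim to byte-level compatibility with proprietary vendor
exports — the dialects are documented simplifications. Multi-state
experiments are one file per state; the package does not merge states.
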