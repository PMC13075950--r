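# Envelope numerics: normalization, centroid (mean deuteration), and
# deuterium uptake with zero-timepoint referencing.

# Adjacent isotope peaks are treated as exactly 1 Da apart, so peak-index
# units coincide with daltons. The H->D increment (1.00628 Da) and the 13C
# spacing (1.00336 Da) differ from 1 only at the third decimal, below the
# format's 2-decimal UPTAKE precision; the spacing is overridable where it
# matters.
.PEAK_SPACING_DA <- 1.0

#' Normalize isotope-peak intensities to unit sum
#'
#' @param intensities Non-negative relative intensities of consecutive
#'   isotope peaks (peak index 0 = lightest); at least one must be strictly
#'   positive.
#' @return The envelope as a numeric vector summing to 1.
#' @examples
#' normalizeEnvelope(c(527, 298, 116, 36, 0, 23, 0))
#' @export
normalizeEnvelope <- function(intensities) {
  if (!is.numeric(intensities) || length(intensities) < 1)
    hxmsStop("ENVELOPE_VALUES", "envelope needs at least one intensity")
  if (anyNA(intensities) || any(intensities < 0))
    hxmsStop("ENVELOPE_VALUES", "envelope intensities must be non-negative")
  total <- sum(intensities)
  if (total <= 0)
    hxmsStop("ENVELOPE_VALUES", "envelope needs at least one positive intensity")
  intensities / total
}

#' Mean deuteration (centroid) of an isotopic envelope
#'
#' The intensity-weighted mean peak index, `sum(i * p_i) / sum(p_i)`, with
#' peak 0 the lightest isotopologue and adjacent peaks `peakSpacingDa` apart.
#' This is the conventional peptide-level HX-MS summary of an envelope.
#'
#' @param envelope Numeric vector of peak intensities (need not be
#'   normalized; the centroid is scale-invariant).
#' @param peakSpacingDa Mass difference between adjacent peaks, daltons.
#' @return Centroid in daltons above the lightest peak.
#' @export
envelopeCentroid <- function(envelope, peakSpacingDa = .PEAK_SPACING_DA) {
  if (!is.numeric(envelope) || length(envelope) < 1 ||
      anyNA(envelope) || any(envelope < 0) || sum(envelope) <= 0)
    hxmsStop("ENVELOPE_VALUES",
             "centroid needs a non-empty, non-negative envelope with mass")
  idx <- seq_along(envelope) - 1
  sum(idx * envelope) / sum(envelope) * peakSpacingDa
}

# Centroid for a series point: use the stored centroid when present,
# otherwise derive it from the envelope.
.pointCentroids <- function(series) {
  if (!is.null(series$centroid)) return(as.numeric(series$centroid))
  if (!is.null(series$envelope))
    return(vapply(series$envelope, envelopeCentroid, numeric(1)))
  hxmsStop("SCHEMA_ERROR", "series needs a 'centroid' or 'envelope' column")
}

#' Deuterium uptake of a peptide time series
#'
#' Uptake at each timepoint is the mean deuteration (centroid) at that time
#' minus the mean deuteration at the 0 s timepoint of the same series, in
#' daltons. The 0 s point itself therefore maps to exactly 0. Fully
#' deuterated controls (`time_s = Inf`) are referenced the same way. No
#' back-exchange or D2O-saturation correction is applied: the format stores
#' raw incorporation.
#'
#' @param series data.frame of one peptide x replicate x mode series, ordered
#'   by time, with column `time_s` and either `centroid` (daltons) or
#'   `envelope` (list of intensity vectors).
#' @param zeroReference Centroid (daltons) to subtract instead of the
#'   series' own 0 s centroid — use [zeroReferenceForReplicate()] when a
#'   replicate lacks its own 0 s point. Default `NULL` uses the series' 0 s
#'   point(s) and raises `MISSING_ZERO` if there are none.
#' @return Numeric vector of uptake values, one per series row.
#' @examples
#' s <- data.frame(time_s = c(0, 60))
#' s$envelope <- list(c(1, 0), c(0, 1))
#' computeUptake(s)   # 0, 1
#' @export
computeUptake <- function(series, zeroReference = NULL) {
  cen <- .pointCentroids(series)
  if (is.null(zeroReference)) {
    z <- which(series$time_s == 0)
    if (!length(z))
      hxmsStop("MISSING_ZERO",
               "series has no 0 s timepoint and no zero reference was given")
    zeroReference <- mean(cen[z])
  }
  cen - zeroReference
}

#' Zero-timepoint reference for one replicate of a peptide
#'
#' Returns the replicate's own 0 s centroid when it has one; when that
#' replicate is missing a zero timepoint, falls back to the arithmetic mean
#' of the 0 s centroids of the replicates that do have one.
#'
#' @param peptideData data.frame covering all replicates of one peptide (one
#'   mode series each), with columns `replicate`, `time_s` and `centroid`
#'   (or `envelope`).
#' @param replicate Integer replicate number to reference.
#' @return The zero-timepoint centroid, daltons.
#' @section Errors: raises `MISSING_ZERO` when no replicate has a 0 s point.
#' @export
zeroReferenceForReplicate <- function(peptideData, replicate) {
  cen <- .pointCentroids(peptideData)
  isZero <- peptideData$time_s == 0
  own <- isZero & peptideData$replicate == replicate
  if (any(own)) return(mean(cen[own]))
  if (!any(isZero))
    hxmsStop("MISSING_ZERO", "no replicate of this peptide has a 0 s timepoint")
  perRep <- tapply(cen[isZero], peptideData$replicate[isZero], mean)
  mean(perRep)
}

#' Recompute UPTAKE for every record of a dataset from its envelopes
#'
#' Applies [computeUptake()] across a whole dataset: records are grouped by
#' peptide (`start`, `end`, `ptm_id`) and mode; each replicate is referenced
#' against its own mode-"A" 0 s centroid, with the replicate-average fallback
#' of [zeroReferenceForReplicate()] when it lacks one. Modes beyond "A" are
#' referenced against the mode-"A" zero as well, since 0 s samples are taken
#' to be unimodal. Records without an envelope keep their stored uptake.
#'
#' @param dataset An [HXMSDataset-class] whose records carry envelopes.
#' @return The dataset with the `uptake` column recomputed.
#' @export
recomputeUptake <- function(dataset) {
  stopifnot(is(dataset, "HXMSDataset"))
  tp <- dataset@timepoints
  if (!nrow(tp)) return(dataset)
  hasEnv <- !vapply(tp$envelope, is.null, logical(1))
  cen <- rep(NA_real_, nrow(tp))
  cen[hasEnv] <- vapply(tp$envelope[hasEnv], envelopeCentroid, numeric(1))
  pepKey <- paste(tp$start, tp$end, tp$ptm_id)
  for (k in unique(pepKey)) {
    rows <- which(pepKey == k & hasEnv)
    if (!length(rows)) next
    base <- rows[tp$mod[rows] == "A"]
    refTab <- data.frame(replicate = tp$rep[base], time_s = tp$time_s[base])
    refTab$centroid <- cen[base]
    for (r in unique(tp$rep[rows])) {
      ref <- tryCatch(zeroReferenceForReplicate(refTab, r),
                      hxms_missing_zero = function(e) NA_real_)
      sel <- rows[tp$rep[rows] == r]
      if (!is.na(ref)) tp$uptake[sel] <- cen[sel] - ref
    }
  }
  dataset@timepoints <- tp
  dataset
}
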