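#' @import methods
NULL

# Titles of the metadata entries the format requires exactly once.
.REQUIRED_METADATA <- c("PROTEIN_SEQUENCE", "TEMPERATURE (K)", "pH(READ)",
                        "D_2_O_SATURATION")
.OPTIONAL_METADATA <- c("PROTEIN_NAME", "PROTEIN_STATE")
.FORMAT_VERSION <- "v1.0"

#' Experiment-level metadata of an HXMS dataset
#'
#' Holds the required experimental conditions of an HX-MS experiment (protein
#' sequence, labeling temperature, pH(read) of the D2O buffer, D2O
#' saturation), the optional protein name and state, free-form REMARK
#' entries, and the file format version. Optional fields are stored as
#' zero-length vectors when absent so that structurally incomplete metadata
#' can be represented and reported by [validateDataset()] rather than
#' rejected at construction time.
#'
#' @slot proteinSequence character; one-letter amino-acid sequence
#'   (zero-length when absent).
#' @slot proteinName,proteinState optional character.
#' @slot temperatureK numeric, kelvin (zero-length when absent).
#' @slot pHRead numeric; uncorrected pH-meter reading of the D2O buffer.
#' @slot d2oSaturation numeric in (0, 1]; deuterium fraction of the labeling
#'   buffer (stored but never applied as a correction).
#' @slot remarks data.frame with columns `kind` ("METADATA" or "REMARK"),
#'   `title`, `value`; user-supplied extra entries.
#' @slot formatVersion character; serialized automatically as a REMARK.
#' @aliases HXMSMetadata
#' @exportClass HXMSMetadata
setClass("HXMSMetadata", representation(
  proteinSequence = "character",
  proteinName     = "character",
  proteinState    = "character",
  temperatureK    = "numeric",
  pHRead          = "numeric",
  d2oSaturation   = "numeric",
  remarks         = "data.frame",
  formatVersion   = "character"
))

setValidity("HXMSMetadata", function(object) {
  msgs <- character(0)
  for (s in c("proteinSequence", "proteinName", "proteinState",
              "temperatureK", "pHRead", "d2oSaturation"))
    if (length(slot(object, s)) > 1)
      msgs <- c(msgs, sprintf("slot '%s' must have length 0 or 1", s))
  need <- c("kind", "title", "value")
  if (!all(need %in% names(object@remarks)))
    msgs <- c(msgs, "remarks must have columns kind, title, value")
  if (length(object@formatVersion) != 1)
    msgs <- c(msgs, "formatVersion must be a single string")
  if (length(msgs)) msgs else TRUE
})

#' Construct HXMS experiment metadata
#'
#' @param proteinSequence One-letter amino-acid sequence of the protein.
#' @param temperatureK Labeling temperature in kelvin.
#' @param pHRead pH(read) of the labeling buffer.
#' @param d2oSaturation D2O saturation of the labeling buffer, in (0, 1].
#' @param proteinName,proteinState Optional descriptive strings.
#' @param remarks Optional data.frame of extra entries with columns
#'   `kind` ("METADATA"/"REMARK"), `title`, `value`.
#' @param formatVersion Format version string; serialized as a REMARK.
#' @return An [HXMSMetadata-class] object.
#' @examples
#' md <- hxmsMetadata("GSHMKTVEVNGADASDDN", temperatureK = 293.15,
#'                    pHRead = 6.0, d2oSaturation = 0.91)
#' @export
hxmsMetadata <- function(proteinSequence = NULL, temperatureK = NULL,
                         pHRead = NULL, d2oSaturation = NULL,
                         proteinName = NULL, proteinState = NULL,
                         remarks = NULL, formatVersion = .FORMAT_VERSION) {
  if (is.null(remarks))
    remarks <- data.frame(kind = character(0), title = character(0),
                          value = character(0), stringsAsFactors = FALSE)
  chr <- function(x) if (is.null(x)) character(0) else as.character(x)
  num <- function(x) if (is.null(x)) numeric(0) else as.numeric(x)
  new("HXMSMetadata",
      proteinSequence = chr(proteinSequence),
      proteinName     = chr(proteinName),
      proteinState    = chr(proteinState),
      temperatureK    = num(temperatureK),
      pHRead          = num(pHRead),
      d2oSaturation   = num(d2oSaturation),
      remarks         = remarks,
      formatVersion   = as.character(formatVersion))
}

#' One protein state's HX-MS experiment in the HXMS v1.0 model
#'
#' The central container: experiment metadata plus three tables mirroring the
#' file sections. `timepoints` holds one row per peptide x time x replicate x
#' mode measurement; `ptms` is the PTM dictionary resolving nonzero PTM IDs;
#' `matches` preserves raw matched spectral evidence keyed to timepoint
#' indices. Structural shape is enforced by the validity method; the format's
#' semantic rules (index contiguity, coordinate sanity, envelope
#' normalization, dangling references) are checked by [validateDataset()],
#' which reports rather than throws so imperfect files remain inspectable.
#'
#' @slot metadata An [HXMSMetadata-class].
#' @slot timepoints data.frame with columns `index` (integer, 0-based file
#'   order), `mod` (single letter A-Z; coexisting envelope populations),
#'   `start`,`end` (1-based inclusive residue coordinates), `rep` (integer
#'   replicate, default 0), `ptm_id` (integer, 0 = no PTM), `time_s`
#'   (seconds; `Inf` marks a fully deuterated control), `uptake` (daltons,
#'   relative to the 0 s timepoint), and list column `envelope` (numeric
#'   vector of relative isotope-peak intensities summing to 1, or NULL).
#' @slot ptms data.frame with columns `ptm_id` (integer) and `content`
#'   (free-text modification description(s), comma-separated).
#' @slot matches data.frame with columns `tp_id`, `conf`, `rt_min`, `charge`,
#'   `mono_mass` and list column `mz` (list of peak groups; each group a
#'   two-column matrix `mz`, `intensity`).
#' @aliases HXMSDataset
#' @exportClass HXMSDataset
setClass("HXMSDataset", representation(
  metadata   = "HXMSMetadata",
  timepoints = "data.frame",
  ptms       = "data.frame",
  matches    = "data.frame"
))

.TP_COLS    <- c("index", "mod", "start", "end", "rep", "ptm_id",
                 "time_s", "uptake", "envelope")
.PTM_COLS   <- c("ptm_id", "content")
.MATCH_COLS <- c("tp_id", "conf", "rt_min", "charge", "mono_mass", "mz")

setValidity("HXMSDataset", function(object) {
  msgs <- character(0)
  if (!all(.TP_COLS %in% names(object@timepoints)))
    msgs <- c(msgs, paste("timepoints must have columns",
                          paste(.TP_COLS, collapse = ", ")))
  if (!all(.PTM_COLS %in% names(object@ptms)))
    msgs <- c(msgs, "ptms must have columns ptm_id, content")
  if (!all(.MATCH_COLS %in% names(object@matches)))
    msgs <- c(msgs, paste("matches must have columns",
                          paste(.MATCH_COLS, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

# Canonical builders so every producer (reader, converters, generator) yields
# byte-identical column types and attributes.
newTimepointTable <- function(index = integer(0), mod = character(0),
                              start = integer(0), end = integer(0),
                              rep = integer(0), ptm_id = integer(0),
                              time_s = numeric(0), uptake = numeric(0),
                              envelope = NULL) {
  n <- length(index)
  if (is.null(envelope)) envelope <- vector("list", n)
  df <- data.frame(index = as.integer(index), mod = as.character(mod),
                   start = as.integer(start), end = as.integer(end),
                   rep = as.integer(rep), ptm_id = as.integer(ptm_id),
                   time_s = as.numeric(time_s), uptake = as.numeric(uptake),
                   stringsAsFactors = FALSE)
  df$envelope <- envelope
  rownames(df) <- NULL
  df
}

newPTMTable <- function(ptm_id = integer(0), content = character(0)) {
  data.frame(ptm_id = as.integer(ptm_id), content = as.character(content),
             stringsAsFactors = FALSE)
}

newMatchTable <- function(tp_id = integer(0), conf = numeric(0),
                          rt_min = numeric(0), charge = integer(0),
                          mono_mass = numeric(0), mz = NULL) {
  n <- length(tp_id)
  if (is.null(mz)) mz <- vector("list", n)
  df <- data.frame(tp_id = as.integer(tp_id), conf = as.numeric(conf),
                   rt_min = as.numeric(rt_min), charge = as.integer(charge),
                   mono_mass = as.numeric(mono_mass),
                   stringsAsFactors = FALSE)
  df$mz <- mz
  rownames(df) <- NULL
  df
}

# One peak group of a MATCH M/Z field: matrix with columns mz, intensity.
mzGroup <- function(mz, intensity) {
  m <- cbind(mz = as.numeric(mz), intensity = as.numeric(intensity))
  rownames(m) <- NULL
  m
}

#' Construct an HXMS dataset
#'
#' @param metadata An [HXMSMetadata-class] (see [hxmsMetadata()]).
#' @param timepoints data.frame of timepoint records; see
#'   [HXMSDataset-class] for the column contract. Missing columns of the
#'   right default (e.g. `rep`, `ptm_id`) are not filled in automatically.
#' @param ptms Optional PTM dictionary data.frame (`ptm_id`, `content`).
#' @param matches Optional MATCH table data.frame.
#' @return An [HXMSDataset-class].
#' @seealso [validateDataset()], [readHXMS()], [writeHXMS()]
#' @export
HXMSDataset <- function(metadata, timepoints = newTimepointTable(),
                        ptms = newPTMTable(), matches = newMatchTable()) {
  new("HXMSDataset", metadata = metadata,
      timepoints = timepoints, ptms = ptms, matches = matches)
}

#' @describeIn HXMSDataset-class Experiment metadata accessor.
#' @param x,object An `HXMSDataset`.
#' @export
experimentMetadata <- function(x) x@metadata

#' @describeIn HXMSDataset-class Timepoint table accessor.
#' @export
timepoints <- function(x) x@timepoints

#' @describeIn HXMSDataset-class PTM dictionary accessor.
#' @export
ptmTable <- function(x) x@ptms

#' @describeIn HXMSDataset-class MATCH table accessor.
#' @export
matchTable <- function(x) x@matches

#' @describeIn HXMSDataset-class Protein sequence accessor (empty string when
#'   the metadata lacks one).
#' @export
proteinSequence <- function(x) {
  s <- x@metadata@proteinSequence
  if (length(s)) s else ""
}

setMethod("show", "HXMSMetadata", function(object) {
  val <- function(x, unit = "") if (length(x)) paste0(x, unit) else "<absent>"
  cat("HXMSMetadata (format ", object@formatVersion, ")\n", sep = "")
  seq <- val(object@proteinSequence)
  if (nchar(seq) > 40) seq <- paste0(substr(seq, 1, 37), "...")
  cat("  protein:  ", val(object@proteinName), " [",
      val(object@proteinState), "]\n", sep = "")
  cat("  sequence: ", seq, " (", nchar(val(object@proteinSequence, "")),
      " aa)\n", sep = "")
  cat("  T = ", val(object@temperatureK, " K"),
      ", pH(read) = ", val(object@pHRead),
      ", D2O saturation = ", val(object@d2oSaturation), "\n", sep = "")
  if (nrow(object@remarks))
    cat("  ", nrow(object@remarks), " additional remark(s)\n", sep = "")
  invisible(NULL)
})

setMethod("show", "HXMSDataset", function(object) {
  tp <- object@timepoints
  cat("HXMSDataset: ", nrow(tp), " timepoint record(s), ",
      nrow(object@ptms), " PTM entr", if (nrow(object@ptms) == 1) "y" else "ies",
      ", ", nrow(object@matches), " MATCH record(s)\n", sep = "")
  show(object@metadata)
  if (nrow(tp)) {
    pep <- unique(tp[, c("start", "end", "ptm_id")])
    tms <- sort(unique(tp$time_s))
    cat("  ", nrow(pep), " peptide(s); times (s): ",
        paste(ifelse(is.infinite(tms), "inf", format(tms, trim = TRUE)),
              collapse = ", "), "\n", sep = "")
    nEnv <- sum(!vapply(tp$envelope, is.null, logical(1)))
    cat("  ", nEnv, " record(s) carry isotopic envelopes\n", sep = "")
  }
  invisible(NULL)
})
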