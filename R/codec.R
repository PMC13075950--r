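# Writer and reader for HXMS v1.0 text files.
#
# Tabular rows are written fixed-width: each field left-justified and
# space-padded to the column width below (PDB-style), with the final
# variable-length field (ENVELOPE / CONTENT / M/Z) unpadded. The reader also
# accepts tab-separated rows, auto-detected per line, since files edited by
# hand or emitted by other writers commonly use tabs.

.TP_WIDTHS    <- c(TITLE = 12L, INDEX = 8L, MOD = 7L, START = 7L, END = 7L,
                   REP = 5L, PTM_ID = 8L, "TIME(SEC)" = 16L, UPTAKE = 9L)
.PTM_WIDTHS   <- c(TITLE = 12L, PTM_ID = 8L)
.MATCH_WIDTHS <- c(TITLE = 12L, TP_ID = 8L, CONF = 8L, "RT(min)" = 8L,
                   Z = 5L, MONO_M = 16L)

#' Column widths and numeric formats of the HXMS v1.0 serialization
#'
#' @return A list with the fixed character width of every tabular column
#'   (`tp`, `ptm`, `match`) and the decimal precision used for each numeric
#'   field (`formats`). Variable-length trailing fields (ENVELOPE, CONTENT,
#'   M/Z) have no width entry.
#' @export
hxmsSerializationProfile <- function() {
  list(tp = .TP_WIDTHS, ptm = .PTM_WIDTHS, match = .MATCH_WIDTHS,
       formats = c(UPTAKE = 2L, ENVELOPE_PEAK = 3L, CONF = 2L,
                   "RT(min)" = 3L, MONO_M = 6L, MZ = 4L, INTENSITY = 4L))
}

#' Serialize an incubation time for the TIME(SEC) field
#'
#' Finite times are written in lowercase scientific notation with six
#' fractional digits and a two-digit signed exponent; the fully deuterated
#' control time is the distinguished value `Inf` and serializes as `"inf"`.
#'
#' @param seconds Non-negative number of seconds, or `Inf`.
#' @return A single string, e.g. `formatTime(0)` is `"0.000000e+00"`.
#' @export
formatTime <- function(seconds) {
  if (!is.numeric(seconds) || length(seconds) != 1 || is.na(seconds))
    hxmsStop("FORMAT_ERROR", "time must be a single non-negative number or Inf")
  if (seconds < 0)
    hxmsStop("FORMAT_ERROR", "negative incubation time")
  if (is.infinite(seconds)) "inf" else sprintf("%.6e", seconds)
}

#' Parse a TIME(SEC) field
#'
#' Inverse of [formatTime()]; also accepts plain decimal notation for
#' robustness against hand-edited files.
#'
#' @param text The field text, e.g. `"6.000000e+01"` or `"inf"`.
#' @return Seconds as a number; `Inf` for fully deuterated controls.
#' @export
parseTime <- function(text) {
  text <- trimws(text)
  if (!isSingleString(text) || !nzchar(text))
    hxmsStop("FORMAT_ERROR", "empty TIME(SEC) field")
  if (tolower(text) %in% c("inf", "infinite")) return(Inf)
  val <- suppressWarnings(as.numeric(text))
  if (is.na(val))
    hxmsStop("FORMAT_ERROR", sprintf("unparseable TIME(SEC) value '%s'", text))
  if (val < 0)
    hxmsStop("FORMAT_ERROR", sprintf("negative TIME(SEC) value '%s'", text))
  val
}

.formatEnvelope <- function(env) paste(sprintf("%.3f", env), collapse = ",")

.parseEnvelope <- function(text, line = NULL) {
  text <- trimws(text)
  if (!nzchar(text)) return(NULL)
  vals <- suppressWarnings(as.numeric(trimws(strsplit(text, ",", fixed = TRUE)[[1]])))
  if (anyNA(vals))
    hxmsStop("FORMAT_ERROR", sprintf("unparseable ENVELOPE field '%s'", text), line)
  vals
}

.metaLine <- function(kind, title, value) paste(kind, title, value, sep = "\t")

#' Write a dataset as HXMS v1.0 text
#'
#' Emits, in order: the METADATA/REMARK block (tag, tab, title, tab, value
#' per line, with the format version appended automatically as a REMARK),
#' then TP rows, PTM rows and MATCH rows in fixed-width layout. Output is
#' byte-deterministic: identical datasets yield identical files. Envelope
#' peaks are written at 3 decimals, UPTAKE at 2, CONF at 2, RT at 3, MONO_M
#' at 6, m/z and intensity at 4.
#'
#' @param dataset A valid [HXMSDataset-class]; error-severity violations from
#'   [validateDataset()] abort the write (validate and repair first).
#' @param file Path or connection to write to; `NULL` (default) returns the
#'   file content as a single string.
#' @return The HXMS text invisibly (or visibly when `file` is `NULL`).
#' @seealso [readHXMS()] for the inverse; the two are an exact round trip for
#'   datasets already on the serialization grid (3-decimal envelopes etc.).
#' @export
writeHXMS <- function(dataset, file = NULL) {
  stopifnot(is(dataset, "HXMSDataset"))
  rep_ <- validateDataset(dataset)
  if (any(rep_$severity == "error")) {
    bad <- rep_[rep_$severity == "error", ]
    hxmsStop("INVALID_DATASET",
             paste0("refusing to write an invalid dataset: ",
                    paste(unique(bad$code), collapse = ", ")))
  }
  md <- dataset@metadata
  lines <- character(0)
  addMeta <- function(title, value)
    lines <<- c(lines, .metaLine("METADATA", title, value))
  if (length(md@proteinSequence)) addMeta("PROTEIN_SEQUENCE", md@proteinSequence)
  if (length(md@proteinName))     addMeta("PROTEIN_NAME", md@proteinName)
  if (length(md@proteinState))    addMeta("PROTEIN_STATE", md@proteinState)
  if (length(md@temperatureK))    addMeta("TEMPERATURE (K)",
                                          formatMetaNumber(md@temperatureK))
  if (length(md@pHRead))          addMeta("pH(READ)", formatMetaNumber(md@pHRead))
  if (length(md@d2oSaturation))   addMeta("D_2_O_SATURATION",
                                          formatMetaNumber(md@d2oSaturation))
  if (nrow(md@remarks))
    lines <- c(lines, .metaLine(md@remarks$kind, md@remarks$title,
                                md@remarks$value))
  lines <- c(lines, .metaLine("REMARK", "FORMAT_VERSION", md@formatVersion))

  tp <- dataset@timepoints
  if (nrow(tp)) {
    w <- .TP_WIDTHS
    for (i in seq_len(nrow(tp))) {
      env <- tp$envelope[[i]]
      row <- paste0(
        padField("TP", w[["TITLE"]]),
        padField(tp$index[i], w[["INDEX"]]),
        padField(tp$mod[i], w[["MOD"]]),
        padField(tp$start[i], w[["START"]]),
        padField(tp$end[i], w[["END"]]),
        padField(tp$rep[i], w[["REP"]]),
        padField(sprintf("%04d", tp$ptm_id[i]), w[["PTM_ID"]]),
        padField(formatTime(tp$time_s[i]), w[["TIME(SEC)"]]),
        padField(sprintf("%.2f", tp$uptake[i]), w[["UPTAKE"]]),
        if (is.null(env)) "" else .formatEnvelope(env))
      lines <- c(lines, sub(" +$", "", row))
    }
  }

  ptm <- dataset@ptms
  if (nrow(ptm)) {
    w <- .PTM_WIDTHS
    for (i in seq_len(nrow(ptm))) {
      row <- paste0(padField("PTM", w[["TITLE"]]),
                    padField(sprintf("%04d", ptm$ptm_id[i]), w[["PTM_ID"]]),
                    ptm$content[i])
      lines <- c(lines, sub(" +$", "", row))
    }
  }

  mt <- dataset@matches
  if (nrow(mt)) {
    w <- .MATCH_WIDTHS
    for (i in seq_len(nrow(mt))) {
      row <- paste0(padField("MATCH", w[["TITLE"]]),
                    padField(mt$tp_id[i], w[["TP_ID"]]),
                    padField(sprintf("%.2f", mt$conf[i]), w[["CONF"]]),
                    padField(sprintf("%.3f", mt$rt_min[i]), w[["RT(min)"]]),
                    padField(mt$charge[i], w[["Z"]]),
                    padField(sprintf("%.6f", mt$mono_mass[i]), w[["MONO_M"]]),
                    encodeMZ(mt$mz[[i]]))
      lines <- c(lines, sub(" +$", "", row))
    }
  }

  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(file)) return(text)
  con <- if (inherits(file, "connection")) file else base::file(file, "wb")
  if (!inherits(file, "connection")) on.exit(close(con))
  writeBin(charToRaw(enc2utf8(text)), con)
  invisible(text)
}

# Slice a fixed-width line into trimmed fields given a width vector; the
# remainder past the last fixed column is the variable-length tail.
.sliceFixed <- function(line, widths) {
  starts <- cumsum(c(1L, widths))
  fields <- character(length(widths))
  for (i in seq_along(widths))
    fields[i] <- trimws(substr(line, starts[i], starts[i + 1] - 1L))
  tail <- trimws(substr(line, starts[length(starts)], nchar(line)))
  list(fields = fields, tail = tail)
}

.rowFields <- function(line, widths, lineno) {
  if (grepl("\t", line, fixed = TRUE)) {
    parts <- trimws(strsplit(line, "\t", fixed = TRUE)[[1]])
    nfixed <- length(widths)
    if (length(parts) < nfixed)
      hxmsStop("FORMAT_ERROR",
               sprintf("expected at least %d tab-separated fields, got %d",
                       nfixed, length(parts)), lineno)
    list(fields = parts[seq_len(nfixed)],
         tail = if (length(parts) > nfixed)
           paste(parts[-seq_len(nfixed)], collapse = "\t") else "")
  } else {
    .sliceFixed(line, widths)
  }
}

.parseIntField <- function(x, what, lineno, default = NA_integer_) {
  if (!nzchar(x)) {
    if (!is.na(default)) return(default)
    hxmsStop("FORMAT_ERROR", sprintf("empty %s field", what), lineno)
  }
  val <- suppressWarnings(as.integer(x))
  if (is.na(val))
    hxmsStop("FORMAT_ERROR", sprintf("unparseable %s value '%s'", what, x), lineno)
  val
}

.parseNumField <- function(x, what, lineno) {
  val <- suppressWarnings(as.numeric(x))
  if (!nzchar(x) || is.na(val))
    hxmsStop("FORMAT_ERROR", sprintf("unparseable %s value '%s'", what, x), lineno)
  val
}

#' Read an HXMS v1.0 file
#'
#' Parses by row tag (METADATA, REMARK, TP, PTM, MATCH). Each tabular row may
#' be fixed-width or tab-separated; the dialect is detected per line.
#' Sections may appear in any order. Rows with an unknown tag are collected
#' as warnings rather than failing the parse, so files written by newer
#' format revisions degrade gracefully.
#'
#' @param source Path to a file, or the file content as a character vector
#'   (one string with embedded newlines, or one element per line).
#' @return An [HXMSDataset-class]. Semantic problems (missing required
#'   metadata, index gaps, dangling references) are *not* raised here; run
#'   [validateDataset()] on the result.
#' @section Errors: A row matching no known shape, an unparseable field, a
#'   duplicated required metadata entry, or input with no metadata section at
#'   all raise a `FORMAT_ERROR` condition carrying the line number.
#' @export
readHXMS <- function(source) {
  if (is.character(source) && length(source) == 1 &&
      !grepl("\n", source, fixed = TRUE) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE, encoding = "UTF-8")
  } else if (is.character(source)) {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
  } else {
    hxmsStop("FORMAT_ERROR", "source must be a path or character text")
  }

  meta <- list(remarks_kind = character(0), remarks_title = character(0),
               remarks_value = character(0), formatVersion = .FORMAT_VERSION)
  seen <- character(0)
  tpRows <- list(); ptmRows <- list(); matchRows <- list()
  unknown <- character(0)

  setRequired <- function(title, value, lineno) {
    if (title %in% seen)
      hxmsStop("FORMAT_ERROR",
               sprintf("duplicate required metadata '%s'", title), lineno)
    seen <<- c(seen, title)
    value
  }

  for (lineno in seq_along(lines)) {
    line <- lines[[lineno]]
    if (!nzchar(trimws(line))) next
    tag <- if (grepl("\t", line, fixed = TRUE))
      trimws(strsplit(line, "\t", fixed = TRUE)[[1]][1])
    else
      trimws(substr(line, 1L, 12L))

    if (tag %in% c("METADATA", "REMARK")) {
      parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(parts) < 3)
        hxmsStop("FORMAT_ERROR",
                 "metadata rows need tag, title and value separated by tabs",
                 lineno)
      title <- trimws(parts[2])
      value <- paste(parts[-(1:2)], collapse = "\t")
      if (tag == "METADATA" && title == "PROTEIN_SEQUENCE") {
        meta$proteinSequence <- setRequired(title, value, lineno)
      } else if (tag == "METADATA" && title == "TEMPERATURE (K)") {
        meta$temperatureK <- .parseNumField(setRequired(title, value, lineno),
                                            title, lineno)
      } else if (tag == "METADATA" && title == "pH(READ)") {
        meta$pHRead <- .parseNumField(setRequired(title, value, lineno),
                                      title, lineno)
      } else if (tag == "METADATA" && title == "D_2_O_SATURATION") {
        meta$d2oSaturation <- .parseNumField(setRequired(title, value, lineno),
                                             title, lineno)
      } else if (tag == "METADATA" && title == "PROTEIN_NAME") {
        meta$proteinName <- setRequired(title, value, lineno)
      } else if (tag == "METADATA" && title == "PROTEIN_STATE") {
        meta$proteinState <- setRequired(title, value, lineno)
      } else if (tag == "REMARK" && title == "FORMAT_VERSION") {
        meta$formatVersion <- value
      } else {
        meta$remarks_kind <- c(meta$remarks_kind, tag)
        meta$remarks_title <- c(meta$remarks_title, title)
        meta$remarks_value <- c(meta$remarks_value, value)
      }
    } else if (tag == "TP") {
      f <- .rowFields(line, .TP_WIDTHS, lineno)
      v <- f$fields
      tpRows[[length(tpRows) + 1L]] <- list(
        index  = .parseIntField(v[2], "INDEX", lineno),
        mod    = if (nzchar(v[3])) v[3] else "A",
        start  = .parseIntField(v[4], "START", lineno),
        end    = .parseIntField(v[5], "END", lineno),
        rep    = .parseIntField(v[6], "REP", lineno, default = 0L),
        ptm_id = .parseIntField(v[7], "PTM_ID", lineno, default = 0L),
        time_s = tryCatch(parseTime(v[8]), hxms_error = function(e)
          hxmsStop("FORMAT_ERROR", conditionMessage(e), lineno)),
        uptake = .parseNumField(v[9], "UPTAKE", lineno),
        envelope = .parseEnvelope(f$tail, lineno))
    } else if (tag == "PTM") {
      f <- .rowFields(line, .PTM_WIDTHS, lineno)
      ptmRows[[length(ptmRows) + 1L]] <- list(
        ptm_id = .parseIntField(f$fields[2], "PTM_ID", lineno),
        content = f$tail)
    } else if (tag == "MATCH") {
      f <- .rowFields(line, .MATCH_WIDTHS, lineno)
      v <- f$fields
      matchRows[[length(matchRows) + 1L]] <- list(
        tp_id = .parseIntField(v[2], "TP_ID", lineno),
        conf = .parseNumField(v[3], "CONF", lineno),
        rt_min = .parseNumField(v[4], "RT(min)", lineno),
        charge = .parseIntField(v[5], "Z", lineno),
        mono_mass = .parseNumField(v[6], "MONO_M", lineno),
        mz = tryCatch(decodeMZ(f$tail), hxms_error = function(e)
          hxmsStop("FORMAT_ERROR", conditionMessage(e), lineno)))
    } else {
      unknown <- c(unknown, sprintf("line %d: unknown row tag '%s'", lineno, tag))
    }
  }

  hasMeta <- length(seen) > 0 || length(meta$remarks_kind) > 0
  if (!hasMeta)
    hxmsStop("FORMAT_ERROR", "no metadata section found (empty or non-HXMS input)")

  if (length(unknown))
    warning(paste(unknown, collapse = "; "), call. = FALSE)

  md <- hxmsMetadata(
    proteinSequence = meta$proteinSequence,
    temperatureK = meta$temperatureK, pHRead = meta$pHRead,
    d2oSaturation = meta$d2oSaturation,
    proteinName = meta$proteinName, proteinState = meta$proteinState,
    remarks = data.frame(kind = meta$remarks_kind, title = meta$remarks_title,
                         value = meta$remarks_value, stringsAsFactors = FALSE),
    formatVersion = meta$formatVersion)

  g <- function(rows, name) vapply(rows, `[[`, numeric(1), name)
  tp <- if (length(tpRows)) newTimepointTable(
    index = g(tpRows, "index"),
    mod = vapply(tpRows, `[[`, character(1), "mod"),
    start = g(tpRows, "start"), end = g(tpRows, "end"),
    rep = g(tpRows, "rep"), ptm_id = g(tpRows, "ptm_id"),
    time_s = g(tpRows, "time_s"), uptake = g(tpRows, "uptake"),
    envelope = lapply(tpRows, `[[`, "envelope")) else newTimepointTable()
  ptm <- if (length(ptmRows)) newPTMTable(
    ptm_id = g(ptmRows, "ptm_id"),
    content = vapply(ptmRows, `[[`, character(1), "content")) else newPTMTable()
  mt <- if (length(matchRows)) newMatchTable(
    tp_id = g(matchRows, "tp_id"), conf = g(matchRows, "conf"),
    rt_min = g(matchRows, "rt_min"), charge = g(matchRows, "charge"),
    mono_mass = g(matchRows, "mono_mass"),
    mz = lapply(matchRows, `[[`, "mz")) else newMatchTable()

  HXMSDataset(md, tp, ptm, mt)
}
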