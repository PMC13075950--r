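# Converters from vendor-export dialects to HXMSDataset.
#
# The vendor programs' exact export schemas are proprietary; each dialect
# here is a documented minimal column schema that captures what the vendor
# can express (see the capability matrix in hxmsDialects()). Real-world
# exports with extra columns are accepted; missing required columns fail
# loudly with SCHEMA_ERROR. Column-name matching is case-insensitive.

#' Capability matrix of the supported input dialects
#'
#' * `uptake_direct`: the export reports deuterium uptake itself, used
#'   as-is (DynamX, BioPharma Finder).
#' * `envelopes_available`: the export can carry full isotopic spectra,
#'   enabling ENVELOPE fields and the MATCH section (HDX Workbench,
#'   HDExaminer).
#' * `ptms_supported`: modification annotations are harvested into the PTM
#'   dictionary (all except HDExaminer and BioPharma Finder, whose HXMS
#'   files need PTMs added manually).
#'
#' @return data.frame with one row per dialect and logical capability
#'   columns.
#' @export
hxmsDialects <- function() {
  data.frame(
    name = c("custom", "dynamx", "hdx_workbench", "hdexaminer",
             "biopharma_finder"),
    uptake_direct       = c(TRUE,  TRUE,  FALSE, FALSE, TRUE),
    envelopes_available = c(TRUE,  FALSE, TRUE,  TRUE,  FALSE),
    ptms_supported      = c(TRUE,  TRUE,  TRUE,  FALSE, FALSE),
    stringsAsFactors = FALSE)
}

# ---- shared table plumbing -------------------------------------------------

# Read a delimited table from a path, text, or data.frame; all cells kept as
# character so each dialect controls its own parsing and error reporting.
# Comma vs tab is auto-detected from the header line.
.readDelimTable <- function(table) {
  if (is.data.frame(table)) {
    df <- table
    df[] <- lapply(df, as.character)
    return(df)
  }
  if (!is.character(table))
    hxmsStop("SCHEMA_ERROR", "input must be a path, text, or data.frame")
  if (length(table) == 1 && !grepl("\n", table, fixed = TRUE) &&
      file.exists(table)) {
    lines <- readLines(table, warn = FALSE, encoding = "UTF-8")
  } else {
    lines <- unlist(strsplit(paste(table, collapse = "\n"), "\n", fixed = TRUE))
  }
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    hxmsStop("SCHEMA_ERROR", "empty export (no header row)")
  sep <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
  utils::read.table(text = paste(lines, collapse = "\n"), sep = sep,
                    header = TRUE, colClasses = "character",
                    check.names = FALSE, quote = "\"", comment.char = "",
                    stringsAsFactors = FALSE)
}

# Case-insensitive column fetch; NULL when absent.
.col <- function(df, name) {
  hit <- match(tolower(name), tolower(names(df)))
  if (is.na(hit)) NULL else df[[hit]]
}

.requireCols <- function(df, cols, dialect) {
  have <- tolower(names(df))
  for (nm in cols)
    if (!(tolower(nm) %in% have))
      hxmsStop("SCHEMA_ERROR",
               sprintf("dialect '%s' requires column '%s'", dialect, nm))
  if (nrow(df) == 0)
    hxmsStop("SCHEMA_ERROR", sprintf("empty export for dialect '%s'", dialect))
  invisible(df)
}

.cellNum <- function(x, col, rows = seq_along(x)) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & nzchar(trimws(x)))
  if (length(bad) || anyNA(out))
    hxmsStop("SCHEMA_ERROR",
             sprintf("unparseable value '%s' in column '%s' (row %d)",
                     x[c(bad, which(is.na(out)))[1]], col,
                     rows[c(bad, which(is.na(out)))[1]]))
  out
}

.cellInt <- function(x, col, default = 0L) {
  x <- trimws(x)
  x[!nzchar(x)] <- as.character(default)
  as.integer(.cellNum(x, col))
}

# Exposure parser: seconds, with dialect sentinels for fully deuterated rows.
.cellExposure <- function(x, sentinels) {
  x <- trimws(x)
  out <- numeric(length(x))
  fd <- tolower(x) %in% c(tolower(sentinels), "inf", "infinite")
  out[fd] <- Inf
  out[!fd] <- .cellNum(x[!fd], "Exposure", rows = which(!fd))
  if (any(out[!fd] < 0))
    hxmsStop("SCHEMA_ERROR", "negative exposure time in export")
  out
}

# Harvest modification texts into the PTM dictionary: each unique nonempty
# text gets the next nonzero ID in first-appearance order; empty text is
# "no PTM" (ID 0).
.harvestPTMs <- function(ptmText) {
  ptmText <- trimws(ptmText)
  uniq <- unique(ptmText[nzchar(ptmText)])
  ids <- integer(length(ptmText))
  ids[nzchar(ptmText)] <- match(ptmText[nzchar(ptmText)], uniq)
  list(ids = ids,
       table = newPTMTable(ptm_id = seq_along(uniq), content = uniq))
}

# Mode labels: pass single letters through; map numeric populations 1,2,...
# to A,B,...; empty -> "A".
.modeLetters <- function(x) {
  x <- toupper(trimws(x))
  x[!nzchar(x)] <- "A"
  num <- grepl("^[0-9]+$", x)
  x[num] <- LETTERS[as.integer(x[num])]
  x
}

# Recompute uptake from per-row centroids: each replicate is referenced
# against its own mode-"A" 0 s centroid for the peptide, with the
# replicate-average fallback; raises MISSING_ZERO naming the peptide when no
# replicate has one.
.uptakeFromCentroids <- function(start, end, pep_extra, rep, mod, time_s,
                                 centroid) {
  uptake <- numeric(length(start))
  pepKey <- paste(start, end, pep_extra)
  for (k in unique(pepKey)) {
    rows <- which(pepKey == k)
    base <- rows[mod[rows] == "A"]
    refTab <- data.frame(replicate = rep[base], time_s = time_s[base])
    refTab$centroid <- centroid[base]
    for (r in unique(rep[rows])) {
      ref <- tryCatch(zeroReferenceForReplicate(refTab, r),
        hxms_missing_zero = function(e)
          hxmsStop("MISSING_ZERO",
                   sprintf("peptide %d-%d has no 0 s timepoint in any replicate",
                           start[rows[1]], end[rows[1]])))
      sel <- rows[rep[rows] == r]
      uptake[sel] <- centroid[sel] - ref
    }
  }
  uptake
}

# Assemble the dataset: INDEX by row order, then a sanity renumber.
.assembleDataset <- function(metadata, start, end, rep, mod, ptm_id, time_s,
                             uptake, envelope = NULL, ptms = newPTMTable(),
                             matches = newMatchTable()) {
  tp <- newTimepointTable(
    index = seq_along(start) - 1L, mod = mod, start = start, end = end,
    rep = rep, ptm_id = ptm_id, time_s = time_s, uptake = uptake,
    envelope = envelope)
  HXMSDataset(metadata, tp, ptms, matches)
}

# ---- dialects --------------------------------------------------------------

#' Convert a PFLink-style custom CSV to an HXMS dataset
#'
#' The custom table is the dialect users populate by hand. Required columns
#' (case-insensitive): `start`, `end`, `replicate`, `mode`, `time_s`, plus
#' `uptake` and/or `envelope`. Optional: `ptm` (free-text modification
#' description; identical texts share one PTM dictionary entry). The
#' `envelope` cell holds semicolon-separated relative intensities (e.g.
#' `"527;298;116"`), normalized on import; `time_s` accepts `"inf"` for
#' fully deuterated controls. When `uptake` is absent it is recomputed from
#' envelope centroids by zero-timepoint referencing.
#'
#' @param table Path to the delimited file, its text, or a data.frame
#'   (comma or tab separated, auto-detected).
#' @param experimentInfo An [HXMSMetadata-class] carrying the experimental
#'   conditions (see [hxmsMetadata()]).
#' @return An [HXMSDataset-class] with INDEX assigned by row order.
#' @family vendor converters
#' @export
parseCustomCSV <- function(table, experimentInfo) {
  df <- .readDelimTable(table)
  .requireCols(df, c("start", "end", "replicate", "mode", "time_s"), "custom")
  hasUptake <- !is.null(.col(df, "uptake"))
  hasEnv <- !is.null(.col(df, "envelope"))
  if (!hasUptake && !hasEnv)
    hxmsStop("SCHEMA_ERROR",
             "dialect 'custom' requires an 'uptake' and/or 'envelope' column")
  start <- .cellInt(.col(df, "start"), "start", default = NA_integer_)
  end <- .cellInt(.col(df, "end"), "end", default = NA_integer_)
  rep <- .cellInt(.col(df, "replicate"), "replicate")
  mod <- .modeLetters(.col(df, "mode"))
  time_s <- .cellExposure(.col(df, "time_s"), sentinels = "FD")
  envelope <- NULL
  if (hasEnv) {
    envelope <- lapply(seq_len(nrow(df)), function(i) {
      cell <- trimws(.col(df, "envelope")[i])
      if (!nzchar(cell)) return(NULL)
      normalizeEnvelope(.cellNum(strsplit(cell, ";", fixed = TRUE)[[1]],
                                 "envelope", rows = rep(i, 99)))
    })
  }
  ptmCol <- .col(df, "ptm")
  h <- .harvestPTMs(if (is.null(ptmCol)) character(nrow(df)) else ptmCol)
  if (hasUptake) {
    uptake <- .cellNum(.col(df, "uptake"), "uptake")
  } else {
    cen <- vapply(envelope, envelopeCentroid, numeric(1))
    uptake <- .uptakeFromCentroids(start, end, h$ids, rep, mod, time_s, cen)
  }
  .assembleDataset(experimentInfo, start, end, rep, mod, h$ids, time_s,
                   uptake, envelope, ptms = h$table)
}

#' Convert a DynamX-style export to an HXMS dataset
#'
#' DynamX reports deuterium uptake directly, so the `Uptake` column is used
#' as-is and the resulting HXMS file is mean-deuteration level (no
#' envelopes). Required columns: `Start`, `End`, `Exposure` (seconds; the
#' literal `"FD"` marks a fully deuterated control), `Uptake` (Da).
#' Optional: `Modification` (harvested into the PTM dictionary),
#' `Replicate` (default 0), `State`, `Protein`, `Sequence`.
#'
#' @inheritParams parseCustomCSV
#' @return An [HXMSDataset-class].
#' @family vendor converters
#' @export
parseDynamX <- function(table, experimentInfo) {
  df <- .readDelimTable(table)
  .requireCols(df, c("Start", "End", "Exposure", "Uptake"), "dynamx")
  start <- .cellInt(.col(df, "Start"), "Start", default = NA_integer_)
  end <- .cellInt(.col(df, "End"), "End", default = NA_integer_)
  rep <- .cellInt(if (is.null(.col(df, "Replicate"))) character(nrow(df))
                  else .col(df, "Replicate"), "Replicate")
  time_s <- .cellExposure(.col(df, "Exposure"), sentinels = "FD")
  uptake <- .cellNum(.col(df, "Uptake"), "Uptake")
  modCol <- .col(df, "Modification")
  h <- .harvestPTMs(if (is.null(modCol)) character(nrow(df)) else modCol)
  .assembleDataset(experimentInfo, start, end, rep,
                   rep("A", nrow(df)), h$ids, time_s, uptake, ptms = h$table)
}

# Parse one Spectrum cell (MATCH M/Z codec syntax) into groups + envelope.
.spectrumCell <- function(cell) {
  cell <- trimws(cell)
  if (!nzchar(cell)) return(NULL)
  groups <- decodeMZ(cell)
  list(groups = groups,
       intensities = vapply(groups, function(g) sum(g[, "intensity"]),
                            numeric(1)))
}

#' Convert an HDX Workbench-style export to an HXMS dataset
#'
#' Workbench exports per-timepoint centroids (and optionally full spectra),
#' not uptake, so deuterium uptake is recomputed here: the zero-timepoint
#' centroid is identified for each peptide and replicate (or the average
#' over replicates when a replicate lacks a 0 s point) and subtracted from
#' every timepoint centroid. Required columns: `Start`, `End`, `Exposure`
#' (seconds; `"FD"`/`"inf"` for fully deuterated), `Centroid`
#' (deconvoluted mass scale, Da). Optional: `Replicate`, `Charge`,
#' `Modification` (harvested into PTMs), `Spectrum` (m/z-intensity text in
#' the MATCH M/Z syntax, quoted in CSV), `RT` (min), `Conf`, `MonoMass`.
#'
#' Rows that differ only in `Charge` are the same measurement observed at
#' several charge states; they are merged into one record by
#' intensity-weighted averaging of their normalized envelopes (set
#' `mergeCharges = FALSE` to keep the highest-total-intensity charge
#' instead). Each charge row with a spectrum still contributes its own MATCH
#' record, so per-charge raw evidence stays traceable.
#'
#' @inheritParams parseCustomCSV
#' @param mergeCharges How to combine per-charge rows; see Details.
#' @return An [HXMSDataset-class].
#' @family vendor converters
#' @export
parseHDXWorkbench <- function(table, experimentInfo, mergeCharges = TRUE) {
  df <- .readDelimTable(table)
  .requireCols(df, c("Start", "End", "Exposure", "Centroid"), "hdx_workbench")
  n <- nrow(df)
  start <- .cellInt(.col(df, "Start"), "Start", default = NA_integer_)
  end <- .cellInt(.col(df, "End"), "End", default = NA_integer_)
  rep <- .cellInt(if (is.null(.col(df, "Replicate"))) character(n)
                  else .col(df, "Replicate"), "Replicate")
  time_s <- .cellExposure(.col(df, "Exposure"), sentinels = "FD")
  centroid <- .cellNum(.col(df, "Centroid"), "Centroid")
  charge <- .cellInt(if (is.null(.col(df, "Charge"))) character(n)
                     else .col(df, "Charge"), "Charge", default = 1L)
  modCol <- .col(df, "Modification")
  modText <- trimws(if (is.null(modCol)) character(n) else modCol)
  specCol <- .col(df, "Spectrum")
  spectra <- if (is.null(specCol)) vector("list", n)
             else lapply(specCol, .spectrumCell)
  rtCol <- .col(df, "RT")
  rt <- if (is.null(rtCol)) numeric(n) else .cellNum(rtCol, "RT")
  confCol <- .col(df, "Conf")
  conf <- if (is.null(confCol)) rep_len(1, n) else .cellNum(confCol, "Conf")
  monoCol <- .col(df, "MonoMass")
  mono <- if (is.null(monoCol)) rep_len(NA_real_, n)
          else .cellNum(monoCol, "MonoMass")

  # group per measurement; charge states of the same measurement merge
  key <- paste(start, end, rep, modText, time_s)
  first <- which(!duplicated(key))
  mergedEnv <- vector("list", length(first))
  mergedCen <- numeric(length(first))
  matchOf <- integer(0)   # row in df -> merged record number
  for (j in seq_along(first)) {
    rows <- which(key == key[first[j]])
    matchOf[rows] <- j
    specs <- spectra[rows]
    haveSpec <- !vapply(specs, is.null, logical(1))
    wt <- ifelse(haveSpec,
                 vapply(specs, function(s) if (is.null(s)) 0 else
                   sum(s$intensities), numeric(1)), 0)
    if (any(haveSpec) && all(wt[haveSpec] == 0)) wt[haveSpec] <- 1
    if (any(haveSpec)) {
      if (!mergeCharges && sum(haveSpec) > 1) {
        # keep only the highest-total-intensity charge state
        wt[-which.max(wt)] <- 0
      }
      maxlen <- max(vapply(specs[haveSpec], function(s)
        length(s$intensities), integer(1)))
      acc <- numeric(maxlen)
      for (i in which(haveSpec & wt > 0)) {
        e <- normalizeEnvelope(specs[[i]]$intensities)
        acc[seq_along(e)] <- acc[seq_along(e)] + e * wt[i]
      }
      mergedEnv[[j]] <- normalizeEnvelope(acc)
    }
    mergedCen[j] <- if (any(wt > 0)) sum(centroid[rows] * wt) / sum(wt)
                    else mean(centroid[rows])
  }

  mStart <- start[first]; mEnd <- end[first]; mRep <- rep[first]
  mTime <- time_s[first]; mMod <- modText[first]
  h <- .harvestPTMs(mMod)
  uptake <- .uptakeFromCentroids(mStart, mEnd, h$ids, mRep, rep("A",
    length(first)), mTime, mergedCen)

  # MATCH rows: one per charge row that carries a spectrum
  withSpec <- which(!vapply(spectra, is.null, logical(1)))
  matches <- if (length(withSpec)) {
    monoOut <- mono[withSpec]
    for (i in seq_along(withSpec)) {
      r <- withSpec[i]
      if (is.na(monoOut[i]))  # fall back to the first point and the charge
        monoOut[i] <- (spectra[[r]]$groups[[1]][1, "mz"] - 1.007276) * charge[r]
    }
    newMatchTable(
      tp_id = matchOf[withSpec] - 1L, conf = conf[withSpec],
      rt_min = rt[withSpec], charge = charge[withSpec],
      mono_mass = monoOut,
      mz = lapply(spectra[withSpec], `[[`, "groups"))
  } else newMatchTable()

  .assembleDataset(experimentInfo, mStart, mEnd, mRep,
                   rep("A", length(first)), h$ids, mTime, uptake,
                   envelope = mergedEnv, ptms = h$table, matches = matches)
}

#' Convert an HDExaminer-style export to an HXMS dataset
#'
#' HDExaminer results carry per-timepoint centroids and, optionally,
#' separate full spectra; uptake is recomputed by zero-timepoint referencing
#' exactly as for HDX Workbench. Multimodal (e.g. EX1 bimodal) rows carry a
#' `Population` column (letters, or 1,2,... mapped to A,B,...) that becomes
#' the MOD field. Modification annotations are *not* harvested — the dialect
#' does not support PTMs and they must be added to the HXMS file manually.
#'
#' Required result columns: `Start`, `End`, `Exposure` (seconds, `"FD"` /
#' `"inf"` sentinel), `Centroid` (Da). Optional: `Replicate`, `Population`,
#' `State`, `Sequence`. The optional `spectra` table is keyed by `Start`,
#' `End`, `Exposure` and optionally `Replicate`/`Population`, with columns
#' `Spectrum` (MATCH M/Z syntax), `Charge`, `RT`, `Conf`, `MonoMass`;
#' matched spectra become ENVELOPE fields, and with `fineMatch = TRUE` also
#' MATCH records preserving the uncentroided fine structure.
#'
#' @inheritParams parseCustomCSV
#' @param spectra Optional spectra table (path, text, or data.frame).
#' @param fineMatch Emit MATCH records from the spectra (default `FALSE`:
#'   spectra populate envelopes only).
#' @return An [HXMSDataset-class].
#' @family vendor converters
#' @export
parseHDExaminer <- function(table, experimentInfo, spectra = NULL,
                            fineMatch = FALSE) {
  df <- .readDelimTable(table)
  .requireCols(df, c("Start", "End", "Exposure", "Centroid"), "hdexaminer")
  n <- nrow(df)
  start <- .cellInt(.col(df, "Start"), "Start", default = NA_integer_)
  end <- .cellInt(.col(df, "End"), "End", default = NA_integer_)
  rep <- .cellInt(if (is.null(.col(df, "Replicate"))) character(n)
                  else .col(df, "Replicate"), "Replicate")
  popCol <- .col(df, "Population")
  mod <- .modeLetters(if (is.null(popCol)) character(n) else popCol)
  time_s <- .cellExposure(.col(df, "Exposure"), sentinels = "FD")
  centroid <- .cellNum(.col(df, "Centroid"), "Centroid")
  uptake <- .uptakeFromCentroids(start, end, "", rep, mod, time_s, centroid)

  envelope <- vector("list", n)
  matches <- newMatchTable()
  if (!is.null(spectra)) {
    sp <- .readDelimTable(spectra)
    .requireCols(sp, c("Start", "End", "Exposure", "Spectrum"),
                 "hdexaminer spectra")
    sStart <- .cellInt(.col(sp, "Start"), "Start", default = NA_integer_)
    sEnd <- .cellInt(.col(sp, "End"), "End", default = NA_integer_)
    sRep <- .cellInt(if (is.null(.col(sp, "Replicate"))) character(nrow(sp))
                     else .col(sp, "Replicate"), "Replicate")
    sPopCol <- .col(sp, "Population")
    sMod <- .modeLetters(if (is.null(sPopCol)) character(nrow(sp)) else sPopCol)
    sTime <- .cellExposure(.col(sp, "Exposure"), sentinels = "FD")
    sCharge <- .cellInt(if (is.null(.col(sp, "Charge"))) character(nrow(sp))
                        else .col(sp, "Charge"), "Charge", default = 1L)
    rtCol <- .col(sp, "RT")
    sRt <- if (is.null(rtCol)) numeric(nrow(sp)) else .cellNum(rtCol, "RT")
    confCol <- .col(sp, "Conf")
    sConf <- if (is.null(confCol)) rep_len(1, nrow(sp))
             else .cellNum(confCol, "Conf")
    monoCol <- .col(sp, "MonoMass")
    sMono <- if (is.null(monoCol)) rep_len(NA_real_, nrow(sp))
             else .cellNum(monoCol, "MonoMass")

    recKey <- paste(start, end, rep, mod, time_s)
    spKey <- paste(sStart, sEnd, sRep, sMod, sTime)
    mtRows <- list()
    for (i in seq_len(nrow(sp))) {
      cell <- .spectrumCell(.col(sp, "Spectrum")[i])
      if (is.null(cell)) next
      hit <- match(spKey[i], recKey)
      if (is.na(hit)) next
      envelope[[hit]] <- normalizeEnvelope(cell$intensities)
      if (fineMatch) {
        mono <- sMono[i]
        if (is.na(mono))
          mono <- (cell$groups[[1]][1, "mz"] - 1.007276) * sCharge[i]
        mtRows[[length(mtRows) + 1L]] <- list(
          tp_id = hit - 1L, conf = sConf[i], rt_min = sRt[i],
          charge = sCharge[i], mono_mass = mono, mz = cell$groups)
      }
    }
    if (length(mtRows))
      matches <- newMatchTable(
        tp_id = vapply(mtRows, `[[`, numeric(1), "tp_id"),
        conf = vapply(mtRows, `[[`, numeric(1), "conf"),
        rt_min = vapply(mtRows, `[[`, numeric(1), "rt_min"),
        charge = vapply(mtRows, `[[`, numeric(1), "charge"),
        mono_mass = vapply(mtRows, `[[`, numeric(1), "mono_mass"),
        mz = lapply(mtRows, `[[`, "mz"))
  }

  .assembleDataset(experimentInfo, start, end, rep, mod,
                   integer(n), time_s, uptake, envelope = envelope,
                   matches = matches)
}

#' Convert a BioPharma Finder-style export to an HXMS dataset
#'
#' BioPharma Finder reports deuterium uptake directly, so the `Uptake`
#' column is copied verbatim; the output is mean-deuteration level with no
#' PTM harvesting (the dialect cannot carry modifications). Required
#' columns: `Start`, `End`, `Exposure` (seconds; the literal `"MAX"` flags
#' a fully deuterated control), `Uptake` (Da). Optional: `Replicate`
#' (default 0), `Sequence`.
#'
#' @inheritParams parseCustomCSV
#' @return An [HXMSDataset-class].
#' @family vendor converters
#' @export
parseBioPharma <- function(table, experimentInfo) {
  df <- .readDelimTable(table)
  .requireCols(df, c("Start", "End", "Exposure", "Uptake"), "biopharma_finder")
  n <- nrow(df)
  start <- .cellInt(.col(df, "Start"), "Start", default = NA_integer_)
  end <- .cellInt(.col(df, "End"), "End", default = NA_integer_)
  rep <- .cellInt(if (is.null(.col(df, "Replicate"))) character(n)
                  else .col(df, "Replicate"), "Replicate")
  time_s <- .cellExposure(.col(df, "Exposure"), sentinels = "MAX")
  uptake <- .cellNum(.col(df, "Uptake"), "Uptake")
  .assembleDataset(experimentInfo, start, end, rep, rep("A", n),
                   integer(n), time_s, uptake)
}

#' Dispatch a vendor table to its dialect parser
#'
#' @inheritParams parseCustomCSV
#' @param dialect One of `"custom"`, `"dynamx"`, `"hdx_workbench"`,
#'   `"hdexaminer"`, `"biopharma_finder"` (hyphens accepted).
#' @param ... Passed on to the dialect parser (e.g. `spectra`, `fineMatch`).
#' @return An [HXMSDataset-class].
#' @export
parseVendorExport <- function(table, dialect, experimentInfo, ...) {
  dialect <- gsub("-", "_", tolower(dialect))
  switch(dialect,
    custom = parseCustomCSV(table, experimentInfo),
    dynamx = parseDynamX(table, experimentInfo),
    hdx_workbench = parseHDXWorkbench(table, experimentInfo, ...),
    hdexaminer = parseHDExaminer(table, experimentInfo, ...),
    biopharma = ,
    biopharma_finder = parseBioPharma(table, experimentInfo),
    hxmsStop("SCHEMA_ERROR", sprintf("unknown dialect '%s'", dialect)))
}
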