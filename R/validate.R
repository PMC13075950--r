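#' Validate an HXMS dataset against the v1.0 semantic rules
#'
#' Checks every dataset-level rule of the format — required metadata present
#' exactly once, contiguous 0-based timepoint indices, peptide coordinates
#' within the protein sequence, single-letter A-Z mode labels with the base
#' mode "A" present wherever higher letters occur, unit-sum isotopic
#' envelopes, a resolvable PTM dictionary with ID 0 reserved for "no PTM",
#' and MATCH rows whose `tp_id` resolves to an existing timepoint. Bad
#' content is reported, never thrown: the return value is a violation table
#' and an empty table means the dataset is clean.
#'
#' @param dataset An [HXMSDataset-class].
#' @return data.frame with columns `code` (stable machine code, e.g.
#'   `MISSING_METADATA`, `INDEX_GAP`, `START_GT_END`, `END_GT_SEQLEN`,
#'   `ENVELOPE_SUM`, `DANGLING_PTM_ID`, `TP_ID_UNRESOLVED`), `severity`
#'   ("error" or "warning"), `message`, and `locator` (which record the
#'   violation points at). Zero rows iff the dataset is fully valid.
#' @details Uptake below -1 Da is reported as a warning (`UPTAKE_SUSPECT`),
#'   not an error: mildly negative uptake is ordinary measurement noise and
#'   the format does not forbid it. Envelope sums are accepted within 5e-3 of
#'   1 to absorb the 3-decimal serialization rounding of each peak.
#' @examples
#' md <- hxmsMetadata("GSHMKTVEVNGADASDDN", 293.15, 6.0, 0.91)
#' ds <- HXMSDataset(md)
#' validateDataset(ds)           # empty: nothing wrong with an empty dataset
#' @seealso [renumberIndices()] to repair `INDEX_GAP` after filtering rows.
#' @export
validateDataset <- function(dataset) {
  stopifnot(is(dataset, "HXMSDataset"))
  md <- dataset@metadata
  tp <- dataset@timepoints
  out <- list()

  ## --- metadata -----------------------------------------------------------
  present <- c(
    "PROTEIN_SEQUENCE" = length(md@proteinSequence) == 1 &&
      nzchar(md@proteinSequence),
    "TEMPERATURE (K)"  = length(md@temperatureK) == 1,
    "pH(READ)"         = length(md@pHRead) == 1,
    "D_2_O_SATURATION" = length(md@d2oSaturation) == 1)
  for (title in names(present)[!present])
    out <- c(out, list(violation("MISSING_METADATA", "error",
      sprintf("required metadata '%s' is absent", title), "metadata")))
  if (present[["PROTEIN_SEQUENCE"]] &&
      !grepl("^[A-Za-z]+$", md@proteinSequence))
    out <- c(out, list(violation("BAD_SEQUENCE", "error",
      "PROTEIN_SEQUENCE must be alphabetic one-letter codes", "metadata")))
  if (present[["TEMPERATURE (K)"]] && md@temperatureK <= 0)
    out <- c(out, list(violation("TEMPERATURE_RANGE", "error",
      "TEMPERATURE (K) must be positive", "metadata")))
  if (present[["D_2_O_SATURATION"]] &&
      (md@d2oSaturation <= 0 || md@d2oSaturation > 1))
    out <- c(out, list(violation("D2O_RANGE", "error",
      "D_2_O_SATURATION must lie in (0, 1]", "metadata")))
  bad <- grepl("[\t\n]", md@remarks$title) | grepl("[\t\n]", md@remarks$value)
  if (any(bad))
    out <- c(out, list(violation("REMARK_CHARS", "error",
      "remark titles/values must not contain tabs or newlines",
      sprintf("remarks[%d]", which(bad)[1]))))

  seqlen <- if (present[["PROTEIN_SEQUENCE"]]) nchar(md@proteinSequence) else NA

  ## --- timepoints ---------------------------------------------------------
  if (nrow(tp)) {
    loc <- sprintf("TP[index=%d]", tp$index)
    if (!identical(tp$index, seq_len(nrow(tp)) - 1L))
      out <- c(out, list(violation("INDEX_GAP", "error",
        "timepoint INDEX must run 0,1,2,... in file order", "TP")))
    bad <- tp$start > tp$end
    if (any(bad))
      out <- c(out, list(violation("START_GT_END", "error",
        "peptide START exceeds END", loc[which(bad)[1]])))
    bad <- tp$start < 1
    if (any(bad))
      out <- c(out, list(violation("START_LT_ONE", "error",
        "peptide coordinates are 1-based", loc[which(bad)[1]])))
    if (!is.na(seqlen)) {
      bad <- tp$end > seqlen
      if (any(bad))
        out <- c(out, list(violation("END_GT_SEQLEN", "error",
          sprintf("peptide END exceeds protein length %d", seqlen),
          loc[which(bad)[1]])))
    }
    bad <- !grepl("^[A-Z]$", tp$mod)
    if (any(bad))
      out <- c(out, list(violation("BAD_MODE", "error",
        "MOD must be a single letter A-Z", loc[which(bad)[1]])))
    bad <- tp$rep < 0
    if (any(bad))
      out <- c(out, list(violation("BAD_REPLICATE", "error",
        "REP must be non-negative", loc[which(bad)[1]])))
    bad <- tp$ptm_id < 0 | tp$ptm_id >= 10000
    if (any(bad))
      out <- c(out, list(violation("PTM_ID_RANGE", "error",
        "PTM_ID must lie in [0, 9999]", loc[which(bad)[1]])))
    bad <- is.na(tp$time_s) | tp$time_s < 0
    if (any(bad))
      out <- c(out, list(violation("BAD_TIME", "error",
        "TIME(SEC) must be non-negative or inf", loc[which(bad)[1]])))

    # base mode "A" must exist in any (peptide, rep, ptm, time) group that
    # has a higher mode letter
    key <- paste(tp$start, tp$end, tp$rep, tp$ptm_id, tp$time_s)
    for (k in unique(key[tp$mod != "A" & grepl("^[A-Z]$", tp$mod)])) {
      if (!any(tp$mod[key == k] == "A"))
        out <- c(out, list(violation("MODE_BASE_MISSING", "error",
          "group has modes beyond 'A' but no 'A' record",
          loc[which(key == k)[1]])))
    }
    dup <- duplicated(paste(key, tp$mod))
    if (any(dup))
      out <- c(out, list(violation("DUPLICATE_TIMEPOINT", "warning",
        "more than one record for the same (peptide, replicate, PTM, time, mode)",
        loc[which(dup)[1]])))

    for (i in seq_len(nrow(tp))) {
      env <- tp$envelope[[i]]
      if (is.null(env)) next
      if (length(env) < 1 || any(env < 0)) {
        out <- c(out, list(violation("ENVELOPE_VALUES", "error",
          "envelope must be a non-empty vector of non-negative intensities",
          loc[i])))
      } else if (abs(sum(env) - 1) > 5e-3) {
        out <- c(out, list(violation("ENVELOPE_SUM", "error",
          sprintf("envelope sums to %.4f, not 1", sum(env)), loc[i])))
      }
    }

    bad <- tp$uptake < -1
    if (any(bad))
      out <- c(out, list(violation("UPTAKE_SUSPECT", "warning",
        "uptake below -1 Da is unusual for measurement noise",
        loc[which(bad)[1]])))
  }

  ## --- PTM dictionary -----------------------------------------------------
  ptm <- dataset@ptms
  if (nrow(ptm)) {
    if (any(ptm$ptm_id == 0))
      out <- c(out, list(violation("PTM_ZERO_ENTRY", "error",
        "PTM_ID 0 is reserved for 'no PTM' and must not appear as an entry",
        "PTM[0]")))
    dup <- duplicated(ptm$ptm_id)
    if (any(dup))
      out <- c(out, list(violation("DUPLICATE_PTM_ID", "error",
        sprintf("PTM_ID %d defined more than once", ptm$ptm_id[which(dup)[1]]),
        sprintf("PTM[%d]", ptm$ptm_id[which(dup)[1]]))))
  }
  if (nrow(tp)) {
    ref <- unique(tp$ptm_id[tp$ptm_id != 0])
    missing <- setdiff(ref, ptm$ptm_id)
    for (id in missing)
      out <- c(out, list(violation("DANGLING_PTM_ID", "error",
        sprintf("PTM_ID %d referenced but not defined in the PTM section", id),
        sprintf("PTM[%d]", id))))
  }

  ## --- MATCH section ------------------------------------------------------
  mt <- dataset@matches
  if (nrow(mt)) {
    for (i in seq_len(nrow(mt)))
      out <- c(out, list(.checkMatchRow(dataset, mt[i, , drop = FALSE],
                                        sprintf("MATCH[%d]", i))))
  }

  bindViolations(do.call(bindViolations, out))
}

# Shared between validateDataset and linkMatch.
.checkMatchRow <- function(dataset, row, loc) {
  out <- list()
  tp <- dataset@timepoints
  hit <- match(row$tp_id, tp$index)
  if (is.na(hit)) {
    out <- c(out, list(violation("TP_ID_UNRESOLVED", "error",
      sprintf("MATCH TP_ID %d does not resolve to a timepoint INDEX",
              row$tp_id), loc)))
  } else {
    env <- tp$envelope[[hit]]
    groups <- row$mz[[1]]
    if (!is.null(env) && length(groups) > 0 && length(groups) != length(env))
      out <- c(out, list(violation("GROUP_COUNT_MISMATCH", "warning",
        sprintf("%d M/Z peak group(s) but the linked envelope has %d peak(s)",
                length(groups), length(env)), loc)))
  }
  if (row$conf < 0 || row$conf > 1)
    out <- c(out, list(violation("CONF_RANGE", "error",
      "CONF must lie in [0, 1]", loc)))
  if (row$rt_min < 0)
    out <- c(out, list(violation("RT_RANGE", "error",
      "RT(min) must be non-negative", loc)))
  if (row$charge < 1)
    out <- c(out, list(violation("CHARGE_RANGE", "error",
      "Z must be a positive integer", loc)))
  if (row$mono_mass <= 0)
    out <- c(out, list(violation("MONO_M_RANGE", "error",
      "MONO_M must be positive", loc)))
  for (g in row$mz[[1]]) {
    if (nrow(g) > 1 && any(diff(g[, "mz"]) <= 0)) {
      out <- c(out, list(violation("MZ_NOT_INCREASING", "warning",
        "m/z values within a peak group should strictly increase", loc)))
      break
    }
  }
  do.call(bindViolations, out)
}

#' Rewrite timepoint indices to a contiguous 0-based sequence
#'
#' After filtering or reordering timepoint records the INDEX column may have
#' gaps, which the format forbids. This rewrites indices to `0..n-1` in the
#' current row order and remaps every MATCH `tp_id` through the same old-to-new
#' mapping, so raw-evidence links stay attached to the records they annotated.
#' MATCH rows whose `tp_id` did not resolve before renumbering are left
#' untouched (and still reported by [validateDataset()]).
#'
#' @param dataset An [HXMSDataset-class].
#' @return The dataset with contiguous indices and remapped matches.
#' @export
renumberIndices <- function(dataset) {
  stopifnot(is(dataset, "HXMSDataset"))
  tp <- dataset@timepoints
  if (!nrow(tp)) return(dataset)
  old <- tp$index
  tp$index <- seq_len(nrow(tp)) - 1L
  mt <- dataset@matches
  if (nrow(mt)) {
    hit <- match(mt$tp_id, old)
    mt$tp_id[!is.na(hit)] <- tp$index[hit[!is.na(hit)]]
  }
  dataset@timepoints <- tp
  dataset@matches <- mt
  dataset
}
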