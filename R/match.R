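# The MATCH section's hierarchical M/Z field: commas separate envelope peak
# groups, semicolons separate uncentroided fine-structure points within a
# group, and a colon separates each m/z value from its intensity.

.formatIntensity <- function(x) {
  s <- sprintf("%.4f", x)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

#' Encode M/Z peak groups as the MATCH field text
#'
#' @param groups List of peak groups, one per envelope peak of the matched
#'   timepoint; each group a two-column matrix (`mz`, `intensity`) as built
#'   by [decodeMZ()]. m/z values are written at 4 decimals; intensities at 4
#'   decimals with trailing zeros trimmed.
#' @return A single string, e.g. `"523.9764:2.076; 523.9792:2698.8441"`.
#' @export
encodeMZ <- function(groups) {
  if (!is.list(groups) || length(groups) < 1)
    hxmsStop("FORMAT_ERROR", "M/Z needs at least one peak group")
  enc <- vapply(groups, function(g) {
    if (is.null(g) || nrow(g) < 1)
      hxmsStop("FORMAT_ERROR", "empty M/Z peak group")
    if (any(g[, "mz"] <= 0))
      hxmsStop("FORMAT_ERROR", "m/z values must be positive")
    paste(sprintf("%.4f", g[, "mz"]), .formatIntensity(g[, "intensity"]),
          sep = ":", collapse = "; ")
  }, character(1))
  paste(enc, collapse = ",")
}

#' Decode a MATCH M/Z field
#'
#' Inverse of [encodeMZ()]; whitespace around any delimiter is tolerated and
#' the order of groups and points is preserved exactly.
#'
#' @param text The M/Z field text.
#' @return List of peak groups (two-column `mz`/`intensity` matrices).
#' @section Errors: an empty field, a point without a colon, or a
#'   non-numeric m/z or intensity raise `FORMAT_ERROR` naming the offending
#'   token.
#' @export
decodeMZ <- function(text) {
  if (!isSingleString(text) || !nzchar(trimws(text)))
    hxmsStop("FORMAT_ERROR", "empty M/Z field")
  groups <- strsplit(text, ",", fixed = TRUE)[[1]]
  lapply(groups, function(g) {
    pts <- trimws(strsplit(g, ";", fixed = TRUE)[[1]])
    pts <- pts[nzchar(pts)]
    if (!length(pts))
      hxmsStop("FORMAT_ERROR", sprintf("empty M/Z peak group in '%s'", g))
    vals <- lapply(pts, function(p) {
      halves <- trimws(strsplit(p, ":", fixed = TRUE)[[1]])
      if (length(halves) != 2)
        hxmsStop("FORMAT_ERROR",
                 sprintf("M/Z point '%s' is not of the form mz:intensity", p))
      num <- suppressWarnings(as.numeric(halves))
      if (anyNA(num))
        hxmsStop("FORMAT_ERROR", sprintf("non-numeric M/Z point '%s'", p))
      num
    })
    mzGroup(vapply(vals, `[[`, numeric(1), 1),
            vapply(vals, `[[`, numeric(1), 2))
  })
}

#' Check one MATCH record against its dataset
#'
#' Verifies that the record's `tp_id` resolves to an existing timepoint
#' INDEX and, when the linked timepoint carries an ENVELOPE, that the number
#' of M/Z peak groups equals the number of envelope peaks. A count mismatch
#' is reported as a warning, not an error, because centroided-only exports
#' may legitimately store fewer groups.
#'
#' @param dataset An [HXMSDataset-class].
#' @param match Either a row number into `matchTable(dataset)` or a one-row
#'   data.frame in the MATCH table shape.
#' @return A consistency report in the [validateDataset()] violation shape;
#'   zero rows means the link is clean.
#' @export
linkMatch <- function(dataset, match) {
  stopifnot(is(dataset, "HXMSDataset"))
  if (is.numeric(match) && length(match) == 1) {
    loc <- sprintf("MATCH[%d]", as.integer(match))
    match <- dataset@matches[as.integer(match), , drop = FALSE]
  } else {
    loc <- sprintf("MATCH[tp_id=%d]", match$tp_id)
  }
  bindViolations(.checkMatchRow(dataset, match, loc))
}
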