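# Internal helpers shared across modules.

# Classed error so callers can condition on the failure category
# (hxms_format_error, hxms_schema_error, hxms_missing_zero, ...).
hxmsStop <- function(code, msg, line = NULL) {
  full <- if (is.null(line)) sprintf("%s: %s", code, msg)
          else sprintf("%s (line %d): %s", code, line, msg)
  stop(errorCondition(full, class = c(paste0("hxms_", tolower(code)), "hxms_error")))
}

# Left-justified space padding to a fixed field width; values wider than the
# field are kept whole rather than truncated.
padField <- function(x, width) sprintf("%-*s", width, as.character(x))

# Round to a fixed number of decimals via the decimal string, so the stored
# value is exactly what fixed-point serialization reproduces.
quantizeDecimal <- function(x, digits) {
  out <- x
  fin <- is.finite(x)
  out[fin] <- as.numeric(sprintf("%.*f", digits, x[fin]))
  out
}

# Plain decimal rendering for metadata values (no scientific notation).
formatMetaNumber <- function(x) format(x, trim = TRUE, scientific = FALSE, digits = 15)

isSingleString <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# One violation-report row; validateDataset and linkMatch both use this shape.
violation <- function(code, severity, message, locator) {
  data.frame(code = code, severity = severity, message = message,
             locator = locator, stringsAsFactors = FALSE)
}

emptyViolations <- function() {
  data.frame(code = character(0), severity = character(0),
             message = character(0), locator = character(0),
             stringsAsFactors = FALSE)
}

bindViolations <- function(...) {
  parts <- Filter(function(v) !is.null(v) && nrow(v) > 0, list(...))
  if (length(parts) == 0) return(emptyViolations())
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
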