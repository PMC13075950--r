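test_that("incubation times serialize in scientific notation with inf controls", {
  expect_identical(formatTime(0), "0.000000e+00")
  expect_identical(formatTime(60), "6.000000e+01")
  expect_identical(formatTime(Inf), "inf")
  expect_error(formatTime(-1), class = "hxms_format_error")

  expect_identical(parseTime("inf"), Inf)
  expect_identical(parseTime("0.000000e+00"), 0)
  expect_identical(parseTime("3.0e1"), 30)
  expect_identical(parseTime("45"), 45)   # plain decimals tolerated
  expect_error(parseTime("soon"), class = "hxms_format_error")
  expect_error(parseTime("-5"), class = "hxms_format_error")

  # parseTime inverts formatTime across magnitudes
  for (t in c(0, 1e-3, 30, 61.5, 3600, 86400, Inf))
    expect_identical(parseTime(formatTime(t)), t)
})

test_that("metadata lines parse titles and typed values", {
  ds <- readHXMS(exampleFileText())
  md <- experimentMetadata(ds)
  expect_identical(md@temperatureK, 293.15)
  expect_identical(md@pHRead, 6.0)
  expect_identical(md@d2oSaturation, 0.91)
  expect_identical(proteinSequence(ds), "GSHMKTVEVNGADASDDN")
  expect_identical(md@proteinName, "Human PFK-1")
  expect_identical(md@formatVersion, "v1.0")
})

test_that("the writer emits the documented layout", {
  ds <- tinyDataset()
  txt <- writeHXMS(ds)
  lines <- strsplit(txt, "\n")[[1]]
  tpLines <- grep("^TP ", lines, value = TRUE)
  expect_gt(length(tpLines), 0)

  # no-PTM records carry the zero-padded reserved ID
  expect_true(any(grepl(" 0000 ", tpLines)))
  # the TIME(SEC) field occupies exactly its 16 characters in every row
  timeField <- substr(tpLines, 55, 70)
  expect_true(all(nchar(timeField) == 16))
  expect_true(all(grepl("^(\\d\\.\\d{6}e[+-]\\d{2}|inf) *$", timeField)))
  # format version is appended automatically as a REMARK
  expect_true(any(grepl("^REMARK\tFORMAT_VERSION\tv1.0$", lines)))
  # deterministic: same dataset, same bytes
  expect_identical(txt, writeHXMS(ds))
})

test_that("3-decimal envelopes are written verbatim", {
  md <- exampleMetadata()
  tab <- data.frame(start = 1, end = 10, replicate = 0, mode = "A",
                    time_s = 0, uptake = 0,
                    envelope = "527;298;116;36;0;23;0",
                    stringsAsFactors = FALSE)
  ds <- parseCustomCSV(tab, md)
  txt <- writeHXMS(ds)
  expect_match(txt, "0.527,0.298,0.116,0.036,0.000,0.023,0.000", fixed = TRUE)
})

test_that("read(write(d)) is an exact identity for grid-quantized datasets", {
  res <- generateExperiment(testConfig(seed = 11))
  ds <- res$dataset
  txt <- writeHXMS(ds)
  ds2 <- readHXMS(txt)
  expect_equal(ds2, ds)
  expect_identical(writeHXMS(ds2), txt)
})

test_that("arbitrary-precision envelopes survive a round trip within 5e-4 per peak", {
  md <- exampleMetadata()
  set.seed(5)
  for (i in 1:20) {
    env <- normalizeEnvelope(runif(sample(3:9, 1)))
    tab <- data.frame(start = 1, end = 10, replicate = 0, mode = "A",
                      time_s = 0, uptake = 0,
                      envelope = paste(sprintf("%.10f", env), collapse = ";"),
                      stringsAsFactors = FALSE)
    ds2 <- readHXMS(writeHXMS(parseCustomCSV(tab, md)))
    expect_lt(max(abs(timepoints(ds2)$envelope[[1]] - env)), 5e-4)
  }
})

test_that("the reader accepts tab-separated rows and shuffled sections", {
  fixed <- writeHXMS(tinyDataset())
  ds <- readHXMS(fixed)
  tabbed <- readHXMS(exampleFileText())   # fully tab-separated
  expect_identical(timepoints(tabbed)$start[1], 1L)
  expect_identical(timepoints(tabbed)$envelope[[1]],
                   c(0.527, 0.298, 0.116, 0.036, 0.000, 0.023, 0.000))

  # PTM and TP sections swapped, metadata interleaved: still parses
  lines <- strsplit(fixed, "\n")[[1]]
  shuffled <- c(grep("^PTM", lines, value = TRUE),
                grep("^METADATA|^REMARK", lines, value = TRUE),
                grep("^TP", lines, value = TRUE))
  ds3 <- readHXMS(paste(shuffled, collapse = "\n"))
  expect_equal(timepoints(ds3), timepoints(ds))
  expect_equal(ptmTable(ds3), ptmTable(ds))
})

test_that("malformed input raises FORMAT_ERROR; unknown tags only warn", {
  expect_error(readHXMS(""), class = "hxms_format_error")
  expect_error(readHXMS("\n\n"), class = "hxms_format_error")

  dup <- paste("METADATA\tPROTEIN_SEQUENCE\tAAA",
               "METADATA\tPROTEIN_SEQUENCE\tBBB", sep = "\n")
  expect_error(readHXMS(dup), class = "hxms_format_error")

  bad <- paste("METADATA\tPROTEIN_SEQUENCE\tAAA",
               "TP\t0\tA\tone\t10\t0\t0000\t0.0\t0.00", sep = "\n")
  expect_error(readHXMS(bad), "line 2", class = "hxms_format_error")

  odd <- paste("METADATA\tPROTEIN_SEQUENCE\tAAA",
               "FROBNICATE\t1\t2", sep = "\n")
  expect_warning(ds <- readHXMS(odd), "unknown row tag")
  expect_identical(nrow(timepoints(ds)), 0L)
})

test_that("writing an invalid dataset is refused", {
  ds <- tinyDataset()
  ds@timepoints$start[1] <- 10L
  ds@timepoints$end[1] <- 2L
  expect_error(writeHXMS(ds), "START_GT_END", class = "hxms_invalid_dataset")
})
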