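test_that("a well-formed converter-built dataset validates cleanly", {
  ds <- tinyDataset()
  expect_s4_class(ds, "HXMSDataset")
  v <- validateDataset(ds)
  expect_identical(nrow(v), 0L)
})

test_that("missing required metadata entries are reported, not thrown", {
  ds <- HXMSDataset(hxmsMetadata())   # nothing filled in
  v <- validateDataset(ds)
  expect_setequal(v$code, "MISSING_METADATA")
  expect_identical(nrow(v), 4L)       # one per required entry
  expect_true(all(v$severity == "error"))

  # only the sequence missing
  md <- hxmsMetadata(temperatureK = 293.15, pHRead = 6, d2oSaturation = 0.91)
  v <- validateDataset(HXMSDataset(md))
  expect_identical(nrow(v), 1L)
  expect_match(v$message, "PROTEIN_SEQUENCE")
})

test_that("coordinate, mode and envelope rules produce their stable codes", {
  ds <- tinyDataset()
  tp <- timepoints(ds)

  bad <- ds
  bad@timepoints$start[1] <- 10L
  bad@timepoints$end[1] <- 5L
  expect_true("START_GT_END" %in% validateDataset(bad)$code)

  bad <- ds
  bad@timepoints$end[1] <- 999L
  expect_true("END_GT_SEQLEN" %in% validateDataset(bad)$code)

  # a mode "B" record with no "A" sibling in its group
  bad <- ds
  bad@timepoints$mod[2] <- "B"
  expect_true("MODE_BASE_MISSING" %in% validateDataset(bad)$code)

  bad <- ds
  bad@timepoints$envelope[[1]] <- c(0.9, 0.2)   # sums to 1.1
  expect_true("ENVELOPE_SUM" %in% validateDataset(bad)$code)

  bad <- ds
  bad@timepoints$uptake[2] <- -2.5
  v <- validateDataset(bad)
  expect_identical(v$severity[v$code == "UPTAKE_SUSPECT"], "warning")
})

test_that("PTM dictionary rules: reserved zero, dangling and duplicate IDs", {
  ds <- tinyDataset()

  bad <- ds
  bad@timepoints$ptm_id[1] <- 77L
  expect_true("DANGLING_PTM_ID" %in% validateDataset(bad)$code)

  bad <- ds
  bad@ptms <- rbind(bad@ptms,
                    data.frame(ptm_id = 0L, content = "Acetyl (1)"))
  expect_true("PTM_ZERO_ENTRY" %in% validateDataset(bad)$code)

  bad <- ds
  bad@ptms <- rbind(bad@ptms, bad@ptms)
  expect_true("DUPLICATE_PTM_ID" %in% validateDataset(bad)$code)
})

test_that("renumberIndices repairs gaps and remaps MATCH tp_ids", {
  ds <- tinyDataset()
  n <- nrow(timepoints(ds))
  ds@timepoints$index <- c(0L, 2L, 5L, seq(6L, length.out = n - 3L))
  ds@matches <- ds@matches[0, ]
  ds@matches <- rbind(ds@matches, data.frame(
    tp_id = 5L, conf = 1, rt_min = 8.68, charge = 4L,
    mono_mass = 2091.977598, mz = I(list(list(mzGroup_(523.9764, 2.076))))))
  expect_true("INDEX_GAP" %in% validateDataset(ds)$code)

  fixed <- renumberIndices(ds)
  expect_identical(timepoints(fixed)$index, seq_len(n) - 1L)
  expect_identical(matchTable(fixed)$tp_id, 2L)
  expect_false("INDEX_GAP" %in% validateDataset(fixed)$code)

  # already-contiguous datasets pass through unchanged
  ds0 <- tinyDataset()
  expect_equal(renumberIndices(ds0), ds0)
})

test_that("renumbering any index permutation leaves no INDEX_GAP and the validator is pure", {
  ds <- tinyDataset()
  n <- nrow(timepoints(ds))
  set.seed(42)
  for (i in 1:5) {
    shuffled <- ds
    shuffled@timepoints$index <- sort(sample.int(3L * n, n)) - 1L
    v <- validateDataset(renumberIndices(shuffled))
    expect_false("INDEX_GAP" %in% v$code)
  }
  expect_identical(validateDataset(ds), validateDataset(ds))
})
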