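test_that("the custom CSV maps rows to records and harvests PTMs", {
  ds <- tinyDataset()
  tp <- timepoints(ds)
  expect_identical(nrow(tp), 24L)   # 3 peptides x 4 times x 2 replicates
  expect_identical(tp$index, 0:23)
  expect_identical(nrow(validateDataset(ds)), 0L)

  # empty PTM cells -> reserved ID 0; identical texts share one entry
  expect_true(all(tp$ptm_id[tp$start != 5] == 0L))
  expect_true(all(tp$ptm_id[tp$start == 5] == 1L))
  expect_identical(ptmTable(ds),
                   data.frame(ptm_id = 1L, content = "Phosphoryl STY (7)"))

  noCol <- tinyCustomTable()[, -1]
  expect_error(parseCustomCSV(noCol, exampleMetadata()), "start",
               class = "hxms_schema_error")
  noVal <- tinyCustomTable()[, setdiff(names(tinyCustomTable()), "uptake")]
  expect_error(parseCustomCSV(noVal, exampleMetadata()),
               class = "hxms_schema_error")
})

test_that("DynamX uptake is taken as-is and round-trips losslessly", {
  md <- exampleMetadata()
  tab <- data.frame(
    Start = c(1, 1, 1, 5), End = c(10, 10, 10, 14),
    Modification = c("", "", "", "Oxidation M (6)"),
    State = "APO", Exposure = c("0", "60", "FD", "0"),
    Uptake = c("0.00", "1.23", "4.56", "0.00"),
    Replicate = 0, stringsAsFactors = FALSE)
  ds <- parseDynamX(tab, md)
  tp <- timepoints(ds)
  expect_identical(tp$uptake, c(0, 1.23, 4.56, 0))
  expect_identical(tp$time_s, c(0, 60, Inf, 0))
  expect_identical(tp$ptm_id, c(0L, 0L, 0L, 1L))
  expect_identical(ptmTable(ds)$content, "Oxidation M (6)")
  expect_identical(nrow(validateDataset(ds)), 0L)

  ds2 <- readHXMS(writeHXMS(ds))
  expect_equal(ds2, ds)
})

test_that("HDX Workbench uptake is recomputed by zero-timepoint referencing", {
  md <- exampleMetadata()
  tab <- data.frame(
    Start = 1, End = 10, Replicate = c(0, 0, 2, 2, 1),
    Exposure = c("0", "60", "0", "60", "60"),
    Centroid = c("800.00", "802.50", "801.00", "803.00", "802.60"),
    stringsAsFactors = FALSE)
  ds <- parseHDXWorkbench(tab, md)
  tp <- timepoints(ds)
  expect_equal(tp$uptake[tp$rep == 0], c(0, 2.5))
  # replicate 1 has no 0 s point: referenced against (800 + 801)/2
  expect_equal(tp$uptake[tp$rep == 1 & tp$time_s == 60], 802.60 - 800.5)

  noZero <- tab[tab$Exposure != "0", ]
  expect_error(parseHDXWorkbench(noZero, md), "1-10",
               class = "hxms_missing_zero")
})

test_that("Workbench charge states merge by intensity-weighted envelopes", {
  md <- exampleMetadata()
  # charge 2 carries twice the signal of charge 3 at t=60
  tab <- data.frame(
    Start = 1, End = 10, Charge = c(2, 2, 3),
    Replicate = 0, Exposure = c("0", "60", "60"),
    Centroid = c("0.0", "1.0", "1.0"),
    Spectrum = c("400.0000:1000", "400.0000:800,400.5000:1200",
                 "267.0000:600,267.3300:400"),
    stringsAsFactors = FALSE)
  ds <- parseHDXWorkbench(tab, md)
  tp <- timepoints(ds)
  expect_identical(nrow(tp), 2L)            # charge rows merged
  merged <- tp$envelope[[which(tp$time_s == 60)]]
  w2 <- c(0.4, 0.6) * 2000 / 3000
  w3 <- c(0.6, 0.4) * 1000 / 3000
  expect_equal(merged, w2 + w3, tolerance = 1e-12)
  # each charge row still contributes its own MATCH evidence
  expect_identical(nrow(matchTable(ds)), 3L)
  expect_identical(sort(matchTable(ds)$charge), c(2L, 2L, 3L))

  # alternative policy: keep only the strongest charge state
  ds2 <- parseHDXWorkbench(tab, md, mergeCharges = FALSE)
  kept <- timepoints(ds2)$envelope[[which(timepoints(ds2)$time_s == 60)]]
  expect_equal(kept, c(0.4, 0.6), tolerance = 1e-12)
})

test_that("HDExaminer maps populations to MOD letters and gates MATCH on fineMatch", {
  md <- exampleMetadata()
  results <- data.frame(
    Start = 1, End = 10, Exposure = c("0", "60", "60"), Replicate = 0,
    Population = c("1", "1", "2"),
    Centroid = c("0.00", "1.20", "3.40"), stringsAsFactors = FALSE)
  spectra <- data.frame(
    Start = 1, End = 10, Exposure = "60", Replicate = 0, Population = "2",
    Charge = 2, RT = "8.680", Conf = "0.95", MonoMass = "1000.000000",
    Spectrum = "501.0000:100,501.5000:300", stringsAsFactors = FALSE)

  ds <- parseHDExaminer(results, md, spectra = spectra, fineMatch = TRUE)
  tp <- timepoints(ds)
  expect_identical(tp$mod, c("A", "A", "B"))
  # mode B is referenced against the mode-A zero centroid
  expect_equal(tp$uptake, c(0, 1.2, 3.4))
  expect_equal(tp$envelope[[3]], c(0.25, 0.75))
  expect_identical(matchTable(ds)$tp_id, 2L)
  expect_identical(matchTable(ds)$charge, 2L)
  # PTMs are never harvested for this dialect
  expect_identical(nrow(ptmTable(ds)), 0L)

  # without fineMatch the spectra only populate envelopes
  ds2 <- parseHDExaminer(results, md, spectra = spectra)
  expect_identical(nrow(matchTable(ds2)), 0L)
  expect_equal(timepoints(ds2)$envelope[[3]], c(0.25, 0.75))

  # without spectra: mean-deuteration dataset, validates cleanly
  ds3 <- parseHDExaminer(results, md)
  expect_identical(nrow(matchTable(ds3)), 0L)
  expect_identical(nrow(validateDataset(ds3)), 0L)
})

test_that("BioPharma Finder copies uptake verbatim with the MAX sentinel", {
  md <- exampleMetadata()
  tab <- data.frame(Start = 1, End = 10, Exposure = c("0", "300", "MAX"),
                    Uptake = c("0.0000", "2.7183", "5.1200"),
                    stringsAsFactors = FALSE)
  ds <- parseBioPharma(tab, md)
  tp <- timepoints(ds)
  expect_identical(tp$uptake, c(0, 2.7183, 5.12))
  expect_identical(tp$time_s[3], Inf)
  expect_identical(nrow(ptmTable(ds)), 0L)

  expect_error(parseBioPharma(tab[0, ], md), "empty export",
               class = "hxms_schema_error")
})

test_that("conversion is order-stable: same input bytes, same HXMS bytes", {
  res <- generateExperiment(testConfig(seed = 4))
  md <- res$metadata
  csv <- tempfile(fileext = ".csv")
  write.csv(res$exports$custom, csv, row.names = FALSE)
  t1 <- writeHXMS(parseCustomCSV(csv, md))
  t2 <- writeHXMS(parseCustomCSV(csv, md))
  expect_identical(t1, t2)
  unlink(csv)
})

test_that("the dialect dispatcher routes names and rejects unknowns", {
  md <- exampleMetadata()
  ds <- parseVendorExport(tinyCustomTable(), "custom", md)
  expect_equal(ds, tinyDataset())
  expect_error(parseVendorExport(tinyCustomTable(), "maxent", md),
               class = "hxms_schema_error")
})
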