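test_that("first-order exchange kinetics hit their closed-form anchors", {
  k <- c(1e-3, 0.1, 2)
  expect_identical(simulateResidueDeuteration(k, 0, 0.91), c(0, 0, 0))
  expect_identical(simulateResidueDeuteration(k, Inf, 0.91), rep(0.91, 3))
  expect_equal(simulateResidueDeuteration(log(2), 1, 1), 0.5,
               tolerance = 1e-12)
  expect_error(simulateResidueDeuteration(k, -1))
})

test_that("convolved envelopes match 2^n enumeration and the mean identity", {
  set.seed(13)
  for (n in 1:10) {
    f <- runif(n)
    env <- envelopeFromFractions(f)
    expect_lt(max(abs(env - bruteForceEnvelope(f))), 1e-12)
    expect_equal(sum(env), 1, tolerance = 1e-12)
    expect_equal(envelopeCentroid(env), sum(f), tolerance = 1e-12)
  }
  expect_identical(envelopeFromFractions(c(0, 0, 0)), c(1, 0, 0, 0))
  expect_identical(envelopeFromFractions(c(1, 1)), c(0, 0, 1))
})

test_that("a fixed seed reproduces the experiment byte for byte", {
  t1 <- writeHXMS(generateExperiment(testConfig(seed = 21))$dataset)
  t2 <- writeHXMS(generateExperiment(testConfig(seed = 21))$dataset)
  expect_identical(t1, t2)
  t3 <- writeHXMS(generateExperiment(testConfig(seed = 22))$dataset)
  expect_false(identical(t1, t3))
})

test_that("generated datasets validate cleanly and honour config switches", {
  res <- generateExperiment(testConfig(seed = 5))
  expect_identical(nrow(validateDataset(res$dataset)), 0L)
  tp <- timepoints(res$dataset)
  expect_true(any(tp$mod == "B"))            # bimodal_fraction 0.5, seeded
  expect_true(any(is.infinite(tp$time_s)))   # FD controls present
  expect_true(all(tp$uptake[tp$time_s == 0] == 0))

  mono <- generateExperiment(testConfig(seed = 5, bimodal_fraction = 0))
  expect_true(all(timepoints(mono$dataset)$mod == "A"))

  fine <- generateExperiment(testConfig(seed = 5, natural_isotopes = TRUE))
  expect_true(all(vapply(matchTable(fine$dataset)$mz[[1]], nrow,
                         integer(1)) > 1))
  expect_identical(nrow(validateDataset(fine$dataset)), 0L)
})

test_that("noise-free fixtures recover the Poisson-binomial mean uptake", {
  res <- generateExperiment(testConfig(seed = 6, noise_sd = 0))
  ds <- parseCustomCSV(res$exports$custom, res$metadata)
  tp <- timepoints(ds)
  truth <- res$truth
  key <- function(s, e, r, m, t) paste(s, e, r, m, t)
  hit <- match(key(tp$start, tp$end, tp$rep, tp$mod, tp$time_s),
               key(truth$start, truth$end, truth$replicate, truth$mode,
                   truth$time_s))
  expect_false(anyNA(hit))
  # the export prints uptake at 4 decimals: recovery to serialization precision
  expect_lt(max(abs(tp$uptake - truth$uptake_true[hit])), 5.01e-5)
})

test_that("generateExperiment writes its fixture files when asked", {
  dir <- tempfile("synthfix")
  res <- generateExperiment(testConfig(seed = 8), dir = dir)
  expect_true(all(file.exists(unlist(res$files))))
  back <- readHXMS(res$files[["reference"]])
  expect_equal(back, res$dataset)
  truthBack <- read.delim(res$files[["truth"]])
  expect_identical(nrow(truthBack), nrow(res$truth))
  unlink(dir, recursive = TRUE)
})
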