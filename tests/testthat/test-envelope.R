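test_that("normalization divides by the total and rejects degenerate input", {
  expect_equal(normalizeEnvelope(c(527, 298, 116, 36, 0, 23, 0)),
               c(0.527, 0.298, 0.116, 0.036, 0, 0.023, 0))
  expect_identical(normalizeEnvelope(5), 1)
  expect_equal(normalizeEnvelope(c(1, 1, 1, 1)), rep(0.25, 4))
  expect_error(normalizeEnvelope(c(0, 0)), class = "hxms_envelope_values")
  expect_error(normalizeEnvelope(c(1, -1)), class = "hxms_envelope_values")
  expect_error(normalizeEnvelope(numeric(0)), class = "hxms_envelope_values")
})

test_that("normalization is idempotent and scale-invariant", {
  set.seed(7)
  for (i in 1:25) {
    x <- runif(sample(1:12, 1))
    if (sum(x) == 0) x[1] <- 1
    n1 <- normalizeEnvelope(x)
    expect_equal(sum(n1), 1, tolerance = 1e-12)
    expect_equal(normalizeEnvelope(n1), n1, tolerance = 1e-12)
    k <- runif(1, 0.01, 100)
    expect_equal(normalizeEnvelope(k * x), n1, tolerance = 1e-12)
    expect_equal(envelopeCentroid(normalizeEnvelope(x)), envelopeCentroid(x),
                 tolerance = 1e-12)
  }
})

test_that("the centroid is the intensity-weighted mean peak index", {
  expect_identical(envelopeCentroid(1), 0)
  expect_identical(envelopeCentroid(c(1, 0, 0, 0)), 0)
  expect_identical(envelopeCentroid(c(0.5, 0.5)), 0.5)
  # frozen weighted-sum oracle over the 7-peak documented example:
  # 1*0.298 + 2*0.116 + 3*0.036 + 5*0.023 = 0.753 (peak sum is 1.000)
  expect_equal(envelopeCentroid(c(0.527, 0.298, 0.116, 0.036, 0, 0.023, 0)),
               0.753, tolerance = 1e-12)
  # peak spacing override scales the result
  expect_equal(envelopeCentroid(c(0.5, 0.5), peakSpacingDa = 1.00628),
               0.50314, tolerance = 1e-12)
})

test_that("uptake is the centroid difference from the 0 s point", {
  s <- data.frame(time_s = c(0, 60))
  s$envelope <- list(c(1, 0), c(0, 1))
  expect_equal(computeUptake(s), c(0, 1))

  # constant signal: all uptakes zero
  s <- data.frame(time_s = c(0, 30, 300))
  s$envelope <- list(c(0.2, 0.5, 0.3), c(0.2, 0.5, 0.3), c(0.2, 0.5, 0.3))
  expect_equal(computeUptake(s), c(0, 0, 0))

  # works from a centroid column and an explicit reference
  s <- data.frame(time_s = c(0, 60), centroid = c(800.00, 802.50))
  expect_equal(computeUptake(s), c(0, 2.5))
  expect_equal(computeUptake(s, zeroReference = 799.5), c(0.5, 3.0))

  noZero <- data.frame(time_s = c(30, 60), centroid = c(1, 2))
  expect_error(computeUptake(noZero), class = "hxms_missing_zero")

  # scaling every envelope uniformly leaves uptake unchanged
  s <- data.frame(time_s = c(0, 30, 300))
  s$envelope <- list(c(5, 1, 0), c(2, 4, 1), c(1, 4, 4))
  u <- computeUptake(s)
  s2 <- s
  s2$envelope <- lapply(s$envelope, function(e) 17.3 * e)
  expect_equal(computeUptake(s2), u, tolerance = 1e-12)
})

test_that("the zero reference falls back to the replicate average", {
  pep <- data.frame(replicate = c(0, 0, 2, 2, 1),
                    time_s = c(0, 60, 0, 60, 60),
                    centroid = c(800.0, 802.0, 801.0, 803.0, 802.6))
  expect_equal(zeroReferenceForReplicate(pep, 0), 800.0)   # its own
  expect_equal(zeroReferenceForReplicate(pep, 2), 801.0)
  expect_equal(zeroReferenceForReplicate(pep, 1), 800.5)   # (800+801)/2

  none <- data.frame(replicate = 0:2, time_s = c(30, 60, 60),
                     centroid = c(1, 2, 3))
  expect_error(zeroReferenceForReplicate(none, 0), class = "hxms_missing_zero")
})

test_that("recomputeUptake references every mode against the mode-A zero", {
  md <- exampleMetadata()
  tab <- data.frame(
    start = 1, end = 10, replicate = 0,
    mode = c("A", "A", "B"), time_s = c(0, 60, 60),
    envelope = c("1;0;0", "0;1;0", "0;0;1"),
    uptake = 0, stringsAsFactors = FALSE)
  ds <- recomputeUptake(parseCustomCSV(tab, md))
  expect_equal(timepoints(ds)$uptake, c(0, 1, 2))
})
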