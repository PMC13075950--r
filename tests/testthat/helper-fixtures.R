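# Fixtures built in code; nothing is read from disk except what a test
# writes itself.

# Metadata assembled from the format's documented example values.
exampleMetadata <- function() {
  hxmsMetadata(proteinSequence = "GSHMKTVEVNGADASDDN",
               temperatureK = 293.15, pHRead = 6.0, d2oSaturation = 0.91,
               proteinName = "Human PFK-1", proteinState = "APO")
}

# The documented example TP row (peptide 1-10, 0 s, 7-peak envelope) plus a
# second timepoint and the documented example MATCH row bound to it.
exampleFileText <- function() {
  paste(
    "METADATA\tPROTEIN_SEQUENCE\tGSHMKTVEVNGADASDDN",
    "METADATA\tPROTEIN_NAME\tHuman PFK-1",
    "METADATA\tPROTEIN_STATE\tAPO",
    "METADATA\tTEMPERATURE (K)\t293.15",
    "METADATA\tpH(READ)\t6.0",
    "METADATA\tD_2_O_SATURATION\t0.91",
    "REMARK\tFORMAT_VERSION\tv1.0",
    "TP\t0\tA\t1\t10\t0\t0000\t0.000000e+00\t0.00\t0.527,0.298,0.116,0.036,0.000,0.023,0.000",
    "TP\t1\tA\t1\t10\t0\t0000\t6.000000e+01\t1.25\t0.100,0.200,0.400,0.200,0.100,0.000,0.000",
    paste0("MATCH\t1\t1.00\t8.680\t4\t2091.977598\t",
           exampleMZText()),
    sep = "\n")
}

# The documented example M/Z field: two envelope peak groups with 3 and 7
# fine-structure points.
exampleMZText <- function() {
  paste0("523.9764:2.076; 523.9792:2698.8441; 523.982:1595.0798,",
         "524.319:7.059; 524.3218:3170.0975; 524.3246:8130.5251; ",
         "524.3273:9330.6525; 524.3301:7816.5479; 524.3329:3718.9259; ",
         "524.3357:1818.192")
}

# A small converter-built dataset: 3 peptides x 4 times x 2 replicates.
tinyCustomTable <- function() {
  peps <- data.frame(start = c(1, 5, 9), end = c(8, 14, 18))
  grid <- expand.grid(p = 1:3, rep = 0:1, t = c(0, 30, 300, 3600))
  grid <- grid[order(grid$p, grid$rep, grid$t), ]
  data.frame(
    start = peps$start[grid$p], end = peps$end[grid$p],
    replicate = grid$rep, mode = "A", time_s = grid$t,
    uptake = round(grid$t / (grid$t + 100) * grid$p, 2),
    ptm = ifelse(grid$p == 2, "Phosphoryl STY (7)", ""),
    stringsAsFactors = FALSE)
}

tinyDataset <- function() parseCustomCSV(tinyCustomTable(), exampleMetadata())

# Independent oracle: Poisson-binomial probabilities by explicit enumeration
# over all 2^n deuteration outcomes (n <= 10 or so).
bruteForceEnvelope <- function(fractions) {
  n <- length(fractions)
  p <- numeric(n + 1)
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    prob <- prod(ifelse(bits == 1, fractions, 1 - fractions))
    p[sum(bits) + 1] <- p[sum(bits) + 1] + prob
  }
  p
}

# Peak-group matrices shaped exactly as decodeMZ builds them.
mzGroup_ <- function(mz, intensity) {
  m <- cbind(mz = as.numeric(mz), intensity = as.numeric(intensity))
  rownames(m) <- NULL
  m
}

# Fast synthetic config for tests: small but exercising every feature.
testConfig <- function(seed = 1L, bimodal_fraction = 0.5,
                       ptm_probability = 0.5, ...) {
  synthConfig(seed = seed, sequence_length = 40L, n_peptides = 3L,
              times_s = c(0, 30, 3600, Inf), n_replicates = 2L,
              bimodal_fraction = bimodal_fraction,
              ptm_probability = ptm_probability, ...)
}
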