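# Seeded synthetic HX-MS experiments with known ground truth, plus the
# vendor-dialect export tables that the converters read. Everything is
# deterministic for a fixed config, so fixtures are generated at test time
# instead of being shipped.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Proton and 13C-12C mass differences used when laying out m/z grids.
.PROTON_DA <- 1.007276
.C13_SPACING_DA <- 1.003355

#' Configuration of a synthetic HX-MS experiment
#'
#' Defaults describe a small but complete experiment: a 60-residue protein,
#' 8 peptides, a five-point time course with a 0 s point and a fully
#' deuterated control, duplicate measurements, D2O saturation 0.91 at
#' 293.15 K and pH(read) 6.0, per-residue exchange rates log-uniform over
#' 1e-4..1 s^-1 (spanning the seconds-to-hours window the time course
#' samples), a quarter of peptides bimodal, 2% lognormal intensity noise,
#' and one peptide in five carrying a PTM.
#'
#' @param seed Integer RNG seed; a fixed seed makes every output
#'   byte-identical.
#' @param sequence_length Protein length, residues.
#' @param n_peptides Number of peptides tiled onto the sequence.
#' @param times_s Incubation times in seconds; must include 0 and may
#'   include `Inf` (fully deuterated control).
#' @param n_replicates Experimental replicates (REP 0..n-1).
#' @param d2o_saturation Labeling-buffer D2O fraction in (0, 1].
#' @param rate_log10_range Bounds of log10 per-residue exchange rate, s^-1.
#' @param bimodal_fraction Fraction of peptides given a second (mode "B")
#'   envelope population.
#' @param noise_sd SD of the lognormal multiplicative noise applied to each
#'   envelope intensity (0 = noise-free).
#' @param ptm_probability Probability a peptide carries a PTM annotation.
#' @param natural_isotopes Convolve envelopes with a natural carbon-isotope
#'   distribution and emit multi-point fine structure in MATCH groups.
#' @param temperature_K,pH_read,protein_name,protein_state Metadata values
#'   for the generated experiment.
#' @return A validated config list for [generateExperiment()].
#' @export
synthConfig <- function(seed = 1L, sequence_length = 60L, n_peptides = 8L,
                        times_s = c(0, 30, 300, 3600, Inf),
                        n_replicates = 2L, d2o_saturation = 0.91,
                        rate_log10_range = c(-4, 0),
                        bimodal_fraction = 0.25, noise_sd = 0.02,
                        ptm_probability = 0.2, natural_isotopes = FALSE,
                        temperature_K = 293.15, pH_read = 6.0,
                        protein_name = "SYNTH-PROTEIN",
                        protein_state = "SIMULATED") {
  stopifnot(length(seed) == 1, is.finite(seed),
            sequence_length >= 20, n_peptides >= 1,
            0 %in% times_s, all(times_s >= 0),
            n_replicates >= 1,
            d2o_saturation > 0, d2o_saturation <= 1,
            length(rate_log10_range) == 2,
            rate_log10_range[1] <= rate_log10_range[2],
            bimodal_fraction >= 0, bimodal_fraction <= 1,
            noise_sd >= 0, ptm_probability >= 0, ptm_probability <= 1)
  as.list(environment())
}

#' Per-residue deuteration fractions under first-order exchange
#'
#' Each residue exchanges independently with first-order kinetics toward the
#' buffer's deuterium fraction: `d_j(t) = saturation * (1 - exp(-k_j t))`.
#' The fully deuterated control (`time_s = Inf`) reaches `saturation` at
#' every residue.
#'
#' @param rates Per-residue exchange rate constants, s^-1 (positive).
#' @param time_s Incubation time, seconds (non-negative or `Inf`).
#' @param saturation D2O saturation in (0, 1].
#' @return Deuteration probability per residue, in \[0, saturation\].
#' @export
simulateResidueDeuteration <- function(rates, time_s, saturation = 1) {
  stopifnot(is.numeric(rates), all(rates > 0),
            length(time_s) == 1, !is.na(time_s))
  if (time_s < 0) hxmsStop("SCHEMA_ERROR", "negative incubation time")
  if (is.infinite(time_s)) return(rep(saturation, length(rates)))
  saturation * (1 - exp(-rates * time_s))
}

#' Poisson-binomial isotopic envelope from residue deuteration fractions
#'
#' The number of deuterons on a peptide whose exchangeable residues carry
#' independent deuteration probabilities `d_1..d_n` follows a
#' Poisson-binomial distribution; peak `i` of the envelope is the
#' probability that exactly `i` residues are deuterated. Computed by
#' iterative convolution, one residue at a time, in O(n^2).
#'
#' @param fractions Per-residue deuteration probabilities in \[0, 1\].
#' @return An envelope of length `length(fractions) + 1` summing to 1; its
#'   centroid equals `sum(fractions)` (the Poisson-binomial mean).
#' @export
envelopeFromFractions <- function(fractions) {
  stopifnot(is.numeric(fractions), all(fractions >= 0), all(fractions <= 1))
  p <- 1
  for (f in fractions)
    p <- c(p * (1 - f), 0) + c(0, p * f)
  p
}

# Natural carbon-isotope distribution for a peptide of the given residue
# count: binomial over ~4.9 carbons per residue at 1.07% 13C, truncated.
.naturalIsotopes <- function(n_residues) {
  nC <- max(1L, round(4.9 * n_residues))
  d <- stats::dbinom(0:3, size = nC, prob = 0.0107)
  d / sum(d)
}

.convolve <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(b))
    out[i:(i + length(a) - 1L)] <- out[i:(i + length(a) - 1L)] + a * b[i]
  out
}

# Quantize an envelope to the 3-decimal serialization grid and absorb the
# rounding residue into the largest peak so the sum stays within 5e-4 of 1.
.quantizeEnvelope <- function(env) {
  q <- quantizeDecimal(env, 3L)
  i <- which.max(q)
  q[i] <- quantizeDecimal(q[i] + (1 - sum(q)), 3L)
  q
}

#' Generate a ground-truthed synthetic HX-MS experiment
#'
#' Builds one protein state end to end: a random sequence with per-residue
#' exchange rates, a random peptide tiling, per-replicate envelopes from
#' first-order kinetics through Poisson-binomial convolution (with optional
#' lognormal intensity noise), bimodal peptides as paired MOD "A"/"B"
#' records, PTM annotations, fully deuterated controls at TIME `"inf"`, and
#' a MATCH record with an m/z-intensity group per envelope peak for every
#' timepoint. The returned dataset is quantized to the format's
#' serialization grid, so writing and re-reading it is an exact round trip.
#' Alongside the dataset it produces the five vendor-dialect export tables
#' for the same measurements and a truth table of noise-free uptake values.
#'
#' @param config A [synthConfig()].
#' @param dir Optional directory: when given, writes `reference.hxms`, the
#'   dialect CSVs, and `truth.tsv` there and records the paths.
#' @return A list with elements `dataset` ([HXMSDataset-class]), `truth`
#'   (data.frame: `start`, `end`, `replicate`, `mode`, `ptm`, `time_s`,
#'   `uptake_true` — the exact Poisson-binomial mean uptake), `exports`
#'   (named list of data.frames: `custom`, `dynamx`, `hdx_workbench`,
#'   `hdexaminer`, `hdexaminer_spectra`, `biopharma_finder`), `metadata`,
#'   and `files` (paths, when `dir` was given).
#' @export
generateExperiment <- function(config = synthConfig(), dir = NULL) {
  set.seed(config$seed)
  L <- config$sequence_length
  sequence <- paste(sample(.AA20, L, replace = TRUE), collapse = "")
  ratesA <- 10^stats::runif(L, config$rate_log10_range[1],
                            config$rate_log10_range[2])
  ratesB <- 10^stats::runif(L, config$rate_log10_range[1],
                            config$rate_log10_range[2])

  # peptide tiling: unique (start, end) windows of 8-15 residues
  peps <- list()
  seen <- character(0)
  tries <- 0
  while (length(peps) < config$n_peptides && tries < 1000) {
    tries <- tries + 1
    len <- sample(8:15, 1)
    if (len > L) next
    start <- sample.int(L - len + 1L, 1)
    key <- paste(start, start + len - 1L)
    if (key %in% seen) next
    seen <- c(seen, key)
    peps[[length(peps) + 1L]] <- list(start = start, end = start + len - 1L)
  }
  for (i in seq_along(peps)) {
    peps[[i]]$bimodal <- stats::runif(1) < config$bimodal_fraction
    hasPTM <- stats::runif(1) < config$ptm_probability
    peps[[i]]$ptm <- if (hasPTM)
      sprintf("Phosphoryl STY (%d)",
              sample(seq(peps[[i]]$start, peps[[i]]$end), 1)) else ""
  }

  sat <- config$d2o_saturation
  rows <- list()
  for (p in peps) {
    # first two residues of the peptide exchange back too fast to retain
    # label; only start+2 .. end count as exchangeable amides
    exch <- seq(p$start + 2L, p$end)
    nat <- if (config$natural_isotopes) .naturalIsotopes(p$end - p$start + 1L)
           else NULL
    for (r in seq_len(config$n_replicates) - 1L) {
      for (t in config$times_s) {
        modes <- if (p$bimodal && t > 0) c("A", "B") else "A"
        for (m in modes) {
          k <- if (m == "A") ratesA[exch] else ratesB[exch]
          frac <- simulateResidueDeuteration(k, t, sat)
          env <- envelopeFromFractions(frac)
          if (!is.null(nat)) env <- .convolve(env, nat)
          if (config$noise_sd > 0) {
            env <- env * exp(stats::rnorm(length(env), 0, config$noise_sd))
            env <- env / sum(env)
          }
          rows[[length(rows) + 1L]] <- list(
            start = p$start, end = p$end, rep = r, mod = m, ptm = p$ptm,
            time_s = t, envQ = .quantizeEnvelope(env),
            centroid_true = sum(frac),
            charge = sample(2:4, 1),
            rt = quantizeDecimal(stats::runif(1, 5, 15), 3L),
            conf = quantizeDecimal(stats::runif(1, 0.90, 1), 2L),
            mono = quantizeDecimal(
              111.1 * (p$end - p$start + 1L) + 18.010565 +
                stats::runif(1, -0.5, 0.5), 6L))
        }
      }
    }
  }

  n <- length(rows)
  g <- function(name) vapply(rows, `[[`, numeric(1), name)
  gc_ <- function(name) vapply(rows, `[[`, character(1), name)
  start <- g("start"); end <- g("end"); rep_ <- g("rep")
  mod <- gc_("mod"); ptmText <- gc_("ptm"); time_s <- g("time_s")
  envQ <- lapply(rows, `[[`, "envQ")
  cenQ <- vapply(envQ, envelopeCentroid, numeric(1))

  # uptake of each record against its replicate's mode-"A" 0 s centroid
  zeroKey <- paste(start, end, rep_, ptmText)
  zeroRows <- which(time_s == 0 & mod == "A")
  zeroRef <- cenQ[zeroRows][match(zeroKey, zeroKey[zeroRows])]
  uptakeQ <- quantizeDecimal(cenQ - zeroRef, 2L)

  h <- .harvestPTMs(ptmText)
  tp <- newTimepointTable(index = seq_len(n) - 1L, mod = mod, start = start,
                          end = end, rep = rep_, ptm_id = h$ids,
                          time_s = time_s, uptake = uptakeQ, envelope = envQ)

  # one MATCH record per timepoint: one m/z group per envelope peak, laid
  # out on the 13C-spaced grid of the record's charge state
  mzAll <- vector("list", n)
  for (i in seq_len(n)) {
    z <- rows[[i]]$charge
    env <- envQ[[i]]
    groups <- vector("list", length(env))
    for (j in seq_along(env)) {
      center <- (rows[[i]]$mono + (j - 1L) * .C13_SPACING_DA +
                   z * .PROTON_DA) / z
      if (config$natural_isotopes) {
        mzs <- quantizeDecimal(center + c(-0.0028, 0, 0.0028), 4L)
        ints <- quantizeDecimal(env[j] * 1e4 * c(0.25, 0.5, 0.25), 4L)
      } else {
        mzs <- quantizeDecimal(center, 4L)
        ints <- quantizeDecimal(env[j] * 1e4, 4L)
      }
      groups[[j]] <- mzGroup(mzs, ints)
    }
    mzAll[[i]] <- groups
  }
  matches <- newMatchTable(
    tp_id = seq_len(n) - 1L, conf = g("conf"), rt_min = g("rt"),
    charge = g("charge"), mono_mass = g("mono"), mz = mzAll)

  metadata <- hxmsMetadata(
    proteinSequence = sequence, temperatureK = config$temperature_K,
    pHRead = config$pH_read, d2oSaturation = sat,
    proteinName = config$protein_name, proteinState = config$protein_state)
  dataset <- HXMSDataset(metadata, tp, h$table, matches)

  truth <- data.frame(start = as.integer(start), end = as.integer(end),
                      replicate = as.integer(rep_), mode = mod,
                      ptm = ptmText, time_s = time_s,
                      uptake_true = g("centroid_true"),
                      stringsAsFactors = FALSE)

  exports <- .dialectExports(rows, envQ, config)

  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- c(reference = file.path(dir, "reference.hxms"),
               truth = file.path(dir, "truth.tsv"))
    writeHXMS(dataset, files[["reference"]])
    utils::write.table(truth, files[["truth"]], sep = "\t",
                       row.names = FALSE, quote = FALSE)
    for (nm in names(exports)) {
      path <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(exports[[nm]], path, row.names = FALSE)
      files[[nm]] <- path
    }
  }

  list(dataset = dataset, truth = truth, exports = exports,
       metadata = metadata, files = files)
}

# Vendor-export views of the generated measurements. Centroid columns carry
# the exact (noise-free-grid) envelope centroid at 6 decimals; uptake-direct
# columns carry the centroid-difference uptake at 4 decimals, the precision
# vendor tables typically print.
.dialectExports <- function(rows, envQ, config) {
  n <- length(rows)
  g <- function(name) vapply(rows, `[[`, numeric(1), name)
  gc_ <- function(name) vapply(rows, `[[`, character(1), name)
  start <- g("start"); end <- g("end"); rep_ <- g("rep")
  mod <- gc_("mod"); ptmText <- gc_("ptm"); time_s <- g("time_s")
  cenTrue <- g("centroid_true")

  # uptake from the true centroids (0 s true centroid is exactly 0)
  uptakeTrue <- cenTrue
  expCell <- function(t, sentinel) ifelse(is.infinite(t), sentinel,
                                          formatMetaNumber(t))
  spectrumCell <- function(i) {
    z <- rows[[i]]$charge
    env <- envQ[[i]]
    groups <- lapply(seq_along(env), function(j) {
      center <- (rows[[i]]$mono + (j - 1L) * .C13_SPACING_DA +
                   z * .PROTON_DA) / z
      mzGroup(quantizeDecimal(center, 4L),
              quantizeDecimal(env[j] * 1e4, 4L))
    })
    encodeMZ(groups)
  }

  isA <- mod == "A"
  custom <- data.frame(
    start = start, end = end, replicate = rep_, mode = mod,
    time_s = expCell(time_s, "inf"),
    uptake = sprintf("%.4f", uptakeTrue),
    envelope = vapply(envQ, function(e)
      paste(sprintf("%.3f", e), collapse = ";"), character(1)),
    ptm = ptmText, stringsAsFactors = FALSE)

  dynamx <- data.frame(
    Start = start[isA], End = end[isA], Modification = ptmText[isA],
    State = config$protein_state, Exposure = expCell(time_s[isA], "FD"),
    Uptake = sprintf("%.4f", uptakeTrue[isA]), Replicate = rep_[isA],
    stringsAsFactors = FALSE)

  wb <- data.frame(
    Start = start[isA], End = end[isA],
    Charge = vapply(rows[isA], `[[`, numeric(1), "charge"),
    Replicate = rep_[isA], Exposure = expCell(time_s[isA], "inf"),
    Centroid = sprintf("%.6f", cenTrue[isA]),
    Modification = ptmText[isA],
    Spectrum = vapply(which(isA), spectrumCell, character(1)),
    RT = sprintf("%.3f", g("rt")[isA]),
    Conf = sprintf("%.2f", g("conf")[isA]),
    MonoMass = sprintf("%.6f", g("mono")[isA]),
    stringsAsFactors = FALSE)

  hdx <- data.frame(
    Start = start, End = end, Exposure = expCell(time_s, "inf"),
    Replicate = rep_, Population = mod,
    Centroid = sprintf("%.6f", cenTrue), stringsAsFactors = FALSE)

  hdxSpec <- data.frame(
    Start = start, End = end, Exposure = expCell(time_s, "inf"),
    Replicate = rep_, Population = mod,
    Charge = g("charge"), RT = sprintf("%.3f", g("rt")),
    Conf = sprintf("%.2f", g("conf")),
    MonoMass = sprintf("%.6f", g("mono")),
    Spectrum = vapply(seq_len(n), spectrumCell, character(1)),
    stringsAsFactors = FALSE)

  biopharma <- data.frame(
    Start = start[isA], End = end[isA],
    Exposure = expCell(time_s[isA], "MAX"),
    Uptake = sprintf("%.4f", uptakeTrue[isA]), Replicate = rep_[isA],
    stringsAsFactors = FALSE)

  list(custom = custom, dynamx = dynamx, hdx_workbench = wb,
       hdexaminer = hdx, hdexaminer_spectra = hdxSpec,
       biopharma_finder = biopharma)
}
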