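# Seeded synthetic multi-database ECG generation. Each beat class is a sum of
# five Gaussian bumps (P, Q, R, S, T); each emulated database has its own
# sampling frequency, amplitude gain/offset, noise levels and class mixture,
# mirroring the ways real source databases differ.

#' Construct a MorphologySpec
#'
#' @param className Class name.
#' @param amplitudes Numeric length 5 (P, Q, R, S, T) in mV; the R amplitude
#'   must dominate in magnitude.
#' @param centers Numeric length 5, seconds relative to the R peak.
#' @param widths Numeric length 5, positive Gaussian sigmas in seconds.
#' @param amplitudeJitter Relative sd of the per-beat amplitude factor.
#' @param timingJitter Sd (seconds) of per-beat P/T centre jitter.
#' @return A validated [MorphologySpec-class].
#' @export
morphologySpec <- function(className, amplitudes, centers, widths,
                           amplitudeJitter = 0.05, timingJitter = 0.005) {
  waves <- c("P", "Q", "R", "S", "T")
  new("MorphologySpec", className = className,
      amplitudes = stats::setNames(as.numeric(amplitudes), waves),
      centers = stats::setNames(as.numeric(centers), waves),
      widths = stats::setNames(as.numeric(widths), waves),
      amplitudeJitter = amplitudeJitter, timingJitter = timingJitter)
}

#' Morphology templates for the 16 beat classes
#'
#' Sixteen editable parameter sets, one per class of the default scheme.
#' They encode textbook-style contrasts — absent or inverted P waves for
#' escape and junctional beats, widened R and discordant T for ventricular
#' and bundle-branch-block beats, early prominent P for atrial prematures —
#' chosen to be mutually separable, with no claim of clinical fidelity.
#' All classes keep a positive dominant R bump so the annotated R index is
#' always a local amplitude maximum.
#'
#' @return Named list of 16 [MorphologySpec-class] objects ("0".."15").
#' @export
classMorphologies <- function() {
  base <- list(a = c(0.15, -0.10, 1.00, -0.20, 0.30),
               c = c(-0.200, -0.035, 0.000, 0.035, 0.160),
               w = c(0.025, 0.010, 0.012, 0.010, 0.050))
  mk <- function(name, a = base$a, c. = base$c, w = base$w)
    morphologySpec(name, a, c., w)
  specs <- list(
    "0" = mk("Normal beat"),
    "1" = mk("Fusion of paced and normal beat",
             a = c(0.05, -0.08, 1.10, -0.30, 0.40),
             w = c(0.025, 0.010, 0.030, 0.015, 0.055)),
    "2" = mk("Atrial escape beat",
             a = c(-0.08, -0.10, 0.85, -0.20, 0.25),
             w = c(0.030, 0.010, 0.014, 0.010, 0.050)),
    "3" = mk("Paced beat",
             a = c(0.00, -0.05, 1.30, -0.50, -0.25),
             w = c(0.025, 0.012, 0.035, 0.030, 0.060)),
    "4" = mk("Nodal (junctional) escape beat",
             a = c(0.00, -0.10, 0.95, -0.20, 0.30),
             c. = c(-0.200, -0.035, 0.000, 0.035, 0.190)),
    "5" = mk("Supraventricular escape beat",
             a = c(-0.05, -0.08, 0.90, -0.18, 0.28),
             c. = c(-0.120, -0.035, 0.000, 0.035, 0.160)),
    "6" = mk("Left bundle branch block beat",
             a = c(0.12, -0.05, 1.20, -0.35, -0.30),
             w = c(0.025, 0.010, 0.040, 0.025, 0.060)),
    "7" = mk("Right bundle branch block beat",
             a = c(0.12, -0.08, 1.10, -0.45, -0.20),
             c. = c(-0.200, -0.035, 0.000, 0.055, 0.170),
             w = c(0.025, 0.010, 0.030, 0.030, 0.055)),
    "8" = mk("Supraventricular premature",
             a = c(0.20, -0.10, 1.00, -0.20, 0.30),
             c. = c(-0.150, -0.035, 0.000, 0.035, 0.160),
             w = c(0.018, 0.010, 0.012, 0.010, 0.050)),
    "9" = mk("Atrial premature beat",
             a = c(0.22, -0.10, 0.95, -0.20, 0.28),
             c. = c(-0.170, -0.035, 0.000, 0.035, 0.160),
             w = c(0.020, 0.010, 0.012, 0.010, 0.050)),
    "10" = mk("Nodal (junctional) premature beat",
              a = c(0.00, -0.12, 1.05, -0.25, 0.32),
              c. = c(-0.200, -0.035, 0.000, 0.035, 0.150)),
    "11" = mk("Aberrated atrial premature beat",
              a = c(0.10, -0.10, 0.90, -0.30, 0.25),
              c. = c(-0.130, -0.035, 0.000, 0.040, 0.160),
              w = c(0.035, 0.010, 0.020, 0.015, 0.050)),
    "12" = mk("Premature ventricular contraction",
              a = c(0.00, -0.05, 1.40, -0.60, -0.45),
              c. = c(-0.200, -0.040, 0.000, 0.060, 0.180),
              w = c(0.025, 0.012, 0.045, 0.040, 0.070)),
    "13" = mk("Ventricular escape beat",
              a = c(0.00, -0.05, 0.80, -0.50, -0.35),
              w = c(0.025, 0.012, 0.050, 0.045, 0.065)),
    "14" = mk("Fusion of ventricular and normal beat",
              a = c(0.08, -0.08, 1.15, -0.40, 0.10),
              w = c(0.025, 0.010, 0.028, 0.020, 0.060)),
    "15" = mk("Unclassifiable beat",
              a = c(0.05, -0.05, 0.75, -0.10, 0.15),
              c. = c(-0.250, -0.035, 0.000, 0.035, 0.200),
              w = c(0.030, 0.012, 0.022, 0.012, 0.055))
  )
  specs
}

#' Construct a DatabaseProfile
#'
#' @param name Database tag.
#' @param fs Sampling frequency in Hz.
#' @param gain,offset Amplitude scale and shift applied to the whole signal
#'   (emulating device/population differences between databases).
#' @param baselineWander `c(freqLo, freqHi, amp)`: respiration-band sinusoid.
#' @param powerline `c(freq, amp)`: mains interference (50 or 60 Hz).
#' @param emg Sd (mV) of band-limited 5 Hz-Nyquist muscle noise.
#' @param heartRate `c(lo, hi)` resting range in bpm.
#' @param classMix Named numeric mixture over class ids (normalized).
#' @return A validated [DatabaseProfile-class].
#' @export
databaseProfile <- function(name, fs, gain = 1, offset = 0,
                            baselineWander = c(0.2, 0.5, 0.05),
                            powerline = c(50, 0.02), emg = 0.02,
                            heartRate = c(60, 100),
                            classMix = c("0" = 1)) {
  classMix <- classMix / sum(classMix)
  new("DatabaseProfile", name = name, fs = as.numeric(fs),
      gain = as.numeric(gain), offset = as.numeric(offset),
      baselineWander = as.numeric(baselineWander),
      powerline = as.numeric(powerline), emg = as.numeric(emg),
      heartRate = as.numeric(heartRate), classMix = classMix)
}

#' Default three-database profiles
#'
#' Profiles emulating the three real source databases this pipeline targets:
#' 360, 128 and 257 Hz sampling; distinct amplitude gains and offsets of the
#' magnitude seen in published per-database signal statistics (the 12-lead
#' Holter database shows roughly fourfold larger amplitude spread than the
#' reference database); 60 Hz mains for the two US collections and 50 Hz for
#' the European one. Class mixtures follow the published per-database beat
#' counts, including which classes are absent from each source.
#'
#' @param noiseScale Multiplier on all three noise amplitudes (default 1;
#'   0 gives clean records).
#' @return Named list of three [DatabaseProfile-class] objects.
#' @export
defaultProfiles <- function(noiseScale = 1) {
  mix <- function(counts) {
    names(counts) <- as.character(0:15)
    counts[counts > 0] / sum(counts)
  }
  mitCounts <- c(75052, 982, 16, 7028, 229, 0, 8075, 7259,
                 2, 2546, 83, 150, 7130, 106, 803, 33)
  supCounts <- c(162339, 0, 0, 0, 0, 0, 0, 0,
                 12188, 0, 9, 1, 9943, 0, 23, 79)
  incCounts <- c(150410, 0, 0, 0, 92, 32, 0, 3174,
                 16, 1944, 0, 0, 20013, 0, 219, 6)
  list(
    mitdb = databaseProfile("mitdb", fs = 360, gain = 1.0, offset = 0,
      baselineWander = c(0.2, 0.5, 0.05 * noiseScale),
      powerline = c(60, 0.02 * noiseScale), emg = 0.02 * noiseScale,
      classMix = mix(mitCounts)),
    supdb = databaseProfile("supdb", fs = 128, gain = 1.2, offset = -0.1,
      baselineWander = c(0.2, 0.5, 0.05 * noiseScale),
      powerline = c(60, 0.02 * noiseScale), emg = 0.02 * noiseScale,
      classMix = mix(supCounts)),
    incartdb = databaseProfile("incartdb", fs = 257, gain = 3.6, offset = -0.3,
      baselineWander = c(0.2, 0.5, 0.05 * noiseScale),
      powerline = c(50, 0.02 * noiseScale), emg = 0.02 * noiseScale,
      classMix = mix(incCounts))
  )
}

# Band-limited (5 Hz-Nyquist) white noise via an FFT mask.
emgNoise <- function(n, fs, sd) {
  if (sd <= 0 || n < 4) return(numeric(n))
  e <- stats::rnorm(n)
  E <- stats::fft(e)
  freqs <- (seq_len(n) - 1) / n * fs
  freqs <- pmin(freqs, fs - freqs)   # two-sided
  E[freqs < 5] <- 0
  out <- Re(stats::fft(E, inverse = TRUE)) / n
  if (stats::sd(out) > 0) out <- out * sd / stats::sd(out)
  out
}

evalTemplate <- function(spec, tRel, ampFactor = 1, centerShift = NULL) {
  centers <- spec@centers
  if (!is.null(centerShift)) centers <- centers + centerShift
  y <- numeric(length(tRel))
  for (k in seq_len(5)) {
    a <- spec@amplitudes[[k]] * ampFactor
    if (a == 0) next
    y <- y + a * exp(-0.5 * ((tRel - centers[[k]]) / spec@widths[[k]])^2)
  }
  y
}

#' Generate one annotated synthetic ECG record
#'
#' Lays `nBeats` beats along the record at RR intervals drawn uniformly from
#' the profile's heart-rate range, places each class's Gaussian P-QRS-T
#' template at its R time (with small seeded per-beat amplitude and P/T
#' timing jitter), adds the profile's three noise processes, then applies the
#' profile's gain and offset. Annotation indices sit exactly at the planted R
#' peak samples, which at zero noise are strict local maxima. Deterministic
#' given the seed.
#'
#' @param profile A [DatabaseProfile-class].
#' @param nBeats Number of beats (>= 1).
#' @param seed Integer seed.
#' @param classMap A [ClassMap-class] supplying the class-id to beat-code
#'   inverse mapping for the annotations.
#' @param morphologies Named list of [MorphologySpec-class] per class id.
#' @return List with elements `record` ([EcgRecord-class]), `annotations`
#'   ([BeatAnnotationSet-class]) and `labels` (integer class ids).
#' @export
generateRecord <- function(profile, nBeats, seed,
                           classMap = buildClassMap(),
                           morphologies = classMorphologies()) {
  stopifnot(is(profile, "DatabaseProfile"), nBeats >= 1)
  fs <- profile@fs
  idToCode <- stats::setNames(names(classMap@codes), classMap@codes)
  withSeed(seed, {
    classes <- names(profile@classMix)
    labels <- as.integer(sample(classes, nBeats, replace = TRUE,
                                prob = profile@classMix))
    hr <- stats::runif(nBeats, profile@heartRate[1], profile@heartRate[2])
    rr <- 60 / hr
    tR <- 0.6 + cumsum(c(0, rr[-nBeats]))
    rIdx <- round(tR * fs)
    rIdx <- as.integer(rIdx + cumsum(c(0, as.integer(diff(rIdx) <= 0))))
    tR <- rIdx / fs                      # R peaks exactly on the grid
    nSamples <- as.integer(max(rIdx) + ceiling(0.6 * fs))
    t <- (seq_len(nSamples) - 1) / fs
    clean <- numeric(nSamples)
    for (b in seq_len(nBeats)) {
      spec <- morphologies[[as.character(labels[b])]]
      ampF <- 1 + spec@amplitudeJitter * stats::rnorm(1)
      shift <- c(P = stats::rnorm(1, 0, spec@timingJitter), Q = 0, R = 0,
                 S = 0, T = stats::rnorm(1, 0, spec@timingJitter))
      lo <- max(1L, rIdx[b] - as.integer(0.45 * fs) + 1L)
      hi <- min(nSamples, rIdx[b] + as.integer(0.45 * fs) + 1L)
      win <- lo:hi
      clean[win] <- clean[win] +
        evalTemplate(spec, t[win] - tR[b], ampF, shift)
    }
    # snap each annotation to the clean-signal local maximum near the planted
    # R time: neighbouring Q/S/T bumps can shift the composite peak by a
    # sample or two, and the annotation must sit on the R maximum itself
    snap <- max(1L, as.integer(round(0.02 * fs)))
    for (b in seq_len(nBeats)) {
      lo <- max(1L, rIdx[b] + 1L - snap)
      hi <- min(nSamples, rIdx[b] + 1L + snap)
      rIdx[b] <- lo + which.max(clean[lo:hi]) - 2L   # back to 0-based
    }
    bw <- profile@baselineWander
    noise <- numeric(nSamples)
    if (bw[3] > 0)
      noise <- noise + bw[3] * sin(2 * pi * stats::runif(1, bw[1], bw[2]) * t +
                                   stats::runif(1, 0, 2 * pi))
    pl <- profile@powerline
    if (pl[2] > 0)
      noise <- noise + pl[2] * sin(2 * pi * pl[1] * t +
                                   stats::runif(1, 0, 2 * pi))
    noise <- noise + emgNoise(nSamples, fs, profile@emg)
    signal <- profile@gain * (clean + noise) + profile@offset
    record <- ecgRecord(signal, fs = fs, leadNames = "MLII",
                        recordId = sprintf("%s_s%d", profile@name,
                                           as.integer(seed)),
                        sourceDb = profile@name)
    ann <- beatAnnotationSet(rIdx, unname(idToCode[as.character(labels)]))
    list(record = record, annotations = ann, labels = labels)
  })
}

#' Generate an on-disk multi-database synthetic corpus
#'
#' Writes, for each profile, a database directory of annotated records in a
#' [readEcgRecord()] format, plus per-record ground-truth `<rec>.labels.csv`
#' files and a corpus `manifest.json`. Record seeds are derived
#' deterministically from `seed`, so the corpus is reproducible.
#'
#' @param profiles List of [DatabaseProfile-class] objects.
#' @param nRecords Records per profile (recycled; may be 0).
#' @param beatsPerRecord Beats per record (recycled).
#' @param outDir Output directory (created).
#' @param seed Integer master seed.
#' @param format "wfdb" or "csv", passed to [writeEcgRecord()].
#' @param classMap Class map for annotation codes.
#' @return Invisibly, the manifest as a data.frame (profile, record base
#'   path, n_beats).
#' @export
generateCorpus <- function(profiles, nRecords, beatsPerRecord = 100,
                           outDir, seed = 1, format = "wfdb",
                           classMap = buildClassMap()) {
  stopifnot(length(profiles) >= 1)
  nRecords <- rep_len(nRecords, length(profiles))
  beatsPerRecord <- rep_len(beatsPerRecord, length(profiles))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  morph <- classMorphologies()
  for (p in seq_along(profiles)) {
    prof <- profiles[[p]]
    dbDir <- file.path(outDir, prof@name)
    dir.create(dbDir, recursive = TRUE, showWarnings = FALSE)
    for (r in seq_len(nRecords[p])) {
      recSeed <- deriveSeed(seed, p * 1000 + r)
      gen <- generateRecord(prof, beatsPerRecord[p], recSeed, classMap, morph)
      recId <- sprintf("%s%03d", prof@name, r)
      gen$record@recordId <- recId
      base <- file.path(dbDir, recId)
      writeEcgRecord(gen$record, gen$annotations, base, format = format)
      utils::write.csv(
        data.frame(index = gen$annotations@indices, label = gen$labels),
        paste0(base, ".labels.csv"), row.names = FALSE)
      rows[[length(rows) + 1L]] <-
        data.frame(profile = prof@name, record = base,
                   n_beats = beatsPerRecord[p])
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows)
    else data.frame(profile = character(0), record = character(0),
                    n_beats = integer(0))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       dataframe = "rows", digits = NA)
  invisible(manifest)
}
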