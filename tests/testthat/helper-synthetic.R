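# Shared fixture builders: small seeded synthetic corpora and records.

# Profiles for a k-class balanced corpus over the three emulated databases
# (360 / 128 / 257 Hz with distinct gains and offsets).
balancedProfiles <- function(nClasses = 8, noiseScale = 1) {
  mix <- stats::setNames(rep(1 / nClasses, nClasses),
                         as.character(seq_len(nClasses) - 1L))
  lapply(defaultProfiles(noiseScale), function(p) {
    p@classMix <- mix
    p
  })
}

# Write a corpus under a fresh temp directory; returns the directory.
makeCorpus <- function(profiles, nRecords, beatsPerRecord, seed,
                       format = "wfdb") {
  dir <- tempfile("corpus")
  generateCorpus(profiles, nRecords = nRecords,
                 beatsPerRecord = beatsPerRecord, outDir = dir, seed = seed,
                 format = format)
  dir
}

dbPaths <- function(corpusDir, profiles) {
  vapply(profiles, function(p) file.path(corpusDir, p@name), "")
}

# A deterministic single-lead ramp record, handy for index arithmetic.
rampRecord <- function(n = 1000, fs = 360) {
  ecgRecord(seq_len(n) - 1, fs = fs, leadNames = "MLII", recordId = "ramp")
}
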