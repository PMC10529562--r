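# Per-beat sampling window, beat extraction around annotated R peaks, and
# band-limited resampling to the unified frequency.

#' Samples per heartbeat from heart rate and sampling frequency
#'
#' At a heart rate of `fHeart` beats per minute a single beat lasts
#' `60 / fHeart` seconds, i.e. `60 * fSample / fHeart` samples. Over the
#' resting range 60-100 bpm this puts the admissible per-beat sample count
#' between `0.6 * fSample` and `fSample`: fewer samples would truncate the
#' waveform, more would bleed into neighbouring beats.
#'
#' @param fHeart Heart rate in beats per minute, within [60, 100].
#' @param fSample Sampling frequency in Hz.
#' @return Integer sample count, `round(60 * fSample / fHeart)`.
#' @examples
#' numOfSample(100, 360)  # 216
#' numOfSample(60, 360)   # 360
#' @export
numOfSample <- function(fHeart, fSample) {
  if (!is.numeric(fHeart) || any(fHeart < 60) || any(fHeart > 100))
    stop("fHeart must lie in the resting range [60, 100] bpm", call. = FALSE)
  if (!is.numeric(fSample) || any(fSample <= 0))
    stop("fSample must be positive", call. = FALSE)
  as.integer(round(60 * fSample / fHeart))
}

#' Split a beat window into pre- and post-R-peak sample counts
#'
#' The `L` samples of a beat are centred on the R peak: `M = floor((L-1)/2)`
#' samples before it and `N = L - 1 - M` after it (so `M + N + 1 == L`, and
#' `N == M + 1` for even `L`).
#'
#' @param L Samples per beat, at least 3.
#' @return Named integer vector `c(M = ..., N = ...)`.
#' @examples
#' splitWindow(260)  # M = 129, N = 130
#' @export
splitWindow <- function(L) {
  L <- as.integer(L)
  if (length(L) != 1 || is.na(L) || L < 3)
    stop("L must be a single integer >= 3", call. = FALSE)
  M <- (L - 1L) %/% 2L
  c(M = M, N = L - 1L - M)
}

# Fourier-domain resampling of a real signal to an exact output length.
# Zero-pads (up) or truncates (down) the spectrum, with the Nyquist bin
# split/folded so the output stays real. Exact for DC; band-limited content
# below the lower Nyquist frequency is preserved away from the edges.
resampleToLength <- function(x, nOut) {
  nIn <- length(x)
  nOut <- as.integer(nOut)
  if (nIn == 0) stop("cannot resample an empty signal", call. = FALSE)
  if (nOut < 1) stop("output length must be >= 1", call. = FALSE)
  if (nOut == nIn) return(x)
  X <- stats::fft(x)
  Y <- complex(real = numeric(nOut), imaginary = numeric(nOut))
  nKeep <- min(nIn, nOut)
  nyq <- nKeep %/% 2L + 1L                  # non-negative bins kept
  Y[seq_len(nyq)] <- X[seq_len(nyq)]
  nTail <- nKeep - nyq                      # negative-frequency bins kept
  if (nTail > 0)
    Y[(nOut - nTail + 1L):nOut] <- X[(nIn - nTail + 1L):nIn]
  if (nKeep %% 2L == 0L) {
    if (nOut < nIn) {
      Y[nyq] <- Y[nyq] + X[nIn - nKeep %/% 2L + 1L]   # fold -Nyquist in
    } else {
      Y[nyq] <- Y[nyq] / 2                             # split Nyquist
      Y[nOut - nKeep %/% 2L + 1L] <- Y[nyq]
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / nIn
}

#' Resample a signal to a new sampling frequency
#'
#' Band-limited (Fourier) resampling: the output has length
#' `round(length(x) * fsOut / fsIn)` and preserves spectral content below
#' the lower of the two Nyquist frequencies. Deterministic; the identity
#' when `fsOut == fsIn`.
#'
#' @param x Numeric amplitude vector.
#' @param fsIn,fsOut Input and output sampling frequencies in Hz.
#' @return Numeric vector of the resampled signal.
#' @examples
#' length(resampleSignal(rnorm(128), 128, 360))  # 360
#' @export
resampleSignal <- function(x, fsIn, fsOut) {
  if (length(x) == 0) stop("cannot resample an empty signal", call. = FALSE)
  if (fsIn <= 0 || fsOut <= 0)
    stop("sampling frequencies must be positive", call. = FALSE)
  if (fsIn == fsOut) return(x)
  resampleToLength(x, round(length(x) * fsOut / fsIn))
}

# Resample a beat to exactly L samples, absorbing the +/-1 rounding that a
# frequency-ratio length can produce.
resampleBeat <- function(x, L) {
  y <- resampleToLength(x, L)
  stopifnot(length(y) == L)
  y
}

#' Extract fixed-length heartbeats around annotated R peaks
#'
#' For every annotation whose symbol the class map assigns to a class, reads
#' `M` samples before and `N` samples after the R peak (window `[r-M, r+N]`
#' inclusive, length `L`). Annotations whose window crosses a record boundary
#' are dropped and logged; symbols not in the class map are skipped silently
#' (they are non-beat marks or deliberately excluded codes).
#'
#' Records whose native sampling frequency differs from `window@fsTarget` are
#' handled on one of two paths. The default (`"beatwise"`) extracts a
#' native-length window `L_native = round(L * fs_native / fsTarget)`, split
#' by the same centring rule, and then resamples each beat to exactly `L`
#' samples — extraction before resampling. The alternative (`"recordwise"`)
#' resamples the whole record first and rescales the annotation indices.
#'
#' @param record A single-lead [EcgRecord-class].
#' @param annotations A [BeatAnnotationSet-class] for that record.
#' @param window A [WindowSpec-class].
#' @param classMap A [ClassMap-class].
#' @param path "beatwise" (default) or "recordwise".
#' @return A [BeatDataset-class] of kept beats, with the boundary drop log in
#'   [dropLog()].
#' @export
extractBeats <- function(record, annotations, window,
                         classMap = buildClassMap(),
                         path = c("beatwise", "recordwise")) {
  stopifnot(is(record, "EcgRecord"), is(annotations, "BeatAnnotationSet"),
            is(window, "WindowSpec"), is(classMap, "ClassMap"))
  path <- match.arg(path)
  if (ncol(record@signal) != 1)
    stop("extractBeats needs a single-lead record; use leadPriority at read time",
         call. = FALSE)
  sig <- record@signal[, 1]
  fsNative <- record@fs
  fsTarget <- window@fsTarget
  L <- window@L

  if (path == "recordwise" && fsNative != fsTarget) {
    sig <- resampleSignal(sig, fsNative, fsTarget)
    rIdx <- as.integer(round(annotations@indices * fsTarget / fsNative))
    M <- window@M; N <- window@N
    needResample <- FALSE
  } else if (fsNative != fsTarget) {
    Lnat <- as.integer(round(L * fsNative / fsTarget))
    if (Lnat < 3) stop("native window too short at fs = ", fsNative,
                       call. = FALSE)
    mn <- splitWindow(Lnat)
    M <- mn[["M"]]; N <- mn[["N"]]
    rIdx <- annotations@indices
    needResample <- TRUE
  } else {
    M <- window@M; N <- window@N
    rIdx <- annotations@indices
    needResample <- FALSE
  }

  ids <- classMap@codes[annotations@symbols]
  mapped <- which(!is.na(ids))
  len <- length(sig)
  keep <- integer(0)
  dropIdx <- integer(0)
  for (k in mapped) {
    r <- rIdx[[k]]
    if (r - M < 0 || r + N > len - 1) dropIdx <- c(dropIdx, k)
    else keep <- c(keep, k)
  }
  beats <- matrix(0, nrow = length(keep),
                  ncol = if (needResample) M + N + 1L else L)
  for (i in seq_along(keep)) {
    r <- rIdx[[keep[i]]]
    beats[i, ] <- sig[(r - M):(r + N) + 1L]   # 0-based index -> R index
  }
  if (needResample && length(keep)) {
    beats <- t(apply(beats, 1, resampleBeat, L = L))
  } else if (needResample) {
    beats <- matrix(0, 0, L)
  }
  drop <- data.frame(
    record_id = rep(record@recordId, length(dropIdx)),
    r_index = annotations@indices[dropIdx],
    reason = rep("window crosses record boundary", length(dropIdx))
  )
  beatDataset(beats, labels = as.integer(ids[keep]),
              sourceDb = record@sourceDb, sourceRecord = record@recordId,
              classNames = classMap@classNames, fs = fsTarget,
              dropLog = drop)
}
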