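# Acoustic features defining the 3D voice space: fundamental frequency (f0),
# formant dispersion (FD, the mean frequency difference of successive
# formants F1 through F4), and harmonics-to-noise ratio (HNR). Speakers are
# placed in this space after within-stratum z-standardization.

#' Formant dispersion
#'
#' Mean frequency difference of successive formants F1 through F4. For
#' formants \eqn{F_1 < F_2 < F_3 < F_4} this is
#' \eqn{((F_2-F_1)+(F_3-F_2)+(F_4-F_3))/3}, which telescopes to
#' \eqn{(F_4-F_1)/3}.
#'
#' @param formants numeric vector of length 4 (Hz, strictly increasing), or
#'   a matrix with 4 columns for several speakers at once.
#' @return formant dispersion in Hz (scalar or per-row vector).
#' @examples
#' formantDispersion(c(500, 1500, 2500, 3500)) # 1000
#' @export
formantDispersion <- function(formants) {
  if (is.matrix(formants)) {
    if (ncol(formants) != 4L) stop("formants must have 4 columns (F1..F4)")
    return(apply(formants, 1L, formantDispersion))
  }
  if (length(formants) != 4L) stop("formants must be a 4-tuple (F1..F4)")
  if (!all(is.finite(formants))) stop("formants must be finite")
  d <- diff(formants)
  if (any(d <= 0)) stop("formants must be strictly increasing")
  mean(d)
}

#' RMS level normalization
#'
#' Scales a waveform by a single positive factor so that its RMS level,
#' `20 * log10(rms / reference)`, equals `targetDb`. With the default
#' reference of 2e-5 (the convention under which 60 dB is a standard
#' comfortable playback level for unscaled digital audio), a target of 60 dB
#' yields an output RMS of 0.02.
#'
#' @param waveform numeric vector of sampled amplitudes; must not be all
#'   zero.
#' @param targetDb target level in dB (default 60).
#' @param reference reference amplitude (default 2e-5).
#' @return the rescaled waveform.
#' @export
rmsNormalize <- function(waveform, targetDb = 60, reference = 2e-5) {
  if (!is.finite(targetDb)) stop("targetDb must be finite")
  rms <- sqrt(mean(waveform^2))
  if (!is.finite(rms) || rms <= 0) stop("cannot normalize an all-zero (silent) waveform")
  waveform * (reference * 10^(targetDb / 20) / rms)
}

#' Validate (and complete) a voice feature table
#'
#' Checks the invariants of a speaker feature table: positive finite f0,
#' strictly increasing formants where present, and consistency of `fd_hz`
#' with the formants. When formants are present and `fd_hz` absent, it is
#' computed. Tables may also carry `fd_hz` directly with no formant columns.
#'
#' @param features data.frame with columns `speaker_id`, `gender`, `f0_hz`,
#'   `hnr_db`, and either `f1_hz`..`f4_hz` or `fd_hz` (or both).
#' @return the validated data.frame with `fd_hz` populated.
#' @export
voiceFeatureTable <- function(features) {
  need <- c("speaker_id", "gender", "f0_hz", "hnr_db")
  miss <- setdiff(need, names(features))
  if (length(miss)) stop("feature table lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(features$speaker_id)) stop("duplicate speaker_id")
  if (any(!is.finite(features$f0_hz) | features$f0_hz <= 0))
    stop("f0_hz must be finite and positive")
  fcols <- paste0("f", 1:4, "_hz")
  hasF <- all(fcols %in% names(features))
  if (!hasF && !"fd_hz" %in% names(features))
    stop("feature table needs either f1_hz..f4_hz or fd_hz")
  if (hasF) {
    fm <- as.matrix(features[fcols])
    fd <- formantDispersion(fm)
    if ("fd_hz" %in% names(features)) {
      if (any(abs(features$fd_hz - fd) > 1e-6 * pmax(1, fd)))
        stop("fd_hz inconsistent with formants (must equal mean successive difference)")
    } else {
      features$fd_hz <- fd
    }
  }
  if (any(!is.finite(features$fd_hz) | features$fd_hz <= 0))
    stop("fd_hz must be finite and positive")
  if (any(!is.finite(features$hnr_db))) stop("hnr_db must be finite")
  features$speaker_id <- as.character(features$speaker_id)
  features$gender <- as.character(features$gender)
  features
}

#' Read a voice feature table from CSV
#'
#' @param path CSV file with columns `speaker_id`, `gender`, `f0_hz`,
#'   `f1_hz`..`f4_hz` (or `fd_hz`), `hnr_db`.
#' @return validated feature data.frame (see [voiceFeatureTable()]).
#' @export
readFeatureTable <- function(path) {
  voiceFeatureTable(read.csv(path, stringsAsFactors = FALSE))
}

#' Build a standardized 3D voice space for one gender stratum
#'
#' Z-standardizes (f0, FD, HNR) within the stratum and records the
#' standardization parameters, so coordinates are auditable back to raw
#' values. Spaces are built per gender because triplets are gender-matched
#' (foils always share the target's gender); a pooled space is available via
#' `stratum = "pooled"`.
#'
#' f0 is standardized on the raw Hz scale by default; set `logF0 = TRUE` to
#' standardize log(f0) instead. The choice is recorded in the
#' standardization parameters. Sample SDs use the n-1 denominator.
#'
#' @param features validated feature table (see [voiceFeatureTable()]).
#' @param stratum gender value to select, or "pooled" for all speakers.
#' @param logF0 standardize log-Hz instead of Hz for f0.
#' @return a [VoiceSpace-class] object.
#' @export
buildVoiceSpace <- function(features, stratum, logF0 = FALSE) {
  features <- voiceFeatureTable(features)
  sel <- if (identical(stratum, "pooled")) features else
    features[features$gender == stratum, , drop = FALSE]
  if (nrow(sel) < 3L)
    stop(sprintf("need at least 3 speakers in stratum '%s' (got %d)", stratum, nrow(sel)))
  f0 <- if (logF0) log(sel$f0_hz) else sel$f0_hz
  raw <- cbind(f0 = f0, fd = sel$fd_hz, hnr = sel$hnr_db)
  ctr <- colMeans(raw)
  scl <- apply(raw, 2, sd)
  if (any(scl <= 0)) stop("zero-variance dimension; cannot standardize")
  z <- sweep(sweep(raw, 2, ctr), 2, scl, "/")
  rownames(z) <- sel$speaker_id
  new("VoiceSpace",
      stratum = as.character(stratum),
      speakerIds = sel$speaker_id,
      coords = z,
      standardization = list(center = ctr, scale = scl,
                             transform = if (logF0) "log_f0" else "identity"))
}

#' Aggregate framewise acoustic analyses into speaker features
#'
#' The toolkit defines only the aggregation contract, not the
#' signal-processing internals: a pluggable backend supplies framewise f0
#' (NA on unvoiced frames), formants (frames x 4) and HNR, and this
#' function reduces them to a single [voiceFeatureTable()] row: mean f0
#' over voiced frames, mean F1..F4 with the derived formant dispersion, and
#' mean HNR.
#'
#' @param recording list with `samples` (numeric mono waveform) and `rate`
#'   (Hz); passed through to the backend.
#' @param backend a function `(recording) -> list(f0, formants, hnr)` with
#'   `f0` a numeric vector (NA = unvoiced frame), `formants` a frames x 4
#'   matrix, `hnr` a numeric vector; or `NULL` if no analyzer is available.
#' @param speakerId,gender identity metadata for the output row.
#' @return one-row feature data.frame.
#' @export
aggregateFeatures <- function(recording, backend, speakerId = "spk", gender = NA_character_) {
  if (is.null(backend))
    stop("no acoustic analysis backend available; supply a feature table instead")
  if (!is.null(recording$samples) && is.matrix(recording$samples))
    stop("recording must be mono (a plain numeric vector of samples)")
  fr <- backend(recording)
  voiced <- fr$f0[!is.na(fr$f0) & fr$f0 > 0]
  if (!length(voiced)) stop("no voiced frames; cannot aggregate f0")
  fmean <- colMeans(fr$formants, na.rm = TRUE)
  data.frame(speaker_id = speakerId, gender = gender,
             f0_hz = mean(voiced),
             f1_hz = fmean[1], f2_hz = fmean[2], f3_hz = fmean[3], f4_hz = fmean[4],
             fd_hz = formantDispersion(fmean),
             hnr_db = mean(fr$hnr, na.rm = TRUE),
             row.names = NULL)
}
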