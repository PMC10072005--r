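#' Detect motion artifacts by moving-window excursion
#'
#' A sample is flagged when the signal excursion (max minus min) inside a
#' centred moving window exceeds \code{k} times the channel's robust SD
#' (median absolute deviation, scaled for normal consistency). Flagged
#' samples are dilated by half a window on each side and merged into
#' contiguous segments. Channels with zero robust SD (constant signal)
#' are never flagged.
#'
#' @param recording a \linkS4class{HemodynamicRecording}.
#' @param window moving-window length in seconds (default 1 s).
#' @param k excursion threshold in robust-SD multiples (default 5).
#' @return An \linkS4class{ArtifactMask}.
#' @export
detectArtifacts <- function(recording, window = 1, k = 5) {
  x <- sigData(recording)
  fs <- samplingRate(recording)
  nt <- ncol(x)
  w <- round(window * fs)
  stopifnot2(w >= 2, "window * fs must be at least 2 samples")
  stopifnot2(w <= nt, "window longer than the recording")
  half <- floor(w / 2)
  mask <- matrix(FALSE, nrow(x), nt)
  segs <- data.frame(channel = integer(0), start = integer(0),
                     end = integer(0))
  for (ch in seq_len(nrow(x))) {
    y <- x[ch, ]
    robSD <- mad(y)
    if (robSD == 0) next
    hi <- zoo::rollmax(y, w, fill = NA, align = "center")
    lo <- -zoo::rollmax(-y, w, fill = NA, align = "center")
    flag <- which((hi - lo) > k * robSD)
    if (!length(flag)) next
    hit <- rep(FALSE, nt)
    for (f in flag) hit[max(1, f - half):min(nt, f + half)] <- TRUE
    mask[ch, ] <- hit
    r <- rle(hit)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    on <- which(r$values)
    segs <- rbind(segs, data.frame(channel = ch, start = starts[on],
                                   end = ends[on]))
  }
  new("ArtifactMask", mask = mask, segments = segs)
}

#' Correct flagged artifact segments with smoothing splines
#'
#' MARA-style correction: within each flagged segment a cubic smoothing
#' spline is fitted and subtracted, removing the artifact's trajectory;
#' the residual is then re-anchored to a linear ramp between the mean
#' signal levels just before and after the segment, so segments re-join
#' the surrounding clean signal without steps. Samples outside flagged
#' segments are untouched. A segment covering an entire channel is left
#' unchanged with a warning.
#'
#' @param recording a \linkS4class{HemodynamicRecording}.
#' @param mask an \linkS4class{ArtifactMask} from
#'   \code{\link{detectArtifacts}}.
#' @param smooth smoothing parameter in (0, 1]; higher values let the
#'   spline follow the artifact more closely (default 0.99).
#' @return Corrected \linkS4class{HemodynamicRecording}.
#' @export
correctArtifactsSpline <- function(recording, mask, smooth = 0.99) {
  stopifnot2(is(mask, "ArtifactMask"), "mask must be an ArtifactMask")
  x <- sigData(recording)
  stopifnot2(all(dim(mask@mask) == dim(x)), "mask does not fit recording")
  stopifnot2(smooth > 0 && smooth <= 1, "smooth must be in (0, 1]")
  fs <- samplingRate(recording)
  segs <- mask@segments
  nt <- ncol(x)
  pad <- max(2L, round(fs)) # context window for edge-mean matching
  for (s in seq_len(nrow(segs))) {
    ch <- segs$channel[s]; a <- segs$start[s]; b <- segs$end[s]
    if (a == 1L && b == nt) {
      warning("segment covers entire channel ", ch, "; left unchanged")
      next
    }
    y <- x[ch, a:b]
    len <- b - a + 1L
    if (len >= 4L) {
      fit <- suppressWarnings(
        smooth.spline(seq_len(len), y, spar = 1 - smooth))
      resid <- y - predict(fit, seq_len(len))$y
    } else {
      resid <- rep(0, len) # too short for a spline: drop to the baseline
    }
    before <- x[ch, max(1, a - pad):max(1, a - 1)]
    after <- x[ch, min(nt, b + 1):min(nt, b + pad)]
    lv <- if (a > 1) mean(before) else mean(after)
    rv <- if (b < nt) mean(after) else mean(before)
    ramp <- seq(lv, rv, length.out = len)
    x[ch, a:b] <- resid - mean(resid) + ramp
  }
  out <- recording
  out@data <- x
  out
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass of the stated design order per channel
#' in a forward-backward (zero-phase) pass, so no phase distortion is
#' introduced into between-channel correlations. The effective magnitude
#' response is the squared design response.
#'
#' @param recording a \linkS4class{HemodynamicRecording}.
#' @param low,high band edges in Hz; \code{0 < low < high < fs / 2}.
#' @param order filter design order (default 2).
#' @return Filtered \linkS4class{HemodynamicRecording} of unchanged length.
#' @export
bandpass <- function(recording, low = 0.01, high = 0.1, order = 2) {
  fs <- samplingRate(recording)
  stopifnot2(low > 0 && low < high && high < fs / 2,
             "band must satisfy 0 < low < high < fs/2")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  x <- sigData(recording)
  y <- t(apply(x, 1, function(ch) signal::filtfilt(bf, ch)))
  dimnames(y) <- dimnames(x)
  out <- recording
  out@data <- y
  out
}

#' Common average reference spatial filter
#'
#' Subtracts the cross-channel mean from every channel at every sample,
#' suppressing the shared superficial component. The cross-channel mean
#' of the output is exactly zero at every sample.
#'
#' @param recording a \linkS4class{HemodynamicRecording} with at least 2
#'   channels.
#' @return Re-referenced \linkS4class{HemodynamicRecording}.
#' @export
commonAverageReference <- function(recording) {
  x <- sigData(recording)
  stopifnot2(nrow(x) >= 2, "CAR undefined for a single channel")
  out <- recording
  out@data <- sweep(x, 2, colMeans(x), "-")
  out
}

#' Trim unstable head and tail seconds
#'
#' @param recording a \linkS4class{HemodynamicRecording}.
#' @param head,tail seconds to drop from the start / end (default 5 each).
#' @return Trimmed \linkS4class{HemodynamicRecording}.
#' @export
trimEdges <- function(recording, head = 5, tail = 5) {
  x <- sigData(recording)
  fs <- samplingRate(recording)
  nh <- round(head * fs); ntl <- round(tail * fs)
  nt <- ncol(x)
  if (nh + ntl >= nt)
    stop("trim of ", nh + ntl, " samples leaves nothing of ", nt,
         call. = FALSE)
  out <- recording
  out@data <- x[, (nh + 1):(nt - ntl), drop = FALSE]
  out
}

#' Default preprocessing parameters
#'
#' @param window,k artifact-detection window (s) and threshold (robust-SD
#'   multiples).
#' @param smooth spline smoothing parameter in (0, 1].
#' @param low,high,order band-pass design (Hz, Hz, design order).
#' @param headTrim,tailTrim edge trim in seconds.
#' @param residualLimit maximum tolerated post-correction artifact
#'   fraction before falling back to the cleanest shorter window.
#' @param fallbackDuration analyzed duration (s) of the fallback window.
#' @return A named list of parameters.
#' @export
preprocessParams <- function(window = 1, k = 5, smooth = 0.99,
                             low = 0.01, high = 0.1, order = 2,
                             headTrim = 5, tailTrim = 5,
                             residualLimit = 0.05,
                             fallbackDuration = 180) {
  list(window = window, k = k, smooth = smooth, low = low, high = high,
       order = order, headTrim = headTrim, tailTrim = tailTrim,
       residualLimit = residualLimit, fallbackDuration = fallbackDuration)
}

#' Full preprocessing pipeline for one recording
#'
#' Applies, in order: artifact detection, spline correction, band-pass
#' filtering, common average referencing, and edge trimming. If the
#' residual artifact fraction after correction (re-detected with the
#' same parameters) exceeds \code{residualLimit}, the cleanest
#' contiguous window of \code{fallbackDuration + headTrim + tailTrim}
#' seconds is analyzed instead, so the final output is exactly
#' \code{fallbackDuration} seconds.
#'
#' @param recording a \linkS4class{HemodynamicRecording}.
#' @param params a \code{\link{preprocessParams}} list.
#' @return Preprocessed \linkS4class{HemodynamicRecording} with a
#'   \code{"preprocessLog"} attribute (segments found, residual artifact
#'   fraction, fallback flag and window).
#' @export
preprocess <- function(recording, params = preprocessParams()) {
  p <- params
  mask <- detectArtifacts(recording, window = p$window, k = p$k)
  corrected <- correctArtifactsSpline(recording, mask, smooth = p$smooth)
  residMask <- detectArtifacts(corrected, window = p$window, k = p$k)
  residFraction <- mean(residMask@mask)
  log <- list(nSegments = nrow(mask@segments),
              segments = mask@segments,
              residualFraction = residFraction,
              fallback = FALSE, window = c(1L, nSamples(recording)))
  fs <- samplingRate(recording)
  if (residFraction > p$residualLimit) {
    need <- round((p$fallbackDuration + p$headTrim + p$tailTrim) * fs)
    nt <- nSamples(corrected)
    if (need < nt) {
      badPerSample <- colSums(residMask@mask)
      cum <- c(0, cumsum(badPerSample))
      starts <- seq_len(nt - need + 1)
      load <- cum[starts + need] - cum[starts]
      a <- starts[which.min(load)]
      corrected@data <- corrected@data[, a:(a + need - 1), drop = FALSE]
      log$fallback <- TRUE
      log$window <- c(a, a + need - 1L)
    }
  }
  out <- bandpass(corrected, low = p$low, high = p$high, order = p$order)
  out <- commonAverageReference(out)
  out <- trimEdges(out, head = p$headTrim, tail = p$tailTrim)
  attr(out, "preprocessLog") <- log
  out
}
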