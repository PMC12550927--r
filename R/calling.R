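# Droplet calling: one fluorescence threshold per channel, placed at the
# amplitude of lowest droplet density between the two dominant clusters.

#' Well-level quality control
#'
#' A well passes QC when its accepted event count is at least `minEvents`
#' (default 10,000); wells below that are excluded from analysis.
#'
#' @param well a [DropletWell-class].
#' @param minEvents minimum accepted droplet count.
#' @return list with `acceptedEvents`, `passed`, `reason` (empty when passed).
#' @examples
#' cfg <- AssayConfig(dropletsPerWell = 2000L)
#' qcWell(simulateWell(SampleTruth(), cfg, seed = 1))$passed # FALSE
#' @export
qcWell <- function(well, minEvents = 10000) {
  n <- acceptedEvents(well)
  passed <- n >= minEvents
  list(
    acceptedEvents = n,
    passed = passed,
    reason = if (passed) "" else {
      sprintf("accepted event count %d < %d", n, as.integer(minEvents))
    }
  )
}

#' Estimate the positive/negative fluorescence threshold for one channel
#'
#' Builds a smoothed histogram density of the amplitudes (256 bins, moving
#' average over 5 bins), finds local maxima above 1% of the peak density, and
#' places the threshold at the amplitude of minimum density strictly between
#' the two dominant modes — the region of lowest droplet density between the
#' clusters.
#'
#' Fallbacks when only one mode is detected: if it sits at the
#' negative-cluster level (below the midpoint of the configured cluster
#' means) the threshold is the mode plus `k` robust spreads (default 7, far
#' enough that Gaussian negative-cluster tails never cross it at realistic
#' droplet counts)
#' (`fallback_no_positive`; any droplet above it is positive, normally none);
#' otherwise the midpoint of the configured cluster means is used
#' (`fallback_midpoint`).
#'
#' @param amps numeric amplitude vector (>= 100 droplets).
#' @param negMean,posMean configured cluster means used only by the fallbacks.
#' @param bins histogram bins.
#' @param smoothWindow moving-average window, bins.
#' @param minDensityFrac modes must exceed this fraction of the peak density.
#' @param k spread multiplier for the no-positive fallback.
#' @return list with `threshold` and `method` (`"valley"`,
#'   `"fallback_midpoint"` or `"fallback_no_positive"`).
#' @examples
#' a <- c(rnorm(900, 1000, 150), rnorm(100, 9000, 300))
#' estimateThreshold(a)$method # "valley"
#' @export
estimateThreshold <- function(amps, negMean = 1000, posMean = 9000,
                              bins = 256, smoothWindow = 5,
                              minDensityFrac = 0.01, k = 7) {
  if (length(amps) < 100) {
    ddStop("threshold estimation needs at least 100 droplets",
           "ddInsufficientDataError")
  }
  rng <- range(amps)
  spread <- stats::mad(amps)
  if (spread == 0) spread <- max(stats::sd(amps), 1)
  if (diff(rng) <= .Machine$double.eps * max(abs(rng), 1)) {
    # degenerate: all amplitudes identical
    return(list(threshold = rng[1] + k * spread, method = "fallback_no_positive"))
  }
  h <- graphics::hist(amps, breaks = seq(rng[1], rng[2], length.out = bins + 1),
                      plot = FALSE)
  d <- as.numeric(stats::filter(h$counts, rep(1 / smoothWindow, smoothWindow),
                                sides = 2))
  # moving average leaves NAs at the ends; fall back to raw counts there
  d[is.na(d)] <- h$counts[is.na(d)]
  mids <- h$mids
  # local maxima above the density floor (plateaus count once, at their
  # lowest-amplitude bin)
  floorD <- minDensityFrac * max(d)
  nb <- length(d)
  left <- c(-Inf, d[-nb])
  right <- c(d[-1], -Inf)
  isMax <- d > floorD & d >= left & d > right
  peaks <- which(isMax)
  if (length(peaks) >= 2) {
    # two dominant modes = the two tallest peaks; ties toward lower amplitude
    ord <- order(-d[peaks], mids[peaks])
    two <- sort(peaks[ord[1:2]])
    if (two[2] - two[1] > 1) {
      between <- (two[1] + 1):(two[2] - 1)
      vi <- between[which.min(d[between])]
      # genuine clusters are separated by a near-empty region; sampling
      # noise on a single mode produces shallow "valleys" that stay close
      # to the peak density
      if (d[vi] < 0.5 * min(d[two])) {
        return(list(threshold = mids[vi], method = "valley"))
      }
    }
    # adjacent or insufficiently separated peaks: effectively one mode
    peaks <- peaks[ord[1]]
  }
  modeAmp <- if (length(peaks) >= 1) mids[peaks[which.max(d[peaks])]] else mids[which.max(d)]
  if (modeAmp < (negMean + posMean) / 2) {
    list(threshold = modeAmp + k * spread, method = "fallback_no_positive")
  } else {
    list(threshold = (negMean + posMean) / 2, method = "fallback_midpoint")
  }
}

#' Call positive and negative droplets in all four channels
#'
#' Applies [estimateThreshold()] per channel of a QC-passed well. Droplets
#' with amplitude above the channel threshold are positive; counts partition
#' the accepted events.
#'
#' @param well a [DropletWell-class].
#' @param cfg an [AssayConfig-class] (supplies channel map and the cluster
#'   means used by threshold fallbacks).
#' @param minEvents QC minimum accepted events.
#' @param overrideQC call a QC-failed well anyway (diagnostics only).
#' @return data.frame with one row per channel: `wellId`, `sampleId`,
#'   `channel`, `target`, `threshold`, `nPositive`, `nNegative`, `method`,
#'   `qcPass`.
#' @examples
#' cfg <- AssayConfig(dropletsPerWell = 2000L)
#' w <- simulateWell(SampleTruth(), cfg, seed = 2)
#' callWell(w, cfg, overrideQC = TRUE)
#' @export
callWell <- function(well, cfg = AssayConfig(), minEvents = 10000,
                     overrideQC = FALSE) {
  qc <- qcWell(well, minEvents)
  if (!qc$passed && !overrideQC) {
    ddStop(
      sprintf("well %s excluded by QC: %s", well@wellId, qc$reason),
      "ddQCError"
    )
  }
  targetByChannel <- names(sort(cfg@channelMap))
  rows <- lapply(1:4, function(ch) {
    a <- well@amplitudes[, ch]
    th <- estimateThreshold(a, negMean = cfg@negMean[ch],
                            posMean = cfg@posMean[ch])
    nPos <- sum(a > th$threshold)
    data.frame(
      wellId = well@wellId, sampleId = well@sampleId,
      channel = ch, target = targetByChannel[ch],
      threshold = th$threshold,
      nPositive = nPos, nNegative = length(a) - nPos,
      method = th$method, qcPass = qc$passed,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
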