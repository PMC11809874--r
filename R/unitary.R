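## Unitary AP response extraction and the linear spectral model
## S(f) = Ssyn(f) + beta * Sap(f), where Sap is the energy spectrum of the
## unitary AP response and the fitted beta estimates the firing rate.

#' Detect spikes in a somatic-voltage trace
#'
#' Local maxima exceeding `minHeight` (default 0 mV), separated by at
#' least `refractory` samples; of two peaks closer than that, the larger
#' wins.
#'
#' @param voltage single-channel [TimeSeries-class] (mV).
#' @param minHeight minimum peak height (mV).
#' @param refractory minimum separation in samples.
#' @return spike times in ms (possibly empty), ordered.
#' @export
detectSpikes <- function(voltage, minHeight = 0, refractory = 1L) {
  stopifnot(is(voltage, "TimeSeries"))
  if (ncol(voltage@samples) != 1)
    stop("spike detection expects a single-channel voltage trace")
  v <- voltage@samples[, 1]
  n <- length(v)
  if (n < 3) return(numeric(0))
  isPeak <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] &
                v[2:(n - 1)] >= v[3:n], FALSE) & v > minHeight
  idx <- which(isPeak)
  if (length(idx) > 1 && refractory > 1) {
    keep <- logical(length(idx))
    last <- -Inf
    for (k in order(-v[idx])) {        # greedy by height
      if (all(abs(idx[k] - idx[keep]) >= refractory)) keep[k] <- TRUE
    }
    idx <- sort(idx[keep])
  }
  (idx - 1L) * voltage@dt
}

#' Spike-triggered average of the AP dipole component
#'
#' Averages `active - passive` over windows aligned to the spike times,
#' yielding the unitary AP response. Spikes whose window would run off
#' the record are dropped and counted; at least 10 usable spikes are
#' required for a stable average.
#'
#' @param active,passive 3-channel [TimeSeries-class] with equal `dt` and
#'   length.
#' @param spikes spike times (ms).
#' @param window (pre, post) in ms around the spike peak; default
#'   (-10, 150) captures slow AHP tails.
#' @param minSpikes minimum usable spikes.
#' @param excludeOverlaps drop spikes closer than the window span to
#'   their neighbour (off by default: a plain STA includes them).
#' @return a [UnitaryKernel-class]; attribute `nUsed` / `nDropped` count
#'   spikes.
#' @export
spikeTriggeredAverage <- function(active, passive, spikes,
                                  window = c(-10, 150), minSpikes = 10,
                                  excludeOverlaps = FALSE) {
  stopifnot(is(active, "TimeSeries"), is(passive, "TimeSeries"))
  if (abs(active@dt - passive@dt) > 1e-12)
    stop("active and passive traces must share a sampling interval")
  if (nrow(active@samples) != nrow(passive@samples))
    stop("active and passive traces must have equal length")
  dt <- active@dt
  d <- active@samples - passive@samples
  n <- nrow(d)
  off <- round(window[1] / dt)
  len <- round(diff(window) / dt) + 1L
  idx <- round(spikes / dt) + 1L
  usable <- idx + off >= 1L & idx + off + len - 1L <= n
  if (excludeOverlaps && length(spikes) > 1) {
    isi <- diff(spikes)
    close <- c(isi < diff(window), FALSE) | c(FALSE, isi < diff(window))
    usable <- usable & !close
  }
  nUse <- sum(usable)
  if (nUse < minSpikes)
    stop(sprintf("only %d usable spike(s); at least %d required",
                 nUse, minSpikes))
  acc <- matrix(0, len, ncol(d))
  for (i in idx[usable]) {
    rows <- (i + off):(i + off + len - 1L)
    acc <- acc + d[rows, , drop = FALSE]
  }
  out <- UnitaryKernel(t(acc / nUse), dt, window, classLabel = "sta")
  attr(out, "nUsed") <- nUse
  attr(out, "nDropped") <- length(spikes) - nUse
  out
}

#' Fit the linear AP spectral model
#'
#' Least-squares estimate of the scaling factor `beta` in
#' `S(f) = Ssyn(f) + beta * Sap(f)` over a frequency band, with
#' log-spaced weighting (each bin weighted by its local d(log f), so
#' every decade contributes equally). `Sap` must be an energy spectrum;
#' its densities (value^2*ms/Hz) are converted to value^2*s/Hz inside the
#' fit so that `beta` comes out in spikes per second. By default `beta`
#' is constrained to be non-negative (it estimates a rate).
#'
#' @param S power [Spectrum-class] of the active (spiking) signal.
#' @param Ssyn power [Spectrum-class] of the synaptic (passive) signal.
#' @param Sap energy [Spectrum-class] of the unitary AP response.
#' @param band fit band (Hz), default c(1, 500).
#' @param nonNegative constrain beta >= 0.
#' @return a [LinearFitResult-class].
#' @export
fitLinearApModel <- function(S, Ssyn, Sap, band = c(1, 500),
                             nonNegative = TRUE) {
  stopifnot(is(S, "Spectrum"), is(Ssyn, "Spectrum"), is(Sap, "Spectrum"))
  if (length(S@freqs) != length(Ssyn@freqs) ||
      length(S@freqs) != length(Sap@freqs) ||
      any(abs(S@freqs - Ssyn@freqs) > 1e-9) ||
      any(abs(S@freqs - Sap@freqs) > 1e-9))
    stop("S, Ssyn and Sap must share a common frequency grid")
  sel <- S@freqs >= band[1] & S@freqs <= band[2]
  if (!any(sel)) stop("band contains no frequency bins")
  f <- S@freqs[sel]
  y <- Re(S@values)[sel] - Re(Ssyn@values)[sel]
  x <- Re(Sap@values)[sel] * MS_TO_S    # -> value^2*s/Hz, beta in 1/s
  if (all(x == 0))
    stop("Sap is identically zero over the band; beta is unidentifiable")
  w <- c(diff(log(f)), 0)
  w[length(w)] <- w[length(w) - 1]
  beta <- sum(w * x * y) / sum(w * x^2)
  if (nonNegative) beta <- max(beta, 0)
  resid <- y - beta * x
  sTot <- Re(S@values)[sel]
  ssTot <- sum(w * (sTot - stats::weighted.mean(sTot, w))^2)
  ssRes <- sum(w * resid^2)
  r2 <- if (ssTot > 0) 1 - ssRes / ssTot else 1
  new("LinearFitResult", beta = beta, rSquared = min(r2, 1),
      residual = Spectrum(f, resid, units = S@units, kind = "cross"))
}
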