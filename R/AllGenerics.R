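#' @name accessors
#' @title Accessors for apEEG classes
#' @description Slot access for the package's S4 containers. Use these in
#'   preference to `@`.
#' @param object an apEEG S4 object.
NULL

#' @rdname accessors
#' @export
setGeneric("freqs", function(object) standardGeneric("freqs"))
#' @rdname accessors
#' @export
setMethod("freqs", "Spectrum", function(object) object@freqs)

#' @rdname accessors
#' @export
setGeneric("specValues", function(object) standardGeneric("specValues"))
#' @rdname accessors
#' @export
setMethod("specValues", "Spectrum", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("specUnits", function(object) standardGeneric("specUnits"))
#' @rdname accessors
#' @export
setMethod("specUnits", "Spectrum", function(object) object@units)

#' @rdname accessors
#' @export
setGeneric("specKind", function(object) standardGeneric("specKind"))
#' @rdname accessors
#' @export
setMethod("specKind", "Spectrum", function(object) object@kind)

#' @rdname accessors
#' @export
setGeneric("sampleInterval", function(object) standardGeneric("sampleInterval"))
#' @rdname accessors
#' @export
setMethod("sampleInterval", "TimeSeries", function(object) object@dt)
#' @rdname accessors
#' @export
setMethod("sampleInterval", "UnitaryKernel", function(object) object@dt)

#' @rdname accessors
#' @export
setGeneric("tsSamples", function(object) standardGeneric("tsSamples"))
#' @rdname accessors
#' @export
setMethod("tsSamples", "TimeSeries", function(object) object@samples)

#' @rdname accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setMethod("nChannels", "TimeSeries", function(object) ncol(object@samples))

#' @rdname accessors
#' @export
setGeneric("kernelWaveform", function(object) standardGeneric("kernelWaveform"))
#' @rdname accessors
#' @export
setMethod("kernelWaveform", "UnitaryKernel", function(object) object@waveform)

#' @rdname accessors
#' @export
setGeneric("kernelWindow", function(object) standardGeneric("kernelWindow"))
#' @rdname accessors
#' @export
setMethod("kernelWindow", "UnitaryKernel", function(object) object@window)

#' @rdname accessors
#' @export
setGeneric("classLabel", function(object) standardGeneric("classLabel"))
#' @rdname accessors
#' @export
setMethod("classLabel", "UnitaryKernel", function(object) object@classLabel)

#' @rdname accessors
#' @export
setGeneric("segmentMidpoints",
           function(object) standardGeneric("segmentMidpoints"))
#' @rdname accessors
#' @export
setMethod("segmentMidpoints", "Morphology", function(object) object@midpoints)

#' @rdname accessors
#' @export
setGeneric("segmentVolumes",
           function(object) standardGeneric("segmentVolumes"))
#' @rdname accessors
#' @export
setMethod("segmentVolumes", "Morphology", function(object) object@volumes)

#' @rdname accessors
#' @export
setGeneric("perClassSpectra",
           function(object) standardGeneric("perClassSpectra"))
#' @rdname accessors
#' @export
setMethod("perClassSpectra", "MeanUnitarySpectrum",
          function(object) object@perClass)

#' @rdname accessors
#' @export
setGeneric("classEnergies", function(object) standardGeneric("classEnergies"))
#' @rdname accessors
#' @export
setMethod("classEnergies", "MeanUnitarySpectrum",
          function(object) object@classEnergies)

#' @rdname accessors
#' @export
setGeneric("classWeights", function(object) standardGeneric("classWeights"))
#' @rdname accessors
#' @export
setMethod("classWeights", "MeanUnitarySpectrum",
          function(object) object@weights)

#' @rdname accessors
#' @export
setGeneric("fittedBeta", function(object) standardGeneric("fittedBeta"))
#' @rdname accessors
#' @export
setMethod("fittedBeta", "LinearFitResult", function(object) object@beta)

#' @rdname accessors
#' @export
setGeneric("fitRSquared", function(object) standardGeneric("fitRSquared"))
#' @rdname accessors
#' @export
setMethod("fitRSquared", "LinearFitResult", function(object) object@rSquared)

#' Energy spectrum of a finite-duration kernel
#'
#' One-sided energy spectral density `|FT u|^2` of a finite kernel, on the
#' FFT frequency grid. The integral over frequency (Hz) equals the kernel
#' energy `sum(u(t)^2) * dt` with `dt` in ms, so densities carry units
#' value^2*ms/Hz. Multi-channel kernels (e.g. 3-component dipoles) are
#' summed across channels.
#'
#' @param kernel a [TimeSeries-class] or [UnitaryKernel-class].
#' @param ... unused.
#' @return a [Spectrum-class] of kind `"energy"`.
#' @export
setGeneric("energySpectrum", function(kernel, ...)
  standardGeneric("energySpectrum"))

#' Dendrite asymmetry index
#'
#' Measures how far the volume-weighted centroid of a dendritic arbour
#' lies from the soma, normalized coordinate-wise by the spread of the
#' segment midpoints:
#' `AI = || (sum_i V_i x_i) / sqrt( (1/(N-1)) sum_i x_i * x_i ) ||`
#' with element-wise division and product, and the convention that a
#' coordinate with zero spread (0/0) contributes nothing. Larger values
#' predict stronger unitary scalp signals (open-field-like arbours);
#' point-symmetric equal-volume arbours score 0.
#'
#' @param m a [Morphology-class] with at least 2 segments.
#' @return non-negative scalar (scale is arbitrary; comparisons of AI are
#'   invariant to rescaling the morphology units).
#' @export
setGeneric("asymmetryIndex", function(m) standardGeneric("asymmetryIndex"))
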