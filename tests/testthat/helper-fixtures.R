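## Shared fixtures, built once per run. The "patch" fixture is a small
## spherical cortical patch (R = 8 mm) holding 50 neurons, dense enough
## that neighbours fall within the spatial synchrony scale (sigmaX =
## sqrt(3) mm), so the pair term is non-trivial.

.fixtures <- new.env()

fixtureCached <- function(name, build) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

patchLeadField <- function() leadFieldInfinite(c(0, 0, 16))

patchGeometry <- function() sphereGeometry(8, density = 50 / (4 * pi * 8^2))

patchPopulation <- function() fixtureCached("patchPop", function()
  makePopulation(excFraction = 0.85, nClasses = 4, seed = 5))

patchClasses <- function() fixtureCached("patchClasses", function()
  populationClasses(patchPopulation()))

patchBank <- function() fixtureCached("patchBank", function()
  calibrateKernelBank(makeKernelBank(patchClasses(), dt = 0.5),
                      patchClasses(), patchGeometry(), patchLeadField()))

patchPlaced <- function() fixtureCached("patchPlaced", function()
  placePopulation(patchGeometry(), patchPopulation(), 50, seed = 7))

patchFreqs <- function() exp(seq(log(1), log(1000), length.out = 40))

patchSynchrony <- function(sigmaT = 11.3, f0 = 0, rmax = 0.2)
  SynchronyParams(lambda = 1, rmax = rmax, sigmaX = sqrt(3),
                  sigmaT = sigmaT, f0 = f0)

## Brain-scale fixture for the unitary-energy and detectability checks.
brainMeanSpectrum <- function() fixtureCached("brainMS", function() {
  geom <- sphereGeometry(50, density = 16e9 / (4 * pi * 50^2))
  lf <- leadFieldInfinite(c(0, 0, 58))
  pop <- makePopulation(excFraction = 0.85, nClasses = 6, seed = 1)
  classes <- populationClasses(pop)
  bank <- calibrateKernelBank(makeKernelBank(classes), classes, geom, lf)
  meanUnitarySpectrum(bank, classes, geom, lf)
})

## Test kernel for the unitary-response pipeline.
unitKernel <- function(dt = 0.5) fixtureCached("unitKernel", function()
  makeClassKernel(NeuronClassSpec("E01", kernelParams =
                                    list(amplitude = 1)), dt = 0.5))

## Fit beta at one firing rate through the full synthetic pipeline.
pipelineBeta <- function(lambda, seed, duration = 60000, noiseSd = 0.05) {
  k <- unitKernel()
  tr <- makeActivePassiveTraces(k, lambda, duration = duration,
                                noiseSd = noiseSd, seed = seed)
  S <- estimatePsd(tr$active)
  Ssyn <- estimatePsd(tr$passive)
  fitLinearApModel(S, Ssyn, energySpectrumAt(k, freqs(S)), band = c(1, 500))
}

## Square flat mesh patch in the z = 0 plane, for pair-density checks.
flatPatchMesh <- function(halfSide = 30, step = 2) {
  g <- expand.grid(x = seq(-halfSide, halfSide, by = step),
                   y = seq(-halfSide, halfSide, by = step))
  side <- length(seq(-halfSide, halfSide, by = step))
  vid <- matrix(seq_len(nrow(g)), side, side)
  fcs <- matrix(0L, 2 * (side - 1)^2, 3)
  r <- 1L
  for (i in 1:(side - 1)) for (j in 1:(side - 1)) {
    fcs[r, ] <- c(vid[i, j], vid[i + 1, j], vid[i, j + 1])
    fcs[r + 1L, ] <- c(vid[i + 1, j], vid[i + 1, j + 1], vid[i, j + 1])
    r <- r + 2L
  }
  meshGeometry(cbind(g$x, g$y, 0), fcs, density = 1)
}

## Minimal SWC writer for morphometry tests.
writeSwc <- function(rows, path = tempfile(fileext = ".swc")) {
  writeLines(c("# synthetic test morphology", rows), path)
  path
}
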