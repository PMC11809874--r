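## Source geometry and lead fields. Unit conventions are fixed package-wide:
## positions in mm, dipole moments in nA.um, potentials in uV, conductivity
## in S/m. The single conversion from SI to these units lives in
## leadFieldInfinite().

#' Analytic infinite-medium lead field
#'
#' Point-electrode potential of a current dipole in an infinite homogeneous
#' conductor: `phi = p . r_hat / (4 pi sigma |r|^2)` with `r` running from
#' the source to the electrode. Serves as the analytic surrogate for a
#' realistic head model: it preserves the 1/r^2 falloff and the
#' orientation selectivity that drive the ensemble statistics.
#'
#' @param electrode electrode position (mm), numeric length 3.
#' @param conductivity tissue conductivity (S/m), default 0.33.
#' @return a [LeadField-class] whose evaluator maps a source position (mm)
#'   to the 3-vector nu in uV per nA.um.
#' @examples
#' lf <- leadFieldInfinite(c(0, 0, 10))
#' sum(lf@evaluator(c(0, 0, 0)) * c(0, 0, 1)) * 1e6   # 2.4115 pV
#' @export
leadFieldInfinite <- function(electrode, conductivity = 0.33) {
  stopifnot(length(electrode) == 3, conductivity > 0)
  force(electrode); force(conductivity)
  ## 1 nA.um = 1e-15 A.m; mm^2 = 1e-6 m^2; output uV = 1e6 V
  ## => prefactor 1e-15 * 1e6 / (1e-6) = 1e-3 in (mm, nA.um, uV) units
  ev <- function(position) {
    r <- electrode - position
    d2 <- sum(r^2)
    if (d2 == 0) stop("lead field is singular: source at the electrode")
    1e-3 * r / (4 * pi * conductivity * d2^1.5)
  }
  LeadField(ev, provenance = "analytic-infinite-medium")
}

#' Lead field from a precomputed table
#'
#' Wraps a matrix of lead-field vectors at known source positions
#' (nearest-neighbour lookup), e.g. loaded from a head-model export
#' (positions CSV + nu CSV). Reproduces analytic values exactly when the
#' table was generated from an analytic model at the same positions.
#'
#' @param positions N x 3 matrix of source positions (mm).
#' @param nu N x 3 matrix of lead-field vectors (uV per nA.um).
#' @return a [LeadField-class] with provenance `"file"`.
#' @export
leadFieldFromTable <- function(positions, nu) {
  positions <- as.matrix(positions); nu <- as.matrix(nu)
  stopifnot(ncol(positions) == 3, ncol(nu) == 3,
            nrow(positions) == nrow(nu))
  ev <- function(position) {
    d2 <- colSums((t(positions) - position)^2)
    nu[which.min(d2), ]
  }
  LeadField(ev, provenance = "file")
}

#' Spherical cortex geometry
#'
#' @param radius sphere radius (mm).
#' @param density areal neuron density (neurons/mm^2).
#' @return a [CortexGeometry-class] of type `"sphere"`.
#' @export
sphereGeometry <- function(radius = 50, density = 1) {
  area <- 4 * pi * radius^2
  new("CortexGeometry", type = "sphere", radius = radius,
      vertices = matrix(numeric(0), 0, 3),
      faces = matrix(integer(0), 0, 3),
      density = density, nNeurons = density * area)
}

#' Triangle-mesh cortex geometry
#'
#' @param vertices V x 3 matrix (mm).
#' @param faces F x 3 matrix of 1-based vertex indices.
#' @param density areal neuron density (neurons/mm^2).
#' @return a [CortexGeometry-class] of type `"mesh"`. Degenerate
#'   (zero-area) faces are dropped with a warning count.
#' @export
meshGeometry <- function(vertices, faces, density = 1) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  a <- faceAreas(vertices, faces)
  bad <- a <= 0 | !is.finite(a)
  if (any(bad)) {
    warning(sprintf("%d degenerate face(s) skipped", sum(bad)))
    faces <- faces[!bad, , drop = FALSE]
    a <- a[!bad]
  }
  new("CortexGeometry", type = "mesh", radius = NA_real_,
      vertices = vertices, faces = faces, density = density,
      nNeurons = density * sum(a))
}

#' Read a mesh from vertex/face CSV files
#'
#' @param vertexPath CSV with columns x, y, z (mm).
#' @param facePath CSV with columns v1, v2, v3 (1-based indices).
#' @param density areal neuron density (neurons/mm^2).
#' @return a [CortexGeometry-class].
#' @export
readMeshCsv <- function(vertexPath, facePath, density = 1) {
  v <- utils::read.csv(vertexPath)
  f <- utils::read.csv(facePath)
  meshGeometry(v[, c("x", "y", "z")], f[, 1:3], density = density)
}

faceAreas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c <- vertices[faces[, 3], , drop = FALSE]
  cr <- cross3(b - a, c - a)
  0.5 * sqrt(rowSums(cr^2))
}

cross3 <- function(u, v) {
  if (is.null(dim(u))) u <- matrix(u, 1)
  if (is.null(dim(v))) v <- matrix(v, 1)
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Total surface area of a geometry
#' @param geometry a [CortexGeometry-class].
#' @return area in mm^2.
#' @export
surfaceArea <- function(geometry) {
  if (geometry@type == "sphere") 4 * pi * geometry@radius^2
  else sum(faceAreas(geometry@vertices, geometry@faces))
}

#' Quasi-uniform or random points on a geometry
#'
#' Deterministic Fibonacci-lattice sampling is available on spheres (used
#' for location averaging so that repeated runs agree exactly); meshes and
#' `method = "random"` sample uniformly by area.
#'
#' @param geometry a [CortexGeometry-class].
#' @param n number of points.
#' @param method `"fibonacci"` (spheres only) or `"random"`.
#' @param seed RNG seed for random sampling.
#' @return list with `points` (n x 3, mm) and `normals` (n x 3, unit).
#' @export
surfacePoints <- function(geometry, n, method = c("fibonacci", "random"),
                          seed = 1) {
  method <- match.arg(method)
  if (geometry@type == "sphere") {
    R <- geometry@radius
    if (method == "fibonacci") {
      i <- seq_len(n) - 0.5
      z <- 1 - 2 * i / n
      phi <- 2 * pi * i * (sqrt(5) - 1) / 2
      s <- sqrt(pmax(1 - z^2, 0))
      dirs <- cbind(s * cos(phi), s * sin(phi), z)
    } else {
      set.seed(seed)
      dirs <- matrix(stats::rnorm(3 * n), ncol = 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
    }
    return(list(points = R * dirs, normals = dirs))
  }
  set.seed(seed)
  a <- faceAreas(geometry@vertices, geometry@faces)
  fi <- sample.int(length(a), n, replace = TRUE, prob = a)
  u <- stats::runif(n); v <- stats::runif(n)
  flip <- u + v > 1
  u[flip] <- 1 - u[flip]; v[flip] <- 1 - v[flip]
  A <- geometry@vertices[geometry@faces[fi, 1], , drop = FALSE]
  B <- geometry@vertices[geometry@faces[fi, 2], , drop = FALSE]
  C <- geometry@vertices[geometry@faces[fi, 3], , drop = FALSE]
  pts <- A + u * (B - A) + v * (C - A)
  nrm <- cross3(B - A, C - A)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  ## orient outward from the mesh centroid
  ctr <- colMeans(geometry@vertices)
  out <- rowSums(nrm * sweep(pts, 2, ctr)) < 0
  nrm[out, ] <- -nrm[out, ]
  list(points = pts, normals = nrm)
}

#' Orthonormal source frame from an outward normal
#'
#' Columns are (tangent1, tangent2, normal), right-handed; the neuron's
#' apical-basal (z) axis maps onto the local outward normal, emulating the
#' perpendicular embedding of cortical neurons.
#'
#' @param normal unit outward normal.
#' @param azimuth tangent-plane rotation (radians).
#' @return 3 x 3 rotation matrix, det +1.
#' @export
orientationFrame <- function(normal, azimuth = 0) {
  n <- normal / sqrt(sum(normal^2))
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  t1 <- cross3(a, n)[1, ]; t1 <- t1 / sqrt(sum(t1^2))
  t2 <- cross3(n, t1)[1, ]
  ca <- cos(azimuth); sa <- sin(azimuth)
  cbind(ca * t1 + sa * t2, -sa * t1 + ca * t2, n)
}

#' PlacedPopulation: neurons embedded in the cortical geometry
#'
#' @slot classes character class label per neuron.
#' @slot excitatory logical per neuron.
#' @slot positions N x 3 matrix (mm).
#' @slot frames list of 3 x 3 orientation frames (columns t1, t2, normal).
#' @export
setClass("PlacedPopulation",
  representation(classes = "character", excitatory = "logical",
                 positions = "matrix", frames = "list"))

setMethod("show", "PlacedPopulation", function(object) {
  cat(sprintf("PlacedPopulation: %d neurons (%d excitatory), %d class(es)\n",
              length(object@classes), sum(object@excitatory),
              length(unique(object@classes))))
})

#' Place a neuron population on the cortex
#'
#' Samples neuron positions uniformly by area, assigns classes with
#' probability proportional to abundance, and builds an orientation frame
#' per neuron whose z-axis is the local outward normal (apical-basal axis
#' perpendicular to the surface) with a random azimuth.
#'
#' @param geometry a [CortexGeometry-class].
#' @param population data.frame with columns `name`, `excitatory`,
#'   `abundance` (see [makePopulation()]).
#' @param n number of neurons to place.
#' @param seed RNG seed.
#' @return a [PlacedPopulation-class].
#' @export
placePopulation <- function(geometry, population, n, seed = 1) {
  stopifnot(is(geometry, "CortexGeometry"), n >= 1)
  sp <- surfacePoints(geometry, n, method = "random", seed = seed)
  set.seed(seed + 1L)
  ki <- sample.int(nrow(population), n, replace = TRUE,
                   prob = population$abundance)
  az <- stats::runif(n, 0, 2 * pi)
  frames <- lapply(seq_len(n),
                   function(i) orientationFrame(sp$normals[i, ], az[i]))
  new("PlacedPopulation", classes = as.character(population$name[ki]),
      excitatory = as.logical(population$excitatory[ki]),
      positions = sp$points, frames = frames)
}

## Area of (triangle intersect Euclidean ball) by recursive subdivision.
triBallArea <- function(A, B, C, ctr, r, depth = 5) {
  d <- sqrt(c(sum((A - ctr)^2), sum((B - ctr)^2), sum((C - ctr)^2)))
  area <- 0.5 * sqrt(sum(cross3(B - A, C - A)^2))
  if (all(d <= r)) return(area)
  edge <- max(sqrt(sum((A - B)^2)), sqrt(sum((B - C)^2)),
              sqrt(sum((C - A)^2)))
  if (min(d) - edge > r) return(0)
  if (depth == 0) return(area * sum(d <= r) / 3)
  ab <- (A + B) / 2; bc <- (B + C) / 2; ca <- (C + A) / 2
  triBallArea(A, ab, ca, ctr, r, depth - 1) +
    triBallArea(ab, B, bc, ctr, r, depth - 1) +
    triBallArea(ca, bc, C, ctr, r, depth - 1) +
    triBallArea(ab, bc, ca, ctr, r, depth - 1)
}

ballSurfaceArea <- function(geometry, ctr, r) {
  if (geometry@type == "sphere") {
    ## exact: a Euclidean ball of radius r centred on the sphere surface
    ## cuts a cap of area pi r^2 (for r <= 2R)
    R <- geometry@radius
    if (r >= 2 * R) 4 * pi * R^2 else pi * r^2
  } else {
    v <- geometry@vertices; fc <- geometry@faces
    tot <- 0
    for (k in seq_len(nrow(fc)))
      tot <- tot + triBallArea(v[fc[k, 1], ], v[fc[k, 2], ], v[fc[k, 3], ],
                               ctr, r)
    tot
  }
}

#' Pair-distance density dN(r)
#'
#' The expected number of neighbouring neurons per mm of Euclidean
#' separation from a source on the cortex. For each of `nCenters` surface
#' points, the cortical surface area inside a Euclidean ball of radius r
#' is computed (triangle clipping on meshes; the exact cap identity on
#' spheres), converted to a neighbour count via the areal density, and
#' differentiated by central differences on the radii grid. The result is
#' scaled by (N-1)/N so it integrates to one less than the total neuron
#' count per source.
#'
#' @param geometry a [CortexGeometry-class].
#' @param radii increasing grid starting at 0 (mm).
#' @param nCenters number of ball centres averaged.
#' @param seed RNG seed for centre sampling.
#' @return a [PairDensity-class].
#' @export
pairDistanceDensity <- function(geometry, radii, nCenters = 20, seed = 1) {
  stopifnot(is(geometry, "CortexGeometry"))
  if (length(radii) < 3 || radii[1] != 0 || any(diff(radii) <= 0))
    stop("radii must be strictly increasing from 0")
  centers <- surfacePoints(geometry, nCenters, method = "random",
                           seed = seed)$points
  if (geometry@type == "sphere") nCenters <- 1L  # all centres equivalent
  counts <- matrix(0, nCenters, length(radii))
  for (i in seq_len(nCenters))
    for (j in seq_along(radii))
      counts[i, j] <- geometry@density *
        ballSurfaceArea(geometry, centers[i, ], radii[j])
  avg <- colMeans(counts)
  ## central differences in the interior, one-sided at the ends
  n <- length(radii)
  d <- numeric(n)
  d[1] <- (avg[2] - avg[1]) / (radii[2] - radii[1])
  d[n] <- (avg[n] - avg[n - 1]) / (radii[n] - radii[n - 1])
  if (n > 2)
    d[2:(n - 1)] <- (avg[3:n] - avg[1:(n - 2)]) /
      (radii[3:n] - radii[1:(n - 2)])
  d[1] <- 0   # no neighbours at zero separation
  scale <- (geometry@nNeurons - 1) / geometry@nNeurons
  PairDensity(radii, pmax(d * scale, 0))
}

#' Displace a surface point by a Euclidean distance
#'
#' Returns a point on the geometry at (approximately, exactly on spheres)
#' the requested Euclidean distance from `point`, in a uniformly random
#' surface direction, together with its outward normal. Used by the
#' continuum Monte Carlo pair sampler.
#'
#' @param geometry a [CortexGeometry-class] (sphere support only).
#' @param point source position (mm) on the surface.
#' @param r Euclidean displacement (mm), <= 2R.
#' @return list(point, normal).
#' @export
displaceOnSurface <- function(geometry, point, r) {
  if (geometry@type != "sphere")
    stop("continuum displacement sampling is implemented for spheres; ",
         "use the discrete pair sampler for meshes")
  R <- geometry@radius
  n0 <- point / sqrt(sum(point^2))
  theta <- 2 * asin(min(r / (2 * R), 1))   # geodesic angle for chord r
  fr <- orientationFrame(n0, stats::runif(1, 0, 2 * pi))
  dir <- fr[, 1]
  nNew <- cos(theta) * n0 + sin(theta) * dir
  list(point = R * nNew, normal = nNew)
}
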