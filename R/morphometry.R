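## Dendritic morphometry: SWC parsing into truncated-cone segments and the
## volume-weighted dendrite asymmetry index.

#' Read a neuron morphology from an SWC file
#'
#' Parses the standard 7-column SWC format (`id type x y z radius parent`,
#' '#' comments) into a cone-segment [Morphology-class]. Only dendritic
#' nodes (SWC types 3 and 4) generate segments; each segment runs from the
#' parent node to the child node, with volume
#' `(1/3) pi L (r1^2 + r1 r2 + r2^2)` and midpoint halfway between the two
#' nodes. All coordinates are re-expressed relative to the soma (the
#' centroid of type-1 nodes), so translated files load identically.
#'
#' @param path SWC file path.
#' @return a [Morphology-class].
#' @export
readSwcMorphology <- function(path) {
  lines <- readLines(path)
  raw <- trimws(lines)
  keep <- which(nzchar(raw) & !startsWith(raw, "#"))
  if (length(keep) == 0) stop("SWC file contains no data lines: ", path)
  fields <- strsplit(raw[keep], "[[:space:]]+")
  bad <- which(vapply(fields, length, 1L) != 7)
  if (length(bad))
    stop(sprintf("malformed SWC line %d (expected 7 columns): '%s'",
                 keep[bad[1]], raw[keep[bad[1]]]))
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 7, byrow = TRUE)
  nonNum <- which(apply(m, 1, function(r) any(!is.finite(r))))
  if (length(nonNum))
    stop(sprintf("malformed SWC line %d (non-numeric field): '%s'",
                 keep[nonNum[1]], raw[keep[nonNum[1]]]))
  colnames(m) <- c("id", "type", "x", "y", "z", "radius", "parent")

  soma <- m[m[, "type"] == 1, , drop = FALSE]
  if (nrow(soma) == 0) stop("SWC file has no soma node (type 1): ", path)
  origin <- colMeans(soma[, c("x", "y", "z"), drop = FALSE])

  idx <- match(m[, "parent"], m[, "id"])
  dend <- which(m[, "type"] %in% c(3, 4) & !is.na(idx))
  if (length(dend) == 0)
    stop("SWC file contains no dendritic segments (types 3/4): ", path)

  child <- m[dend, , drop = FALSE]
  parent <- m[idx[dend], , drop = FALSE]
  p1 <- parent[, c("x", "y", "z"), drop = FALSE]
  p2 <- child[, c("x", "y", "z"), drop = FALSE]
  len <- sqrt(rowSums((p2 - p1)^2))
  r1 <- parent[, "radius"]; r2 <- child[, "radius"]
  vol <- pi * len * (r1^2 + r1 * r2 + r2^2) / 3
  mid <- sweep((p1 + p2) / 2, 2, origin)
  ok <- len > 0
  Morphology(midpoints = unname(mid[ok, , drop = FALSE]),
             volumes = unname(vol[ok]))
}

#' @rdname asymmetryIndex
#' @export
setMethod("asymmetryIndex", "Morphology", function(m) {
  n <- length(m@volumes)
  if (n < 2)
    stop("the asymmetry index requires at least 2 segments ",
         "(the 1/(N-1) spread factor is undefined for N < 2)")
  num <- colSums(m@midpoints * m@volumes)
  spread <- sqrt(colSums(m@midpoints^2) / (n - 1))
  ## 0/0 convention: a coordinate with zero spread contributes nothing
  ratio <- ifelse(spread > 0, num / spread, 0)
  sqrt(sum(ratio^2))
})
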