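.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                SE = 1.90, H = 1.20)

elementRadius <- function(element) {
  r <- .VDW_RADII[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

# canonical molecular frame: centroid origin, principal axes, signs fixed by
# third moments. Because the sphere sampling grid is laid out in this frame,
# SASA is invariant under rigid transforms of the input coordinates (the
# canonical coordinates agree to rounding error).
.canonicalFrame <- function(xyz) {
  xc <- sweep(xyz, 2, colMeans(xyz))
  if (nrow(xc) < 3) return(xc)
  ev <- eigen(crossprod(xc), symmetric = TRUE)
  y <- xc %*% ev$vectors
  for (k in 1:3) {
    s <- sum(y[, k]^3)
    if (s < 0) y[, k] <- -y[, k]
  }
  y
}

# deterministic near-uniform sphere point set (golden spiral)
spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Sphere-sampling SASA: each heavy atom is expanded by the probe radius and
#' sampled with a deterministic golden-spiral point set; a point is
#' accessible iff it lies outside every neighbouring expanded sphere. The
#' per-residue SASA is the sum over the residue's atoms. Accuracy improves
#' with \code{nPoints}; results are rotation- and translation-invariant up to
#' the sampling resolution.
#'
#' @param track a [StructureTrack-class] with heavy-atom coordinates, or a
#'   data.frame of atoms (\code{residue, element, x, y, z}).
#' @param probeRadius solvent probe radius in Angstrom (water = 1.4).
#' @param nPoints sphere sample points per atom (>= 100).
#' @return list: \code{sasa} per residue (Angstrom^2), \code{atomSasa} per
#'   atom.
#' @export
computeSasa <- function(track, probeRadius = 1.4, nPoints = 960) {
  stopifnot(nPoints >= 100)
  atoms <- if (methods::is(track, "StructureTrack")) track@atoms else track
  if (!nrow(atoms)) stop("no atoms available for SASA")
  xyz <- .canonicalFrame(as.matrix(atoms[, c("x", "y", "z")]))
  R <- elementRadius(atoms$element) + probeRadius
  n <- nrow(xyz)
  pts <- spherePoints(nPoints)
  atomSasa <- numeric(n)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (R[i] + R)^2 & seq_len(n) != i)
    if (!length(nb)) {
      atomSasa[i] <- 4 * pi * R[i]^2
      next
    }
    p <- pts * R[i]
    p <- sweep(p, 2, xyz[i, ], `+`)
    free <- rep(TRUE, nPoints)
    for (j in nb) {
      dd <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      free <- free & dd >= R[j]^2
      if (!any(free)) break
    }
    atomSasa[i] <- 4 * pi * R[i]^2 * sum(free) / nPoints
  }
  sasaRes <- vapply(split(atomSasa, atoms$residue), sum, 0)
  L <- max(atoms$residue)
  out <- numeric(L)
  out[as.integer(names(sasaRes))] <- sasaRes
  list(sasa = out, atomSasa = atomSasa)
}

#' Maximum per-residue SASA reference values
#'
#' \code{"empirical"} returns the Tien et al empirical maximum accessible
#' surface areas of residues in a Gly-X-Gly context (Tyr = 255 Angstrom^2),
#' the normalisation used for relative solvent accessibility of real
#' all-atom models. \code{"calpha"} returns the analytic SASA of a C-alpha
#' sphere flanked by two bonded neighbours in a straight chain (the same
#' quantity for every residue), the appropriate reference for the package's
#' reduced C-alpha models.
#'
#' @param type \code{"empirical"} or \code{"calpha"}.
#' @param probeRadius probe radius used for the C-alpha reference.
#' @return named numeric vector over the 20 amino acids (Angstrom^2).
#' @export
maxSasaReference <- function(type = c("empirical", "calpha"),
                             probeRadius = 1.4) {
  type <- match.arg(type)
  if (type == "empirical") {
    return(c(A = 121, C = 148, D = 187, E = 214, F = 228, G = 97, H = 216,
             I = 195, K = 230, L = 191, M = 203, N = 187, P = 154, Q = 214,
             R = 265, S = 143, T = 163, V = 165, W = 264, Y = 255))
  }
  R <- 1.70 + probeRadius
  bond <- 3.8
  capFrac <- (1 - bond / (2 * R)) / 2       # spherical cap cut per neighbour
  area <- 4 * pi * R^2 * (1 - 2 * capFrac)
  setNames(rep(area, 20), AA20)
}
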