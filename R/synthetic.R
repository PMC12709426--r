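## Synthetic bilayer and landscape generators with closed-form ground truth.
##
## These emulate the inputs of the three analyses (planar insertion, buckled
## sensing, free-energy post-processing): phosphate/tail bead clouds on a
## lattice with Gaussian thermal jitter, a single-mode sinusoidal buckle
## h(x) = A sin(2 pi x / lambda) along x, collinear backbone-bead peptides
## placed at prescribed depth and tilt, curvature-biased position samples,
## separable double-well free-energy surfaces, and exponential defect-area
## samples. Every generator attaches the parameters needed to predict the
## downstream estimate analytically, and is bit-reproducible under its seed.

#' Parameters for synthetic bilayers
#'
#' @param nPerLeaflet lipids per leaflet (default 92, the planar study
#'   system size).
#' @param targetAPL target area per lipid, Angstrom^2 (default 65).
#' @param thickness phosphate-plane separation, nm (default 4).
#' @param jitterXY,jitterZ Gaussian thermal jitter (sd, nm) applied to bead
#'   positions laterally and vertically.
#' @param buckleAmplitude buckle amplitude A, nm (0 = planar).
#' @param buckleWavelength buckle wavelength lambda, nm; the buckled box
#'   has Lx = lambda (single-mode buckle).
#' @param nTailBeads tail beads per lipid between the phosphate plane and
#'   the midplane.
#' @param moleculeName lipid residue name.
#' @param thinAmplitude,thinSigma,thinCenter optional programmed Gaussian
#'   thinning of the local thickness: amplitude (nm, > 0 thins), lateral
#'   sd (nm) and xy center (defaults to the box center).
#' @param seed RNG seed.
#' @return a `SyntheticBilayerParams` list.
#' @export
bilayerParams <- function(nPerLeaflet = 92L, targetAPL = 65, thickness = 4,
                          jitterXY = 0.05, jitterZ = 0.1,
                          buckleAmplitude = 0, buckleWavelength = 20,
                          nTailBeads = 4L, moleculeName = "POPC",
                          thinAmplitude = 0, thinSigma = 1,
                          thinCenter = NULL, seed = 1L) {
  stopifnot(nPerLeaflet >= 1, targetAPL > 0, thickness > 0,
            buckleAmplitude >= 0, buckleWavelength > 0, jitterXY >= 0,
            jitterZ >= 0)
  if (buckleAmplitude >= buckleWavelength / 4)
    .stopf("buckle amplitude %.3g >= lambda/4 = %.3g: height field would be too steep",
           buckleAmplitude, buckleWavelength / 4)
  structure(list(nPerLeaflet = as.integer(nPerLeaflet), targetAPL = targetAPL,
                 thickness = thickness, jitterXY = jitterXY, jitterZ = jitterZ,
                 buckleAmplitude = buckleAmplitude,
                 buckleWavelength = buckleWavelength,
                 nTailBeads = as.integer(nTailBeads),
                 moleculeName = moleculeName,
                 thinAmplitude = thinAmplitude, thinSigma = thinSigma,
                 thinCenter = thinCenter, seed = as.integer(seed)),
            class = "SyntheticBilayerParams")
}

#' Closed-form mean curvature of the synthetic buckle
#'
#' For `h(x) = A sin(k x)`, `k = 2*pi/lambda`, the Monge-gauge mean
#' curvature of the upper surface is
#' `H(x) = -A k^2 sin(k x) / (2 (1 + A^2 k^2 cos^2(k x))^(3/2))`;
#' the Gaussian curvature is identically zero.
#'
#' @param x positions, nm.
#' @param A amplitude, nm.
#' @param lambda wavelength, nm.
#' @return mean curvature, nm^-1.
#' @export
buckleMeanCurvature <- function(x, A, lambda) {
  k <- 2 * pi / lambda
  -A * k^2 * sin(k * x) / (2 * (1 + A^2 * k^2 * cos(k * x)^2)^1.5)
}

## lattice site coordinates for n lipids in an Lx x Ly box
.leafletLattice <- function(n, Lx, Ly) {
  nx <- max(1L, round(sqrt(n * Lx / Ly)))
  ny <- ceiling(n / nx)
  while (nx * ny < n) { nx <- nx + 1L; ny <- ceiling(n / nx) }
  sites <- expand.grid(ix = seq_len(nx) - 0.5, iy = seq_len(ny) - 0.5)
  sites <- sites[seq_len(n), ]
  cbind(x = sites$ix * Lx / nx, y = sites$iy * Ly / ny)
}

## one leaflet's beads for one frame (jitter applied); leaflet +1 upper/-1 lower
.leafletBeads <- function(lat, params, leaflet, box) {
  n <- nrow(lat)
  t2 <- params$thickness / 2
  nb <- 2L + params$nTailBeads            # NC3, PO4, tails
  x <- rep(lat[, 1], each = nb) + rnorm(n * nb, 0, params$jitterXY)
  y <- rep(lat[, 2], each = nb) + rnorm(n * nb, 0, params$jitterXY)
  ## per-bead offsets from the phosphate plane, along the leaflet normal
  off <- c(0.3, 0, -seq_len(params$nTailBeads) * t2 / (params$nTailBeads + 1))
  z0 <- leaflet * (t2 + rep(off, n) * 1)
  ## programmed local thinning moves the phosphate plane toward the midplane
  if (params$thinAmplitude != 0) {
    ctr <- if (is.null(params$thinCenter)) box[1:2] / 2 else params$thinCenter
    r <- minImageDistXY(rep(lat[, 1], each = nb), rep(lat[, 2], each = nb),
                        ctr[1], ctr[2], box)
    z0 <- z0 - leaflet * (params$thinAmplitude / 2) *
      exp(-r^2 / (2 * params$thinSigma^2))
  }
  ## buckle displacement rides on the (jitter-free) lattice x
  if (params$buckleAmplitude > 0)
    z0 <- z0 + params$buckleAmplitude *
      sin(2 * pi * rep(lat[, 1], each = nb) / params$buckleWavelength)
  z <- z0 + rnorm(n * nb, 0, params$jitterZ) + box[3] / 2
  cbind(x, y, z)
}

.bilayerMeta <- function(params) {
  n <- params$nPerLeaflet
  nb <- 2L + params$nTailBeads
  beadNames <- c("NC3", "PO4", paste0("C", seq_len(params$nTailBeads), "A"))
  data.frame(
    moleculeId = rep(seq_len(2L * n), each = nb),
    moleculeName = params$moleculeName,
    beadName = rep(beadNames, 2L * n),
    stringsAsFactors = FALSE)
}

.genBilayer <- function(params, nFrames, squareBox) {
  n <- params$nPerLeaflet
  aplNm2 <- params$targetAPL / .NM2_TO_A2
  area <- n * aplNm2
  if (squareBox) {
    Lx <- sqrt(area); Ly <- sqrt(area)
  } else {
    Lx <- params$buckleWavelength
    Ly <- area / Lx
  }
  Lz <- params$thickness + 2 * params$buckleAmplitude + 9
  box <- c(Lx, Ly, Lz)
  lat <- .leafletLattice(n, Lx, Ly)
  meta <- .bilayerMeta(params)
  coords <- withSeed(params$seed, lapply(seq_len(nFrames), function(i)
    rbind(.leafletBeads(lat, params, +1, box),
          .leafletBeads(lat, params, -1, box))))
  gt <- list(params = params, box = box,
             phosphatePlanes = c(upper = Lz / 2 + params$thickness / 2,
                                 lower = Lz / 2 - params$thickness / 2),
             A = params$buckleAmplitude, lambda = params$buckleWavelength,
             meanCurvature = function(x)
               buckleMeanCurvature(x, params$buckleAmplitude,
                                   params$buckleWavelength))
  newTrajectory(coords, box, (seq_len(nFrames) - 1) * 400, meta,
                groundTruth = gt)
}

#' Generate a planar bilayer trajectory
#'
#' Two phosphate lattices at `z = +/- thickness/2` (about the box center)
#' with Gaussian jitter, head beads above and tail beads interpolated
#' toward the midplane. The box satisfies `Lx*Ly / nPerLeaflet =
#' targetAPL` exactly.
#'
#' @param params from [bilayerParams()].
#' @param nFrames number of frames (400 ps spacing).
#' @param squareBox use a square box (default); with `FALSE` the box takes
#'   `Lx = buckleWavelength` as the buckled generator does, so that a
#'   zero-amplitude buckle is bitwise identical to the planar system.
#' @return a [Trajectory-class] with ground truth attached.
#' @export
genPlanarBilayer <- function(params = bilayerParams(), nFrames = 1L,
                             squareBox = TRUE) {
  params$buckleAmplitude <- 0
  .genBilayer(params, nFrames, squareBox)
}

#' Generate a quasi-1D buckled bilayer trajectory
#'
#' Both leaflets are displaced by `h(x) = A sin(2 pi x / lambda)` with
#' `Lx = lambda` (one full buckle period per box). Ground truth mean
#' curvature (see [buckleMeanCurvature()]) is attached; the Gaussian
#' curvature of this developable surface is identically zero.
#'
#' @param params from [bilayerParams()]; requires `buckleAmplitude <
#'   buckleWavelength/4`.
#' @param nFrames number of frames.
#' @return a [Trajectory-class] with ground truth attached.
#' @export
genBuckledBilayer <- function(params = bilayerParams(buckleAmplitude = 1),
                              nFrames = 1L) {
  .genBilayer(params, nFrames, squareBox = FALSE)
}

#' Place a collinear backbone-bead peptide on a frame
#'
#' Adds `nBackbone` collinear beads (0.35 nm spacing) whose center of mass
#' sits exactly `depth` below the local phosphate plane of the chosen
#' leaflet (mean z of that leaflet's phosphates within `radius` of the
#' lateral position, i.e. the same reference [insertionDepth()] uses), with
#' the axis at `tilt` degrees from +z.
#'
#' @param frame a [BeadFrame-class].
#' @param leaflet `"upper"` or `"lower"`.
#' @param depth insertion depth, nm; positive = toward the membrane core.
#' @param tilt axis angle from +z, degrees.
#' @param x,y lateral center-of-mass position (defaults to the box center).
#' @param nBackbone backbone bead count (default 21).
#' @param spacing bead spacing along the axis, nm.
#' @param radius cylinder radius for the local phosphate plane, nm.
#' @return a new [BeadFrame-class] including the peptide beads
#'   (moleculeName `"PEP"`, beadName `"BB"`).
#' @export
placePeptide <- function(frame, leaflet = c("upper", "lower"), depth = 0,
                         tilt = 90, x = NULL, y = NULL, nBackbone = 21L,
                         spacing = 0.35, radius = 1.0) {
  leaflet <- match.arg(leaflet)
  box <- frame@box
  if (is.null(x)) x <- box[1] / 2
  if (is.null(y)) y <- box[2] / 2
  leaf <- assignLeaflets(frame)
  m <- frame@beadMeta
  phos <- which(m$beadName == "PO4" &
                  leaf[as.character(m$moleculeId)] == leaflet)
  if (!length(phos)) .stopf("no phosphates on the %s leaflet", leaflet)
  p <- frame@positions
  d <- minImageDistXY(p[phos, 1], p[phos, 2], x, y, box)
  sel <- phos[d <= radius]
  if (!length(sel)) sel <- phos
  plane <- mean(p[sel, 3])
  sgn <- if (leaflet == "upper") 1 else -1
  comZ <- plane - sgn * depth
  th <- tilt * pi / 180
  u <- c(sin(th), 0, cos(th))
  s <- (seq_len(nBackbone) - (nBackbone + 1) / 2) * spacing
  beads <- cbind(x + s * u[1], y + s * u[2], comZ + s * u[3])
  if (any(beads[, 3] < 0 | beads[, 3] > box[3]))
    .stopf("peptide would exit the box in z (z range %.2f..%.2f, box %.2f)",
           min(beads[, 3]), max(beads[, 3]), box[3])
  pepMeta <- data.frame(moleculeId = max(m$moleculeId) + 1L,
                        moleculeName = "PEP", beadName = "BB",
                        stringsAsFactors = FALSE)[rep(1, nBackbone), ]
  newBeadFrame(rbind(p, beads), box, rbind(m, pepMeta), frame@time,
               wrap = FALSE)
}

#' Add a peptide to every frame of a trajectory
#'
#' Vectorized over frames; `depth`, `tilt`, `x` and `y` may be per-frame
#' vectors (recycled), which is how biased lateral sampling or programmed
#' depth fluctuations are injected.
#'
#' @inheritParams placePeptide
#' @param trajectory a [Trajectory-class].
#' @return a new [Trajectory-class] with the peptide beads appended.
#' @export
addPeptide <- function(trajectory, leaflet = "upper", depth = 0, tilt = 90,
                       x = NULL, y = NULL, nBackbone = 21L, spacing = 0.35,
                       radius = 1.0) {
  nf <- nFrames(trajectory)
  depth <- rep_len(depth, nf); tilt <- rep_len(tilt, nf)
  if (!is.null(x)) x <- rep_len(x, nf)
  if (!is.null(y)) y <- rep_len(y, nf)
  frames <- lapply(seq_len(nf), function(i)
    placePeptide(getFrame(trajectory, i), leaflet, depth[i], tilt[i],
                 if (is.null(x)) NULL else x[i],
                 if (is.null(y)) NULL else y[i],
                 nBackbone, spacing, radius))
  newTrajectory(lapply(frames, beadPositions), trajectory@boxes,
                trajectory@times, frames[[1]]@beadMeta,
                groundTruth = c(trajectory@groundTruth,
                                list(peptide = list(leaflet = leaflet,
                                                    depth = depth,
                                                    tilt = tilt))),
                wrap = FALSE)
}

#' Sample lateral positions with a curvature-coupled Boltzmann bias
#'
#' Draws (x, y) over the analytic buckle surface with density proportional
#' to `dA * exp(a * H(x))`, `dA = sqrt(1 + h'(x)^2) dx dy` the surface
#' area element, by rejection sampling. `a = 0` reproduces the accessible
#' (surface-measure) distribution.
#'
#' @param A,lambda buckle amplitude and wavelength, nm.
#' @param Ly box width in y, nm.
#' @param a bias coefficient, nm (curvature couples as `exp(a*H)`).
#' @param n number of samples.
#' @param seed RNG seed.
#' @return data.frame with `x`, `y`; attribute `groundTruth` carries
#'   `list(a, A, lambda)`.
#' @export
sampleBiasedPositions <- function(A, lambda, Ly = 10, a = 0, n = 1000L,
                                  seed = 1L) {
  stopifnot(n >= 1)
  dens <- function(x) {
    k <- 2 * pi / lambda
    hp <- A * k * cos(k * x)
    sqrt(1 + hp^2) * exp(a * buckleMeanCurvature(x, A, lambda))
  }
  M <- max(dens(seq(0, lambda, length.out = 4096))) * 1.0001
  xs <- withSeed(seed, {
    out <- numeric(0)
    while (length(out) < n) {
      m <- ceiling((n - length(out)) * 1.5 * M / mean(dens(seq(0, lambda, length.out = 256))))
      cand <- runif(m, 0, lambda)
      keep <- runif(m) < dens(cand) / M
      out <- c(out, cand[keep])
    }
    list(x = out[seq_len(n)], y = runif(n, 0, Ly))
  })
  structure(data.frame(x = xs$x, y = xs$y),
            groundTruth = list(a = a, A = A, lambda = lambda))
}

## C1 curve through knots with zero slope at every knot: extrema sit
## exactly on the knots, which is what makes the programmed well depths
## exact. Cubic Hermite per segment: p0 + (p1-p0) (3 t^2 - 2 t^3).
.hermiteFlat <- function(xk, yk) {
  force(xk); force(yk)
  function(x) {
    x <- pmin(pmax(x, xk[1]), xk[length(xk)])
    i <- findInterval(x, xk, rightmost.closed = TRUE)
    t <- (x - xk[i]) / (xk[i + 1] - xk[i])
    yk[i] + (yk[i + 1] - yk[i]) * (3 * t^2 - 2 * t^3)
  }
}

#' Generate a synthetic 2D free-energy surface with programmed states
#'
#' Builds a double-well profile in CV1 with adsorbed minima at exactly 0
#' kJ/mol, a transmembrane minimum at exactly `ddg`, and barriers at
#' exactly `barrier` (zero-slope cubic Hermite segments, so the extrema
#' sit on the knots), adds a separable harmonic CV2 term, and subtracts
#' the analytically-known marginalization constant (computed with the same
#' trapezoid rule [marginalizeCV2()] uses) so that the Boltzmann-averaged
#' 1D profile equals the programmed profile to machine precision.
#'
#' @param ddg programmed adsorbed-to-transmembrane free-energy gap, kJ/mol.
#' @param barrier programmed barrier height, kJ/mol; needs
#'   `barrier >= max(0, ddg)`.
#' @param cv1Range CV1 extent, nm.
#' @param n1 CV1 grid size.
#' @param cv2 CV2 grid, degrees.
#' @param temperature K.
#' @param k2 harmonic CV2 force constant, kJ/mol/deg^2 (about 90 deg).
#' @param adsPos,barPos CV1 positions of the adsorbed minima and barriers,
#'   nm.
#' @param C marginalization constant used for the compensation, rad.
#' @return an [FES2D-class]; `@meta$groundTruth` holds `ddg`, `barrier`
#'   and the programmed marginal profile.
#' @export
genFES2D <- function(ddg = 20, barrier = 30, cv1Range = c(-3, 3), n1 = 241L,
                     cv2 = seq(0, 180, by = 2), temperature = 310,
                     k2 = 0.002, adsPos = 1.8, barPos = 0.9, C = NULL) {
  if (barrier < max(0, ddg))
    .stopf("barrier (%.3g) must be >= max(0, ddg) = %.3g", barrier,
           max(0, ddg))
  stopifnot(adsPos < max(cv1Range), barPos < adsPos)
  cv1 <- seq(cv1Range[1], cv1Range[2], length.out = n1)
  edge <- barrier + 25
  g <- .hermiteFlat(c(cv1Range[1], -adsPos, -barPos, 0, barPos, adsPos,
                      cv1Range[2]),
                    c(edge, 0, barrier, ddg, barrier, 0, edge))
  q <- 0.5 * k2 * (cv2 - 90)^2
  cv2rad <- cv2 * pi / 180
  if (is.null(C)) C <- diff(range(cv2rad))
  beta <- 1 / (.R_GAS * temperature)
  w <- .trapWeights(cv2rad)
  delta <- -(1 / beta) * (logSumExp(-beta * q + log(w)) - log(C))
  G <- outer(g(cv1), q, `+`) - delta
  new("FES2D", cv1 = cv1, cv2 = cv2, G = G, temperature = temperature,
      meta = list(groundTruth = list(ddg = ddg, barrier = barrier,
                                     marginal = g(cv1), k2 = k2,
                                     adsPos = adsPos, barPos = barPos)))
}

#' Generate exponential defect-area samples
#'
#' Areas are drawn from an exponential with mean `piConst` above the lower
#' truncation `aMin` (the truncated exponential is `aMin + Exp(piConst)`
#' by memorylessness).
#'
#' @param piConst programmed defect-area constant, Angstrom^2.
#' @param n sample count.
#' @param aMin lower truncation, Angstrom^2.
#' @param seed RNG seed.
#' @return a [DefectSizeSample-class] (single frame, unfitted); the
#'   programmed constant is in `@parameters$piTrue`.
#' @export
genDefectAreas <- function(piConst = 30, n = 10000L, aMin = 15, seed = 1L) {
  stopifnot(piConst > 0, n >= 1)
  areas <- withSeed(seed, aMin + rexp(n, rate = 1 / piConst))
  new("DefectSizeSample", areas = list(areas),
      parameters = list(piTrue = piConst, aMin = aMin, seed = seed),
      constant = NA_real_, ci = NA_real_)
}
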