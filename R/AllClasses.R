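#' @import methods
NULL

#' BeadFrame: one coarse-grained configuration
#'
#' Positions (nm), an orthorhombic box (nm) and per-bead metadata for a
#' single snapshot. Coordinates are wrapped into `[0, L)` per axis on
#' construction; analyses use minimum-image conventions in the membrane
#' plane.
#'
#' @slot positions numeric N x 3 matrix of bead coordinates in nm.
#' @slot box numeric length-3 vector (Lx, Ly, Lz) in nm.
#' @slot beadMeta data.frame with columns `moleculeId` (integer),
#'   `moleculeName`, `beadName` (character), one row per bead.
#' @slot time frame time in ps.
#' @exportClass BeadFrame
setClass("BeadFrame",
  representation(positions = "matrix", box = "numeric",
                 beadMeta = "data.frame", time = "numeric"))

setValidity("BeadFrame", function(object) {
  p <- object@positions
  if (!is.numeric(p) || ncol(p) != 3 || nrow(p) < 1)
    return("positions must be a numeric N x 3 matrix with N >= 1")
  if (!all(is.finite(p))) return("positions must be finite")
  if (length(object@box) != 3 || any(!is.finite(object@box)) ||
      any(object@box <= 0))
    return("box must be three positive finite lengths (orthorhombic)")
  m <- object@beadMeta
  need <- c("moleculeId", "moleculeName", "beadName")
  if (!all(need %in% names(m)))
    return("beadMeta must have moleculeId, moleculeName, beadName")
  if (nrow(m) != nrow(p)) return("beadMeta rows must match positions rows")
  if (anyNA(m$moleculeId)) return("every bead needs a moleculeId")
  TRUE
})

#' Construct a BeadFrame
#'
#' @param positions N x 3 matrix, nm.
#' @param box length-3 vector (Lx, Ly, Lz), nm.
#' @param beadMeta data.frame with `moleculeId`, `moleculeName`, `beadName`.
#' @param time frame time, ps.
#' @param wrap wrap coordinates into `[0, L)`? Default `TRUE`.
#' @return a [BeadFrame-class] object.
#' @export
newBeadFrame <- function(positions, box, beadMeta, time = 0, wrap = TRUE) {
  positions <- as.matrix(positions)
  dimnames(positions) <- NULL
  storage.mode(positions) <- "double"
  if (wrap) positions <- wrapPositions(positions, box)
  new("BeadFrame", positions = positions, box = as.numeric(box),
      beadMeta = beadMeta, time = as.numeric(time))
}

#' Trajectory: an ordered sequence of frames with shared bead metadata
#'
#' @slot coords list of N x 3 position matrices (nm), one per frame.
#' @slot boxes nFrames x 3 matrix of box vectors (nm).
#' @slot times numeric vector of frame times (ps), strictly increasing.
#' @slot beadMeta shared per-bead metadata (see [BeadFrame-class]).
#' @slot groundTruth list; synthetic generators attach the parameters
#'   needed to predict downstream estimates in closed form.
#' @exportClass Trajectory
setClass("Trajectory",
  representation(coords = "list", boxes = "matrix", times = "numeric",
                 beadMeta = "data.frame", groundTruth = "list"))

setValidity("Trajectory", function(object) {
  nf <- length(object@coords)
  if (nf < 1) return("a Trajectory needs at least one frame")
  n <- nrow(object@coords[[1]])
  for (m in object@coords)
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != 3)
      return("all frames must share the bead count")
  if (nrow(object@boxes) != nf || ncol(object@boxes) != 3)
    return("boxes must be nFrames x 3")
  if (length(object@times) != nf) return("one time per frame")
  if (nf > 1 && any(diff(object@times) <= 0))
    return("frame times must be strictly increasing")
  if (nrow(object@beadMeta) != n)
    return("beadMeta rows must match the bead count")
  TRUE
})

#' Construct a Trajectory from per-frame coordinates
#'
#' @param coords list of N x 3 matrices (nm).
#' @param boxes nFrames x 3 matrix, or length-3 vector recycled per frame.
#' @param times frame times (ps); default 400 ps spacing from 0.
#' @param beadMeta shared bead metadata.
#' @param groundTruth optional list of generator ground truth.
#' @param wrap wrap coordinates into the box? Default `TRUE`.
#' @return a [Trajectory-class] object.
#' @export
newTrajectory <- function(coords, boxes, times = NULL, beadMeta,
                          groundTruth = list(), wrap = TRUE) {
  if (is.null(dim(boxes))) boxes <- matrix(boxes, length(coords), 3, byrow = TRUE)
  if (is.null(times)) times <- (seq_along(coords) - 1) * 400
  coords <- lapply(seq_along(coords), function(i) {
    m <- as.matrix(coords[[i]]); dimnames(m) <- NULL
    storage.mode(m) <- "double"
    if (wrap) wrapPositions(m, boxes[i, ]) else m
  })
  new("Trajectory", coords = coords, boxes = boxes, times = as.numeric(times),
      beadMeta = beadMeta, groundTruth = groundTruth)
}

#' SurfaceModel: truncated 2D Fourier height field in the Monge gauge
#'
#' `h(x, y)` is expanded on the tensor-product real Fourier basis
#' `{1, cos(2*pi*m*x/Lx), sin(2*pi*m*x/Lx)} x {...}` with `m <= Mx`,
#' `n <= My`, so `h` and all derivatives are periodic with the box.
#'
#' @slot box length-2 vector (Lx, Ly), nm.
#' @slot modes length-2 integer vector (Mx, My).
#' @slot coef coefficient matrix, `(2*Mx+1) x (2*My+1)`.
#' @slot residualRMS least-squares fit residual RMS, nm.
#' @slot leaflet "upper", "lower" or "mid" (sign convention carrier).
#' @slot time frame time, ps.
#' @exportClass SurfaceModel
setClass("SurfaceModel",
  representation(box = "numeric", modes = "integer", coef = "matrix",
                 residualRMS = "numeric", leaflet = "character",
                 time = "numeric"))

setValidity("SurfaceModel", function(object) {
  if (length(object@box) != 2 || any(object@box <= 0))
    return("box must be two positive lengths")
  if (length(object@modes) != 2 || any(object@modes < 0))
    return("modes must be two non-negative integers")
  d <- 2 * object@modes + 1
  if (!all(dim(object@coef) == d))
    return("coef must be (2*Mx+1) x (2*My+1)")
  if (object@residualRMS < 0) return("residual RMS must be >= 0")
  if (!object@leaflet %in% c("upper", "lower", "mid"))
    return("leaflet must be 'upper', 'lower' or 'mid'")
  TRUE
})

#' CurvatureDistribution: binned mean-curvature weights
#'
#' @slot breaks bin edges, nm^-1 (length nBins + 1, strictly increasing).
#' @slot weights normalized bin weights (sum to 1 over unmasked bins).
#' @slot kind "sampled", "accessible" or "reweighted".
#' @slot leaflet "upper", "lower" or "both".
#' @slot nSamples number of raw samples behind the histogram.
#' @slot masked logical per-bin mask (TRUE = excluded from normalization).
#' @exportClass CurvatureDistribution
setClass("CurvatureDistribution",
  representation(breaks = "numeric", weights = "numeric", kind = "character",
                 leaflet = "character", nSamples = "numeric",
                 masked = "logical"))

setValidity("CurvatureDistribution", function(object) {
  if (length(object@breaks) != length(object@weights) + 1)
    return("breaks must have length(weights) + 1")
  if (any(diff(object@breaks) <= 0)) return("breaks must increase")
  if (length(object@masked) != length(object@weights))
    return("masked must match weights")
  w <- object@weights[!object@masked]
  if (any(w < -1e-12)) return("weights must be non-negative")
  if (length(w) && abs(sum(w) - 1) > 1e-8)
    return("unmasked weights must sum to 1")
  if (!object@kind %in% c("sampled", "accessible", "reweighted"))
    return("kind must be sampled/accessible/reweighted")
  TRUE
})

#' FES2D: free energy over the (CV1, CV2) grid
#'
#' CV1 is the signed z-distance between the peptide and membrane centers of
#' mass (nm); CV2 is the peptide tilt angle from the membrane normal
#' (degrees). Unvisited grid cells are `NA`.
#'
#' @slot cv1 strictly increasing grid, nm.
#' @slot cv2 strictly increasing grid, degrees.
#' @slot G free energy matrix `length(cv1) x length(cv2)`, kJ/mol; NA =
#'   unvisited.
#' @slot temperature K.
#' @slot meta list (force constants, provenance, ground truth, ...).
#' @exportClass FES2D
setClass("FES2D",
  representation(cv1 = "numeric", cv2 = "numeric", G = "matrix",
                 temperature = "numeric", meta = "list"))

setValidity("FES2D", function(object) {
  if (any(diff(object@cv1) <= 0) || any(diff(object@cv2) <= 0))
    return("cv1 and cv2 grids must be strictly increasing")
  if (!all(dim(object@G) == c(length(object@cv1), length(object@cv2))))
    return("G must be length(cv1) x length(cv2)")
  if (any(is.infinite(object@G), na.rm = TRUE))
    return("G must be finite or NA (unvisited)")
  if (object@temperature <= 0) return("temperature must be positive")
  TRUE
})

#' PMF1D: one-dimensional free energy profile along CV1
#'
#' @slot cv1 grid, nm.
#' @slot G free energy, kJ/mol; NA = unvisited.
#' @slot error per-bin error estimate (kJ/mol) or empty.
#' @slot states list with `adsorbed` (data.frame cv1, G per side), `tm`
#'   (cv1, G), `ddg`, `barrier` once annotated; empty before.
#' @slot temperature K.
#' @exportClass PMF1D
setClass("PMF1D",
  representation(cv1 = "numeric", G = "numeric", error = "numeric",
                 states = "list", temperature = "numeric"))

setValidity("PMF1D", function(object) {
  if (length(object@G) != length(object@cv1))
    return("G must match the cv1 grid")
  if (any(diff(object@cv1) <= 0)) return("cv1 grid must increase")
  if (length(object@error) && length(object@error) != length(object@G))
    return("error must be empty or match G")
  if (object@temperature <= 0) return("temperature must be positive")
  TRUE
})

#' DefectSizeSample: per-frame packing-defect areas and the fitted constant
#'
#' @slot areas list of numeric vectors, defect areas per frame, Angstrom^2.
#' @slot parameters list of detection parameters (grid step, depth, ...).
#' @slot constant fitted exponential defect-area constant pi, Angstrom^2
#'   (NA before fitting).
#' @slot ci one-sigma confidence interval half-width, Angstrom^2.
#' @exportClass DefectSizeSample
setClass("DefectSizeSample",
  representation(areas = "list", parameters = "list", constant = "numeric",
                 ci = "numeric"))

setMethod("show", "BeadFrame", function(object) {
  cat(sprintf("BeadFrame: %d beads, box %.3f x %.3f x %.3f nm, t = %g ps\n",
              nrow(object@positions), object@box[1], object@box[2],
              object@box[3], object@time))
  cat(sprintf("  molecules: %d (%s)\n",
              length(unique(object@beadMeta$moleculeId)),
              paste(unique(object@beadMeta$moleculeName), collapse = ", ")))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d frames x %d beads, t = %g..%g ps\n",
              length(object@coords), nrow(object@beadMeta),
              object@times[1], object@times[length(object@times)]))
  if (length(object@groundTruth))
    cat("  synthetic ground truth attached:",
        paste(names(object@groundTruth), collapse = ", "), "\n")
})

setMethod("show", "SurfaceModel", function(object) {
  cat(sprintf(
    "SurfaceModel (%s leaflet): box %.3f x %.3f nm, modes (%d, %d), residual RMS %.4g nm\n",
    object@leaflet, object@box[1], object@box[2], object@modes[1],
    object@modes[2], object@residualRMS))
})

setMethod("show", "CurvatureDistribution", function(object) {
  cat(sprintf(
    "CurvatureDistribution (%s, %s leaflet): %d bins over [%.3g, %.3g] nm^-1, n = %g, %d masked\n",
    object@kind, object@leaflet, length(object@weights),
    min(object@breaks), max(object@breaks), object@nSamples,
    sum(object@masked)))
})

setMethod("show", "FES2D", function(object) {
  cat(sprintf(
    "FES2D: %d x %d grid, CV1 [%.2f, %.2f] nm, CV2 [%.1f, %.1f] deg, T = %g K\n",
    length(object@cv1), length(object@cv2), min(object@cv1), max(object@cv1),
    min(object@cv2), max(object@cv2), object@temperature))
})

setMethod("show", "PMF1D", function(object) {
  cat(sprintf("PMF1D: %d bins, CV1 [%.2f, %.2f] nm, T = %g K\n",
              length(object@cv1), min(object@cv1), max(object@cv1),
              object@temperature))
  if (length(object@states)) {
    s <- object@states
    if (!is.null(s$ddg))
      cat(sprintf("  ddG (adsorbed -> TM) = %.2f kJ/mol, barrier = %.2f kJ/mol\n",
                  s$ddg, if (is.null(s$barrier)) NA_real_ else s$barrier))
  }
})

setMethod("show", "DefectSizeSample", function(object) {
  n <- sum(lengths(object@areas))
  cat(sprintf("DefectSizeSample: %d defects over %d frames", n,
              length(object@areas)))
  if (length(object@constant) && !is.na(object@constant))
    cat(sprintf("; pi = %.2f +/- %.2f A^2", object@constant, object@ci))
  cat("\n")
})

## ---- accessors ------------------------------------------------------------

#' Accessors for memsense objects
#'
#' Small read-only accessors; slots are implementation detail.
#'
#' @param x a memsense object.
#' @param i frame index.
#' @name accessors
NULL

#' @rdname accessors
#' @export
beadPositions <- function(x) x@positions

#' @rdname accessors
#' @export
beadMeta <- function(x) x@beadMeta

#' @rdname accessors
#' @export
boxVectors <- function(x) if (is(x, "Trajectory")) x@boxes else x@box

#' @rdname accessors
#' @export
frameTimes <- function(x) if (is(x, "Trajectory")) x@times else x@time

#' @rdname accessors
#' @export
nFrames <- function(x) if (is(x, "Trajectory")) length(x@coords) else 1L

#' @rdname accessors
#' @export
getFrame <- function(x, i) {
  stopifnot(is(x, "Trajectory"), i >= 1, i <= length(x@coords))
  newBeadFrame(x@coords[[i]], x@boxes[i, ], x@beadMeta, x@times[i],
               wrap = FALSE)
}

#' @rdname accessors
#' @export
groundTruth <- function(x) x@groundTruth

#' @rdname accessors
#' @export
binCenters <- function(x) {
  stopifnot(is(x, "CurvatureDistribution"))
  (x@breaks[-1] + x@breaks[-length(x@breaks)]) / 2
}

#' @rdname accessors
#' @export
binWeights <- function(x) x@weights

#' @rdname accessors
#' @export
maskedBins <- function(x) x@masked

#' @rdname accessors
#' @export
pmfStates <- function(x) x@states

#' @rdname accessors
#' @export
pmfGrid <- function(x) x@cv1

#' @rdname accessors
#' @export
pmfValues <- function(x) x@G

#' @rdname accessors
#' @export
pmfError <- function(x) x@error

#' @rdname accessors
#' @export
defectAreas <- function(x) x@areas

#' @rdname accessors
#' @export
defectConstantValue <- function(x) x@constant

#' @rdname accessors
#' @export
surfaceResidual <- function(x) x@residualRMS
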