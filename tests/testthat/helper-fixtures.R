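## Shared fixtures and independent oracles for the suite. Everything is
## generated in code; no stored data.

selPep <- beadSelection("peptide", moleculeName = "PEP")
selPhos <- beadSelection("phosphates", beadName = "PO4")

## jitter-free planar reference bilayer (92 lipids/leaflet, APL 65 A^2)
cleanPlanar <- function(nFrames = 1L, n = 92L, apl = 65, seed = 1L, ...)
  genPlanarBilayer(bilayerParams(nPerLeaflet = n, targetAPL = apl,
                                 jitterXY = 0, jitterZ = 0, seed = seed,
                                 ...),
                   nFrames = nFrames)

## jitter-free single-mode buckle, A = 1 nm, lambda = 20 nm
cleanBuckle <- function(n = 800L, A = 1, lambda = 20, nFrames = 1L,
                        seed = 1L, ...)
  genBuckledBilayer(bilayerParams(nPerLeaflet = n, targetAPL = 65,
                                  jitterXY = 0, jitterZ = 0,
                                  buckleAmplitude = A,
                                  buckleWavelength = lambda, seed = seed,
                                  ...),
                    nFrames = nFrames)

## fit the upper-leaflet surface of a frame's phosphates
fitUpperSurface <- function(frame, Mx = 3L, My = 3L, leaflet = "upper") {
  leaf <- assignLeaflets(frame)
  m <- beadMeta(frame)
  phos <- which(m$beadName == "PO4" &
                  leaf[as.character(m$moleculeId)] == leaflet)
  fitSurface(beadPositions(frame)[phos, ], boxVectors(frame)[1:2], Mx, My,
             leaflet = leaflet)
}

## finite-difference curvature oracle: uses only surfaceHeight (0th
## derivative path), independent of the analytic-derivative code
fdCurvature <- function(model, x, y, h = 4e-3) {
  f <- function(xx, yy) surfaceHeight(model, xx, yy)
  ## Richardson-extrapolated central differences: the h^2 truncation term
  ## cancels, leaving ~1e-9 absolute error at this step size
  rich <- function(d) (4 * d(h) - d(2 * h)) / 3
  hx <- rich(function(s) (f(x + s, y) - f(x - s, y)) / (2 * s))
  hy <- rich(function(s) (f(x, y + s) - f(x, y - s)) / (2 * s))
  hxx <- rich(function(s) (f(x + s, y) - 2 * f(x, y) + f(x - s, y)) / s^2)
  hyy <- rich(function(s) (f(x, y + s) - 2 * f(x, y) + f(x, y - s)) / s^2)
  hxy <- rich(function(s) (f(x + s, y + s) - f(x + s, y - s) -
                             f(x - s, y + s) + f(x - s, y - s)) / (4 * s^2))
  g <- 1 + hx^2 + hy^2
  H <- ((1 + hy^2) * hxx - 2 * hx * hy * hxy + (1 + hx^2) * hyy) /
    (2 * g^1.5)
  if (model@leaflet == "lower") H <- -H
  list(H = H, K = (hxx * hyy - hxy^2) / g^2)
}

## brute-force packing-defect grid oracle: literal per-cell scan, no
## shared code with detectDefects beyond the definition itself
bruteDefectCells <- function(frame, leaflet, gridStep = 0.1, zDepth = 0.1,
                             beadRadius = 0.26,
                             headBeads = c("NC3", "PO4")) {
  box <- boxVectors(frame)
  leaf <- assignLeaflets(frame)
  m <- beadMeta(frame)
  p <- beadPositions(frame)
  on <- !is.na(leaf[as.character(m$moleculeId)]) &
    leaf[as.character(m$moleculeId)] == leaflet
  sgn <- if (leaflet == "upper") 1 else -1
  zThr <- mean(p[on & m$beadName == "PO4", 3]) - sgn * zDepth
  nx <- max(1L, floor(box[1] / gridStep)); ny <- max(1L, floor(box[2] / gridStep))
  def <- matrix(FALSE, nx, ny)
  idx <- which(on)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    cx <- (i - 0.5) * box[1] / nx; cy <- (j - 0.5) * box[2] / ny
    dx <- p[idx, 1] - cx; dx <- dx - box[1] * round(dx / box[1])
    dy <- p[idx, 2] - cy; dy <- dy - box[2] * round(dy / box[2])
    cover <- idx[dx^2 + dy^2 <= beadRadius^2]
    if (!length(cover)) { def[i, j] <- TRUE; next }
    top <- cover[which.max(sgn * p[cover, 3])]
    def[i, j] <- !(m$beadName[top] %in% headBeads) &&
      sgn * p[top, 3] < sgn * zThr
  }
  def
}

## analytic mean of the exponentially tilted uniform distribution on
## [-c, c]: E[H] under density prop. exp(a H)
tiltedUniformMean <- function(a, c) {
  if (a == 0) return(0)
  c / tanh(a * c) - 1 / a
}
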