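## Monge-gauge surface reconstruction.
##
## The leaflet height field h(x, y) is expanded on the tensor-product real
## Fourier basis periodic with the box and fitted to phosphate bead
## positions by linear least squares. Curvatures follow analytically:
##   H = [(1+h_y^2) h_xx - 2 h_x h_y h_xy + (1+h_x^2) h_yy] /
##       [2 (1+h_x^2+h_y^2)^(3/2)]
##   K = (h_xx h_yy - h_xy^2) / (1+h_x^2+h_y^2)^2
## For the lower leaflet the mean/principal curvatures are negated so that
## positive H always means the leaflet bulges toward its own solvent side.

## 1D basis (or derivative) matrix: columns [1, cos(kx), sin(kx), cos(2kx),
## sin(2kx), ...], k = 2*pi/L. deriv in 0:2.
.fourierBasis1D <- function(x, L, M, deriv = 0L) {
  B <- matrix(0, length(x), 2L * M + 1L)
  B[, 1] <- if (deriv == 0L) 1 else 0
  if (M >= 1L) for (m in seq_len(M)) {
    k <- 2 * pi * m / L
    cm <- cos(k * x); sm <- sin(k * x)
    cs <- switch(deriv + 1L,
                 list(cm, sm),
                 list(-k * sm, k * cm),
                 list(-k * k * cm, -k * k * sm))
    B[, 2L * m] <- cs[[1]]
    B[, 2L * m + 1L] <- cs[[2]]
  }
  B
}

## row-wise tensor product of the x and y bases -> design matrix
.designMatrix <- function(x, y, box, Mx, My, dx = 0L, dy = 0L) {
  Bx <- .fourierBasis1D(x, box[1], Mx, dx)
  By <- .fourierBasis1D(y, box[2], My, dy)
  n <- length(x)
  px <- ncol(Bx); py <- ncol(By)
  D <- matrix(0, n, px * py)
  for (j in seq_len(py)) D[, ((j - 1) * px + 1):(j * px)] <- Bx * By[, j]
  D
}

#' Fit a periodic Fourier height field to scattered points
#'
#' Solves the linear least-squares problem
#' `min sum_i (z_i - h(x_i, y_i))^2` over the truncated tensor-product
#' Fourier basis (coefficient count `(2*Mx+1)*(2*My+1)`), via QR.
#'
#' @param points N x 3 matrix (x, y, z) in nm; xy inside the box.
#' @param box length-2 (Lx, Ly) nm (a length-3 box is accepted; Lz ignored).
#' @param Mx,My non-negative integer mode cutoffs.
#' @param leaflet `"upper"`, `"lower"` or `"mid"`; stored for the curvature
#'   sign convention.
#' @param time frame time (ps), carried through to the model.
#' @return a [SurfaceModel-class].
#' @export
fitSurface <- function(points, box, Mx = 3L, My = 3L, leaflet = "mid",
                       time = 0) {
  points <- as.matrix(points)
  box <- as.numeric(box)[1:2]
  Mx <- as.integer(Mx); My <- as.integer(My)
  ncoef <- (2L * Mx + 1L) * (2L * My + 1L)
  if (nrow(points) < ncoef)
    .stopf("surface fit error: %d points cannot determine %d coefficients (Mx=%d, My=%d)",
           nrow(points), ncoef, Mx, My)
  D <- .designMatrix(points[, 1], points[, 2], box, Mx, My)
  qrD <- qr(D)
  if (qrD$rank < ncoef) {
    s <- svd(D, nu = 0, nv = 0)$d
    .stopf("surface fit error: rank-deficient design (rank %d < %d, condition %.3g)",
           qrD$rank, ncoef, s[1] / max(s[length(s)], .Machine$double.xmin))
  }
  cf <- qr.coef(qrD, points[, 3])
  res <- points[, 3] - D %*% cf
  new("SurfaceModel", box = box, modes = c(Mx, My),
      coef = matrix(cf, 2L * Mx + 1L, 2L * My + 1L),
      residualRMS = sqrt(mean(res^2)), leaflet = leaflet,
      time = as.numeric(time))
}

## evaluate sum_{jk} C_jk phi_j^(dx)(x) psi_k^(dy)(y) at paired points
.evalField <- function(model, x, y, dx = 0L, dy = 0L) {
  Bx <- .fourierBasis1D(x, model@box[1], model@modes[1], dx)
  By <- .fourierBasis1D(y, model@box[2], model@modes[2], dy)
  rowSums((Bx %*% model@coef) * By)
}

#' Evaluate the height field of a surface model
#'
#' @param model a [SurfaceModel-class].
#' @param x,y coordinates (nm); periodic, any value allowed.
#' @return h(x, y) in nm.
#' @export
surfaceHeight <- function(model, x, y) .evalField(model, x, y, 0L, 0L)

#' Curvatures of the fitted surface at given points
#'
#' Derivatives are evaluated analytically from the Fourier basis and
#' combined with the Monge-gauge formulas for mean (H), Gaussian (K) and
#' principal curvatures. For a `"lower"`-leaflet model H, k1 and k2 are
#' negated (K is sign-invariant) so positive H means bulging toward that
#' leaflet's solvent side.
#'
#' @param model a [SurfaceModel-class].
#' @param x,y evaluation coordinates (nm), recycled to a common length.
#' @return data.frame with `x`, `y`, `h`, `H` (nm^-1), `K` (nm^-2), `k1`,
#'   `k2` (nm^-1) and `areaElement` (`sqrt(1+|grad h|^2)`, >= 1).
#' @export
curvatureAt <- function(model, x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  h <- .evalField(model, x, y, 0L, 0L)
  hx <- .evalField(model, x, y, 1L, 0L)
  hy <- .evalField(model, x, y, 0L, 1L)
  hxx <- .evalField(model, x, y, 2L, 0L)
  hyy <- .evalField(model, x, y, 0L, 2L)
  hxy <- .evalField(model, x, y, 1L, 1L)
  g <- 1 + hx^2 + hy^2
  H <- ((1 + hy^2) * hxx - 2 * hx * hy * hxy + (1 + hx^2) * hyy) /
    (2 * g^1.5)
  K <- (hxx * hyy - hxy^2) / g^2
  if (model@leaflet == "lower") H <- -H
  disc <- sqrt(pmax(H^2 - K, 0))
  data.frame(x = x, y = y, h = h, H = H, K = K,
             k1 = H + disc, k2 = H - disc, areaElement = sqrt(g))
}

#' Accessible-curvature distribution of a surface
#'
#' Histograms the mean curvature over a uniform xy grid, weighting each
#' grid point by its local area element (surface measure), normalized to 1.
#' The grid must resolve the highest fitted mode.
#'
#' @param model a [SurfaceModel-class].
#' @param gridNx,gridNy grid resolution; defaults resolve 4 points per mode
#'   with a floor of 64.
#' @param breaks histogram bin edges, nm^-1.
#' @param measure `"surface"` (area-element weights, default) or
#'   `"projected"` (flat xy measure).
#' @return a [CurvatureDistribution-class] of kind `"accessible"`.
#' @export
accessibleCurvature <- function(model, gridNx = NULL, gridNy = NULL,
                                breaks = seq(-0.15, 0.15, by = 0.005),
                                measure = c("surface", "projected")) {
  measure <- match.arg(measure)
  if (is.null(gridNx)) gridNx <- max(512L, 16L * model@modes[1])
  if (is.null(gridNy)) gridNy <- max(128L, 16L * model@modes[2])
  if (gridNx < 4 * model@modes[1] || gridNy < 4 * model@modes[2])
    .stopf("grid %d x %d does not resolve modes (%d, %d): need >= 4 per mode",
           gridNx, gridNy, model@modes[1], model@modes[2])
  gx <- (seq_len(gridNx) - 0.5) * model@box[1] / gridNx
  gy <- (seq_len(gridNy) - 0.5) * model@box[2] / gridNy
  pts <- expand.grid(x = gx, y = gy)
  cv <- curvatureAt(model, pts$x, pts$y)
  w <- if (measure == "surface") cv$areaElement else rep(1, nrow(cv))
  ## anti-aliased binning: each cell's weight is spread uniformly over the
  ## H interval it covers (half-width from central differences of H on the
  ## periodic grid), giving second-order convergence in the grid step
  Hm <- matrix(cv$H, gridNx, gridNy)
  dHx <- abs(Hm[c(2:gridNx, 1), ] - Hm[c(gridNx, 1:(gridNx - 1)), ]) / 2
  dHy <- abs(Hm[, c(2:gridNy, 1)] - Hm[, c(gridNy, 1:(gridNy - 1))]) / 2
  hw <- pmax(as.vector(dHx + dHy) / 2, 1e-15)
  lo <- cv$H - hw
  hi <- cv$H + hw
  nb <- length(breaks) - 1L
  wb <- vapply(seq_len(nb), function(b) {
    ov <- pmin(hi, breaks[b + 1]) - pmax(lo, breaks[b])
    sum(w * pmax(ov, 0) / (hi - lo))
  }, 0)
  lost <- 1 - sum(wb) / sum(w)
  if (lost > 0.01)
    .warnf("%.1f%% of accessible weight outside histogram range", 100 * lost)
  new("CurvatureDistribution", breaks = breaks, weights = wb / sum(wb),
      kind = "accessible", leaflet = model@leaflet,
      nSamples = length(cv$H), masked = rep(FALSE, nb))
}

#' Build a normalized curvature histogram
#'
#' @param H mean-curvature samples, nm^-1.
#' @param breaks bin edges.
#' @param weights optional per-sample weights.
#' @param kind histogram kind (`"sampled"`, `"accessible"`, `"reweighted"`).
#' @param leaflet label.
#' @return a [CurvatureDistribution-class]. Samples outside the bin range
#'   are dropped; their fraction triggers a warning above 1%.
#' @export
curvatureHistogram <- function(H, breaks, weights = NULL, kind = "sampled",
                               leaflet = "both") {
  if (is.null(weights)) weights <- rep(1, length(H))
  keep <- H >= breaks[1] & H <= breaks[length(breaks)]
  lost <- sum(weights[!keep]) / sum(weights)
  if (lost > 0.01)
    .warnf("%.1f%% of curvature weight outside histogram range", 100 * lost)
  idx <- findInterval(H[keep], breaks, rightmost.closed = TRUE)
  w <- vapply(seq_len(length(breaks) - 1L),
              function(b) sum(weights[keep][idx == b]), 0)
  new("CurvatureDistribution", breaks = breaks, weights = w / sum(w),
      kind = kind, leaflet = leaflet, nSamples = length(H),
      masked = rep(FALSE, length(w)))
}
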