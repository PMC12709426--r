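## Curvature-preference statistics: per-frame curvature sampled at the
## peptide position, reweighting by the accessible-curvature distribution,
## mean sensed curvature, leaflet-convergence diagnostics and the
## depth-curvature correlation and slope-difference tests.

#' Sample the membrane curvature at the peptide position
#'
#' Per frame: fits the peptide's leaflet surface from that leaflet's
#' phosphate beads, evaluates the mean curvature at the peptide center of
#' mass (x, y), and applies the leaflet sign convention (positive H =
#' bulging toward the leaflet's own solvent). Frames whose surface fit
#' fails are flagged and skipped.
#'
#' @param trajectory a [Trajectory-class].
#' @param peptideSel,phosphateSel selections.
#' @param leaflet leaflet carrying the peptide.
#' @param Mx,My Fourier truncation for the per-frame fits.
#' @return list with `H` (nm^-1, one per used frame), `leaflet`,
#'   `nSkipped`, and `residualRMS` (per-frame fit residuals).
#' @export
samplePeptideCurvature <- function(trajectory, peptideSel, phosphateSel,
                                   leaflet = c("upper", "lower"),
                                   Mx = 3L, My = 3L) {
  leaflet <- match.arg(leaflet)
  H <- numeric(0); res <- numeric(0); skipped <- 0L
  for (i in seq_len(nFrames(trajectory))) {
    fr <- getFrame(trajectory, i)
    leafLab <- assignLeaflets(fr)
    m <- fr@beadMeta
    phos <- selectBeads(fr, phosphateSel)
    phos <- phos[leafLab[as.character(m$moleculeId[phos])] == leaflet]
    pep <- selectBeads(fr, peptideSel)
    if (!length(pep)) .stopf("input error: empty peptide selection")
    fit <- tryCatch(
      fitSurface(fr@positions[phos, , drop = FALSE], fr@box[1:2], Mx, My,
                 leaflet = leaflet, time = fr@time),
      error = function(e) NULL)
    if (is.null(fit)) { skipped <- skipped + 1L; next }
    com <- .comOf(fr, pep)
    H <- c(H, curvatureAt(fit, com[1], com[2])$H)
    res <- c(res, fit@residualRMS)
  }
  if (skipped)
    .warnf("surface fit failed on %d frame(s); skipped", skipped)
  list(H = H, leaflet = leaflet, nSkipped = skipped, residualRMS = res)
}

#' Reweight a sampled curvature distribution by the accessible one
#'
#' Removes the uneven sampling imposed by the buckle geometry:
#' `w_rw(b) = w_sampled(b) / w_accessible(b)` for bins whose accessible
#' weight reaches `maskThreshold`, renormalized over the surviving bins.
#' Masked bins are reported in the result.
#'
#' @param sampled a `"sampled"` [CurvatureDistribution-class].
#' @param accessible an `"accessible"` [CurvatureDistribution-class] on
#'   the identical binning.
#' @param maskThreshold accessible-weight floor below which a bin is
#'   masked (division blow-up guard).
#' @return a `"reweighted"` [CurvatureDistribution-class].
#' @export
reweightCurvature <- function(sampled, accessible, maskThreshold = 1e-4) {
  if (sampled@kind != "sampled" || accessible@kind != "accessible")
    .stopf("inputs must be a 'sampled' and an 'accessible' distribution")
  if (length(sampled@breaks) != length(accessible@breaks) ||
      any(abs(sampled@breaks - accessible@breaks) > 1e-12))
    .stopf("input error: distributions must share the same binning")
  mask <- accessible@weights < maskThreshold | accessible@masked |
    sampled@masked
  if (all(mask | sampled@weights == 0))
    .stopf("analysis error: disjoint supports, no bin passes the mask")
  w <- rep(0, length(sampled@weights))
  w[!mask] <- sampled@weights[!mask] / accessible@weights[!mask]
  if (any(!mask & accessible@weights < maskThreshold))
    .warnf("accessible bins below mask threshold masked")
  masked0 <- mask & sampled@weights > 0
  if (any(masked0))
    .warnf("%d bin(s) with sampled weight masked by the accessible floor",
           sum(masked0))
  tot <- sum(w[!mask])
  w[!mask] <- w[!mask] / tot
  w[mask] <- 0
  new("CurvatureDistribution", breaks = sampled@breaks, weights = w,
      kind = "reweighted", leaflet = sampled@leaflet,
      nSamples = sampled@nSamples, masked = mask)
}

#' Mean sensed curvature of a reweighted distribution
#'
#' The weight-average of the bin centers, in nm^-1.
#'
#' @param dist a `"reweighted"` [CurvatureDistribution-class].
#' @return numeric, nm^-1.
#' @export
meanSensedCurvature <- function(dist) {
  if (dist@kind != "reweighted")
    .stopf("mean sensed curvature is defined on a reweighted distribution")
  sum(binWeights(dist)[!dist@masked] * binCenters(dist)[!dist@masked])
}

#' Leaflet agreement of two curvature distributions
#'
#' Total-variation distance `0.5 * sum |w_u - w_l|` in `[0, 1]`;
#' convergence of the two independent leaflet estimates is declared below
#' the threshold.
#'
#' @param upper,lower [CurvatureDistribution-class] on identical binning.
#' @param threshold convergence threshold (default 0.1).
#' @return list with `tv`, `converged`.
#' @export
leafletAgreement <- function(upper, lower, threshold = 0.1) {
  if (length(upper@breaks) != length(lower@breaks) ||
      any(abs(upper@breaks - lower@breaks) > 1e-12))
    .stopf("input error: distributions must share the same binning")
  tv <- 0.5 * sum(abs(upper@weights - lower@weights))
  list(tv = tv, converged = tv < threshold)
}

#' Correlation between insertion depth and sensed curvature
#'
#' Pearson correlation (with two-sided p-value) across peptides between
#' the flat-membrane insertion depth and the buckled-membrane mean sensed
#' curvature.
#'
#' @param depth insertion depths, nm (one per peptide).
#' @param curvature mean sensed curvatures, nm^-1.
#' @return list with `r`, `p`, `n`.
#' @export
depthCurvatureCorrelation <- function(depth, curvature) {
  if (length(depth) != length(curvature) || length(depth) < 3)
    .stopf("need >= 3 (depth, curvature) pairs")
  if (var(depth) == 0 || var(curvature) == 0)
    .stopf("undefined correlation: zero variance in an input")
  ct <- cor.test(depth, curvature, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(depth))
}

#' Two-sample test for a difference between regression slopes
#'
#' Ordinary least-squares slope and standard error per series, then
#' `t = (bA - bB) / sqrt(seA^2 + seB^2)` with Welch-Satterthwaite degrees
#' of freedom and a two-sided p-value.
#'
#' @param xA,yA first series (>= 3 points).
#' @param xB,yB second series.
#' @return list with `slopeA`, `slopeB`, `seA`, `seB`, `t`, `df`, `p`.
#' @export
slopeDifferenceTest <- function(xA, yA, xB, yB) {
  fitOne <- function(x, y) {
    if (length(x) < 3) .stopf("need >= 3 points per series")
    if (var(x) == 0) .stopf("degenerate x-variance")
    f <- summary(lm(y ~ x))
    c(b = f$coefficients[2, 1], se = f$coefficients[2, 2],
      df = f$df[2])
  }
  a <- fitOne(xA, yA); b <- fitOne(xB, yB)
  se2 <- a["se"]^2 + b["se"]^2
  if (se2 == 0) {
    ## noise-free series: identical slopes are indistinguishable, any
    ## difference is infinitely significant
    same <- a["b"] == b["b"]
    t <- if (same) 0 else sign(a["b"] - b["b"]) * Inf
    df <- a["df"] + b["df"]
    p <- if (same) 1 else 0
  } else {
    t <- (a["b"] - b["b"]) / sqrt(se2)
    df <- se2^2 / (a["se"]^4 / a["df"] + b["se"]^4 / b["df"])
    p <- 2 * pt(-abs(t), df)
  }
  list(slopeA = unname(a["b"]), slopeB = unname(b["b"]),
       seA = unname(a["se"]), seB = unname(b["se"]),
       t = unname(t), df = unname(df), p = unname(p))
}
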