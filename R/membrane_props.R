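## Bilayer characterization: area per lipid, S_CC order parameters, partial
## density profiles, packing-defect detection and the exponential
## defect-area constant, and peptide-centred local thickness/order maps.
## Areas are reported in Angstrom^2 (1 nm^2 = 100 A^2); everything else nm.

#' Area per lipid
#'
#' Projected lateral box area divided by lipids per leaflet, per frame.
#'
#' @param trajectory a [Trajectory-class].
#' @param nPerLeaflet lipids per leaflet.
#' @return list with `mean`, `sd` (Angstrom^2) and `perFrame`.
#' @export
areaPerLipid <- function(trajectory, nPerLeaflet) {
  stopifnot(nPerLeaflet > 0)
  apl <- trajectory@boxes[, 1] * trajectory@boxes[, 2] / nPerLeaflet *
    .NM2_TO_A2
  list(mean = mean(apl), sd = if (length(apl) > 1) sd(apl) else 0,
       perFrame = apl)
}

## consecutive tail-bead bond vectors for one frame; returns matrix of
## cos(theta) to +z, one row per bond instance
.tailBondCos <- function(frame, tailBeads, lipidIds) {
  m <- frame@beadMeta
  p <- frame@positions
  nb <- length(tailBeads)
  out <- vector("list", nb - 1L)
  for (b in seq_len(nb - 1L)) {
    i1 <- which(m$beadName == tailBeads[b] & m$moleculeId %in% lipidIds)
    i2 <- which(m$beadName == tailBeads[b + 1L] & m$moleculeId %in% lipidIds)
    i1 <- i1[order(m$moleculeId[i1])]
    i2 <- i2[order(m$moleculeId[i2])]
    if (length(i1) != length(i2) || !length(i1))
      .stopf("structural error: tail beads %s/%s missing on some lipids",
             tailBeads[b], tailBeads[b + 1L])
    v <- p[i2, , drop = FALSE] - p[i1, , drop = FALSE]
    v[, 1] <- minImage(v[, 1], frame@box[1])
    v[, 2] <- minImage(v[, 2], frame@box[2])
    out[[b]] <- v[, 3] / sqrt(rowSums(v^2))
  }
  out
}

#' S_CC tail order parameter profile
#'
#' `S = <(3 cos^2 theta - 1) / 2>` per consecutive-tail-bead bond, with
#' theta the angle between the bond and the membrane normal (+z, planar
#' systems), averaged over lipids and frames.
#'
#' @param trajectory a [Trajectory-class].
#' @param tailBeads ordered bead names along the tail (default
#'   `C1A..C4A` as generated by [genPlanarBilayer()]).
#' @param leaflet `"both"` (default), `"upper"` or `"lower"`.
#' @return data.frame with `bond` (label) and `S` in `[-0.5, 1]`.
#' @export
sccOrder <- function(trajectory, tailBeads = paste0("C", 1:4, "A"),
                     leaflet = "both") {
  nb <- length(tailBeads)
  stopifnot(nb >= 2)
  acc <- matrix(0, nFrames(trajectory), nb - 1L)
  for (i in seq_len(nFrames(trajectory))) {
    fr <- getFrame(trajectory, i)
    leafLab <- assignLeaflets(fr)
    ids <- as.integer(names(leafLab))
    if (leaflet != "both") ids <- ids[leafLab == leaflet]
    cosines <- .tailBondCos(fr, tailBeads, ids)
    acc[i, ] <- vapply(cosines, function(cz) mean((3 * cz^2 - 1) / 2), 0)
  }
  data.frame(bond = paste(tailBeads[-nb], tailBeads[-1], sep = "-"),
             S = colMeans(acc))
}

#' Partial density profiles along the membrane normal
#'
#' Bead-mass histogram along z, frame-averaged and normalized by bin
#' volume, after recentring each frame on the lipid center of mass (drift
#' removal). One profile per selection.
#'
#' @param trajectory a [Trajectory-class].
#' @param selections named list of [beadSelection()] specs.
#' @param binWidth bin width, nm.
#' @param beadMass mass per bead (uniform coarse-grained default 72 amu).
#' @param zRange profile extent about the membrane COM, nm.
#' @return data.frame with `z` (bin centers, nm) and one density column
#'   (amu/nm^3) per selection.
#' @export
densityProfile <- function(trajectory, selections, binWidth = 0.1,
                           beadMass = 72, zRange = c(-5, 5)) {
  stopifnot(binWidth > 0)
  breaks <- seq(zRange[1], zRange[2], by = binWidth)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  out <- matrix(0, length(mids), length(selections))
  lipidSel <- beadSelection("lipids", beadName = NULL)
  for (i in seq_len(nFrames(trajectory))) {
    fr <- getFrame(trajectory, i)
    memIdx <- which(fr@beadMeta$moleculeName != "PEP")
    z0 <- mean(fr@positions[memIdx, 3])
    vol <- fr@box[1] * fr@box[2] * binWidth
    for (s in seq_along(selections)) {
      idx <- selectBeads(fr, selections[[s]])
      if (!length(idx)) next
      zz <- fr@positions[idx, 3] - z0
      cnt <- vapply(seq_along(mids), function(b)
        sum(zz >= breaks[b] & zz < breaks[b + 1]), 0)
      out[, s] <- out[, s] + cnt * beadMass / vol
    }
  }
  out <- out / nFrames(trajectory)
  colnames(out) <- names(selections)
  cbind(data.frame(z = mids), as.data.frame(out))
}

#' Detect lipid packing defects on one leaflet
#'
#' Grid scan from the solvent side: a cell is a defect cell if the first
#' bead encountered scanning inward is an acyl-chain bead lying below the
#' local defect threshold (local phosphate mean z minus `zDepth` for the
#' upper leaflet), or if no bead covers the cell at all (void). Beads
#' cover a cell when the cell center lies within `beadRadius` laterally
#' (minimum image). 4-connected defect cells (periodic in xy) are merged
#' and areas returned in Angstrom^2.
#'
#' @param frame a [BeadFrame-class].
#' @param leaflet `"upper"` or `"lower"`.
#' @param gridStep grid step, nm (default 0.1).
#' @param zDepth depth below the local phosphate level, nm (default 0.1).
#' @param beadRadius lateral bead radius, nm (default 0.26).
#' @param headBeads bead names counted as head/interfacial (not defect
#'   when on top).
#' @param minCells drop defects smaller than this many cells (noise guard,
#'   default 1 = keep all).
#' @return numeric vector of defect areas, Angstrom^2 (possibly empty).
#' @export
detectDefects <- function(frame, leaflet = c("upper", "lower"),
                          gridStep = 0.1, zDepth = 0.1, beadRadius = 0.26,
                          headBeads = c("NC3", "PO4", "GL1", "GL2"),
                          minCells = 1L) {
  leaflet <- match.arg(leaflet)
  box <- frame@box
  leafLab <- assignLeaflets(frame)
  m <- frame@beadMeta
  onLeaf <- !is.na(leafLab[as.character(m$moleculeId)]) &
    leafLab[as.character(m$moleculeId)] == leaflet
  if (!any(onLeaf)) .stopf("no lipids on the %s leaflet", leaflet)
  p <- frame@positions
  sgn <- if (leaflet == "upper") 1 else -1
  phos <- which(onLeaf & m$beadName == "PO4")
  zThresh <- mean(p[phos, 3]) - sgn * zDepth
  nx <- max(1L, floor(box[1] / gridStep))
  ny <- max(1L, floor(box[2] / gridStep))
  sx <- box[1] / nx; sy <- box[2] / ny
  ## per-cell topmost covering bead (z toward solvent) and its kind
  topZ <- matrix(-Inf, nx, ny)
  topIsHead <- matrix(NA, nx, ny)
  idx <- which(onLeaf)
  rx <- ceiling(beadRadius / sx); ry <- ceiling(beadRadius / sy)
  for (b in idx) {
    cx0 <- floor(p[b, 1] / sx); cy0 <- floor(p[b, 2] / sy)
    zEff <- sgn * p[b, 3]
    isHead <- m$beadName[b] %in% headBeads
    for (dxc in -rx:rx) for (dyc in -ry:ry) {
      cx <- (cx0 + dxc) %% nx; cy <- (cy0 + dyc) %% ny
      ccx <- (cx + 0.5) * sx; ccy <- (cy + 0.5) * sy
      dd <- minImageDistXY(p[b, 1], p[b, 2], ccx, ccy, box)
      if (dd <= beadRadius && zEff > topZ[cx + 1, cy + 1]) {
        topZ[cx + 1, cy + 1] <- zEff
        topIsHead[cx + 1, cy + 1] <- isHead
      }
    }
  }
  defect <- topZ == -Inf |
    (!topIsHead & topZ < sgn * zThresh)
  defect[is.na(defect)] <- FALSE
  ## periodic 4-connected components by BFS
  comp <- matrix(0L, nx, ny)
  cur <- 0L
  sizes <- integer(0)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    if (!defect[i, j] || comp[i, j] != 0L) next
    cur <- cur + 1L
    queue <- matrix(c(i, j), 1)
    comp[i, j] <- cur
    sz <- 0L
    while (nrow(queue)) {
      c0 <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      sz <- sz + 1L
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        ii <- (c0[1] - 1L + d[1]) %% nx + 1L
        jj <- (c0[2] - 1L + d[2]) %% ny + 1L
        if (defect[ii, jj] && comp[ii, jj] == 0L) {
          comp[ii, jj] <- cur
          queue <- rbind(queue, c(ii, jj))
        }
      }
    }
    sizes <- c(sizes, sz)
  }
  areas <- sizes[sizes >= minCells] * sx * sy * .NM2_TO_A2
  as.numeric(areas)
}

#' Scan a trajectory for packing defects
#'
#' @param trajectory a [Trajectory-class].
#' @param leaflet leaflet to scan (`"upper"`, `"lower"`, or `"both"`).
#' @param ... passed to [detectDefects()].
#' @return a [DefectSizeSample-class] (unfitted).
#' @export
defectSample <- function(trajectory, leaflet = "both", ...) {
  leaves <- if (leaflet == "both") c("upper", "lower") else leaflet
  areas <- lapply(seq_len(nFrames(trajectory)), function(i) {
    fr <- getFrame(trajectory, i)
    unlist(lapply(leaves, function(l) detectDefects(fr, l, ...)))
  })
  new("DefectSizeSample", areas = areas,
      parameters = c(list(leaflet = leaflet), list(...)),
      constant = NA_real_, ci = NA_real_)
}

#' Fit the exponential defect-area constant
#'
#' Maximum-likelihood fit of the exponential tail `P(A) ~ exp(-A/pi)` for
#' `A >= aMin`: `pi = mean(A - aMin)`, with one-sigma CI `pi / sqrt(n)`.
#' A binned log-linear least-squares fit of the same tail is run as a
#' cross-check and its slope-derived constant returned alongside.
#'
#' @param x a [DefectSizeSample-class] or numeric vector of areas (A^2).
#' @param aMin lower cutoff of the exponential tail, Angstrom^2.
#' @param minCount minimum tail sample size (default 50).
#' @return a [DefectSizeSample-class] with `@constant` and `@ci` set;
#'   `@parameters$llsConstant` holds the least-squares cross-check and
#'   `@parameters$nTail` the tail count. Degenerate (zero-variance) input
#'   yields `constant = 0` with a warning flag.
#' @export
defectConstant <- function(x, aMin = 15, minCount = 50L) {
  areas <- if (is(x, "DefectSizeSample")) unlist(x@areas) else as.numeric(x)
  tail <- areas[areas >= aMin]
  if (length(tail) < minCount)
    .stopf("analysis error: only %d defect areas >= %g A^2 (need >= %d)",
           length(tail), aMin, minCount)
  degenerate <- var(tail) == 0
  piHat <- mean(tail - aMin)
  if (degenerate) {
    .warnf("degenerate defect-area sample (all areas equal); constant set to 0")
    piHat <- 0
  }
  ci <- piHat / sqrt(length(tail))
  ## binned log-linear cross-check: log N(A) = const - A/pi; sparse tail
  ## bins (< 5 counts) are excluded, where the log-count noise is strongly
  ## asymmetric
  lls <- NA_real_; llsCI <- NA_real_
  if (!degenerate) {
    h <- hist(tail, breaks = 20, plot = FALSE)
    keep <- h$counts >= 5
    if (sum(keep) >= 3) {
      fit <- summary(lm(log(h$counts[keep]) ~ h$mids[keep]))
      sl <- fit$coefficients[2, 1]
      if (is.finite(sl) && sl < 0) {
        lls <- -1 / sl
        llsCI <- fit$coefficients[2, 2] / sl^2
      }
    }
  }
  prm <- if (is(x, "DefectSizeSample")) x@parameters else list()
  prm$aMin <- aMin
  prm$nTail <- length(tail)
  prm$llsConstant <- unname(lls)
  prm$llsCI <- unname(llsCI)
  prm$degenerate <- degenerate
  new("DefectSizeSample",
      areas = if (is(x, "DefectSizeSample")) x@areas else list(areas),
      parameters = prm, constant = piHat, ci = ci)
}

#' Peptide-centred local thickness and order maps
#'
#' Thickness per radial bin is the difference between the mean phosphate z
#' of the upper and lower leaflets restricted to lipids within the bin
#' (xy minimum image from the peptide center of mass); local S_CC likewise
#' restricted. Empty bins are `NA`, not interpolated.
#'
#' @param trajectory a [Trajectory-class] containing a peptide.
#' @param peptideSel peptide selection.
#' @param radialBreaks radial bin edges, nm.
#' @param tailBeads ordered tail bead names for the local order parameter.
#' @return data.frame with `r` (bin centers), `thickness` (nm), `S` and
#'   `nLipids` per bin (frame-averaged).
#' @export
localMaps <- function(trajectory, peptideSel,
                      radialBreaks = seq(0, 4, by = 0.5),
                      tailBeads = paste0("C", 1:4, "A")) {
  nb <- length(radialBreaks) - 1L
  thick <- matrix(NA_real_, nFrames(trajectory), nb)
  ord <- matrix(NA_real_, nFrames(trajectory), nb)
  cnt <- matrix(0, nFrames(trajectory), nb)
  for (i in seq_len(nFrames(trajectory))) {
    fr <- getFrame(trajectory, i)
    pep <- selectBeads(fr, peptideSel)
    if (!length(pep)) .stopf("input error: empty peptide selection")
    com <- .comOf(fr, pep)
    leafLab <- assignLeaflets(fr)
    m <- fr@beadMeta
    p <- fr@positions
    phos <- which(m$beadName == "PO4")
    ## lipid lateral position = its phosphate
    r <- minImageDistXY(p[phos, 1], p[phos, 2], com[1], com[2], fr@box)
    lab <- leafLab[as.character(m$moleculeId[phos])]
    bin <- findInterval(r, radialBreaks, rightmost.closed = TRUE)
    for (b in seq_len(nb)) {
      up <- phos[bin == b & lab == "upper"]
      lo <- phos[bin == b & lab == "lower"]
      cnt[i, b] <- length(up) + length(lo)
      if (length(up) && length(lo))
        thick[i, b] <- mean(p[up, 3]) - mean(p[lo, 3])
      ids <- m$moleculeId[c(up, lo)]
      if (length(ids)) {
        cz <- .tailBondCos(fr, tailBeads, ids)
        ord[i, b] <- mean(vapply(cz, function(v) mean((3 * v^2 - 1) / 2), 0))
      }
    }
  }
  data.frame(r = (radialBreaks[-1] + radialBreaks[-(nb + 1)]) / 2,
             thickness = colMeans(thick, na.rm = TRUE),
             S = colMeans(ord, na.rm = TRUE),
             nLipids = colMeans(cnt))
}

#' Published reference membrane properties
#'
#' The reported simulation-scale reference values for the three studied
#' membrane compositions: area per lipid and packing defect-area constant
#' (with their uncertainties). These derive from tens of microseconds of
#' coarse-grained sampling and are not reproducible from synthetic
#' fixtures; they are shipped so that user-supplied trajectories (e.g. the
#' deposited simulation data) can be checked against them.
#'
#' @return data.frame with `membrane`, `apl`, `aplSd`, `defectConstant`,
#'   `defectConstantSd` (Angstrom^2).
#' @export
referenceMembraneValues <- function() {
  data.frame(membrane = c("POPC", "DOPC", "PAPC"),
             apl = c(65, 68, 76), aplSd = c(1, 1, 1),
             defectConstant = c(19.2, 22.5, 35.7),
             defectConstantSd = c(0.4, 0.9, 0.2),
             stringsAsFactors = FALSE)
}

#' Check a trajectory against the published membrane reference values
#'
#' Computes area per lipid (and optionally the defect constant) from the
#' supplied trajectory and compares against [referenceMembraneValues()]
#' within `nSigma` combined uncertainties.
#'
#' @param trajectory a [Trajectory-class].
#' @param membrane one of `"POPC"`, `"DOPC"`, `"PAPC"`.
#' @param nPerLeaflet lipids per leaflet.
#' @param nSigma agreement window in combined sd units (default 2).
#' @param checkDefects also fit and compare the defect constant (slower).
#' @param ... passed to [defectSample()] when `checkDefects`.
#' @return data.frame with one row per checked property: `property`,
#'   `computed`, `reference`, `referenceSd`, `agrees`.
#' @export
checkMembraneAgainstReference <- function(trajectory, membrane, nPerLeaflet,
                                          nSigma = 2, checkDefects = FALSE,
                                          ...) {
  ref <- referenceMembraneValues()
  ref <- ref[ref$membrane == membrane, ]
  if (!nrow(ref)) .stopf("unknown membrane '%s'", membrane)
  apl <- areaPerLipid(trajectory, nPerLeaflet)
  rows <- data.frame(property = "apl", computed = apl$mean,
                     reference = ref$apl, referenceSd = ref$aplSd,
                     agrees = abs(apl$mean - ref$apl) <=
                       nSigma * sqrt(ref$aplSd^2 + apl$sd^2),
                     stringsAsFactors = FALSE)
  if (checkDefects) {
    dc <- defectConstant(defectSample(trajectory, ...))
    rows <- rbind(rows, data.frame(
      property = "defectConstant", computed = dc@constant,
      reference = ref$defectConstant, referenceSd = ref$defectConstantSd,
      agrees = abs(dc@constant - ref$defectConstant) <=
        nSigma * sqrt(ref$defectConstantSd^2 + dc@ci^2)))
  }
  rows
}
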