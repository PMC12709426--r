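## Per-frame peptide observables: leaflet assignment, insertion depth in a
## cylindrical phosphate selection, tilt angle, CV coordinates and
## adsorbed/inserted/transmembrane state labels.

#' Assign lipids to leaflets
#'
#' A lipid is `"upper"` if its head (phosphate) center of mass lies above
#' its tail center of mass along +z, else `"lower"`. Because the rule is
#' per-lipid it also works on buckled frames where a global z-cut fails.
#'
#' @param frame a [BeadFrame-class].
#' @param phosphateNames bead names treated as head reference (default
#'   `"PO4"`).
#' @param tailPattern regex matching tail bead names (default Martini-like
#'   `"^[CD][1-9]"`).
#' @return named character vector: moleculeId (as character) -> label.
#'   Molecules without both bead kinds (e.g. peptides) are dropped.
#' @export
assignLeaflets <- function(frame, phosphateNames = "PO4",
                           tailPattern = "^[CD][1-9]") {
  m <- frame@beadMeta
  z <- frame@positions[, 3]
  isHead <- m$beadName %in% phosphateNames
  isTail <- grepl(tailPattern, m$beadName)
  lipids <- intersect(unique(m$moleculeId[isHead]),
                      unique(m$moleculeId[isTail]))
  if (!length(lipids)) .stopf("structural error: no lipid has both phosphate and tail beads")
  headZ <- vapply(split(z[isHead], m$moleculeId[isHead]), mean, 0)
  tailZ <- vapply(split(z[isTail], m$moleculeId[isTail]), mean, 0)
  ids <- as.character(lipids)
  labels <- ifelse(headZ[ids] - tailZ[ids] > 0, "upper", "lower")
  names(labels) <- ids
  labels
}

.comOf <- function(frame, idx) colMeans(frame@positions[idx, , drop = FALSE])

#' Peptide insertion depth within a cylindrical phosphate selection
#'
#' Depth is the z-distance between the mean z of the leaflet's phosphate
#' beads whose xy minimum-image distance to the peptide center of mass is
#' at most `radius`, and the peptide center of mass; the sign is flipped
#' for the lower leaflet so that positive always means deeper (toward the
#' membrane core).
#'
#' @param frame a [BeadFrame-class].
#' @param peptideSel,phosphateSel selections from [beadSelection()].
#' @param leaflet `"upper"` or `"lower"`.
#' @param radius cylinder radius, nm (default 1.0).
#' @return list with `depth` (nm; `NA` if flagged), `nPhosphates` (count in
#'   the cylinder) and `valid`.
#' @export
insertionDepth <- function(frame, peptideSel, phosphateSel,
                           leaflet = c("upper", "lower"), radius = 1.0) {
  leaflet <- match.arg(leaflet)
  leaf <- assignLeaflets(frame)
  pep <- selectBeads(frame, peptideSel)
  if (!length(pep)) .stopf("input error: empty peptide selection")
  phos <- selectBeads(frame, phosphateSel)
  m <- frame@beadMeta
  phos <- phos[leaf[as.character(m$moleculeId[phos])] == leaflet]
  phos <- phos[!is.na(phos)]
  com <- .comOf(frame, pep)
  p <- frame@positions
  d <- minImageDistXY(p[phos, 1], p[phos, 2], com[1], com[2], frame@box)
  sel <- phos[d <= radius]
  if (!length(sel))
    return(list(depth = NA_real_, nPhosphates = 0L, valid = FALSE))
  plane <- mean(p[sel, 3])
  sgn <- if (leaflet == "upper") 1 else -1
  list(depth = sgn * (plane - com[3]), nPhosphates = length(sel),
       valid = TRUE)
}

#' Mean insertion depth over trajectories
#'
#' Averages per-frame depths over all valid frames. With several replicate
#' trajectories, the reported sd is the standard deviation of the replicate
#' means; with one trajectory it is the frame-to-frame sd.
#'
#' @param trajectories a [Trajectory-class] or list of replicates.
#' @param peptideSel,phosphateSel selections.
#' @param leaflet `"upper"` or `"lower"`.
#' @param radius cylinder radius, nm.
#' @return list with `mean`, `sd`, `perFrame` (list per replicate),
#'   `nFlagged` (frames with an empty cylinder, excluded from the mean)
#'   and `nReplicates`.
#' @export
meanDepth <- function(trajectories, peptideSel, phosphateSel,
                      leaflet = "upper", radius = 1.0) {
  if (is(trajectories, "Trajectory")) trajectories <- list(trajectories)
  perFrame <- lapply(trajectories, function(tr)
    vapply(seq_len(nFrames(tr)), function(i)
      insertionDepth(getFrame(tr, i), peptideSel, phosphateSel, leaflet,
                     radius)$depth, 0))
  nFlagged <- sum(vapply(perFrame, function(v) sum(is.na(v)), 0L))
  means <- vapply(perFrame, function(v) mean(v, na.rm = TRUE), 0)
  if (all(is.nan(means))) .stopf("analysis error: no valid frames")
  out <- list(mean = mean(means), perFrame = perFrame, nFlagged = nFlagged,
              nReplicates = length(trajectories))
  out$sd <- if (length(trajectories) > 1) sd(means)
            else sd(perFrame[[1]], na.rm = TRUE)
  out
}

#' Peptide tilt angle
#'
#' Angle between the peptide axis and +z in `[0, 180]` degrees. The axis
#' is the principal component of the backbone bead cloud, oriented from
#' the first to the last bead so that antiparallel orientations are
#' distinguished (CV2 convention).
#'
#' @param frame a [BeadFrame-class].
#' @param backboneSel selection of backbone beads (>= 2 beads).
#' @return angle in degrees.
#' @export
tiltAngle <- function(frame, backboneSel) {
  idx <- selectBeads(frame, backboneSel)
  if (length(idx) < 2) .stopf("input error: need >= 2 backbone beads")
  p <- frame@positions[idx, , drop = FALSE]
  pc <- sweep(p, 2, colMeans(p))
  if (max(abs(pc)) < 1e-12)
    .stopf("analysis error: degenerate backbone (all beads coincident)")
  ax <- eigen(crossprod(pc), symmetric = TRUE)$vectors[, 1]
  ends <- p[length(idx), ] - p[1, ]
  if (sum(ax * ends) < 0) ax <- -ax
  acos(pmin(pmax(ax[3] / sqrt(sum(ax^2)), -1), 1)) * 180 / pi
}

#' Collective variables of a peptide configuration
#'
#' CV1 is the signed z-distance between the peptide center of mass and the
#' membrane (lipid) center of mass; CV2 is the tilt angle from
#' [tiltAngle()].
#'
#' @param frame a [BeadFrame-class].
#' @param peptideSel,membraneSel selections.
#' @return list with `cv1` (nm) and `cv2` (degrees).
#' @export
peptideCV <- function(frame, peptideSel, membraneSel) {
  pep <- selectBeads(frame, peptideSel)
  mem <- selectBeads(frame, membraneSel)
  if (!length(pep) || !length(mem))
    .stopf("input error: empty peptide or membrane selection")
  list(cv1 = .comOf(frame, pep)[3] - .comOf(frame, mem)[3],
       cv2 = tiltAngle(frame, peptideSel))
}

#' Classify a peptide state from its collective variables
#'
#' Transmembrane if `|cv1| <= tmZCut` and the tilt folded into `[0, 90]`
#' is `<= tmTiltCut`; adsorbed (upper/lower by the sign of cv1) if
#' `|cv1| >= adsZCut`; inserted otherwise. The three windows partition the
#' (cv1, cv2) plane; the boundaries are configuration, not
#' literature-fixed values, and are echoed in every report.
#'
#' @param cv1 signed COM z-distance, nm.
#' @param cv2 tilt angle, degrees in `[0, 180]`.
#' @param config an `AnalysisConfig` (uses `tmZCut`, `tmTiltCut`,
#'   `adsZCut`).
#' @return one of `"transmembrane"`, `"adsorbed_upper"`, `"adsorbed_lower"`,
#'   `"inserted"` (vectorized over cv1/cv2).
#' @export
classifyState <- function(cv1, cv2, config = analysisConfig()) {
  n <- max(length(cv1), length(cv2))
  cv1 <- rep_len(cv1, n); cv2 <- rep_len(cv2, n)
  tiltFolded <- pmin(cv2, 180 - cv2)
  out <- rep("inserted", n)
  out[abs(cv1) <= config$tmZCut & tiltFolded <= config$tmTiltCut] <-
    "transmembrane"
  ads <- abs(cv1) >= config$adsZCut & out != "transmembrane"
  out[ads & cv1 > 0] <- "adsorbed_upper"
  out[ads & cv1 < 0] <- "adsorbed_lower"
  out
}
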