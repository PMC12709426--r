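## Orchestration of the two trajectory-level analyses: planar insertion
## (depth vs hydrophobicity with per-membrane regressions and pairwise
## slope tests) and buckled curvature sensing (reweighted distributions,
## mean sensed curvature, leaflet convergence, depth-curvature
## correlation). Reports carry a manifest echoing every parameter so that
## values without a literature-fixed default stay visible.

.manifest <- function(config, inputs, seed = config$seed) {
  list(package = "memsense",
       version = as.character(utils::packageVersion("memsense")),
       seed = seed, config = unclass(config), inputs = inputs)
}

#' Planar insertion analysis
#'
#' For each membrane and peptide, averages the insertion depth over
#' replicate trajectories, regresses depth on peptide mean hydrophobicity
#' per membrane, and runs pairwise two-sample slope tests between
#' membranes.
#'
#' @param systems nested list: `systems[[membrane]][[peptideLabel]]` is a
#'   [Trajectory-class] or list of replicate trajectories, each containing
#'   one peptide (moleculeName `"PEP"`) on the upper leaflet.
#' @param config an `AnalysisConfig`.
#' @param hydrophobicity named numeric vector mapping peptide labels to
#'   mean hydrophobicity; defaults to the built-in registry.
#' @return list with `depths` (data.frame membrane/peptide/depth/sd/
#'   hydrophobicity), `fits` (per-membrane slope, intercept, slope SE; NULL
#'   when fewer than 3 peptides), `slopeTests` (pairwise data.frame) and
#'   `manifest`.
#' @export
runInsertionAnalysis <- function(systems, config = analysisConfig(),
                                 hydrophobicity = NULL) {
  if (is.null(hydrophobicity)) {
    tb <- peptideTable()
    hydrophobicity <- setNames(tb$meanHydrophobicity, tb$label)
  }
  pepSel <- beadSelection("peptide", moleculeName = "PEP")
  phosSel <- beadSelection("phosphates", beadName = "PO4")
  rows <- NULL
  for (mem in names(systems)) {
    for (pep in names(systems[[mem]])) {
      if (!pep %in% names(hydrophobicity))
        .stopf("config error: no hydrophobicity for peptide '%s'", pep)
      md <- meanDepth(systems[[mem]][[pep]], pepSel, phosSel,
                      leaflet = "upper", radius = config$cylinderRadius)
      rows <- rbind(rows, data.frame(
        membrane = mem, peptide = pep, depth = md$mean, sd = md$sd,
        hydrophobicity = unname(hydrophobicity[pep]),
        nReplicates = md$nReplicates, nFlagged = md$nFlagged,
        stringsAsFactors = FALSE))
    }
  }
  fits <- lapply(split(rows, rows$membrane), function(d) {
    if (nrow(d) < 3) return(NULL)
    f <- summary(lm(depth ~ hydrophobicity, data = d))
    list(slope = f$coefficients[2, 1], slopeSE = f$coefficients[2, 2],
         intercept = f$coefficients[1, 1], n = nrow(d))
  })
  mems <- names(systems)
  tests <- NULL
  if (length(mems) >= 2) {
    for (i in seq_len(length(mems) - 1)) for (j in (i + 1):length(mems)) {
      dA <- rows[rows$membrane == mems[i], ]
      dB <- rows[rows$membrane == mems[j], ]
      if (nrow(dA) < 3 || nrow(dB) < 3) next
      st <- slopeDifferenceTest(dA$hydrophobicity, dA$depth,
                                dB$hydrophobicity, dB$depth)
      tests <- rbind(tests, data.frame(
        membraneA = mems[i], membraneB = mems[j], slopeA = st$slopeA,
        slopeB = st$slopeB, t = st$t, df = st$df, p = st$p,
        stringsAsFactors = FALSE))
    }
  }
  list(depths = rows, fits = fits, slopeTests = tests,
       manifest = .manifest(config, lapply(systems, names)))
}

## accessible distribution averaged over (a stride of) frames of one
## leaflet of a buckled trajectory
.accessibleFromTrajectory <- function(trajectory, phosphateSel, leaflet,
                                      config, stride = 10L) {
  idx <- seq(1L, nFrames(trajectory), by = stride)
  acc <- NULL
  for (i in idx) {
    fr <- getFrame(trajectory, i)
    leafLab <- assignLeaflets(fr)
    m <- fr@beadMeta
    phos <- selectBeads(fr, phosphateSel)
    phos <- phos[leafLab[as.character(m$moleculeId[phos])] == leaflet]
    fit <- fitSurface(fr@positions[phos, , drop = FALSE], fr@box[1:2],
                      config$fourierModes[1], config$fourierModes[2],
                      leaflet = leaflet)
    a <- accessibleCurvature(fit, breaks = config$curvatureBreaks)
    acc <- if (is.null(acc)) a@weights else acc + a@weights
  }
  new("CurvatureDistribution", breaks = config$curvatureBreaks,
      weights = acc / sum(acc), kind = "accessible", leaflet = leaflet,
      nSamples = length(idx), masked = rep(FALSE, length(acc)))
}

#' Buckled-membrane curvature sensing analysis
#'
#' For each membrane and peptide: samples the curvature at the peptide
#' position per leaflet, builds the accessible distribution from the
#' fitted surfaces, reweights, reports the mean sensed curvature per
#' leaflet and their average, and the leaflet-agreement diagnostic. If
#' insertion depths are supplied, the depth-curvature Pearson correlation
#' is computed per membrane.
#'
#' @param systems nested list: `systems[[membrane]][[peptideLabel]]` is a
#'   list with `upper` and `lower` [Trajectory-class] objects (one peptide
#'   on the named leaflet each).
#' @param config an `AnalysisConfig`.
#' @param depths optional data.frame with `membrane`, `peptide`, `depth`
#'   (e.g. from [runInsertionAnalysis()]`$depths`).
#' @param accessibleStride frame stride for the accessible-distribution
#'   average.
#' @return list with `sensing` (data.frame per membrane x peptide:
#'   meanCurvature, per-leaflet means, leaflet TV distance, convergence
#'   flag), `distributions` (reweighted, per system and leaflet),
#'   `correlations` (per membrane, when depths given) and `manifest`.
#' @export
runSensingAnalysis <- function(systems, config = analysisConfig(),
                               depths = NULL, accessibleStride = 10L) {
  pepSel <- beadSelection("peptide", moleculeName = "PEP")
  phosSel <- beadSelection("phosphates", beadName = "PO4")
  rows <- NULL
  dists <- list()
  for (mem in names(systems)) {
    for (pep in names(systems[[mem]])) {
      sys <- systems[[mem]][[pep]]
      perLeaf <- lapply(c(upper = "upper", lower = "lower"), function(lf) {
        tr <- sys[[lf]]
        s <- samplePeptideCurvature(tr, pepSel, phosSel, lf,
                                    config$fourierModes[1],
                                    config$fourierModes[2])
        samp <- curvatureHistogram(s$H, config$curvatureBreaks,
                                   kind = "sampled", leaflet = lf)
        acc <- .accessibleFromTrajectory(tr, phosSel, lf, config,
                                         accessibleStride)
        rw <- reweightCurvature(samp, acc, config$maskThreshold)
        list(rw = rw, mean = meanSensedCurvature(rw))
      })
      agree <- leafletAgreement(perLeaf$upper$rw, perLeaf$lower$rw)
      rows <- rbind(rows, data.frame(
        membrane = mem, peptide = pep,
        meanCurvature = (perLeaf$upper$mean + perLeaf$lower$mean) / 2,
        meanUpper = perLeaf$upper$mean, meanLower = perLeaf$lower$mean,
        leafletTV = agree$tv, converged = agree$converged,
        stringsAsFactors = FALSE))
      if (!agree$converged)
        .warnf("leaflet distributions not converged for %s/%s (TV = %.3f)",
               mem, pep, agree$tv)
      dists[[paste(mem, pep, sep = ".")]] <-
        list(upper = perLeaf$upper$rw, lower = perLeaf$lower$rw)
    }
  }
  correlations <- NULL
  if (!is.null(depths)) {
    merged <- merge(rows, depths[, c("membrane", "peptide", "depth")],
                    by = c("membrane", "peptide"))
    correlations <- lapply(split(merged, merged$membrane), function(d) {
      if (nrow(d) < 3) return(NULL)
      depthCurvatureCorrelation(d$depth, d$meanCurvature)
    })
  }
  list(sensing = rows, distributions = dists, correlations = correlations,
       manifest = .manifest(config, lapply(systems, names)))
}

#' Write a JSON run report
#'
#' @param report a list from one of the run functions.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRunReport <- function(report, path) {
  keep <- report[setdiff(names(report), "distributions")]
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
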