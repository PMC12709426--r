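test_that("area per lipid is exact arithmetic on the projected box", {
  tr <- newTrajectory(list(matrix(c(1, 1, 1), 1), matrix(c(1, 1, 1), 1)),
                      boxes = c(6, 6, 8),
                      beadMeta = data.frame(moleculeId = 1L,
                                            moleculeName = "POPC",
                                            beadName = "PO4"))
  out <- areaPerLipid(tr, 50)
  expect_equal(out$mean, 72)       # 36 nm^2 / 50 -> A^2
  expect_equal(out$sd, 0)
  expect_equal(areaPerLipid(cleanPlanar(), 92)$mean, 65)
})

test_that("order parameters hit the P2 limits and the isotropic null", {
  ## generator tails run along z: S = 1 for every bond
  ord <- sccOrder(cleanPlanar(n = 16))
  expect_equal(ord$S, rep(1, 3), tolerance = 1e-12)
  ## synthetic frames with bonds in the xy plane: S = -1/2
  mkLipid <- function(id, x, y, vecs) {
    ## PO4 then C1A..C3A chained by the given bond vectors
    pos <- rbind(c(x, y, 3.2), c(x, y, 3))
    for (v in vecs) pos <- rbind(pos, pos[nrow(pos), ] + v)
    list(pos = pos,
         meta = data.frame(moleculeId = id, moleculeName = "POPC",
                           beadName = c("NC3", "PO4", "C1A", "C2A", "C3A")))
  }
  flatBond <- list(c(0.2, 0, -0.4), c(0.3, 0, 0), c(0, 0.3, 0))
  lips <- lapply(1:9, function(i)
    mkLipid(i, (i - 1) %% 3 + 1, (i - 1) %/% 3 + 1, flatBond))
  fr <- newBeadFrame(do.call(rbind, lapply(lips, `[[`, "pos")),
                     c(6, 6, 6), do.call(rbind, lapply(lips, `[[`, "meta")))
  tr <- newTrajectory(list(beadPositions(fr)), c(6, 6, 6),
                      beadMeta = beadMeta(fr))
  ord2 <- sccOrder(tr, tailBeads = c("C1A", "C2A", "C3A"))
  expect_equal(ord2$S, c(-0.5, -0.5), tolerance = 1e-12)
  ## isotropic bonds average to zero
  set.seed(81)
  n <- 1e5
  u <- matrix(rnorm(3 * n), ncol = 3)
  cz <- u[, 3] / sqrt(rowSums(u^2))
  expect_equal(mean((3 * cz^2 - 1) / 2), 0, tolerance = 0.005)
  ## bounds on arbitrary random inputs
  expect_true(all(ord$S <= 1 & ord$S >= -0.5))
})

test_that("density profiles are symmetric and additive over groups", {
  tr <- genPlanarBilayer(bilayerParams(nPerLeaflet = 64, jitterXY = 0.02,
                                       jitterZ = 0.05, seed = 13),
                         nFrames = 30)
  sels <- list(phos = beadSelection("p", beadName = "PO4"),
               tails = beadSelection("t",
                                     beadName = paste0("C", 1:4, "A")),
               heads = beadSelection("h", beadName = "NC3"),
               all = beadSelection("a"))
  dp <- densityProfile(tr, sels, binWidth = 0.2)
  ## partition identity, bin by bin
  expect_equal(dp$phos + dp$tails + dp$heads, dp$all, tolerance = 1e-9)
  ## phosphate profile symmetric about the membrane COM
  w <- dp$phos
  asym <- sum(abs(w - rev(w))) / sum(w)
  expect_lt(asym, 0.1)
  ## single fixed bead lands in its bin
  one <- newTrajectory(list(matrix(c(1, 1, 6), 1)), c(5, 5, 12),
                       beadMeta = data.frame(moleculeId = 1L,
                                             moleculeName = "X",
                                             beadName = "B"))
  d1 <- densityProfile(one, list(b = beadSelection("b", beadName = "B")),
                       binWidth = 0.5, zRange = c(-3, 3))
  expect_equal(sum(d1$b > 0), 1)
  expect_gt(d1$b[abs(d1$z - 0.25) < 1e-9], 0)
})

test_that("defect detection matches a brute-force cell scan", {
  ## covering lattice: spacing 0.7 nm; radius 0.58 covers every cell
  ## center (max center-to-site distance ~0.55 nm) without boundary ties
  p0 <- bilayerParams(nPerLeaflet = 100, targetAPL = 49, jitterXY = 0,
                      jitterZ = 0)
  fr <- getFrame(genPlanarBilayer(p0), 1)
  expect_length(detectDefects(fr, "upper", beadRadius = 0.58), 0)
  ## delete one lipid: exactly one defect, area = brute-force cell count
  m <- beadMeta(fr)
  gone <- unique(m$moleculeId[m$beadName == "PO4"])[45]
  keep <- m$moleculeId != gone
  fr2 <- newBeadFrame(beadPositions(fr)[keep, ], boxVectors(fr), m[keep, ],
                      wrap = FALSE)
  d <- detectDefects(fr2, "upper", beadRadius = 0.58)
  expect_length(d, 1)
  brute <- bruteDefectCells(fr2, "upper", beadRadius = 0.58)
  cellA <- prod(boxVectors(fr2)[1:2] / dim(brute)) * 100
  expect_equal(d, sum(brute) * cellA, tolerance = 1e-9)
  ## two holes separated by occupied cells: two defects
  gone2 <- unique(m$moleculeId[m$beadName == "PO4"])[c(23, 67)]
  keep2 <- !m$moleculeId %in% gone2
  fr3 <- newBeadFrame(beadPositions(fr)[keep2, ], boxVectors(fr),
                      m[keep2, ], wrap = FALSE)
  expect_length(detectDefects(fr3, "upper", beadRadius = 0.58), 2)
})

test_that("deep exposed tails count as defects; grid origin shifts are bounded", {
  p0 <- bilayerParams(nPerLeaflet = 100, targetAPL = 49, jitterXY = 0,
                      jitterZ = 0)
  fr <- getFrame(genPlanarBilayer(p0), 1)
  m <- beadMeta(fr)
  p <- beadPositions(fr)
  ## push one lipid's head beads deep below the phosphate level so its
  ## exposed tail bead tops the column
  leaf <- assignLeaflets(fr)
  upperIds <- as.integer(names(leaf)[leaf == "upper"])
  id <- upperIds[50]
  rows <- which(m$moleculeId == id & m$beadName %in% c("NC3", "PO4"))
  p[rows, 3] <- p[rows, 3] - 1.5
  frD <- newBeadFrame(p, boxVectors(fr), m, wrap = FALSE)
  d <- detectDefects(frD, "upper", beadRadius = 0.58)
  expect_length(d, 1)
  ## shifting the grid origin (via a rigid xy shift) changes the area by
  ## at most perimeter * gridStep
  shift <- p
  shift[, 1] <- shift[, 1] + 0.05
  frS <- newBeadFrame(shift, boxVectors(fr), m, wrap = TRUE)
  d2 <- detectDefects(frS, "upper", beadRadius = 0.58)
  expect_length(d2, 1)
  nCells <- d / (0.1^2 * 100)          # cell area = 1 A^2 at 0.1 nm step
  perimCells <- 4 * sqrt(nCells) + 8   # square-ish bound on the perimeter
  expect_lt(abs(d2 - d), perimCells * 1 + 1e-9)
})

test_that("the defect constant MLE recovers programmed constants", {
  dc <- defectConstant(genDefectAreas(30, n = 1e4, seed = 3))
  expect_equal(defectConstantValue(dc), 30, tolerance = 1.5 / 30)
  expect_equal(dc@ci, defectConstantValue(dc) / 100, tolerance = 1e-9)
  ## least-squares cross-check agrees within its own CI
  expect_lt(abs(dc@parameters$llsConstant - defectConstantValue(dc)),
            2 * dc@parameters$llsCI)
  ## memorylessness: invariance to the tail cutoff
  for (am in c(15, 20, 25)) {
    dcm <- defectConstant(genDefectAreas(30, n = 1e4, seed = 3), aMin = am)
    expect_equal(defectConstantValue(dcm), 30,
                 tolerance = 3 * dcm@ci / 30)
  }
  ## degenerate input
  expect_warning(dcD <- defectConstant(rep(20, 100)), "degenerate")
  expect_equal(defectConstantValue(dcD), 0)
  expect_true(dcD@parameters$degenerate)
})

test_that("defect-constant CI has near-nominal one-sigma coverage", {
  nRep <- 200; n <- 400; piTrue <- 30
  hits <- vapply(seq_len(nRep), function(i) {
    dc <- defectConstant(genDefectAreas(piTrue, n = n, seed = 1000 + i))
    abs(defectConstantValue(dc) - piTrue) <= dc@ci
  }, TRUE)
  expect_gt(mean(hits), 0.58)
  expect_lt(mean(hits), 0.78)
})

test_that("local maps resolve programmed thinning and translation invariance", {
  p0 <- bilayerParams(nPerLeaflet = 400, targetAPL = 65, jitterXY = 0,
                      jitterZ = 0, thinAmplitude = 0.4, thinSigma = 1)
  tr <- addPeptide(genPlanarBilayer(p0), "upper", depth = 0.5)
  lm1 <- localMaps(tr, selPep, radialBreaks = seq(0, 4, by = 0.5))
  near <- lm1$thickness[2]             # first populated bin, r ~ 0.75 nm
  far <- lm1$thickness[nrow(lm1)]
  expect_lt(near, 3.75)
  expect_equal(far, 4.0, tolerance = 0.02)
  ## xy translation of the whole system leaves the map unchanged
  fr <- getFrame(tr, 1)
  p <- beadPositions(fr); p[, 1] <- p[, 1] + 3.1; p[, 2] <- p[, 2] + 1.7
  tr2 <- newTrajectory(list(p), tr@boxes, tr@times, beadMeta(fr))
  lm2 <- localMaps(tr2, selPep, radialBreaks = seq(0, 4, by = 0.5))
  expect_equal(lm2$thickness, lm1$thickness, tolerance = 1e-9)
  ## homogeneous membrane: all populated bins at the nominal thickness
  trH <- addPeptide(cleanPlanar(n = 400), "upper", depth = 0.5)
  lmH <- localMaps(trH, selPep, radialBreaks = seq(0, 4, by = 0.5))
  ok <- lmH$nLipids > 0
  expect_equal(lmH$thickness[ok], rep(4, sum(ok)), tolerance = 1e-9)
})

test_that("reference comparison machinery distinguishes matching membranes", {
  tr <- genPlanarBilayer(bilayerParams(nPerLeaflet = 92, targetAPL = 65,
                                       seed = 17), nFrames = 3)
  chk <- checkMembraneAgainstReference(tr, "POPC", 92)
  expect_true(chk$agrees[chk$property == "apl"])
  chkBad <- checkMembraneAgainstReference(tr, "PAPC", 92)
  expect_false(chkBad$agrees[chkBad$property == "apl"])
  expect_error(checkMembraneAgainstReference(tr, "DMPC", 92), "unknown")
})
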