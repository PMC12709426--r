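test_that("curvature sampled at pinned peptides equals the closed form", {
  tr <- cleanBuckle(n = 800, nFrames = 3)
  Ly <- tr@boxes[1, 2]
  for (lf in c("upper", "lower")) {
    trp <- addPeptide(tr, lf, depth = 0.3, tilt = 90, x = 5, y = Ly / 2)
    s <- samplePeptideCurvature(trp, selPep, selPhos, lf)
    expected <- if (lf == "upper") -0.04934802 else 0.04934802
    expect_equal(s$H, rep(expected, 3), tolerance = 1e-5)
  }
  ## planar membrane: curvature indistinguishable from zero
  trF <- addPeptide(cleanPlanar(n = 400), "upper", depth = 0.3)
  sF <- samplePeptideCurvature(trF, selPep, selPhos, "upper")
  expect_lt(max(abs(sF$H)), 1e-3)
})

test_that("reweighting identities hold: identity case, masking, scale", {
  br <- seq(-0.1, 0.1, by = 0.01)
  mk <- function(w, kind) new("CurvatureDistribution", breaks = br,
                              weights = w / sum(w), kind = kind,
                              leaflet = "upper", nSamples = 1000,
                              masked = rep(FALSE, length(w)))
  set.seed(91)
  w <- runif(20, 0.5, 2)
  acc <- mk(w, "accessible")
  rw <- reweightCurvature(mk(w, "sampled"), acc)
  wr <- binWeights(rw)[!maskedBins(rw)]
  expect_lt(max(abs(wr - wr[1])), 1e-12)      # flat over unmasked bins
  ## a zero accessible bin inside the support is masked with a warning
  w2 <- w; w2[7] <- 0
  samp <- mk(w, "sampled")
  expect_warning(rw2 <- reweightCurvature(samp, mk(w2, "accessible")),
                 "masked")
  expect_true(maskedBins(rw2)[7])
  expect_equal(sum(binWeights(rw2)), 1, tolerance = 1e-12)
  ## disjoint supports fail
  wl <- c(rep(1, 10), rep(0, 10)); wr2 <- rev(wl)
  expect_error(
    suppressWarnings(reweightCurvature(mk(wl, "sampled"),
                                       mk(wr2, "accessible"))),
    "disjoint")
  expect_error(reweightCurvature(acc, acc), "sampled")
})

test_that("mean sensed curvature is the distribution mean", {
  br <- seq(-0.1, 0.1, by = 0.01)
  w <- rep(0, 20); w[6] <- 1   # delta at center -0.045
  d <- new("CurvatureDistribution", breaks = br, weights = w,
           kind = "reweighted", leaflet = "upper", nSamples = 1,
           masked = rep(FALSE, 20))
  expect_equal(meanSensedCurvature(d), -0.045, tolerance = 1e-12)
  ws <- dnorm(seq(-0.095, 0.095, by = 0.01), 0, 0.03)
  ds <- new("CurvatureDistribution", breaks = br, weights = ws / sum(ws),
            kind = "reweighted", leaflet = "upper", nSamples = 1,
            masked = rep(FALSE, 20))
  expect_equal(meanSensedCurvature(ds), 0, tolerance = 1e-12)
})

test_that("biased sampling recovers mean curvature against quadrature", {
  fit <- fitUpperSurface(getFrame(cleanBuckle(n = 800), 1))
  br <- seq(-0.15, 0.15, by = 0.005)
  acc <- accessibleCurvature(fit, breaks = br)
  xy <- sampleBiasedPositions(1, 20, Ly = 10, a = 10, n = 1e5, seed = 19)
  H <- curvatureAt(fit, xy$x, xy$y)$H
  rw <- reweightCurvature(curvatureHistogram(H, br), acc)
  ## oracle: the reweighted density is exp(a H) over the accessible
  ## curvature support [-Ak^2/2, Ak^2/2]
  cmax <- (2 * pi / 20)^2 / 2
  oracle <- tiltedUniformMean(10, cmax)
  expect_lt(abs(meanSensedCurvature(rw) - oracle), 0.05 * abs(oracle) + 1e-4)
})

test_that("leaflet agreement is a total-variation distance", {
  br <- seq(-0.1, 0.1, by = 0.01)
  mk <- function(w) new("CurvatureDistribution", breaks = br,
                        weights = w / sum(w), kind = "reweighted",
                        leaflet = "upper", nSamples = 100,
                        masked = rep(FALSE, 20))
  a <- mk(runif(20))
  expect_equal(leafletAgreement(a, a)$tv, 0)
  expect_true(leafletAgreement(a, a)$converged)
  d1 <- rep(0, 20); d1[1] <- 1
  d2 <- rep(0, 20); d2[20] <- 1
  expect_equal(leafletAgreement(mk(d1), mk(d2))$tv, 1)
  ## two independent draws of the same biased process converge
  fit <- fitUpperSurface(getFrame(cleanBuckle(n = 800), 1))
  brb <- seq(-0.15, 0.15, by = 0.005)
  acc <- accessibleCurvature(fit, breaks = brb)
  rws <- lapply(c(23, 24), function(s) {
    xy <- sampleBiasedPositions(1, 20, 10, a = 5, n = 1e4, seed = s)
    reweightCurvature(
      curvatureHistogram(curvatureAt(fit, xy$x, xy$y)$H, brb), acc)
  })
  expect_lt(leafletAgreement(rws[[1]], rws[[2]])$tv, 0.05)
})

test_that("depth-curvature correlation matches the covariance formula", {
  expect_equal(depthCurvatureCorrelation(c(0, 1, 2), c(3, 2, 1))$r, -1,
               tolerance = 1e-12)
  expect_equal(depthCurvatureCorrelation(c(0, 1, 2), c(0, 1, 0))$r, 0,
               tolerance = 1e-12)
  set.seed(101)
  depth <- runif(6, 0, 1)
  curv <- -0.05 * depth + rnorm(6, 0, 0.001)
  out <- depthCurvatureCorrelation(depth, curv)
  direct <- sum((depth - mean(depth)) * (curv - mean(curv))) /
    sqrt(sum((depth - mean(depth))^2) * sum((curv - mean(curv))^2))
  expect_equal(out$r, direct, tolerance = 1e-12)
  expect_lt(out$r, -0.9)
  expect_error(depthCurvatureCorrelation(c(1, 1, 1), c(1, 2, 3)),
               "zero variance")
  expect_error(depthCurvatureCorrelation(1:2, 1:2), ">= 3")
})

test_that("slope-difference test behaves at the null and at huge effects", {
  x <- 1:6
  set.seed(111)
  yA <- 2 * x + rnorm(6, 0, 0.1)
  out0 <- slopeDifferenceTest(x, yA, x, yA)
  expect_equal(out0$t, 0)
  expect_equal(out0$p, 1)
  ## slopes 1 vs 2 with tiny residuals: overwhelming evidence
  yB <- 1 * x + rnorm(6, 0, 1e-4)
  yC <- 2 * x + rnorm(6, 0, 1e-4)
  expect_lt(slopeDifferenceTest(x, yB, x, yC)$p, 1e-6)
  expect_error(slopeDifferenceTest(rep(1, 4), 1:4, x, yA), "degenerate")
})

test_that("slope test type-I error is calibrated at the nominal level", {
  set.seed(121)
  nRep <- 1000
  x <- seq(0, 1, length.out = 8)
  rej <- vapply(seq_len(nRep), function(i) {
    yA <- x + rnorm(8, 0, 0.3)
    yB <- x + rnorm(8, 0, 0.3)
    slopeDifferenceTest(x, yA, x, yB)$p < 0.05
  }, TRUE)
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("per-frame fitting recovers the bias end to end", {
  ## the module's headline property: a peptide whose lateral motion is
  ## biased by exp(a H) yields a reweighted distribution with log-slope a,
  ## through per-frame surface fits on lightly jittered membranes
  nF <- 150
  p <- bilayerParams(nPerLeaflet = 512, targetAPL = 65, jitterXY = 0.02,
                     jitterZ = 0.02, buckleAmplitude = 1,
                     buckleWavelength = 20, seed = 31)
  tr <- genBuckledBilayer(p, nFrames = nF)
  Ly <- tr@boxes[1, 2]
  xy <- sampleBiasedPositions(1, 20, Ly, a = 10, n = nF, seed = 33)
  trp <- addPeptide(tr, "upper", depth = 0.3, tilt = 90, x = xy$x, y = xy$y)
  s <- samplePeptideCurvature(trp, selPep, selPhos, "upper", Mx = 3, My = 1)
  ## compare frame-fitted H against the analytic surface value
  gtH <- buckleMeanCurvature(xy$x, 1, 20)
  expect_lt(sqrt(mean((s$H - gtH)^2)), 0.01)
})
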