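RGAS <- 8.314462618e-3

test_that("cv2-independent landscapes marginalize to a shifted copy", {
  cv1 <- seq(-2, 2, by = 0.05)
  cv2 <- seq(0, 180, by = 5)
  g <- 3 * cv1^2
  fes <- new("FES2D", cv1 = cv1, cv2 = cv2,
             G = matrix(g, length(cv1), length(cv2)), temperature = 310,
             meta = list())
  marg <- marginalizeCV2(fes)
  ## constant integrand: output = input + RT log(C / range) = input here
  expect_lt(max(abs(pmfValues(marg) - g)), 1e-9)
  expect_lt(max(abs(pmfValues(shiftMinZero(marg)) - g)), 1e-9)
})

test_that("harmonic cv2 landscapes match the closed-form Gaussian integral", {
  cv1 <- seq(-2, 2, by = 0.1)
  cv2 <- seq(-60, 60, by = 0.25)   # wide, fine grid in degrees
  kdeg <- 0.1                      # kJ/mol/deg^2
  g <- 5 * cos(cv1)
  G <- outer(g, 0.5 * kdeg * cv2^2, `+`)
  T <- 310; beta <- 1 / (RGAS * T)
  fes <- new("FES2D", cv1 = cv1, cv2 = cv2, G = G, temperature = T,
             meta = list())
  C <- diff(range(cv2)) * pi / 180
  marg <- marginalizeCV2(fes, C = C)
  ## analytic: -RT log( sqrt(2 pi / (beta k_rad)) / C ), k in rad units
  krad <- kdeg * (180 / pi)^2
  offset <- -(1 / beta) * log(sqrt(2 * pi / (beta * krad)) / C)
  dev <- pmfValues(marg) - g - offset
  expect_lt(max(abs(dev - mean(dev))), 1e-6)   # constant across cv1
  expect_lt(max(abs(dev)), 1e-3)               # quadrature ~ analytic
  ## grid-refinement convergence of the trapezoid rule
  cv2f <- seq(-60, 60, by = 0.025)
  fesf <- new("FES2D", cv1 = cv1, cv2 = cv2f,
              G = outer(g, 0.5 * kdeg * cv2f^2, `+`), temperature = T,
              meta = list())
  expect_lt(max(abs(pmfValues(marginalizeCV2(fesf, C = C)) -
                      pmfValues(marg))), 1e-4)
})

test_that("marginalization respects the log-sum-exp lower bound", {
  set.seed(71)
  for (rep in 1:5) {
    cv1 <- seq(-1, 1, length.out = 11)
    cv2 <- seq(0, 180, length.out = 25)
    G <- matrix(runif(11 * 25, 0, 50), 11, 25)
    T <- runif(1, 280, 350)
    fes <- new("FES2D", cv1 = cv1, cv2 = cv2, G = G, temperature = T,
               meta = list())
    C <- runif(1, 0.5, 5)
    marg <- pmfValues(marginalizeCV2(fes, C = C))
    bound <- apply(G, 1, min) -
      RGAS * T * log(diff(range(cv2)) * pi / 180 / C)
    expect_true(all(marg >= bound - 1e-9))
  }
})

test_that("marginalization is stable under huge global offsets", {
  fes <- genFES2D(ddg = 12, barrier = 20)
  fesOff <- new("FES2D", cv1 = fes@cv1, cv2 = fes@cv2, G = fes@G + 1e6,
                temperature = fes@temperature, meta = list())
  a <- pmfValues(shiftMinZero(marginalizeCV2(fes)))
  b <- pmfValues(shiftMinZero(marginalizeCV2(fesOff)))
  expect_lt(max(abs(a - b)), 1e-6)
})

test_that("unvisited bins are tolerated at edges and fatal inside", {
  cv1 <- seq(-1, 1, by = 0.5)
  cv2 <- seq(0, 180, by = 30)
  G <- matrix(1, length(cv1), length(cv2))
  Gedge <- G; Gedge[2, 1] <- NA
  fes <- new("FES2D", cv1 = cv1, cv2 = cv2, G = Gedge, temperature = 310,
             meta = list())
  expect_warning(marginalizeCV2(fes), "edges")
  Gmid <- G; Gmid[2, 4] <- NA
  fes2 <- new("FES2D", cv1 = cv1, cv2 = cv2, G = Gmid, temperature = 310,
              meta = list())
  expect_error(suppressWarnings(marginalizeCV2(fes2)), "interior")
  Gall <- G; Gall[3, ] <- NA
  fes3 <- new("FES2D", cv1 = cv1, cv2 = cv2, G = Gall, temperature = 310,
              meta = list())
  expect_error(marginalizeCV2(fes3), "all-unvisited")
})

test_that("symmetrization halves the leaflet asymmetry and is idempotent", {
  z <- seq(-1, 1, by = 0.1)
  pm <- function(G) new("PMF1D", cv1 = z, G = G, error = numeric(0),
                        states = list(), temperature = 310)
  even <- pm(z^2)
  s1 <- symmetrizePMF(even)
  expect_equal(pmfValues(s1), z^2, tolerance = 1e-12)
  expect_lt(max(pmfError(s1)), 1e-12)
  anti <- pm(z)
  s2 <- symmetrizePMF(anti)
  expect_lt(max(abs(pmfValues(s2))), 1e-12)
  expect_equal(pmfError(s2), abs(z), tolerance = 1e-12)
  ## programmed 1 kJ/mol asymmetry between leaflet branches
  s3 <- symmetrizePMF(pm(z^2 + 0.5 * sign(z)))
  expect_equal(max(pmfError(s3)), 0.5, tolerance = 1e-12)
  ## idempotence
  expect_equal(pmfValues(symmetrizePMF(s3)), pmfValues(s3),
               tolerance = 1e-12)
  ## asymmetric grid refused unless interpolation requested
  bad <- new("PMF1D", cv1 = c(-1, -0.5, 0, 0.5, 0.7), G = rep(1, 5),
             error = numeric(0), states = list(), temperature = 310)
  expect_error(symmetrizePMF(bad), "symmetric")
  expect_s4_class(symmetrizePMF(bad, interpolate = TRUE), "PMF1D")
})

test_that("minimum shift is exact, idempotent and gap-preserving", {
  fes <- genFES2D(ddg = 15, barrier = 25)
  pmf <- marginalizeCV2(fes)
  sh <- shiftMinZero(pmf)
  expect_equal(min(pmfValues(sh)), 0, tolerance = 1e-12)
  expect_equal(pmfValues(shiftMinZero(sh)), pmfValues(sh),
               tolerance = 1e-12)
  expect_equal(pmfStates(deltaDeltaG(sh))$ddg,
               pmfStates(deltaDeltaG(pmf))$ddg, tolerance = 1e-12)
})

test_that("the adsorbed-TM gap is C-invariant and shift-invariant", {
  fes <- genFES2D(ddg = 20, barrier = 30)
  d0 <- pmfStates(deltaDeltaG(marginalizeCV2(fes)))$ddg
  for (C in c(0.1, 1, 10)) {
    dC <- pmfStates(deltaDeltaG(marginalizeCV2(fes, C = C)))$ddg
    expect_equal(dC, d0, tolerance = 1e-9)
  }
  expect_equal(d0, 20, tolerance = 0.1)
})

test_that("monotonic profiles trigger a state-detection error", {
  pmf <- new("PMF1D", cv1 = seq(-2, 2, by = 0.1),
             G = seq(-2, 2, by = 0.1) * 3, error = numeric(0),
             states = list(), temperature = 310)
  expect_error(deltaDeltaG(pmf), "state-detection")
})

test_that("Boltzmann inversion inverts analytic and synthetic densities", {
  z <- seq(-2, 2, by = 0.01)
  T <- 310
  rho <- exp(-(z / 0.5)^2 / 2)
  G <- pmfValues(boltzmannInvert(z, rho, T))
  expect_lt(max(abs(G - RGAS * T * z^2 / (2 * 0.5^2))), 1e-9)
  ## uniform density: flat zero profile
  expect_lt(max(abs(pmfValues(boltzmannInvert(z, rep(2, length(z)), T)))),
            1e-12)
  ## round trip through exp(-beta G)
  G0 <- 7 * (1 - cos(z))
  back <- pmfValues(boltzmannInvert(z, exp(-G0 / (RGAS * T)), T))
  expect_lt(max(abs(back - (G0 - min(G0)))), 1e-9)
  ## zero bins flagged, not -Inf
  rho2 <- rho; rho2[1:5] <- 0
  expect_true(all(is.na(pmfValues(boltzmannInvert(z, rho2, T))[1:5])))
  expect_error(boltzmannInvert(z, rep(0, length(z)), T), "all-zero")
})

test_that("text landscape import reconstructs the grid", {
  fes <- genFES2D(ddg = 10, barrier = 15, n1 = 31, cv2 = seq(0, 180, 30))
  path <- withr::local_tempfile(fileext = ".dat")
  grid <- expand.grid(cv1 = fes@cv1, cv2 = fes@cv2)
  writeLines(c("# cv1 cv2 G",
               sprintf("%.6f %.6f %.10f", grid$cv1, grid$cv2,
                       as.vector(fes@G))), path)
  back <- readFESTable(path, temperature = 310)
  expect_equal(back@cv1, fes@cv1, tolerance = 1e-9)
  expect_equal(back@G, fes@G, tolerance = 1e-9)
  expect_equal(pmfStates(deltaDeltaG(marginalizeCV2(back)))$ddg, 10,
               tolerance = 0.1)
})
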