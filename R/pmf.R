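## Free-energy landscape post-processing: Boltzmann marginalization of the
## tilt variable, leaflet symmetrization, minimum shifting, state location
## and the adsorbed-to-transmembrane gap, plus Boltzmann inversion of
## density profiles. All energies kJ/mol; R = 8.314462618e-3 kJ/(mol K).

## trapezoid quadrature weights for an arbitrary strictly-increasing grid
.trapWeights <- function(x) {
  n <- length(x)
  if (n < 2) .stopf("need >= 2 grid points for quadrature")
  w <- numeric(n)
  d <- diff(x)
  w[1] <- d[1] / 2
  w[n] <- d[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (d[-1] + d[-(n - 1)]) / 2
  w
}

#' Import a tabulated free-energy landscape
#'
#' Reads the three-column whitespace- or comma-delimited text layout
#' `cv1 cv2 G` (as dumped by the standard landscape extraction tools);
#' lines starting with `#` or `@` are skipped. The grid is inferred from
#' the unique cv1/cv2 values; missing combinations become unvisited (NA)
#' cells.
#'
#' @param path input file.
#' @param temperature K (not stored in the text layout; mandatory).
#' @return an [FES2D-class].
#' @export
readFESTable <- function(path, temperature = 310) {
  tab <- read.table(path, comment.char = "#", sep = "",
                    blank.lines.skip = TRUE)
  if (ncol(tab) == 1)
    tab <- read.table(path, comment.char = "#", sep = ",")
  if (ncol(tab) < 3) .stopf("FES table needs three columns: cv1 cv2 G")
  cv1 <- sort(unique(tab[[1]])); cv2 <- sort(unique(tab[[2]]))
  G <- matrix(NA_real_, length(cv1), length(cv2))
  G[cbind(match(tab[[1]], cv1), match(tab[[2]], cv2))] <- tab[[3]]
  new("FES2D", cv1 = cv1, cv2 = cv2, G = G, temperature = temperature,
      meta = list(source = path))
}

#' Boltzmann-marginalize CV2 out of a 2D free-energy surface
#'
#' For each CV1 column,
#' `G(cv1) = -RT log( integral exp(-beta G(cv1, cv2)) dcv2 / C )`
#' with the integral by the trapezoid rule on the CV2 grid (internally in
#' radians) and the log-sum-exp trick for numerical stability. Unvisited
#' (NA) cells are tolerated at the edges of a column (dropped with a
#' warning); an interior gap or an all-NA column is an error.
#'
#' @param fes an [FES2D-class].
#' @param C normalization constant with units of length (rad); defaults to
#'   the CV2 integration range, making the log argument dimensionless.
#'   The adsorbed-transmembrane gap is invariant to C.
#' @return an unshifted [PMF1D-class].
#' @export
marginalizeCV2 <- function(fes, C = NULL) {
  cv2rad <- fes@cv2 * pi / 180
  if (length(cv2rad) < 2) .stopf("need >= 2 cv2 points per column")
  if (is.null(C)) C <- diff(range(cv2rad))
  beta <- 1 / (.R_GAS * fes@temperature)
  warned <- FALSE
  G1 <- vapply(seq_along(fes@cv1), function(i) {
    g <- fes@G[i, ]
    ok <- !is.na(g)
    if (!any(ok))
      .stopf("analysis error: all-unvisited column at cv1 = %g", fes@cv1[i])
    rng <- range(which(ok))
    if (!all(ok[rng[1]:rng[2]]))
      .stopf("analysis error: interior unvisited bins at cv1 = %g",
             fes@cv1[i])
    if (!all(ok) && !warned) {
      warned <<- TRUE
      .warnf("unvisited cv2 bins at column edges excluded from marginalization")
    }
    sub <- rng[1]:rng[2]
    if (length(sub) < 2)
      .stopf("analysis error: < 2 visited cv2 bins at cv1 = %g", fes@cv1[i])
    w <- .trapWeights(cv2rad[sub])
    -(1 / beta) * (logSumExp(-beta * g[sub] + log(w)) - log(C))
  }, 0)
  new("PMF1D", cv1 = fes@cv1, G = G1, error = numeric(0), states = list(),
      temperature = fes@temperature)
}

#' Symmetrize a PMF across the membrane midplane
#'
#' `G_sym(z) = (G(z) + G(-z)) / 2`, with the per-bin error estimated as
#' half the difference between the two leaflet branches,
#' `|G(z) - G(-z)| / 2` (the two leaflets are independent data sets).
#'
#' @param pmf a [PMF1D-class].
#' @param interpolate if the grid is not symmetric about zero, linearly
#'   interpolate onto its mirror-symmetric intersection (default `FALSE`:
#'   asymmetric grids are an error).
#' @return a [PMF1D-class] with `@error` filled.
#' @export
symmetrizePMF <- function(pmf, interpolate = FALSE) {
  z <- pmf@cv1
  symGrid <- all(abs(z + rev(z)) < 1e-9)
  if (!symGrid && !interpolate)
    .stopf("input error: cv1 grid not symmetric about 0 (set interpolate = TRUE)")
  if (!symGrid) {
    zmax <- min(max(z), -min(z))
    z2 <- sort(unique(c(z[abs(z) <= zmax], -z[abs(z) <= zmax])))
    G <- approx(z, pmf@G, xout = z2)$y
    z <- z2
  } else G <- pmf@G
  Grev <- rev(G)   # G(-z) on a symmetric grid
  new("PMF1D", cv1 = z, G = (G + Grev) / 2, error = abs(G - Grev) / 2,
      states = pmf@states, temperature = pmf@temperature)
}

#' Shift a PMF so its minimum is zero
#'
#' Idempotent; state free-energy differences are unaffected.
#'
#' @param pmf a [PMF1D-class].
#' @return a [PMF1D-class] with `min(G) == 0`.
#' @export
shiftMinZero <- function(pmf) {
  m <- min(pmf@G, na.rm = TRUE)
  if (!is.finite(m)) .stopf("no finite minimum to shift")
  new("PMF1D", cv1 = pmf@cv1, G = pmf@G - m, error = pmf@error,
      states = pmf@states, temperature = pmf@temperature)
}

## local minima of a discrete profile (NA-safe), with 3-point parabolic
## refinement; returns data.frame(cv1, G)
.localMinima <- function(z, G) {
  n <- length(G)
  idx <- which(vapply(seq_len(n), function(i) {
    if (is.na(G[i])) return(FALSE)
    l <- if (i > 1) G[i - 1] else Inf
    r <- if (i < n) G[i + 1] else Inf
    (is.na(l) || G[i] < l) && (is.na(r) || G[i] <= r)
  }, TRUE))
  if (!length(idx)) return(data.frame(cv1 = numeric(0), G = numeric(0)))
  ref <- t(vapply(idx, function(i) {
    if (i <= 1 || i >= n || anyNA(G[(i - 1):(i + 1)]))
      return(c(z[i], G[i]))
    y <- G[(i - 1):(i + 1)]
    denom <- y[1] - 2 * y[2] + y[3]
    if (denom <= 0) return(c(z[i], G[i]))
    h <- (z[i + 1] - z[i - 1]) / 2
    d <- 0.5 * (y[1] - y[3]) / denom
    c(z[i] + d * h, y[2] - 0.125 * (y[1] - y[3])^2 / denom)
  }, c(0, 0)))
  data.frame(cv1 = ref[, 1], G = ref[, 2])
}

#' Adsorbed-to-transmembrane free-energy gap
#'
#' Locates local minima of the profile, takes the transmembrane state as
#' the lowest minimum with `|cv1| <= tmZCut` and the adsorbed state as the
#' lowest minimum with `|cv1| >= adsZCut`, and returns
#' `ddG = G(TM) - G(adsorbed)`. Minima are refined parabolically over
#' three points. The gap is invariant to any global shift of the profile.
#'
#' @param pmf a [PMF1D-class].
#' @param config an `AnalysisConfig` (uses `tmZCut`, `adsZCut`).
#' @return the input [PMF1D-class] with `@states` holding `tm`,
#'   `adsorbed`, `ddg` and `barrier` (highest point between the adsorbed
#'   minimum and the TM minimum, relative to the adsorbed minimum).
#' @export
deltaDeltaG <- function(pmf, config = analysisConfig()) {
  mins <- .localMinima(pmf@cv1, pmf@G)
  tm <- mins[abs(mins$cv1) <= config$tmZCut, , drop = FALSE]
  ads <- mins[abs(mins$cv1) >= config$adsZCut, , drop = FALSE]
  if (!nrow(tm))
    .stopf("state-detection error: no local minimum inside the transmembrane window (|cv1| <= %g)",
           config$tmZCut)
  if (!nrow(ads))
    .stopf("state-detection error: no local minimum inside the adsorbed window (|cv1| >= %g)",
           config$adsZCut)
  tm <- tm[which.min(tm$G), ]
  adsBest <- ads[which.min(ads$G), ]
  between <- pmf@cv1 >= min(tm$cv1, adsBest$cv1) &
    pmf@cv1 <= max(tm$cv1, adsBest$cv1)
  barrier <- max(pmf@G[between], na.rm = TRUE) - adsBest$G
  new("PMF1D", cv1 = pmf@cv1, G = pmf@G, error = pmf@error,
      states = list(tm = tm, adsorbed = ads, ddg = tm$G - adsBest$G,
                    barrier = barrier),
      temperature = pmf@temperature)
}

#' Boltzmann-invert a density profile into a free-energy profile
#'
#' `G = -RT log(rho / rho_max)`; zero-count bins become unvisited (NA),
#' not `-Inf`.
#'
#' @param cv1 bin centers, nm.
#' @param density non-negative densities/counts per bin.
#' @param temperature K.
#' @return a [PMF1D-class] with `min(G) = 0` at the density maximum.
#' @export
boltzmannInvert <- function(cv1, density, temperature = 310) {
  if (any(density < 0)) .stopf("input error: negative density")
  if (all(density == 0)) .stopf("input error: all-zero density")
  G <- rep(NA_real_, length(density))
  pos <- density > 0
  G[pos] <- -.R_GAS * temperature * log(density[pos] / max(density))
  new("PMF1D", cv1 = cv1, G = G, error = numeric(0), states = list(),
      temperature = temperature)
}

#' Write a PMF with state annotations
#'
#' CSV with `#`-prefixed metadata lines carrying temperature, state
#' positions and the adsorbed-transmembrane gap.
#'
#' @param pmf a [PMF1D-class] (ideally after [deltaDeltaG()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePMF <- function(pmf, path) {
  meta <- list(temperature_K = pmf@temperature)
  s <- pmf@states
  if (length(s)) {
    meta$tm_min_cv1_nm <- s$tm$cv1
    meta$adsorbed_min_cv1_nm <- s$adsorbed$cv1[which.min(s$adsorbed$G)]
    meta$ddg_kJ_mol <- s$ddg
    meta$barrier_kJ_mol <- s$barrier
  }
  df <- data.frame(cv1_nm = pmf@cv1, G_kJ_mol = pmf@G)
  if (length(pmf@error)) df$error_kJ_mol <- pmf@error
  writeResultTable(df, path, meta)
}
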