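---
title: "Membrane curvature sensing by helical peptides: models and methods"
author: "memsense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane curvature sensing by helical peptides: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memsense)
```

# Scope

`memsense` analyses coarse-grained simulations of amphipathic helical
peptides on lipid bilayers. It answers three connected questions:

1. **How deep does a peptide sit** in a planar membrane, and how does that
   depth scale with its hydrophobicity?
2. **What does its reorientation cost**: given a two-dimensional
   free-energy landscape over the peptide's position and tilt, what is the
   gap between the surface-adsorbed and transmembrane states?
3. **Which curvature does it prefer**: on a buckled membrane exposing both
   curvature signs, where does the peptide spend its time once the uneven
   geometry of the buckle is corrected for?

Running the molecular dynamics itself — force fields, enhanced sampling,
system construction — is out of scope; the package post-processes
configurations and landscapes, and generates synthetic versions of both
with known ground truth so that every stage is testable without
simulation data.

# The height-field model of the membrane surface

A gently deformed bilayer leaflet is a single-valued height field
$h(x, y)$ over the membrane plane (the Monge gauge). We expand $h$ on the
real tensor-product Fourier basis periodic with the simulation box,

$$h(x,y) = \sum_{m \le M_x}\,\sum_{n \le M_y} c_{mn}\,
\phi_m\!\left(\tfrac{2\pi x}{L_x}\right)\psi_n\!\left(\tfrac{2\pi y}{L_y}\right),$$

with $\phi, \psi \in \{1, \cos, \sin\}$ and $(2M_x+1)(2M_y+1)$
coefficients, fitted to the phosphate bead positions of one leaflet by
linear least squares (`fitSurface()`, QR factorization; the solution is
cross-checked against a dense SVD solve in the test suite). Because the
basis is smooth and periodic, all derivatives are analytic, and the mean,
Gaussian and principal curvatures follow from the standard Monge-gauge
formulas

$$H = \frac{(1+h_y^2)h_{xx} - 2h_xh_yh_{xy} + (1+h_x^2)h_{yy}}
{2\,(1+h_x^2+h_y^2)^{3/2}}, \qquad
K = \frac{h_{xx}h_{yy}-h_{xy}^2}{(1+h_x^2+h_y^2)^2}.$$

Key choices:

* **Truncation $M_x = M_y = 3$ by default.** A low cutoff is a feature:
  thermal phosphate roughness is white at high wavenumber, and modes
  beyond the box-scale undulations would fit that roughness as spurious
  curvature. The cutoff is configuration, and the synthetic suite
  measures the stack's sensitivity to it. For quasi-one-dimensional
  buckles in narrow boxes, $M_y$ of 0–1 is the appropriate setting; the
  high-wavenumber $y$-modes of a short box edge otherwise amplify bead
  noise in $h_{yy}$.
* **Per-leaflet fitting.** Each leaflet is fitted from its own phosphate
  beads, and a peptide is evaluated on its own leaflet's surface. The
  alternative (one midplane surface) was rejected because the two
  analyses the surface feeds — peptide-position curvature and local
  thickness — are intrinsically per-leaflet.
* **Sign convention.** $h$ is measured along $+z$. For the lower leaflet
  the mean and principal curvatures are negated, so that for *both*
  leaflets positive $H$ means the surface bulges toward that leaflet's
  own solvent. This is what makes the two peptides on a buckled
  membrane — one per leaflet — directly comparable: they sample the same
  physical geometry with consistent signs, which is also the basis of the
  leaflet-convergence diagnostic.

```{r curvature-example}
tr <- genBuckledBilayer(bilayerParams(nPerLeaflet = 800, jitterXY = 0,
                                      jitterZ = 0, buckleAmplitude = 1,
                                      buckleWavelength = 20))
fr <- getFrame(tr, 1)
leaf <- assignLeaflets(fr)
m <- beadMeta(fr)
phos <- which(m$beadName == "PO4" &
                leaf[as.character(m$moleculeId)] == "upper")
fit <- fitSurface(beadPositions(fr)[phos, ], boxVectors(fr)[1:2], 3, 3,
                  leaflet = "upper")
curvatureAt(fit, x = 5, y = 1)   # crest of the buckle: H = -A k^2 / 2
```

# Peptide observables

**Insertion depth** is the z-distance between the peptide center of mass
and the mean z of that leaflet's phosphate beads within a lateral
(minimum-image) cylinder of radius 1.0 nm around the peptide. The local
cylinder, not the global phosphate plane, is what makes the observable
meaningful on membranes that are bent or locally thinned by the peptide
itself. The local reference is the arithmetic mean of the cylinder's
phosphate z values, not a fitted plane. The sign is flipped on the lower
leaflet so that positive depth always means deeper toward the core.
Frames whose cylinder is empty are flagged and excluded from means, never
silently averaged. With replicate trajectories the reported uncertainty
is the standard deviation of replicate means; within a single trajectory
it is the frame-to-frame standard deviation.

**Tilt** is the angle between the peptide axis and $+z$, in
$[0°, 180°]$. The axis is the principal component of the backbone bead
cloud — more robust to bead jitter than the first-to-last bead vector —
oriented from the first toward the last bead so that the two antiparallel
transmembrane orientations remain distinguishable. The suite checks that
the two axis definitions agree within 2° on near-collinear synthetic
peptides.

**State labels.** A configuration is `transmembrane` when
$|\mathrm{CV1}| \le 0.5$ nm and the tilt folded into $[0°, 90°]$ is
$\le 45°$; `adsorbed_upper/lower` when $|\mathrm{CV1}| \ge 1.2$ nm; and
`inserted` otherwise (CV1 = peptide–membrane COM z-distance). These
window boundaries have no literature-fixed values; they are explicit
configuration chosen from the geometry of the synthetic landscapes
(adsorbed minima at ±1.8 nm, barriers at ±0.9 nm) and are echoed into
every report so downstream users see them.

# Free-energy post-processing

The input is a tabulated landscape $\Delta G(\mathrm{CV1}, \mathrm{CV2})$
produced by an adaptive-bias sampler (only its output is consumed; the
sampling itself is out of scope). The one-dimensional profile is the
Boltzmann average over the tilt variable,

$$\Delta G(\mathrm{CV1}) = -RT\,\ln\!\left(\frac{\int
e^{-\beta\,\Delta G(\mathrm{CV1},\mathrm{CV2})}\,d\mathrm{CV2}}{C}\right),$$

computed with the trapezoid rule on the CV2 grid (internally radians) and
the log-sum-exp trick, so landscapes offset by $10^6$ kJ/mol produce
identical shifted output. $R = 8.314462618\times10^{-3}$ kJ/(mol·K). The
constant $C$ defaults to the CV2 integration range, which makes the
argument of the logarithm dimensionless; since the adsorbed–transmembrane
gap is a difference of profile values, it is invariant to $C$, and the
suite asserts exactly that. Unvisited bins at the edges of a CV2 column
are excluded with a warning; an unvisited bin in the interior is an
error, because silently bridging it would fabricate free energy.

Profiles from the peptide sampling the two leaflets are **symmetrized**,
$G_s(z) = [G(z)+G(-z)]/2$, and the two branches being independent data
sets, their half-difference $|G(z)-G(-z)|/2$ is the per-bin error
estimate. After shifting the minimum to zero, states are located by a
discrete local-minimum scan refined parabolically over three points: the
transmembrane state is the lowest minimum with $|\mathrm{CV1}| \le 0.5$
nm, the adsorbed state the lowest with $|\mathrm{CV1}| \ge 1.2$ nm, and

$$\Delta\Delta G = G(\mathrm{TM}) - G(\mathrm{adsorbed}).$$

The parabolic refinement carries a small bias ($\sim 10^{-3}$ kJ/mol)
where the two flanks of a minimum have unequal curvature; the synthetic
recovery tests assert the gap to 0.1 kJ/mol, far above that bias and far
below the kJ/mol-scale differences the statistic is used to resolve.

`boltzmannInvert()` provides the complementary check used for unbiased
simulations: $G = -RT\ln(\rho/\rho_{max})$ from a density histogram, with
zero-count bins flagged unvisited rather than mapped to $-\infty$.

The simulation temperature is not embedded in the text landscape format,
so it is a mandatory, echoed parameter; the default is 310 K, standard
for this class of coarse-grained membrane simulation.

```{r pmf-example}
fes <- genFES2D(ddg = 52.7, barrier = 60)
pmf <- deltaDeltaG(shiftMinZero(symmetrizePMF(marginalizeCV2(fes))))
pmfStates(pmf)$ddg    # recovers the programmed 52.7 kJ/mol
```

# Curvature preference by accessible-curvature reweighting

A buckled membrane does not offer all curvatures in equal amounts: the
surface measure concentrates where the buckle is steep. The raw histogram
of curvature sampled at the peptide position therefore confounds
preference with availability. The correction divides, bin by bin, the
sampled distribution by the **accessible distribution** — the histogram
of $H$ over the whole surface, each point weighted by its area element
$\sqrt{1+|\nabla h|^2}$ — and renormalizes:

$$w_{\mathrm{rw}}(b) =
\frac{w_{\mathrm{sampled}}(b)/w_{\mathrm{accessible}}(b)}
{\sum_{b'} w_{\mathrm{sampled}}(b')/w_{\mathrm{accessible}}(b')}.$$

Design points:

* **Surface measure, not projected measure.** "Accessible at the membrane
  surface" is read as the area the peptide can actually occupy, i.e. the
  curved surface measure. The projected (flat-xy) alternative is exposed
  as an option (`measure = "projected"`) and both are exercised in tests;
  for gentle buckles the difference is second order in $A k$.
* **Mask threshold $10^{-4}$.** Bins whose accessible weight is below the
  threshold are masked before division — the ratio estimator blows up
  where the accessible weight vanishes. Masked bins are reported, never
  silently dropped.
* **Anti-aliased accessible histogram.** Each grid cell's weight is
  spread uniformly over the interval of $H$ it covers (half-width
  estimated by central differences on the periodic evaluation grid).
  Point-assignment binning converges only first order in the grid step
  and visibly staircases against 0.005 nm$^{-1}$ bins; the smoothed
  assignment is second order, and the suite asserts <0.5% change per
  grid doubling.
* **Histogram range** $[-0.15, 0.15]$ nm$^{-1}$ in 0.005 nm$^{-1}$ bins
  by default — generous for the $|H| \le Ak^2/2 \approx 0.05$ nm$^{-1}$
  of the default synthetic buckle, and of the order of what buckled
  coarse-grained membranes of tens of nanometers expose.
* **Peptide position = COM $(x, y)$ only.** Averaging curvature over the
  bead footprint was rejected: it smooths the observable with a kernel
  whose width depends on tilt, making ground-truth testing ambiguous.

Summary statistics: the **mean sensed curvature** is the weight-average
of bin centers of the reweighted distribution; **leaflet agreement** is
the total-variation distance between the upper- and lower-leaflet
reweighted distributions (two independent estimates of the same
preference; convergence is declared below 0.1); the **depth–curvature
relation** across a peptide series is summarized by Pearson correlation,
and differences in depth-vs-hydrophobicity slopes between membranes by a
two-sample $t$-test on the OLS slopes with Welch–Satterthwaite degrees of
freedom.

# Bilayer characterization

* **Area per lipid**: projected box area over lipids per leaflet,
  reported in Å² (all internal lengths are nm; the single conversion
  1 nm² = 100 Å² happens at reporting).
* **Tail order**: $S_{CC} = \langle(3\cos^2\theta - 1)/2\rangle$ per
  consecutive tail-bead bond against the membrane normal, in
  $[-\tfrac12, 1]$.
* **Density profiles**: bead-mass histograms along $z$, recentred on the
  membrane COM per frame to remove drift, normalized by bin volume.
* **Packing defects**: an xy grid (0.1 nm step) is scanned from the
  solvent side; a cell is a defect cell when the first bead encountered
  is an acyl-chain bead deeper than 0.1 nm below the local phosphate
  level, or when no bead covers the cell at all. Beads cover a cell
  within a lateral radius of 0.26 nm (a single coarse-grained bead
  radius for all types; a per-type table would add parameters the
  analyses do not need). 4-connected cells merge into defects whose
  areas, above a 15 Å² cutoff, follow an exponential law
  $P(A) \propto e^{-A/\pi}$. The constant is fitted by the tail MLE
  $\hat\pi = \mathrm{mean}(A - A_{min})$ — unbiased and binning-free —
  with the binned log-linear least-squares fit kept as a cross-check,
  since the two must agree for genuinely exponential tails. Detection
  parameters are configuration and reported alongside any constant:
  defect constants are parameter-dependent quantities and are flagged as
  such.
* **Local maps**: thickness (upper minus lower local phosphate mean z)
  and local $S_{CC}$ in radial bins around the peptide COM; empty bins
  are `NA`, never interpolated.

The published simulation-scale values for the three studied
compositions — area per lipid 65/68/76 Å² and defect constants
19.2/22.5/35.7 Å² for POPC/DOPC/PAPC — derive from tens of microseconds
of sampling. They are shipped as reference data
(`referenceMembraneValues()`) and `checkMembraneAgainstReference()`
compares any user-supplied trajectory against them; nothing at the
package's test scale recomputes them, and the tests only exercise the
comparison machinery on synthetic membranes programmed at those values.

# The synthetic-data generators

The generators produce every input the pipeline consumes, with ground
truth attached:

* **Bilayers** are lipid lattices (phosphate + head bead + four tail
  beads per lipid) at a target area per lipid, with independent Gaussian
  jitter on bead positions standing in for thermal motion. Defaults:
  92 lipids per leaflet (the planar study size), 65 Å² (the
  monounsaturated reference), 4 nm phosphate-plane separation, 0.05 nm
  lateral and 0.1 nm vertical jitter — the vertical figure is the
  phosphate roughness scale of coarse-grained PC bilayers. The jitter
  model is stationary and uncorrelated; real thermal undulations have a
  $q^{-4}$ spectrum, so passing tests demonstrate that the fitting stack
  recovers band-limited shape under noise, not that it reproduces a
  specific undulation spectrum.
* **Buckles** displace both leaflets by $h(x) = A\sin(2\pi x/\lambda)$
  with $L_x = \lambda$; single-mode and $x$-only, so the exact mean
  curvature is closed-form and the Gaussian curvature is identically
  zero — both used as oracles. Defaults $A = 1$ nm, $\lambda = 20$ nm
  are chosen for numerical convenience (the buckle amplitude of the
  simulated systems is not reported); $A \ge \lambda/4$ is rejected to
  keep the height field gentle and single-valued.
* **Peptides** are 21 collinear backbone beads at 0.35 nm spacing —
  helical winding is irrelevant to COM and axis observables — placed at
  exact depth and tilt; placement uses the same local-cylinder reference
  as the depth observable, which is what makes construction the oracle.
* **Biased positions** are drawn by rejection sampling with density
  $\propto dA\,e^{aH}$; rejection is exact (no inverse-CDF
  discretization) at the cost of a seed-dependent acceptance count.
* **Landscapes** (`genFES2D()`) build the 1D profile from zero-slope
  cubic Hermite segments, so the adsorbed minima (0), transmembrane
  minimum (`ddg`) and barriers (`barrier`) sit exactly on the knots,
  add a separable harmonic tilt term, and subtract the marginalization
  constant computed with the same trapezoid rule the analysis uses — the
  marginal therefore equals the programmed profile to machine precision,
  and any recovery error is attributable to the analysis step under
  test.
* **Defect areas** are $A_{min} + \mathrm{Exp}(\pi)$ draws, exactly the
  tail model the MLE assumes.

All generators are bit-reproducible under their seed, and a
zero-amplitude buckle is bitwise identical to the planar system under
the same seed.

# Numerical choices and degenerate inputs

* Coordinates are wrapped into $[0, L)$ per axis on load (the upstream
  wrapping convention of trajectory files varies); all lateral distances
  are minimum-image. Orthorhombic boxes only — all supported systems are
  planar or quasi-1D buckled patches.
* GRO files are parsed by fixed columns so merged fields survive;
  trajectories are supported as multi-frame GRO and (single- or
  double-precision, big-endian) TRR with positions and box.
* The least-squares design is solved by QR; rank deficiency (e.g. all
  points on one $x$-line) is an error with a condition-number
  diagnostic, not a silently pseudo-inverted fit.
* Histogram masking, empty-selection, empty-cylinder, all-unvisited and
  degenerate-fit paths each have a defined outcome (flag, warning or
  typed error) and a test.

Problem sizes in the test suite — leaflets of 16–1600 lipids, 3–150
frames, $10^4$–$10^5$ samples for distributional checks, 200 repetitions
for coverage calibration — were chosen so each assertion's tolerance is
backed by the corresponding CLT or quadrature error estimate.

# Known limitations

* The surface model requires a single-valued height field: vesicles,
  stalks or overhanging folds are out of scope by construction.
* Defect constants depend on grid step, depth threshold and bead radius;
  cross-study comparisons are only meaningful at matched parameters.
* The accessible-curvature measure choice (surface vs projected) changes
  reweighted distributions at second order in the buckle steepness; both
  options are provided because upstream conventions differ.
* Synthetic membranes have uncorrelated jitter and rigid lipids; they
  validate the estimators, not lipid physics. Conclusions about real
  membranes require real trajectories, for which the reference-value
  comparison utilities are provided.
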