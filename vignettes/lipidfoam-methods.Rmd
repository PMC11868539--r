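---
title: "Models and methods behind lipidfoam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lipidfoam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidfoam)
```

# The system and its model

A lipid foam is a quasi-two-dimensional packing of aqueous compartments
(20--50 µm across) separated by lipid bilayer films. Three films meet at
each three-way junction ("vertex"), so the structure is the wet-lab analogue
of a dry soap foam and of confluent epithelial tissue in vertex-model
language. `lipidfoam` implements the quantitative analysis chain for such a
system — geometry, tension balance, fluctuation statistics, an active-matter
coupling to encapsulated swimming bacteria, and spatial correlations —
together with a synthetic-data generator so that every stage can be
validated against known ground truth.

## Foam geometry and tension balance

A `foam_network` stores vertices (µm coordinates), edges, and compartment
polygons. Interior vertices must have degree 3; vertices bordering the
clipped field of view are flagged and excluded from statistics by default,
because their polygons are artifacts of clipping.

Compartment shape is summarized by the shape index $s = p/\sqrt{A}$. A
regular hexagon gives $s = 3.722$, the isoperimetric bound is
$2\sqrt{\pi} \approx 3.545$, and $s \approx 3.81$ marks the
density-independent rigidity transition of vertex models. (One printed
variant of this formula, $A/\sqrt{P}$, is dimensionally inconsistent with
the hexagonal reference value and is not implemented.)

Tension enters at two scales:

* **Membrane scale (mN/m).** At a Plateau--Gibbs border the bilayer unzips
  into two monolayers, giving $\gamma_B = 2\gamma_{ML}\cos\phi$ with
  microscopic contact angle $\phi$. Micropipette aspiration yields the
  critical tension via the Laplace law $\gamma_c = |\Delta P| R_p / 2$; the
  hemispherical-cap geometric factor is exposed as a parameter because the
  aspiration geometry (flat film vs vesicle) changes it.
  The ratio $\gamma_B/\gamma_{ML}$ classifies the packing: confluent above
  0.23, rigidity transition at 2.
* **Fluctuation scale (nN/m).** The effective tension
  $\gamma_e = k_B T/\sigma$ deduced from edge-length variance $\sigma$ is
  many orders of magnitude below $\gamma_B$; it is the spring-constant scale
  that vertex fluctuations actually probe.

`relax_vertex` minimizes $\sum_i \gamma_i L_i$ over one junction position by
adaptive-step gradient descent (the energy is non-increasing by
construction; the step halves on any failed move and convergence is declared
below a displacement tolerance). At equal tensions the equilibrium is the
Fermat point, with 120° inter-edge angles.

T1 transitions are detected in edge-length time series as a drop below a
collapse threshold (default 0.5 µm — well below the compartment scale,
above tracking noise) followed by re-expansion. The topology operator
`apply_t1` rotates the collapsed edge, swapping the flanking and end
compartments; the re-formed edge starts at 30% of the original length so
the new polygons remain simple, and the operator is an involution on the
topology.

## Synthetic data

**Single-vertex dynamics.** `simulate_ou_vertex` integrates the overdamped
Langevin equation $b\dot x = -kx + \sqrt{2 k_B T_{eff} b}\,\xi$ with
$k = 2\pi f_0 b$ (Euler--Maruyama; the configuration refuses steps within a
factor 10 of the relaxation time). Defaults are the fitted experimental
values $b = 0.5\,\mu$Ns/m, $f_0 = 0.9\times10^{-3}$ Hz, $T_{eff}/T = 6.5$.
(The main-text order-of-magnitude $f_0 \sim 10^{-2}$ Hz differs from the
figure-caption value; the caption value is used for defaults.)

**Network dynamics.** `simulate_network_dynamics` evolves all interior
vertices under (i) edge-tension forces, (ii) compartment area elasticity,
(iii) thermal noise, and (iv) per-compartment active forcing. The area term
$\tfrac{K_A}{2}(A-A_0)^2$ with $K_A = \gamma/L_0^3$ is essential: a
degree-3 central-force network is sub-isostatic, and with pure edge tension
the stiffness matrix is singular — physically, compartment contents are
incompressible on these timescales. Fluctuations are therefore collective;
the analytic reference is the equipartition covariance
$k_B T\,K^{-1}$ of the full Hessian (`network_vertex_variance`), not a
single-vertex spring estimate. The default edge tension is calibrated so the
junction stiffness matches $2\pi f_0 b$ from the configured spectrum
parameters.

Active forcing is one Ornstein--Uhlenbeck process per compartment
(correlation time $\tau = 1$ s, the swimmer persistence time), pushing the
compartment's vertices outward from its centroid. Its **mean** is calibrated
through the network compliance so that a compartment of occupancy $\Phi_n$
acting alone displaces its vertices by the swim-pressure law (below); its
**fluctuation** is calibrated so that the low-frequency active force power
reaches the observed effective temperature ratio (default 6.5) when all
three compartments at a vertex carry a reference occupancy (default 0.03,
about 15 swimmers of 2 µm² footprint in a 1000 µm² compartment), scaling
linearly with $\Phi_n$. The fluctuation amplitude must be two orders of
magnitude larger than the mean-imbalance force — collisions are impulsive
and mostly balanced, and the net displacement is the small residual of large
fluctuating forces. Sharing one force process per compartment is what
creates spatial correlation between vertices of the same compartment.

**Swimmers.** `simulate_abp` is a standard active Brownian particle:
constant speed $v = 3.5$ µm/s, rotational diffusion $D_r = 1/\tau$, specular
wall reflection with a collision log (position, incidence angle, normal
momentum transfer). Occupancies are truncated-Poisson counts (cap 40, the
observed range) times a 2 µm² footprint (a projected 0.8 × 2.5 µm rod).
"Heat-killed" mode keeps geometry, occupancy and noise identical but sets
the speed to zero and disables active forcing.

**Rendering.** `render_micrograph` rasterizes edges (membrane dye channel;
junctions are brightest because three edges overlap within the PSF) and
swimmer footprints (bacteria channel), blurs with a Gaussian PSF, and
optionally adds Poisson shot noise plus Gaussian read noise on an
8-bit-style intensity scale. Ground-truth vertex positions and the
rendering-level binarization threshold are attached to the stack.

## Image analysis

Vertex tracking mirrors max-intensity tracking of isolated, smoothed
junction images: per frame the brightest pixel of the Gaussian-smoothed ROI
(σ = 1 px default; the smoothing kernel is otherwise unspecified in common
practice) is the vertex position; frames whose maximum falls more than a
threshold tolerance (default 50 intensity units, meaningful on the 8-bit
scale assumed throughout) below the ROI's overall maximum are flagged
invalid. Raw arg-max is the compatibility default; 3×3 centroid refinement
is available. Occupancy is the foreground-pixel fraction per compartment
polygon after binarization (Otsu by default; a fixed threshold for exact
fixtures). QC removes tracks with frame-to-frame jumps above 10 µm or more
than 20% invalid frames.

## Fluctuation statistics and spectra

Displacement and edge statistics are confined to 60-s blocks re-centred on
the block mean, which suppresses slow drift; the per-vertex summary is the
maximum per-block 2D positional SD (fluctuation maps) and the mean radial
distance from the block centre. Edge deviations $L - \bar L$ pool all
blocks with at least 10 valid common frames.

Spectra are Hann-windowed, linearly detrended Welch periodograms,
density-normalized (Parseval-consistent), estimated on the full 10-min
track rather than 60-s blocks — the sub-mHz knee would be unresolvable in
60-s windows. The model spectrum is the one-sided overdamped-harmonic form
$$S(f) = \frac{4 k_B T_{eff}/b}{(2\pi)^2 (f^2 + f_0^2)},$$
fitted by least squares in log-log space. Two numerical choices matter and
are defaults rather than tunables: the lowest bins (below twice the
frequency resolution) are dropped because detrending and windowing bias
them low, and bins above 40% of the Nyquist frequency are dropped because
discrete sampling of the $f^{-2}$ tail biases them high.

A single active spectrum constrains only $T_{eff}/b$ and $f_0$. The drag
and effective temperature are separated the way the experiment does it:
the heat-killed condition pins $T_{eff} = T$, so a joint fit of an
active/passive pair with shared $(b, f_0)$ (`fit_psd_paired`) returns both.
At 10-min records the corner frequency itself sits below the resolvable
band and is reported but weakly identified; the amplitudes, and hence
$b$ and $T_{eff}/T$, are robust.

## The swim-pressure displacement law

Occupancy imbalance at a junction is the vectorial occupancy
$\Phi = |\sum_n \Phi_n(\cos\varphi_n, \sin\varphi_n)|$ on directions 120°
apart; equal loading cancels exactly. The predicted time-averaged junction
displacement is
$$\Delta\vartheta = c\,\frac{3\eta\tau A}{4R^2}\frac{v^2\Phi}{\gamma_e},$$
with defaults as printed: $\eta = 10$ mPa·s (noted: an order of magnitude
above pure water, taken as an effective-medium value), $\tau = 1$ s,
$A = 200$ µm², $v = 3.5$ µm/s, $\gamma_e = 3.1\times10^{-8}$ N/m. With
prefactor $c = 1$ and $R = 2$ µm this evaluates to 148 µm at $\Phi = 1$;
inverting the experimentally fitted slope of 16.4 µm/Φ at $c = 1$ gives
$R \approx 6$ µm, while $R \approx 2$ µm requires $c \approx 0.11$. The
package treats $c$ as an explicit parameter, reports both inversions, and
uses $c = 0.11$ (slope 16.4 µm at $R = 2$ µm) as the generator default so
synthetic data match the observed displacement scale.

The measured displacement paired with $\Phi$ is the offset of the
time-averaged tracked position from the reference (force-balanced) vertex
position, projected onto the direction the occupancy imbalance predicts.
The projection is used because the offset magnitude has a positive noise
bias (a chi-distributed statistic), which inflates zero-intercept slopes;
the projection is unbiased. Slope fitting is zero-intercept least squares
with $R^2$ about the data mean, and the interaction radius follows by exact
inversion of the law.

The membrane-deformation bound uses the quasi-static point-force response
of a tensed membrane, $h = F/(2\pi\gamma)\,\ln(r_{max}/r_{min})$ with the
bending crossover $\sqrt{\kappa/\gamma}$ capping $r_{min}$: at mN/m bilayer
tension a swimmer's Stokes thrust deforms the membrane by $\sim$0.02 nm,
which is why swim pressure can be mapped directly onto junction positions;
only below µN/m do deformations become optically significant. The full
membrane-shape PDE is deliberately replaced by this closed form — the model
is used only to establish the nanoscopic-deformation regime.

## Spatial correlation

Cross-correlation is the zero-lag Pearson correlation of block-re-centred
radial displacement series per vertex pair, binned by separation (10 µm
default), with a 95% null band from circular-shift permutations (200 by
default) — the null criterion is a design choice, since none is standard.
The correlation length is the interpolated first crossing of the
baseline-subtracted curve below the significance threshold, 0 when never
significant, censored at the largest distance when always significant.
Whether magnitude or vector components are correlated is a free choice;
the radial (magnitude) statistic is the default and components are
available through the same blocked series.

# What the generator does and does not emulate

The generator reproduces: the honeycomb-to-disordered shape-index range
(jitter radius calibrated so disorder 0.3 gives mean $s \approx 3.8$),
thermally and actively driven vertex dynamics with the observed spectrum
parameters, 0--40 swimmers per compartment at 3.5 µm/s with 1 s
persistence, two-channel micrographs at 1 frame/s for 10 min, and matched
heat-killed controls. It does not emulate: optical aberrations beyond a
Gaussian PSF, bilayer sub-structure, swimmer-swimmer interactions or
hydrodynamics, T1 events occurring spontaneously during a simulated
timelapse (the topology is fixed within a run), drift of the stage, or
out-of-plane structure. Passing recovery tests on synthetic data therefore
validates the estimators' correctness, not their robustness to every
artifact of real microscopy.

# Problem sizes and numerical choices

Statistical tests use fast-relaxing parameters (corner frequency 0.05 Hz
instead of 0.9 mHz) so that hundreds of correlation times fit in a
10-minute simulated record; the spectrum-recovery checks use the
experimental parameters exactly (20 repeats of 10 min at 1 frame/s), which
is the regime the study itself reports. Network fixtures are 2×2 to 4×4
compartment lattices of 20 µm edge length; the Voronoi builder is exercised
at 36--100 cells. The end-to-end displacement-law recovery uses two
well-separated loaded compartments: with many simultaneously expanding
compartments the network compliance couples them (the cooperative regime
the correlation analysis measures), and the single-junction law alone then
under-predicts the scatter — the same reason the experimental fit has
$R^2 = 0.76$ rather than 1.

Degenerate inputs are handled explicitly: fourfold Voronoi junctions are
split into two three-way junctions 1 µm/1000 apart; collinear seed points
are retried with fresh jitter; self-intersecting polygons, boundary T1
edges, unstable integration steps and dark ROIs raise errors rather than
propagate.

# Known limitations

* The corner frequency is structurally unidentifiable from 10-min records;
  only amplitude ratios are trustworthy at the experimental acquisition
  settings.
* The displacement-law calibration is linear-response; at occupancies
  driving displacements beyond ~10% of the edge length the response
  saturates below the law.
* `build_disordered_foam` computes Voronoi cells by half-plane clipping
  (quadratic in cell count), adequate below ~10³ cells.
* The T1 operator updates topology and endpoint positions but does not
  re-relax the surrounding network; follow it with `relax_vertex` where
  equilibrated post-T1 geometry matters.
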