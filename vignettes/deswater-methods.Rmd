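---
title: "Methods: structure, hydrogen bonding, transport and water-stability analysis of DES trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure, hydrogen bonding, transport and water-stability analysis of DES trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deswater)
```

# Scope and model

Deep eutectic solvents (DES) pair a hydrogen-bond acceptor (HBA — here a
choline chloride salt or thymol) with a hydrogen-bond donor (HBD — fatty
acids of varying chain length). Whether such a solvent survives contact
with water is governed by the balance between the cohesive HBA–HBD
interaction and how strongly each component binds water. `deswater`
implements the full post-processing chain used to judge that balance from
molecular-dynamics trajectories:

* structural distributions — radial (RDF), angular (ADF), combined 2-D
  (CDF) and spatial 3-D (SDF) distribution functions, with coordination
  numbers from the first RDF minimum;
* geometric hydrogen-bond analysis — detection under distance/angle
  windows, per-frame count series, Gaussian fits of the count histogram,
  per-pair percent occupancy;
* transport estimators — mean-squared displacement (MSD) with the
  anomalous exponent $\beta(\tau)$ and Einstein self-diffusion, velocity
  autocorrelation (VACF) with collision/randomization times, bond-vector
  reorientation (VRD), and Green–Kubo shear viscosity from off-diagonal
  stress series;
* the nonbonded energy decomposition and the relative water-stability
  factor

$$ S \;=\; \frac{\lvert E_{\mathrm{HBA\text{-}HBD}}\rvert}
      {\lvert E_{\mathrm{HBA\text{-}water}}\rvert +
       \lvert E_{\mathrm{HBD\text{-}water}}\rvert }, $$

computed from the frame-averaged total (electrostatic + van der Waals)
pair energies. $S \le 3.30$ classifies a solvent as water-miscible, larger
values as water-stable. The magnitude convention is deliberate: the pair
energies of cohesive systems are negative, and the published values of $S$
for these systems are positive ratios, which forces absolute values in
both numerator and denominator. Because $S$ is a ratio, it is invariant
under any common rescaling of the energy unit, including the choice of the
Coulomb constant.

The package does not run molecular dynamics. Its synthetic-trajectory
module generates inputs with known statistical structure so that every
estimator can be validated without an MD engine (see below).

# Containers and units

A `trajectory()` holds a `topology()` (per-atom element, site name,
partial charge in $e$, Lennard-Jones $\varepsilon$ in kcal/mol and
$\sigma$ in Å, molecule id, species label and an HBA/HBD/water/other role
tag), an orthorhombic `simulation_cell()` and an
$n_\mathrm{atoms} \times 3 \times n_\mathrm{frames}$ coordinate array with
optional velocities. Internal units are Å, ps, kcal/mol, $e$, g/mol and
Kelvin; `des_units()` exposes the constants, including
$k_B = 0.0019872041$ kcal mol$^{-1}$ K$^{-1}$ and the force-field
convention $k_C = 332.0636$ kcal Å mol$^{-1}$ e$^{-2}$.

Design choices a maintainer should know:

* **Orthorhombic cells only.** Every minimum-image kernel divides by the
  edge lengths; triclinic input is a hard error at the reader boundary.
  Any cutoff is validated against half the smallest edge.
* **1-based indexing.** Atom indices are ordinary R indices throughout;
  the on-disk formats carry no indices, so no boundary conversion exists
  to get wrong.
* **Constant frame spacing** (relative tolerance $10^{-6}$) is required at
  construction, because every correlation estimator assumes a uniform
  time grid.
* **Temperature is an argument**, never hard-coded: the studies this
  package serves report mixed conventions (353 K, 353.15 K, 358 K for the
  SDFs), so each estimator takes the temperature it needs.

Readers/writers: extended XYZ (with `Lattice="..."` and `Time=` in the
comment line; positions written to 6 decimals and round-tripping at that
precision), read-only multi-model PDB via `bio3d` with the cell from
`CRYST1`, a documented YAML topology schema, CSV stress series, and
Gaussian cube output for SDF grids (axes converted to Bohr, voxels
z-fastest).

# Structural distributions

`compute_rdf()` estimates

$$ g(r) = \frac{\langle n_{ab}(r, r + \Delta r)\rangle}
               {N_a \; 4\pi r^2 \Delta r \; \rho_b}, \qquad
   \rho_b = N_b / V, $$

with ordered pairs, self pairs always excluded, and same-molecule pairs
excluded by default for site–site RDFs (but not applicable for
centre-of-mass RDFs, which use whole molecules). Binning is half-open
$[r, r + \Delta r)$; distances at or beyond `r_max` are dropped. Defaults
$\Delta r = 0.05$ Å and `r_max = min(12 Å, half smallest edge)` mirror the
cutoff world of the force fields these analyses accompany.

The coordination number integrates the shell population to a limit
$r_\ell$, conventionally the first RDF minimum:
$\mathrm{CN} = 4\pi\rho_b \int_0^{r_\ell} g(r)\, r^2 \mathrm{d}r$
(trapezoid on bin centres, closed at $r = 0$ and linearly interpolated at
$r_\ell$ so the quadrature does not silently lose the first and last
half-bins).

`find_first_extrema()` works on a moving-average smoothed curve (default
window 5 bins). A peak must exceed the bulk level $g = 1$ by at least a
prominence (default 0.02) *and*, when raw pair counts are available, by
three estimated standard errors of the smoothed curve; the subsequent
minimum is the running minimum accepted once the curve has risen back
above it by the same threshold. The statistical guards matter: the
small-$r$ bins of any RDF hold a handful of pairs, and their $g$ estimate
fluctuates wildly — without the significance test an ideal-gas RDF
(correctly featureless) would sprout spurious "first peaks" from noise.

The 2-D combined distributions pair one event per molecular pair per
frame: distance × angle (`compute_cdf_dist_angle()`, with the angle at the
partner-bearing vertex) or distance × distance
(`compute_cdf_dist_dist()`). Counts are raw occurrences; the populated
region — located with `cdf_argmax()` — is how geometric hydrogen-bond
criteria are derived from structure. `compute_sdf()` rebases target
positions into a body-fixed frame per reference molecule (origin at triad
atom 1, $x$ toward atom 2, atom 3 fixing the $xz$ half-plane — the triad
convention is ours, chosen because only the reference species is ever
specified in the literature) and normalizes voxel counts by
$n_\mathrm{frames}\, n_\mathrm{refs}\, V_\mathrm{voxel}\, \rho_\mathrm{bulk}$
so unstructured regions tend to 1.

# Hydrogen bonds

A bond D–H…A is counted when the chosen distance lies in
$[d_\min, d_\max]$ and the D–H…A angle (vertex at the hydrogen, 180° =
linear) lies in $[\theta_\min, \theta_\max]$. Two presets reflect the two
criteria windows appropriate for the two DES families: `"thymol"`
(135–150°, donor–acceptor < 3.5 Å) and `"chloride"` (130–180°,
donor–acceptor 2–3 Å). They are kept as distinct named presets rather
than merged, and every analysis records which preset produced it. The
distance defaults to the donor–acceptor separation, with a
hydrogen–acceptor mode available. Intramolecular bonds are excluded by
default.

Occupancy identity is the donor-*atom*/acceptor-*atom* pair: two
hydrogens of one donor reaching the same acceptor in one frame count once,
because "a unique hydrogen bond" is a pair-level notion. Occupancy is
$100 \times$ (frames with at least one qualifying route) /
$n_\mathrm{frames}$.

The count-series histogram is fitted with
$F(X) = \frac{a}{\sigma\sqrt{2\pi}}
 \exp\!\big(-(X - \bar X)^2 / 2\sigma^2\big)$
by Levenberg–Marquardt least squares started from the sample moments; the
amplitude $a$ absorbs series length and bin width, and $\bar X$ is
reported with its fit standard error. Zero-variance series are a
degenerate-distribution error; non-convergence returns flagged moment
estimates rather than failing.

# Transport estimators

All multi-origin sums use FFT correlation; the test suite pins every FFT
path to a direct double-loop oracle at $10^{-10}$.

**MSD and diffusion.** `compute_msd()` averages over molecular centres of
mass and all time origins. It requires unwrapped coordinates (generator
metadata flags them); wrapped input is unwrapped on request by
accumulating frame-to-frame minimum-image displacements, asserting that no
step exceeds half the box. $\beta(\tau) = \mathrm{d}\log_{10}\mathrm{MSD}/
\mathrm{d}\log_{10}\tau$ is evaluated on a log-spaced resampling (25
points/decade, 5-point smoothing) because raw finite differences are far
too noisy for regime classification; $\beta = 2$ marks the inertial
regime, $\beta = 1$ the diffusive one. `fit_diffusion()` selects the
longest contiguous window with $|\beta - 1| \le 0.1$ (the "$\beta \sim 1$"
rule made precise; the tolerance is exposed) and fits
$\mathrm{MSD} = 6 D \tau + b$ by *weighted* least squares with weights
$n_\mathrm{origins}/\tau^2$ — the approximate inverse variance of a
multi-origin MSD estimate — so the well-averaged short-lag end of the
window dominates; ordinary least squares would let the noisy long-lag end
bias $D$. If no window qualifies, the last 20% of lags is used and
flagged. $D_s$ is reported in Å$^2$/ns ($1$ Å$^2$/ps $= 1000$ Å$^2$/ns).

**VACF and VRD.** The normalized VACF
$C(\tau) = \langle v(t)\!\cdot\!v(t+\tau)\rangle /
\langle v^2\rangle$ is exactly 1 at $\tau = 0$; its first and second zero
crossings (linear interpolation between bracketing lags) estimate the mean
collision and velocity-randomization times, and a missing crossing is a
flagged result, not an error. VRD is the first-rank autocorrelation of a
named intramolecular unit vector; vectors are normalized *before*
correlating and the normalization is fixed so VRD(0) = 1 — that is the
reading of the curve families that "start at 1 and fall to 0", and for
isotropic rotational diffusion VRD decays as $e^{-2 D_r \tau}$.

**Green–Kubo viscosity.**
$\eta = \frac{V}{k_B T}\int_0^{t_u} \langle P_{xy}(0) P_{xy}(t)\rangle\,
\mathrm{d}t$, with the ACF averaged over the three off-diagonal components
and all origins, trapezoidal integration, and $t_u$ defaulting to ten
times the estimated ACF correlation time (capped at half the series). A
single-trajectory Green–Kubo integral never truly converges, so the
running integral and a plateau-drift diagnostic (relative change over the
final quarter of the window) are always returned.
`viscosity_from_acf()` exposes the integration core so an analytic ACF can
be injected directly. The internal unit (stress in kcal mol$^{-1}$
Å$^{-3}$, time in ps) converts to mPa s by a constant derived once from
SI definitions (≈ 6.9477, pinned by a unit test) and applied only on
request.

# Energetics and the stability factor

Pair energies use Lorentz–Berthelot mixing
($\varepsilon = \sqrt{\varepsilon_i \varepsilon_j}$,
$\sigma = (\sigma_i + \sigma_j)/2$) with the 12-6 potential truncated and
shifted to zero at the cutoff (default 12 Å), and a truncated-and-shifted
Coulomb term $k_C q_i q_j (1/r - 1/r_c)$. The shifted Coulomb form stands
in for Ewald summation deliberately: a lattice-sum electrostatic solver is
out of scope here, absolute energies from the two schemes differ, and
every quantity this package reports on top of the decomposition is either
a ratio ($S$) or printed-input arithmetic, which the choice does not
affect. `group_interaction_energy()` sums all intermolecular pairs within
the cutoff per frame (groups sharing a molecule are an error — no
intramolecular or 1-4 terms exist in this decomposition) and keeps the
per-frame series retrievable.

`des_energy_table()` bundles a published-scale reference table of the
three pair energies for eleven DES/water systems; `stability_report()`
recomputes $S$ from any such table, ranks systems and classifies them
against the 3.30 threshold. Two quirks of the reference table are
preserved as printed and flagged in its documentation rather than
corrected: one system (TBA) prints an $S$ inconsistent with its own pair
energies (presumed typographical — it is excluded from validation), and
one electrostatic entry (CMA HBA–water) is sign-discordant with every
other row. One row's components miss its printed total by 0.008 kcal/mol
(CDC donor–water) where all other rows agree within 0.001 — also
preserved as printed.

# The synthetic-trajectory module

Every generator is a pure function of its arguments (seed included, via
R's Mersenne–Twister) and records its ground truth in trajectory
metadata. What each emulates, and what it deliberately does not:

| generator | known truth | validates |
|---|---|---|
| `gen_ideal_gas()` | $g(r) \equiv 1$ | RDF normalization, CN |
| `gen_brownian()` | $\mathrm{MSD} = 6 D \tau$ | MSD, $\beta \to 1$, $D_s$ |
| `gen_langevin()` | exact OU velocities, $C(\tau) = e^{-\gamma\tau}$, $\langle v_x^2\rangle = k_B T / m$ | VACF, equipartition |
| `gen_rotor()` | $\mathrm{VRD} = e^{-2 D_r \tau}$ | VRD |
| `gen_hbond_dimers()` | exact per-pair occupancy schedule | detection, counts, occupancy |
| `gen_toy_mixture()` | exact composition, hard-core exclusion | energetics, RDF plumbing |
| `gen_biphasic_slab()` | two z-stacked phases | interface bookkeeping |
| `gen_ou_stress()` | ACF $= C_0 e^{-t/\tau_c}$, $\eta = V C_0 \tau_c / k_B T$ | Green–Kubo |

The rotor integrates orientation with tangential Gaussian kicks and
renormalization; its leading discretization bias in the decay rate is
$O(D_r \Delta t)$, negligible at the default pairing ($D_r \Delta t \le
10^{-3}$). Brownian/Langevin positions are unwrapped by default with a
wrapped variant to exercise the unwrapping logic. The dimers place each
donor/acceptor pair on a sparse lattice so schedules cannot cross-talk;
in-bond geometry draws the donor–acceptor distance from a truncated
normal inside the distance window and the angle uniformly inside the
angle window, and off frames displace the acceptor to twice the maximum
distance.

None of these fixtures have force-field realism: no excluded volume
beyond the toy mixture's hard cores, no charge ordering, no hydrogen-bond
network dynamics. Passing tests therefore demonstrate estimator
correctness (normalizations, windows, integrators, bookkeeping) — not that
any particular real DES is water-stable. The one result carried at
published scale is the pair-energy table, and the stability analysis is
validated by recomputing its $S$ column from its own energies.

# Problem sizes and numerical tolerances

The validation suite runs at deliberately moderate scale, chosen so each
statistical check has comfortable headroom over its own standard error:
ideal gas at $n = 1000$, 200 frames for RDF flatness within 0.05;
Brownian $n = 500 \times 2000$ steps for $D_s$ within 5%; Langevin
$n = 800 \times 1500$ for the VACF within 0.05; rotors
$n = 400 \times 800$ for the VRD rate within 10%; an OU stress series of
$10^5$ steps for the Green–Kubo integral within 10%. Exact identities
(LJ root and minimum, the Coulomb constant, FFT-vs-direct equality,
schedule-constructed occupancies) are asserted at $10^{-6}$–$10^{-12}$.
Binned estimators are pinned to direct double-loop oracles on small
frames, bin for bin.

# Known limitations

* Orthorhombic cells only; no triclinic minimum image.
* No Ewald/PME electrostatics; absolute interaction energies are
  cutoff-scheme dependent (ratios are not).
* Hydrogen-bond analysis is geometric only — no energetic or orbital
  definitions, and occupancy rather than lifetime correlation.
* Viscosity from a single stress trajectory is intrinsically noisy; the
  plateau diagnostic flags, but cannot repair, an unconverged integral.
* The binary trajectory formats of production MD codes (DCD/XTC/TRR) are
  not read; convert to extended XYZ or multi-model PDB first.
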