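# deswater

Structure, hydrogen bonding, transport and water-stability analysis of
molecular-dynamics trajectories of deep eutectic solvents (DES).

A DES pairs a hydrogen-bond acceptor (HBA — e.g. choline chloride or
thymol) with a hydrogen-bond donor (HBD — e.g. fatty acids). Whether such
a solvent holds together in contact with water is the practical question
behind its use in extraction and separation. `deswater` is for
computational chemists who already have trajectories (extended XYZ or
multi-model PDB, plus a topology with charges, Lennard-Jones parameters
and HBA/HBD/water role tags) and want the standard post-processing chain
in R, tidyverse-style: every analysis takes a `trajectory` object and
returns a tibble, fitted objects have `tidy()`/`glance()` methods, and
result types have `autoplot()` methods.

## What it computes

* **Structural distributions** — radial distribution functions g(r) with
  coordination numbers CN = 4πρ ∫₀^r₁ g(r) r² dr up to the first RDF
  minimum; angular distributions; combined 2-D (distance × angle,
  distance × distance) distributions used to derive hydrogen-bond
  criteria; spatial distribution functions on a voxel grid in a
  molecule-fixed frame, written as Gaussian cube files.
* **Hydrogen bonds** — geometric detection with named criteria presets
  (`"thymol"`: 135–150°, D…A < 3.5 Å; `"chloride"`: 130–180°, D…A
  2–3 Å), per-frame count series, Gaussian fits of the count histogram
  F(X) = a/(σ√2π) · exp(−(X−X̄)²/2σ²), and per-pair percent occupancy.
* **Transport** — MSD over molecular centres of mass with the anomalous
  exponent β(τ) = d log₁₀MSD / d log₁₀τ (β = 2 inertial, β = 1
  diffusive), Einstein self-diffusion D_s = slope/6 in Å²/ns fitted on
  the diffusive window; normalized VACF with mean-collision and
  velocity-randomization times from its first and second zeros;
  bond-vector reorientation dynamics VRD(τ); Green–Kubo shear viscosity
  η = V/(k_B T) ∫ ⟨P_xy(0)P_xy(t)⟩ dt with running-integral and plateau
  diagnostics.
* **Energetics and stability** — pairwise Lennard-Jones + Coulomb
  decomposition (E_elec, E_vdW, E_total) between the HBA, HBD and water
  groups, and the relative water-stability factor

      S = |E(HBA–HBD)| / ( |E(HBA–water)| + |E(HBD–water)| )

  with descending ranking and classification against the miscibility
  threshold S = 3.30 (S ≤ 3.30: water-miscible; S > 3.30: water-stable).
* **Synthetic trajectories** — deterministic generators (ideal gas,
  Brownian, Langevin, rigid rotors, scheduled hydrogen-bonded dimers,
  packed toy mixtures, biphasic slabs, Ornstein-Uhlenbeck stress series)
  whose known ground truth backs the entire test suite.

## Worked example

The bundled reference table `des_energy_table()` carries the three pair
energies (kcal/mol, 353 K) for eleven DES/water systems — six choline
chloride/fatty-acid mixtures (CAC … CMA) and five thymol/fatty-acid
mixtures (TAC … TMA). Recomputing S and ranking:

```r
library(deswater)
des_energy_table() |> stability_report()
#> # A tibble: 11 × 4
#>    system     S  rank classification
#>    <chr>  <dbl> <int> <chr>
#>  1 TMA    4.60      1 water-stable
#>  2 TDA    4.06      2 water-stable
#>  3 TCA    3.70      3 water-stable
#>  4 TBA    1.37      4 water-miscible
#>  5 TAC    0.873     5 water-miscible
#>  6 CMA    0.315     6 water-miscible
#>  7 CLA    0.140     7 water-miscible
#>  8 CDC    0.127     8 water-miscible
#>  9 CCA    0.116     9 water-miscible
#> 10 CBU    0.107    10 water-miscible
#> 11 CAC    0.106    11 water-miscible
```

Reading: the thymol/long-chain-fatty-acid solvents (myristic TMA 4.60,
decanoic TDA 4.06) sit well above the 3.30 threshold — their HBA–HBD
cohesion outweighs their affinity for water — while every choline
chloride solvent is deep in the miscible range (S ≤ 0.315), dominated by
the salt's strong interaction with water. (TBA's component energies give
S = 1.37; the table's own reported value for that system is inconsistent
with its components and is documented as a known quirk.)

The same decomposition runs on any trajectory. On a packed synthetic
mixture:

```r
tr <- gen_toy_mixture(c(anion = 20, cation = 20, donor = 40, water = 80),
                      simulation_cell(c(40, 40, 40)), n_frames = 10,
                      exclusion = 5, jitter = 0.05, seed = 42)
dec <- bind_decompositions("toy",
  group_interaction_energy(tr, "HBA", "HBD",   cutoff = 12, label = "hba-hbd"),
  group_interaction_energy(tr, "HBA", "water", cutoff = 12, label = "hba-water"),
  group_interaction_energy(tr, "HBD", "water", cutoff = 12, label = "hbd-water"))
dec
#> # A tibble: 3 × 5
#>   system pair      e_elec e_vdw e_total
#>   <chr>  <chr>      <dbl> <dbl>   <dbl>
#> 1 toy    hba-hbd   -5.87  -1.60   -7.46
#> 2 toy    hba-water  6.19  -1.97    4.22
#> 3 toy    hbd-water -0.668 -2.04   -2.71
stability_report(dec)
#> # A tibble: 1 × 4
#>   system     S  rank classification
#>   <chr>  <dbl> <int> <chr>
#> 1 toy     1.08     1 water-miscible
```

Randomly packed charges have no cohesive structure, so the toy system
lands in the miscible range — the numbers demonstrate the pipeline, not a
force field.

Other entry points follow the same shape: `compute_rdf()` →
`find_first_extrema()` → `coordination_number()`;
`hbond_count_series()` → `fit_gaussian_histogram()` and
`hbond_occupancy()`; `compute_msd()` → `fit_diffusion()`;
`compute_vacf()` → `vacf_zero_times()`; `green_kubo_viscosity()`;
`run_pipeline()` drives a whole configured sweep from a YAML file (see
`inst/extdata/example-config.yaml`).

## Limitations

Orthorhombic cells only; no Ewald electrostatics (truncated-shifted
Coulomb, so absolute energies are cutoff-scheme dependent while the ratio
S is not); geometric hydrogen-bond criteria only; no binary trajectory
formats (convert DCD/XTC to extended XYZ first). See the methods
vignette (`vignettes/deswater-methods.Rmd`) for the full model
description, numerical choices and validation design.
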