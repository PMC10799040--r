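Package: deswater
Title: Structure, Hydrogen Bonding, Transport and Water-Stability Analysis of
    Deep Eutectic Solvent Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for molecular-dynamics trajectories of deep
    eutectic solvents (DES) and DES/water mixtures. Reads extended-XYZ and
    multi-model PDB trajectories with a YAML topology (charges, Lennard-Jones
    parameters, species and hydrogen-bond role tags), and computes radial,
    angular, combined and spatial distribution functions with coordination
    numbers; geometric hydrogen-bond detection, per-frame count series,
    Gaussian fits of count distributions and per-pair percent occupancy;
    mean-squared displacement with anomalous-exponent classification and
    Einstein self-diffusion, velocity and bond-vector reorientation
    autocorrelation functions, and Green-Kubo shear viscosity from
    off-diagonal stress series; and a pairwise Lennard-Jones/Coulomb
    interaction-energy decomposition between hydrogen-bond acceptor, donor
    and water groups feeding a relative water-stability factor with ranking
    and miscibility classification. A deterministic synthetic-trajectory
    generator (ideal gas, Brownian, Langevin, rigid rotors, hydrogen-bonded
    dimers, packed toy mixtures, biphasic slabs, Ornstein-Uhlenbeck stress)
    provides fixtures with known ground truth for every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
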