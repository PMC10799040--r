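# Example analysis configuration for run_pipeline()/validate_config().
# Paths are relative to the working directory at run time.
trajectory: mixture.xyz
topology: mixture-topology.yaml
outdir: deswater-run
seed: 1
temperature: 353.15
stages:
  rdf:
    group_a: HBA
    group_b: HBD
    r_max: 10
    dr: 0.05
  hbond:
    preset: chloride
  energy:
    cutoff: 12
  stability: ~
  msd:
    unwrap: true
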