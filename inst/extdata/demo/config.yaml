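# Demo configuration: 30-plant synthetic population bundled with the package.
seed: 20
inputs:
  genotypes: genotypes.csv
  format: csv
  coords: coords.csv
  environment: environment.csv
analysis:
  distance_class_width: 0.5
  n_perm_distogram: 99
  n_perm_mantel: 99
  n_perm_fst: 99
  n_bearing_angles: 32
  sector_halfwidth: 15
stages: [diversity, isotropic, anisotropic, spca, sar]
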