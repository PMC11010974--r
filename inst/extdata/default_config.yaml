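cofactor: 150.0
perplexity: 70.0
iterations: 3000.0
pca_dims: 50.0
cell_cap: 1000.0
doublet_max_deviation: 0.3
tie_tol: 1.0e-09
thresholds:
  positive:
    CD34: 500.0
    CD38: 500.0
    CD45RA: 500.0
    CD123: 500.0
    PD-L1: 500.0
  cd123_low_upper: 2000.0
  viability_dead: 1000.0
  cd34: 500.0
grid:
  n_bins: 100.0
  pad: 0.02
  smooth_sigma: 1.0
gates:
  fsc_ssc:
    x: FSC-A
    'y': SSC-A
    vertices:
    - - 20000.0
      - 0.0
    - - 262144.0
      - 0.0
    - - 262144.0
      - 262144.0
    - - 20000.0
      - 262144.0
  cd45_ssc:
    x: CD45
    'y': SSC-A
    vertices:
    - - 500.0
      - 0.0
    - - 262144.0
      - 0.0
    - - 262144.0
      - 262144.0
    - - 500.0
      - 262144.0
  goi:
    x: CD34
    'y': SSC-A
    vertices:
    - - 0.0
      - 0.0
    - - 262144.0
      - 0.0
    - - 262144.0
      - 60000.0
    - - 0.0
      - 60000.0
tsne_gates: ~
seed: 1

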