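# Reference-scale composite-gel experiment (long-running: days of CPU).
# Desk-scale work should reduce Nb and the run lengths; see the package
# vignette for the reduced defaults used by the shipped experiments.
model:
  lambda_emb: 0.4
matrix:
  Nb: 13
  M: 2
embedded:
  composition: 1
system_kinds: [composite, particles, bare_gel]
pressures: [0.001, 0.002, 0.005, 0.01, 0.02, 0.05, 0.1, 0.2, 0.5]
run:
  n_equil_tau: 5000
  n_prod_tau: 150000
  sample_every: 200
  initial_phi: 0.05
master_seed: 1
output_dir: reference_scale_out
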