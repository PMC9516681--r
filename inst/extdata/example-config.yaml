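# Example run configuration: one-leaflet POPC-like membrane model.
# All randomness in a run flows from this single seed.
seed: 1
temperature: 300          # kelvin
preset: popc_like
convention: full          # segment force constants quoted as U = k (z-z0)^2
z_bulk: 37.5              # Angstrom
sampling:
  n_steps: 200000         # Brownian-dynamics steps per window
  dt: 0.05                # ps
  exchange_interval: 200  # steps between exchange attempts (10 ps)
  stride: 5               # save every 5th step
wham:
  bin_width: 0.5          # Angstrom
  tol: 1.0e-7             # kcal/mol on window free energies
  max_iter: 100000
diffusion:
  k: 2.5                  # kcal/mol/A^2, half convention
  n_steps: 400000         # 20 ns at dt = 0.05 ps
  n_repeats: 2
perm:
  combine: min            # headline = rate-limiting of P_flip, P_out
  z_out_limit: 30         # Angstrom
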