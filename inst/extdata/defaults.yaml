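# Default run configuration. Values here mirror the package defaults;
# user config files are merged over this tree key by key.
seed: 1
log_level: info
physics:
  coil:
    n_turns: 500
    wire_diameter_mm: 1.2
    radius_m: 0.1
    separation_m: 0.1
    coil_resistance_ohm: 3.0
  seed_mechanics:
    V_seed: 2.5e-7
    rho_seed: 1250.0
    zeta: 0.1
  losses:
    switching_loss_W: 1.0
    control_power_W: 0.5
  impedance_ohm: 10.0
optimizer:
  ga_pop_size: 50
  crossover_p: 0.8
  mutation_p: 0.02
  tournament_k: 3
  swarm_size: 30
  inertia_max: 0.9
  inertia_min: 0.4
  c1: 2.0
  c2: 2.0
  migration_interval: 10
  migration_count: 5
  max_iters: 100
  archive_capacity: 200
network:
  lr_min: 1.0e-4
  lr_max: 1.0e-2
  cycle: 200
  max_epochs: 10
  clip_norm: 1.0
  batch_size: 32
  momentum: 0.9
fixtures:
  n_per_variety: 2000
  seeds_per_batch: 10
  noiseless: false
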