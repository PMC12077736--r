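# Default Pacific lamprey parameterization of the annual life cycle model.
# Every value here equals the package default; the file doubles as a template
# for user configurations. Capacities may alternatively be supplied as
# {density_per_m2: , area_km2: } blocks.
params:
  fecundity_mean: 127000        # eggs per female (mean)
  fecundity_sd: 33500           # eggs per female (SD)
  female_ratio: 0.5
  egg_survival: 0.02            # density-independent egg -> age-0 survival
  egg_capacity:                 # 575 eggs/m^2 over 1 km^2 = 575e6 eggs
    density_per_m2: 575
    area_km2: 1
  summer_mortality: 0
  winter_mortality: 0
  summer_capacity:              # 0.13 larvae/m^2 over 10 km^2 = 1.3e6 larvae
    density_per_m2: 0.13
    area_km2: 10
  winter_capacity:
    density_per_m2: 0.13
    area_km2: 10
  larval_survival: [0.33, 0.45, 0.61, 0.69, 0.74, 0.77, 0.79, 0.8, 0.8, 0.8, 0.8]
  transform_prob: [0, 0, 0.002, 0.042, 0.555, 1, 1, 1, 1, 1, 1]
  downstream_barriers: []
  ocean_entry_mean: 0.46
  ocean_entry_sd: 0.09
  upriver_prob: [0, 0.02, 0.05, 0.1, 0.15, 0.45, 1, 1, 1, 1, 1]
  yearly_ocean_mean: 0.7
  yearly_ocean_sd: 0.1
  river_entry_mean: 0.67
  river_entry_sd: 0.09
  upstream_barriers: []
  transformer_translocation_n: 0
  transformer_translocation_survival: 0.99
  adult_translocation_n: 0
  adult_translocation_survival: 0.99
  spawn_prob: [0.05, 0.7, 1]
  hatchery_transformers: 0
  initial_spawners: 800
simulation:
  years: 50
  burn_in: 50
  replicates: 100
  seed: 1
  mode: stochastic
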