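# Named parameter presets for the two simulation engines.
# "hoomd_style": reduced units (nm, kBT, tau), rate-based dynamic bonding with
#   Metropolis acceptance, drag proportional to diameter.
# "java_style": physical units (nm, kBT, seconds), diffusion-limited binding
#   on contact, strain-independent unbinding, Stokes drag at the given
#   viscosity.
hoomd_style:
  units: {length: nm, energy: kBT_room, time: tau}
  dt: 0.002
  drag_rule: diameter
  reference_diameter: 12.6
  box_edge: 860.0
  monomeric_box_edge: 400.0
  n_dimer: 1170
  n_hexamer: 390
  n_monomeric: 200
  n_gem: 20
  hexamer_diameter: 12.6
  rod_inner_diameter: 11.7
  rod_outer_diameter: 13.45
  rod_sphere_spacing: 5.0
  crowder_diameter: 30.0
  gem_diameter: 40.0
  site_diameter: 2.0
  d_bind: 1.0
  # binders are 2-nm spheres, so the critical distance is read as the gap
  # between binder-sphere surfaces (capture at 3 nm centre distance)
  bind_criterion: surface
  eps_soft: 500.0
  lj_epsilon: 0.0
  kon: 50.0
  koff: [0.001, 0.0001]
  updater_period: 10
  # bonds rest with the binder spheres in contact; the spring is soft enough
  # that the Metropolis factor does not close off the capture shell
  bond_spring_k: 10.0
  bond_rest_length: 2.0
  crowder_temperature_range: [0.5, 2.0]
  compression_initial_edge: 1400.0
  compression_steps: 500000
java_style:
  units: {length: nm, energy: kBT_room, time: s}
  dt: 1.0e-7
  drag_rule: stokes
  viscosity: 0.03
  box_edge: 860.0
  monomeric_box_edge: 400.0
  n_dimer: 1170
  n_hexamer: 390
  n_monomeric: 200
  n_gem: 0
  hexamer_diameter: 12.6
  rod_diameter: 23.4
  crowder_diameter: 30.0
  gem_diameter: 40.0
  site_diameter: 2.0
  d_bind: 2.3
  # binding criterion: distance between site centres <= d_bind (the
  # "surface" gap convention is available as a config alternative)
  bind_criterion: center
  # collision forces are attenuated for numerical stability at this time
  # step (max contact force x mobility x dt stays well below the particle
  # size); plays the role of the attenuation factor of the collision solver
  eps_soft: 10.0
  lj_epsilon: 0.0
  koff: 26.0
  updater_period: 1
  bond_spring_k: 3.0
  bond_rest_length: 2.0
  crowder_temperature_range: [1.0, 1.0]
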