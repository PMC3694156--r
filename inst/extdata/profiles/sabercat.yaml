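# Large dirk-toothed felid profile: long curved sabers whose arc centre
# sits close to the jaw joint, wide maximum gape, heavy body mass.
name: sabercat
model:
  skull_length: 300
  body_mass: 259
  canine_length: 96
  canine_arc_radius: 120
  canine_arc_ratio: 0.17
  gape_bone_contact_deg: 89.1
  element_budget: 5000
  seed: 1
depressors:
  ellipse_axes: [40, 26]
  circle_radius: 30
gape:
  cartilage_mm: 1
  backoff_deg: 2
scaling:
  exponent: 0.666666666666667
  reference: sabercat
sweep:
  angles: [15, 30, 45, 60]
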