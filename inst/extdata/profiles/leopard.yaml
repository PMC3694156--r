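# Conical-toothed felid profile: short, nearly straight canines, modest
# gape, lightest body mass of the trio.
name: leopard
model:
  skull_length: 210
  body_mass: 68
  canine_length: 28
  canine_arc_radius: 70
  canine_arc_ratio: 0.2
  gape_bone_contact_deg: 74.6
  element_budget: 5000
  seed: 1
depressors:
  ellipse_axes: [30, 20]
  circle_radius: 23
gape:
  cartilage_mm: 1
  backoff_deg: 2
scaling:
  exponent: 0.666666666666667
  reference: sabercat
sweep:
  angles: [15, 30, 45, 60]
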