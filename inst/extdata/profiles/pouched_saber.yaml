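# Saber-toothed sparassodont profile: extreme canines with the arc centre
# far antero-ventral of the joint, the widest gape, moderate body mass.
name: pouched_saber
model:
  skull_length: 260
  body_mass: 82
  canine_length: 100
  canine_arc_radius: 110
  canine_arc_ratio: 0.33
  gape_bone_contact_deg: 98
  element_budget: 5000
  seed: 1
depressors:
  ellipse_axes: [36, 25]
  circle_radius: 26
gape:
  cartilage_mm: 1
  backoff_deg: 2
scaling:
  exponent: 0.666666666666667
  reference: sabercat
sweep:
  angles: [15, 30, 45, 60]
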