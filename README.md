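# craniofem

Comparative cranio-mandibular biomechanics of saber-toothed biting, as a
tested and reusable R pipeline.

Saber-toothed carnivorans — machairodontine cats and the sparassodont
*Thylacosmilus*-grade metatherians — pose a classic functional puzzle:
elongate upper canines demand enormous gapes, wide gapes destroy
jaw-adductor leverage, and the leading killing-bite hypothesis
("canine-shear bite") invokes the head-depressing neck musculature to
drive the sabers home. Quantitative comparison of such skulls rests on a
specific analysis stack: linear-elastic finite-element models of cranium
and mandible with pretensioned truss musculature and a hinged
temporomandibular joint (TMJ); a three-dimensional maximum-gape estimate
built from articular-cartilage offset surfaces, iterative-closest-point
(ICP) seating and rotation to bone contact; the lateral-view circle
fitted to the canine's distal margin (how far its centre sits from the
jaw joint separates rotation-dominated from translation-dominated canine
strokes); and allometric bite-force scaling,

F_target = F_ref (M_target / M_ref)^(2/3),

with muscle recruitment back-calculated by linearity and regional /
landmark von Mises (VM) stress means compared across models.

craniofem implements that stack end to end for anyone who wants to run,
test or extend the method: a compact FE engine (tet4 solids,
pretensioned trusses, beams with torsional release, rigid links by exact
elimination), the TMJ hinge and gape algorithm, dry-skull muscle force
estimation, the depressor "web" reconstruction (40 + 30 trusses at 25 N
pretension on perpendicular elliptical/circular rigid-link webs), and
the scaling/comparison arithmetic. Because fossil CT meshes cannot be
redistributed, everything runs on parametric **synthetic skull models**
with planted, recoverable ground truth; three demo profiles (259, 82 and
68 kg) are bundled. See the methods vignette
(`vignettes/craniofem-methods.Rmd`) for the model details and design
decisions.

## Worked example

```r
library(craniofem)

sk <- make_skull_pair(skull_params(
  skull_length = 300, body_mass = 259,
  canine_length = 96, canine_arc_radius = 120, canine_arc_ratio = 0.17,
  gape_bone_contact_deg = 89.1))
sk
#> skull_model: L = 300 mm, mass = 259 kg
#>  cranium: 1098 nodes / 4032 tets; mandible: 512 nodes / 1800 tets
#>  planted: arc ratio 0.17, bone-contact gape 89.1 deg

g <- find_max_gape(sk)          # cartilage offset + ICP seating + rotation
g
#> gape_result: max gape 87.11 deg (bone contact 89.11 - backoff 2.0)
#>  incisor gape angle 91.50 deg (sagittal 91.50); cartilage 1 mm

fit <- fit_canine_arc(sk$canine_arc_points$left)
arc_center_ratio(fit, c(0, 0))   # planted 0.17 recovered
#> [1] 0.17

fans <- build_adductor_fans(sk)  # dry-skull forces, via-point truss fans
bite <- solve_bite(build_bite_model(sk, adductors = fans,
                                    gape_deg = g$max_gape_deg))
bite
#> bite_result: gape 87.1 deg, muscle 827 N -> bite force 41.6 N (lower canines)

round(allometric_bite_force(519, 259, 82))   # 2/3-power mass scaling
#> [1] 241
```

The maximum gape equals the planted bone-contact rotation minus the
soft-tissue back-off; the arc-centre ratio is the planted 17% of the
fulcrum-to-circumference distance; the adductor-driven bite force at
maximum gape is roughly a third of its value at a 15-degree gape on this
profile (run `gape_sweep(sk, c(15, 30, 45, 60, 87))` to see the curve);
and the allometric line is the scaling used to put models of different
body mass on a common footing.

The full comparative run over the bundled profiles — generate skulls,
estimate gapes, solve adductor- and depressor-driven bites, sweep gape
angles, back-calculate recruitments and tabulate scaled stresses —

```r
cmp <- run_comparison(as.list(demo_profile()))
write_comparison_csv(cmp, "out")
```

takes under a minute and is byte-identical across reruns with the same
seed. The same stages are available from a shell via the thin CLI at
`inst/cli/craniofem` (`generate | gape | solve | sweep | compare |
report`).

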