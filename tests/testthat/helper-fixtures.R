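# shared fixtures, built once per test run

.fixture_env <- new.env()

default_skull <- function() {
  if (is.null(.fixture_env$skull)) {
    .fixture_env$skull <- make_skull_pair(skull_params())
  }
  .fixture_env$skull
}

# unit-variance UV sphere with consistently outward-oriented triangles
uv_sphere <- function(r, nth = 18, nph = 36) {
  th <- seq(0, pi, length.out = nth)
  ph <- seq(0, 2 * pi, length.out = nph + 1)[-(nph + 1)]
  g <- expand.grid(th = th[-c(1, nth)], ph = ph)
  v <- rbind(c(0, 0, r), c(0, 0, -r),
             r * cbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th)))
  idx <- function(i, j) 2 + i + ((j - 1) %% nph) * (nth - 2)
  tris <- list()
  for (j in 1:nph) {
    tris[[length(tris) + 1]] <- cbind(1, idx(1, j), idx(1, j + 1))
    tris[[length(tris) + 1]] <- cbind(2, idx(nth - 2, j + 1), idx(nth - 2, j))
    for (i in 1:(nth - 3)) {
      tris[[length(tris) + 1]] <- cbind(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
      tris[[length(tris) + 1]] <- cbind(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
    }
  }
  tri <- do.call(rbind, tris)
  # flip triangles whose normal points inward
  a <- v[tri[, 2], ] - v[tri[, 1], ]
  b <- v[tri[, 3], ] - v[tri[, 1], ]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  cen <- (v[tri[, 1], ] + v[tri[, 2], ] + v[tri[, 3], ]) / 3
  flip <- rowSums(n * cen) < 0
  tri[flip, c(2, 3)] <- tri[flip, c(3, 2)]
  list(nodes = v, tri = tri)
}

# axial bar model: fixed face restrained axially (plus minimal lateral
# supports that permit free Poisson contraction), area-consistent end load
axial_bar_model <- function(length = 10, side = 1, ndiv = 4, E = 20000,
                            nu = 0.3, force = 100) {
  bar <- make_bar_fixture(length, side, ndiv)
  mod <- fe_from_mesh(bar, list(bone = material("bone", E, nu)))
  fx <- bar$node_sets$fixed
  mod <- add_constraint(mod, fx, 1)
  corner <- fx[which.min(bar$nodes[fx, 2] + bar$nodes[fx, 3])]
  other <- fx[which.min(abs(bar$nodes[fx, 2] - bar$nodes[corner, 2]) +
                          abs(bar$nodes[fx, 3] - side))]
  mod <- add_constraint(mod, corner, 2:3)
  mod <- add_constraint(mod, other, 2)
  list(model = mod, mesh = bar,
       loads = face_load(bar, bar$node_sets$loaded, c(force, 0, 0)))
}
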