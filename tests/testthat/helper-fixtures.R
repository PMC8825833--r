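# Shared fixtures: small meshes, ad-hoc scenes and independent oracles.

# icosahedron-free simple sphere at modest resolution
fixture_ball <- function(radius = 1, centre = c(0, 0, 0), res = 0.3) {
  prof <- bearingrrt:::arc_profile(radius, 0, 0, -pi / 2, pi / 2, res)
  m <- bearingrrt:::revolve_mesh(prof, bearingrrt:::segments_around(radius, res),
                                 name = "ball")
  mesh_translate(m, centre)
}

fixture_slab <- function(lo, hi) box_mesh(lo, hi, name = "slab")

# a hollow room of six slabs with inner cavity [lo, hi]
fixture_room <- function(lo = c(-5, -5, -5), hi = c(5, 5, 5), t = 1) {
  list(
    fixture_slab(c(lo[1] - t, lo[2] - t, lo[3] - t), c(hi[1] + t, hi[2] + t, lo[3])),
    fixture_slab(c(lo[1] - t, lo[2] - t, hi[3]), c(hi[1] + t, hi[2] + t, hi[3] + t)),
    fixture_slab(c(lo[1] - t, lo[2] - t, lo[3]), c(hi[1] + t, lo[2], hi[3])),
    fixture_slab(c(lo[1] - t, hi[2], lo[3]), c(hi[1] + t, hi[2] + t, hi[3])),
    fixture_slab(c(lo[1] - t, lo[2], lo[3]), c(lo[1], hi[2], hi[3])),
    fixture_slab(c(hi[1], lo[2], lo[3]), c(hi[1] + t, hi[2], hi[3])))
}

# free space with a goal slab along +x (package helper, fresh cache per call)
fixture_free_scene <- function(goal_x = 10, environment = list()) {
  free_space_scene(goal_distance = goal_x, environment = environment)
}

# scene with the robot sealed inside a room, goal outside
fixture_sealed_scene <- function() {
  sc <- fixture_free_scene(environment = fixture_room())
  sc$bbox <- rbind(lo = c(-4.5, -4.5, -4.5), hi = c(20, 4.5, 4.5))
  sc$goal <- rbind(lo = c(15, -4.5, -4.5), hi = c(20, 4.5, 4.5))
  sc
}

# ---- independent brute-force triangle-triangle intersection oracle -------
# Pure-R separating-axis test over all triangle pairs; used to cross-check
# the BVH collision pipeline on small meshes.

sat_tri_pair_intersects <- function(A, B) {
  axes <- list(
    pracma_cross(A[2, ] - A[1, ], A[3, ] - A[1, ]),
    pracma_cross(B[2, ] - B[1, ], B[3, ] - B[1, ]))
  ea <- list(A[2, ] - A[1, ], A[3, ] - A[2, ], A[1, ] - A[3, ])
  eb <- list(B[2, ] - B[1, ], B[3, ] - B[2, ], B[1, ] - B[3, ])
  for (u in ea) for (v in eb) axes[[length(axes) + 1L]] <- pracma_cross(u, v)
  for (ax in axes) {
    n2 <- sum(ax^2)
    if (n2 < 1e-18) next
    pa <- A %*% ax
    pb <- B %*% ax
    if (min(pb) > max(pa) || min(pa) > max(pb)) return(FALSE)
  }
  TRUE
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

brute_force_meshes_intersect <- function(mesh_a, mesh_b) {
  va <- mesh_a$vertices
  vb <- mesh_b$vertices
  for (i in seq_len(nrow(mesh_a$faces))) {
    A <- va[mesh_a$faces[i, ], , drop = FALSE]
    for (j in seq_len(nrow(mesh_b$faces))) {
      B <- vb[mesh_b$faces[j, ], , drop = FALSE]
      if (sat_tri_pair_intersects(A, B)) return(TRUE)
    }
  }
  FALSE
}

# planner settings used by fast tests
fixture_settings <- function(iters = 500L, attempts = 2L, seed = 1, ...) {
  planner_settings(collision_resolution = 0.1, max_iterations = as.integer(iters),
                   attempts = as.integer(attempts), seed = seed, ...)
}
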