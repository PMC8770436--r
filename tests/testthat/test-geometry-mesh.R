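test_that("domain spec enforces its geometric invariants", {
  spec <- domain_spec()
  expect_equal(spec$probe_length, 1125)
  expect_equal(spec$probe_width, 125)
  expect_equal(spec$probe_thickness, 25)
  expect_equal(spec$tissue_width, 1500)
  expect_equal(spec$embed_depth, 1125)
  expect_equal(domain_spec(probe_thickness = 63)$probe_thickness, 63)
  expect_error(domain_spec(probe_width = 2000), "inside the tissue width")
  expect_error(domain_spec(probe_width = 1500), "inside the tissue width")
  expect_error(domain_spec(probe_thickness = 1500), "inside the tissue")
  expect_error(domain_spec(tissue_depth = 1000, embed_depth = 1125))
  expect_error(domain_spec(probe_length = -5), "positive")
})

test_that("mesh params validate grading and aspect-ratio bounds", {
  expect_error(mesh_params(ratio = 0.9), ">= 1")
  expect_error(mesh_params(h_near = 2, h_max = 60), "aspect-ratio")
  expect_error(mesh_params(n_through_thickness = 2))
  expect_silent(mesh_params(h_near = 8, ratio = 1.4, h_max = 100))
})

test_that("structured grid gives the exact tensor-product counts", {
  for (n in c(1, 3)) {
    lines <- seq(0, 1, length.out = n + 1)
    m <- hex_grid_mesh(lines, lines, lines)
    expect_equal(nrow(m$elements), n^3)
    expect_equal(nrow(m$nodes), (n + 1)^3)
    expect_true(all(min_jacobians(m) > 0))
    expect_equal(sum(element_volumes(m)), 1, tolerance = 1e-12)
  }
})

test_that("probe-in-tissue mesh is conforming, positive and volume-exact", {
  spec <- domain_spec()
  mesh <- generate_hex_mesh(spec, coarse_mesh_params(), symmetry = "none")
  expect_true(all(min_jacobians(mesh) > 0))
  # carved probe still fills the box: total volume equals the tissue block
  expect_equal(sum(element_volumes(mesh)), 1500^3 * 1, tolerance = 1e-10)
  # bonded contact by construction: every interface node belongs to both a
  # probe and a tissue element
  probe_nodes <- unique(as.vector(mesh$elements[mesh$region == "probe", ]))
  tissue_nodes <- unique(as.vector(mesh$elements[mesh$region == "tissue", ]))
  expect_true(length(mesh$node_sets$interface) > 0)
  expect_true(all(mesh$node_sets$interface %in% probe_nodes))
  expect_true(all(mesh$node_sets$interface %in% tissue_nodes))
  # element aspect ratios bounded
  n <- mesh$nodes; e <- mesh$elements
  dx <- abs(n[e[, 7], 1] - n[e[, 1], 1])
  dy <- abs(n[e[, 7], 2] - n[e[, 1], 2])
  dz <- abs(n[e[, 7], 3] - n[e[, 1], 3])
  aspect <- pmax(dx, dy, dz) / pmin(dx, dy, dz)
  expect_lte(max(aspect), 20 + 1e-9)
})

test_that("meshing is deterministic and refines monotonically", {
  spec <- domain_spec()
  m1 <- generate_hex_mesh(spec, mesh_params(h_near = 10, ratio = 1.4,
                                            h_max = 120))
  m2 <- generate_hex_mesh(spec, mesh_params(h_near = 10, ratio = 1.4,
                                            h_max = 120))
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$elements, m2$elements)
  expect_identical(m1$region, m2$region)
  # halving the near-interface size strictly increases the element count
  m_half <- generate_hex_mesh(spec, mesh_params(h_near = 5, ratio = 1.4,
                                                h_max = 60))
  expect_gt(nrow(m_half$elements), nrow(m1$elements))
  # near-interface size above the probe thickness is rejected
  expect_error(generate_hex_mesh(spec, mesh_params(h_near = 30, ratio = 1.4,
                                                   h_max = 100)),
               "exceeds the probe thickness")
})

test_that("node sets pick the supports, load patch and monitors", {
  spec <- domain_spec()
  mesh <- generate_hex_mesh(spec, coarse_mesh_params(), symmetry = "none")
  ns <- mesh$node_sets
  n <- mesh$nodes
  # bottom_edges: exactly the nodes on the four perimeter edges of the
  # tissue bottom face
  be <- ns$bottom_edges
  expect_true(all(abs(n[be, 2] - 1500) < 1e-6))
  expect_true(all(abs(abs(n[be, 1]) - 750) < 1e-6 |
                  abs(abs(n[be, 3]) - 750) < 1e-6))
  manual <- which(abs(n[, 2] - 1500) < 1e-6 &
                  (abs(abs(n[, 1]) - 750) < 1e-6 |
                   abs(abs(n[, 3]) - 750) < 1e-6))
  expect_setequal(be, manual)
  # probe top face spans the probe cross-section at the tissue surface
  tf <- ns$probe_top_face
  expect_true(all(abs(n[tf, 2]) < 1e-6))
  expect_equal(range(n[tf, 1]), c(-62.5, 62.5))
  expect_equal(range(n[tf, 3]), c(-12.5, 12.5))
  # monitors: tissue nodes within one element size of their physical points
  pts <- rbind(c(0, 1135, 0), c(0, 1115, 22.5), c(0, 10, 22.5),
               c(0, 10, -22.5))
  for (k in 1:4) {
    node <- ns[[paste0("monitor_", k)]]
    expect_lte(sqrt(sum((n[node, ] - pts[k, ])^2)), 1.74 * 8)
  }
})

test_that("monitor points stay at the same physical location across refinement", {
  spec <- domain_spec()
  coarse <- generate_hex_mesh(spec, mesh_params(h_near = 10, ratio = 1.4,
                                                h_max = 120))
  fine <- generate_hex_mesh(spec, mesh_params(h_near = 6, ratio = 1.4,
                                              h_max = 80))
  for (k in 1:4) {
    pc <- coarse$nodes[coarse$node_sets[[paste0("monitor_", k)]], ]
    pf <- fine$nodes[fine$node_sets[[paste0("monitor_", k)]], ]
    expect_lte(sqrt(sum((pc - pf)^2)), 1.74 * 10)
  }
})

test_that("quarter mesh matches the full mesh on its quadrant", {
  spec <- domain_spec()
  mp <- coarse_mesh_params()
  full <- generate_hex_mesh(spec, mp, symmetry = "none")
  quarter <- generate_hex_mesh(spec, mp, symmetry = "quarter")
  expect_equal(4 * nrow(quarter$elements), nrow(full$elements))
  expect_true(all(quarter$nodes[, 1] >= 0), all(quarter$nodes[, 3] >= 0))
  expect_equal(sum(element_volumes(quarter)), 1500^3 / 4, tolerance = 1e-10)
  # grid lines of the quarter are exactly the non-negative full grid lines
  expect_equal(quarter$grid$xs, full$grid$xs[full$grid$xs >= -1e-9])
  expect_equal(quarter$grid$zs, full$grid$zs[full$grid$zs >= -1e-9])
  expect_equal(quarter$grid$ys, full$grid$ys)
  expect_true(length(quarter$node_sets$sym_x0) > 0)
  expect_true(length(quarter$node_sets$sym_z0) > 0)
})
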