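test_that("defect geometry matches the printed anchors", {
  geom <- default_geom()
  expect_equal(unname(geom$rects$defect), c(0, 20, 5, 25))
  # load calibration: 0.637 MPa over the top surface is the 800 N joint force
  expect_equal(geom$load_force, 0.637 * pi * 20^2)
  expect_lt(abs(geom$load_force - 800), 1)
})

test_that("degenerate configurations are rejected", {
  expect_error(build_condyle_geometry(condyle_config(defect_depth = 0)),
               "positive")
  expect_error(build_condyle_geometry(condyle_config(defect_depth = 2)),
               "cancellous")
  expect_error(build_condyle_geometry(condyle_config(cartilage = 30)),
               "height|cancellous")
})

test_that("defect sub-mesh element counts follow the seed", {
  geom <- default_geom()
  mesh <- mesh_geometry(geom, seed = 0.125, meniscus = FALSE)
  expect_identical(sum(mesh$region == "defect"), 1600L)
  expect_identical(dim(mesh$defect_elems), c(40L, 40L))
  mesh2 <- mesh_geometry(geom, seed = 0.25, meniscus = FALSE)
  expect_identical(sum(mesh2$region == "defect"), 400L)
  expect_error(mesh_geometry(geom, seed = 0.3), "divide")
})

test_that("lattice-element map is a bijection and geometrically consistent", {
  mesh <- mesh_geometry(default_geom(), meniscus = FALSE)
  ids <- as.vector(mesh$defect_elems)
  expect_identical(length(unique(ids)), 1600L)
  expect_true(all(mesh$region[ids] == "defect"))
  # element centroids sit at the expected lattice positions
  e1 <- mesh$elems[mesh$defect_elems[1, 1], 1:4]
  expect_equal(mean(mesh$nodes[e1, 1]), 0.0625)
  expect_equal(mean(mesh$nodes[e1, 2]), 20.0625)
  e2 <- mesh$elems[mesh$defect_elems[40, 40], 1:4]
  expect_equal(mean(mesh$nodes[e2, 1]), 5 - 0.0625)
  expect_equal(mean(mesh$nodes[e2, 2]), 25 - 0.0625)
})

test_that("mesh coarsening stays below the maximum seed", {
  mesh <- mesh_geometry(default_geom(), meniscus = TRUE)
  el <- mesh$elems[, 1:4]
  dr <- abs(mesh$nodes[el[, 2], 1] - mesh$nodes[el[, 1], 1])
  dz <- abs(mesh$nodes[el[, 4], 2] - mesh$nodes[el[, 1], 2])
  expect_lt(max(dr), 0.8 + 1e-6)
  expect_lt(max(dz[mesh$region != "meniscus"]), 0.8 + 1e-6)
  # all element Jacobians positive (no inverted elements): proxy via areas
  r <- matrix(mesh$nodes[el, 1], nrow(el), 4)
  z <- matrix(mesh$nodes[el, 2], nrow(el), 4)
  area <- 0.5 * abs(rowSums(r * z[, c(2, 3, 4, 1)] - z * r[, c(2, 3, 4, 1)]))
  expect_true(all(area > 0))
})

test_that("mesh generation is deterministic", {
  m1 <- mesh_geometry(default_geom(), meniscus = TRUE)
  m2 <- mesh_geometry(default_geom(), meniscus = TRUE)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$elems, m2$elems)
})

test_that("marrow source cells are exactly the cancellous-adjacent border", {
  cfg <- condyle_config()
  n_lat <- as.integer((cfg$defect_depth - cfg$cartilage - cfg$subchondral) /
                        0.125)
  src <- lattice_source_mask(default_geom())
  expect_true(all(src[1, ]))                     # proximal base layer
  expect_true(all(src[seq_len(n_lat), 40]))      # lateral border vs cancellous
  expect_false(any(src[(n_lat + 1):40, 40]))     # border vs plate/cartilage
  expect_false(any(src[2:40, 1:39]))
  expect_identical(sum(src), 40L + n_lat - 1L)
  # a thinner cartilage layer exposes more lateral border to the marrow
  thin <- build_condyle_geometry(condyle_config(cartilage = 2))
  expect_identical(sum(lattice_source_mask(thin)), 59L)
})

test_that("scaffold embedding snaps to the lattice and reports areas", {
  mesh <- mesh_geometry(default_geom(), meniscus = FALSE)
  none <- embed_scaffold(mesh, scaffold_spec("none"))
  expect_true(all(none$fs == 0))

  sp <- scaffold_spec("vertical_rings", porosity = 50)
  emb <- embed_scaffold(mesh, sp)
  expect_setequal(unique(as.vector(emb$fs)), c(0, 0.5))
  # each 0.25 mm strut is two lattice columns over the whole depth
  expect_identical(sum(emb$fs > 0), as.integer(3 * 2 * 40))
  expect_equal(emb$strut_area, sum(2 * pi * sp$ring_radii * sp$strut_width))

  bad <- scaffold_spec("vertical_rings", ring_radii = c(1.3, 2.5, 3.75))
  expect_error(embed_scaffold(mesh, bad), "snap")
  out <- scaffold_spec("vertical_rings", ring_radii = c(1.5, 2.625, 4.95))
  expect_error(embed_scaffold(mesh, out), "outside")
})

test_that("scaffold fraction field is invariant under re-meshing", {
  mesh1 <- mesh_geometry(default_geom(), meniscus = FALSE)
  mesh2 <- mesh_geometry(default_geom(), meniscus = TRUE)
  sp <- scaffold_spec("grid")
  expect_identical(embed_scaffold(mesh1, sp)$fs, embed_scaffold(mesh2, sp)$fs)
})
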