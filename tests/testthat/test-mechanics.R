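oc <- asNamespace("ocdheal")

test_that("octahedral shear strain matches the principal-strain formula", {
  expect_equal(octahedral_shear_strain(c(0, 0, 0, 0)), 0)
  expect_equal(octahedral_shear_strain(c(0.01, 0, 0, 0)),
               100 * (2 / 3) * sqrt(2) * 0.01)
  # hydrostatic strain has no deviatoric part
  expect_equal(octahedral_shear_strain(c(0.02, 0.02, 0.02, 0)), 0)
  # matrix input and shear-dominated state
  m <- matrix(c(0, 0.005, 0, 0.005, 0, 0, 0, 0, 0), 3)
  expect_equal(octahedral_shear_strain(m),
               octahedral_shear_strain(c(0, 0, 0, 0.01)))
  expect_error(octahedral_shear_strain(matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3)),
               "symmetric")
})

test_that("fluid speed is the Euclidean norm of the seepage velocity", {
  expect_equal(fluid_speed(c(0, 0)), 0)
  expect_equal(fluid_speed(c(3e-3, 0)), 3e-3)
  expect_equal(fluid_speed(c(3e-4, 4e-4)), 5e-4)
})

test_that("uniaxial elastic column reproduces the closed-form strain", {
  mat <- list(E = 10, nu = 0.3, k = 0, e = 4, Kg = 0)
  sys <- oc$rect_sys(0, 1, 0, 4, 2, 8, mat, law = 1L, pressure = 1)
  ctl <- mech_control(backend = "reduced")
  sch <- data.frame(dt = 1, factor = 1, drained = FALSE, record = TRUE)
  out <- oc$fem_run(sys, sch, ctl)
  g <- out$fields[[1]][, 5]
  g_exact <- 100 * (2 * sqrt(2) / 3) * (1 + 0.3) * 1 / 10
  expect_true(all(abs(g - g_exact) / g_exact < 0.01))
})

test_that("zero applied pressure gives zero strain and fluid speed", {
  mat <- list(E = 0.2, nu = 0.167, k = 9.74e-8, e = 4, Kg = 2300)
  sys <- oc$rect_sys(0, 1, 0, 2, 2, 4, mat, law = 0L, pressure = 0,
                     confined = TRUE, drain_top = TRUE)
  ctl <- mech_control(backend = "reduced")
  sch <- data.frame(dt = 0.1, factor = 1, drained = TRUE, record = TRUE)
  out <- oc$fem_run(sys, sch, ctl)
  expect_true(all(out$fields[[1]][, 5] == 0))
  expect_true(all(out$fields[[1]][, 8] == 0))
})

test_that("confined consolidation matches the Terzaghi series solution", {
  mat <- list(E = 0.2, nu = 0.167, k = 9.74e-8, e = 4, Kg = 2300)
  H <- 1
  sys <- oc$rect_sys(0, 0.25, 0, H, 1, 20, mat, law = 0L, pressure = 0.1,
                     confined = TRUE, drain_top = TRUE)
  Eoed <- 0.2 * (1 - 0.167) / ((1 + 0.167) * (1 - 2 * 0.167))
  cv <- (9.74e-8 / 9.81e-6) * Eoed
  Tv <- 0.2
  nst <- 100
  sch <- data.frame(dt = Tv * H^2 / cv / nst, factor = 1, drained = TRUE,
                    record = FALSE)[rep(1, nst), ]
  sch$record[nst] <- TRUE
  midn <- which(abs(sys$nodes[, 1]) < 1e-9 &
                  abs(sys$nodes[, 2] - 0.5) < 1e-9)
  midn <- midn[sys$pidx[midn] >= 0][1]
  out <- oc$fem_run(sys, sch, mech_control(backend = "reduced"),
                    record_p_nodes = midn)
  p_num <- out$phist[[1]]
  p_ref <- 0.1 * terzaghi_series(0.5, Tv)
  expect_lt(abs(p_num - p_ref) / p_ref, 0.02)
})

test_that("surrogate fields drive the documented downstream stimulus", {
  st <- surrogate_field(gamma = 2, v = 0)
  S <- compute_stimulus(st)
  expect_equal(S[1, 1], 2 / 3.75)
  expect_true(all(S == S[1, 1]))
  st0 <- surrogate_field(gamma = 0, v = 0)
  expect_true(all(classify_stimulus(compute_stimulus(st0)) == "resorption"))
  # monotone ramp in depth gives a monotone stimulus ramp
  str <- surrogate_field(gamma = function(r, d) d, v = 0)
  Sr <- compute_stimulus(str)
  expect_true(all(diff(Sr[, 1]) > 0))
  expect_error(surrogate_field(gamma = -1), "non-negative")
})

test_that("the full backend solves the condyle and fields are admissible", {
  geom <- default_geom()
  mesh <- mesh_geometry(geom, meniscus = TRUE)
  ctl <- mech_control(backend = "full")
  model <- build_mech_model(mesh, load_case(), ctl)
  ms <- material_state(mesh)
  st <- solve_step(model, ms)
  expect_identical(dim(st$gamma), c(40L, 40L))
  expect_true(all(is.finite(st$gamma)) && all(st$gamma >= 0))
  expect_true(all(is.finite(st$v)) && all(st$v >= 0))
  # symmetry axis: no blow-up in the first lattice column
  expect_true(all(st$gamma[, 1] < 1e3))
  # proximal defect base is strain-shielded by the surrounding bone
  expect_lt(mean(st$gamma[1:5, ]), mean(st$gamma[36:40, ]))
  # contact: penetration bounded by the penalty compliance
  rg <- model$contact$rigid
  pen <- st$u[2 * rg$nodes] - rg$gap0
  expect_lt(max(pen), 1e-3)
})

test_that("defect-average strain is consistent under mesh refinement", {
  geom <- default_geom()
  # Halving the production defect seed (surround held fixed) changes the
  # defect-average gamma by about 15%: the shear boundary layers along the
  # soft-tissue walls are only marginally resolved at 0.125 mm, so pointwise
  # convergence there is slow. The check below is a consistency envelope for
  # that documented behaviour; the production mesh is the 1600-element
  # lattice the cell model is defined on.
  ctl <- mech_control(backend = "reduced", n_ramp = 2, n_consol = 2,
                      sampling = "end_load")
  g_avg <- sapply(c(0.125, 0.0625), function(seed) {
    mesh <- mesh_geometry(geom, seed = seed, meniscus = FALSE)
    model <- build_mech_model(mesh, load_case(), ctl)
    ms <- material_state(mesh)
    st <- solve_step(model, ms)
    mean(st$gamma)
  })
  expect_lt(abs(g_avg[2] - g_avg[1]) / g_avg[2], 0.25)
})
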