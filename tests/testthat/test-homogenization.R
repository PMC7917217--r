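test_that("table rows carry the poroelastic constants verbatim", {
  tab <- tissue_property_table()
  expect_equal(tab["cancellous", "E"], 6000)
  expect_equal(tab["subchondral", "E"], 17000)
  expect_equal(tab["granulation", c("E", "nu", "k", "e", "Kg")],
               data.frame(E = 0.2, nu = 0.167, k = 9.74e-8, e = 4, Kg = 2300,
                          row.names = "granulation"))
  expect_equal(tab["cartilage", "k"], 4.87e-8)
  expect_equal(tab["fibrous", "E"], 2)
})

test_that("day-1 strut blending follows the porosity rule", {
  sp <- scaffold_spec("vertical_rings", E_scaffold = 1000, porosity = 50)
  cell <- list(msc = 0, ob = 0, ch = 0, fb = 0, fs = 0.5, E_scaffold = 1000)
  p <- update_element_properties(cell, spec = sp)
  expect_equal(p$E, 0.5 * 0.2 + 0.5 * 1000)
  expect_equal(p$k, 0.5 * 9.74e-8 + 0.5 * 3.63e-8)
  expect_equal(p$Kg, 0.5 * 2300 + 0.5 * 0)
  expect_equal(p$nu, 0.5 * 0.167 + 0.5 * 0.3)
})

test_that("pure compositions reproduce the table rows verbatim", {
  full_ob <- list(msc = 0, ob = 100, ch = 0, fb = 0, fs = 0)
  p <- update_element_properties(full_ob)
  expect_equal(p$E, 6000)
  expect_equal(p$nu, 0.3)
  expect_equal(p$k, 3.63e-8)
  empty <- list(msc = 0, ob = 0, ch = 0, fb = 0, fs = 0)
  expect_equal(update_element_properties(empty)$E, 0.2)
  # MSC-occupied space also counts as granulation
  mscful <- list(msc = 100, ob = 0, ch = 0, fb = 0, fs = 0)
  expect_equal(update_element_properties(mscful)$E, 0.2)
})

test_that("bone-row choice is configurable and validated", {
  expect_equal(bone_phenotype_property_choice(tissue_property_table())$E, 6000)
  tab2 <- tissue_property_table(bone_row = "subchondral")
  expect_equal(bone_phenotype_property_choice(tab2)$E, 17000)
  tab3 <- tissue_property_table()
  attr(tab3, "bone_row") <- "cortical"
  expect_error(bone_phenotype_property_choice(tab3), "unknown")
})

test_that("homogenized properties are bounded, idempotent and monotone", {
  set.seed(11)
  g <- small_grid("marrow_invasion")
  # random admissible composition
  tot <- matrix(runif(1600, 0, 100), 40, 40)
  fr <- matrix(runif(1600 * 4), 1600, 4)
  fr <- fr / rowSums(fr)
  g$msc <- matrix(fr[, 1], 40, 40) * tot
  g$ob <- matrix(fr[, 2], 40, 40) * tot
  g$ch <- matrix(fr[, 3], 40, 40) * tot
  g$fb <- matrix(fr[, 4], 40, 40) * tot
  tab <- tissue_property_table()
  hp <- ocdheal:::homogenize_grid(g, tab)
  for (prop in c("E", "nu", "k", "Kg")) {
    vals <- c(tab["granulation", prop], tab["cancellous", prop],
              tab["cartilage", prop], tab["fibrous", prop])
    expect_true(all(hp[[prop]] >= min(vals) - 1e-12))
    expect_true(all(hp[[prop]] <= max(vals) + 1e-12))
  }
  # idempotence: same grid, same properties
  hp2 <- ocdheal:::homogenize_grid(g, tab)
  expect_identical(hp, hp2)
  # monotonicity: osteoblasts replacing empty space never soften an element
  g2 <- g
  room <- 100 - (g2$msc + g2$ob + g2$ch + g2$fb)
  g2$ob <- g2$ob + 0.5 * room
  hpb <- ocdheal:::homogenize_grid(g2, tab)
  expect_true(all(hpb$E >= hp$E - 1e-9))
})

test_that("material updates land on the defect elements of the mesh", {
  mesh <- mesh_geometry(default_geom(), meniscus = FALSE)
  ms <- material_state(mesh)
  g <- small_grid("marrow_invasion")
  g$ob[3, 3] <- 100; g$msc[3, 3] <- 0
  ms2 <- update_defect_materials(ms, mesh, g)
  id <- mesh$defect_elems[3, 3]
  expect_equal(ms2$E[id], 6000)
  other <- mesh$defect_elems[10, 10]
  expect_equal(ms2$E[other], 0.2)
  # non-defect rows untouched
  outside <- which(mesh$region == "cancellous")[1]
  expect_equal(ms2$E[outside], ms$E[outside])
})
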