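# Poroelastic tissue property table and per-element material state.

#' Poroelastic tissue properties
#'
#' Returns the table of poroelastic constants used for the condyle tissues and
#' for the homogenized defect mixture: elastic modulus E (MPa), Poisson's
#' ratio, hydraulic conductivity k (mm/s), void ratio, and bulk modulus of the
#' solid grains (MPa). The granulation row is also the property of empty and
#' MSC-occupied space.
#'
#' @param bone_row which bone row newly formed (osteoblast-occupied) tissue
#'   takes; the defect sits in cancellous bone, so `"cancellous"` is the
#'   default.
#' @return data.frame with one row per tissue.
#' @export
tissue_property_table <- function(bone_row = c("cancellous", "subchondral")) {
  bone_row <- match.arg(bone_row)
  tab <- data.frame(
    tissue = c("cancellous", "subchondral", "granulation", "cartilage",
               "fibrous"),
    E  = c(6000, 17000, 0.2, 10, 2),
    nu = c(0.3, 0.3, 0.167, 0.167, 0.167),
    k  = c(3.63e-8, 9.74e-11, 9.74e-8, 4.87e-8, 9.74e-8),
    e  = c(4, 0.042, 4, 4, 4),
    Kg = c(13920, 13920, 2300, 3700, 2300),
    row.names = c("cancellous", "subchondral", "granulation", "cartilage",
                  "fibrous"))
  attr(tab, "bone_row") <- bone_row
  tab
}

#' Bone-row choice for osteoblast-occupied space
#'
#' The homogenization rule needs a bone property row for the space occupied by
#' osteoblasts; the configured row is returned (default cancellous bone, since
#' the defect lies within cancellous bone).
#'
#' @param table a [tissue_property_table()].
#' @return single-row data.frame of properties.
#' @export
bone_phenotype_property_choice <- function(table = tissue_property_table()) {
  row <- attr(table, "bone_row")
  if (is.null(row) || !row %in% rownames(table))
    stop("unknown bone property row: ", row)
  table[row, ]
}

# neo-Hookean constants for healthy articular cartilage
cartilage_hyper <- function() list(C10 = 2.14, D1 = 0.399)

# fixed scaffold material constants (E comes from the scaffold spec)
scaffold_material <- function() {
  list(k = 3.63e-8, e = 4, Kg = 0, nu = 0.3)
}

# transversely isotropic meniscus stiffness (4x4, strain order
# [err, ezz, ethh, grz]); circumferential direction is the stiff one.
meniscus_stiffness <- function() {
  Er <- 0.5; Ez <- 0.5; Eth <- 100
  nu_zr <- 0.5      # in the (r,z) plane
  G_zr <- 0.167
  nu_th <- 0.0015   # circumferential vs the other two directions
  S <- matrix(0, 4, 4)
  S[1, 1] <- 1 / Er; S[2, 2] <- 1 / Ez; S[3, 3] <- 1 / Eth
  S[1, 2] <- S[2, 1] <- -nu_zr / Ez
  S[1, 3] <- S[3, 1] <- -nu_th / Eth
  S[2, 3] <- S[3, 2] <- -nu_th / Eth
  S[4, 4] <- 1 / G_zr
  D <- solve(S)
  ev <- eigen(D[1:3, 1:3], symmetric = TRUE, only.values = TRUE)$values
  stopifnot(all(ev > 0))
  D
}

# pack the upper triangle of a symmetric 4x4 into 10 values (row-major)
pack_sym4 <- function(D) {
  out <- numeric(10); c <- 0L
  for (i in 1:4) for (j in i:4) { c <- c + 1L; out[c] <- D[i, j] }
  out
}

#' Initial material state for a mesh
#'
#' Builds the per-element material table: fixed Table-style properties for the
#' condyle tissues (hyperelastic healthy cartilage, transversely isotropic
#' poroelastic meniscus), and the day-1 defect properties from the cell grid
#' (granulation everywhere, scaffold struts blended by the porosity rule).
#'
#' @param mesh a [mesh_geometry()] mesh.
#' @param table a [tissue_property_table()].
#' @param grid a `cell_grid` ([initialize_grid()]); `NULL` for an all-
#'   granulation defect.
#' @param spec a [scaffold_spec()] (architecture `"none"` for no scaffold).
#' @return object of class `material_state`: data.frame with columns E, nu,
#'   k, e, Kg, C10, D1 and one row per element.
#' @export
material_state <- function(mesh, table = tissue_property_table(),
                           grid = NULL, spec = scaffold_spec("none")) {
  ne <- nrow(mesh$elems)
  ms <- data.frame(E = numeric(ne), nu = numeric(ne), k = numeric(ne),
                   e = numeric(ne), Kg = numeric(ne),
                   C10 = 0, D1 = 0)
  fill <- function(idx, row) {
    ms$E[idx] <<- row$E; ms$nu[idx] <<- row$nu; ms$k[idx] <<- row$k
    ms$e[idx] <<- row$e; ms$Kg[idx] <<- row$Kg
  }
  fill(mesh$region == "cancellous", table["cancellous", ])
  fill(mesh$region == "subchondral", table["subchondral", ])
  fill(mesh$region == "defect", table["granulation", ])
  hy <- cartilage_hyper()
  ic <- mesh$region == "cartilage"
  ms$E[ic] <- 10; ms$nu[ic] <- 0.167  # informative only; law is neo-Hookean
  ms$C10[ic] <- hy$C10; ms$D1[ic] <- hy$D1
  im <- mesh$region == "meniscus"
  if (any(im)) {
    ms$E[im] <- 0.5; ms$nu[im] <- 0.3
    ms$k[im] <- table["cartilage", "k"]; ms$e[im] <- table["cartilage", "e"]
    ms$Kg[im] <- table["cartilage", "Kg"]
  }
  attr(ms, "law") <- element_laws(mesh)
  class(ms) <- c("material_state", "data.frame")
  if (!is.null(grid)) ms <- update_defect_materials(ms, mesh, grid, table, spec)
  validate_material_state(ms)
  ms
}

element_laws <- function(mesh) {
  law <- integer(nrow(mesh$elems))          # 0 = poroelastic
  law[mesh$region == "cartilage"] <- 2L     # neo-Hookean
  law[mesh$region == "meniscus"] <- 3L      # transversely isotropic poroelastic
  law
}

validate_material_state <- function(ms) {
  law <- attr(ms, "law")
  lin <- law != 2L
  if (any(ms$E[lin] <= 0) || any(ms$nu[lin] <= -1) || any(ms$nu[lin] >= 0.5))
    stop("invalid elastic constants in material state")
  if (any(ms$k < 0) || any(ms$Kg < 0) || any(ms$e[law %in% c(0L, 3L)] <= 0))
    stop("invalid poroelastic constants in material state")
  invisible(ms)
}
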