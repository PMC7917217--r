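# Rule-of-mixtures update of defect element properties from cell composition.

#' Homogenized properties of one defect element
#'
#' Space-fraction-weighted arithmetic mean of the constituent tissue
#' properties: empty + MSC space counts as granulation, chondrocytes as
#' poroelastic cartilage, fibroblasts as fibrous tissue, osteoblasts as bone
#' (cancellous row by default, see [bone_phenotype_property_choice()]), and
#' the scaffold occupancy fraction as scaffold material. E, Poisson's ratio,
#' hydraulic conductivity, grain bulk modulus and void ratio are all averaged
#' the same way.
#'
#' @param cell list with counts `msc`, `ob`, `ch`, `fb`, scaffold fraction
#'   `fs`, scaffold modulus `E_scaffold` (required if `fs > 0`), and optional
#'   `n_max` (default 100).
#' @param table a [tissue_property_table()].
#' @param spec a [scaffold_spec()] supplying the scaffold material constants.
#' @return list with E, nu, k, e, Kg.
#' @export
update_element_properties <- function(cell, table = tissue_property_table(),
                                      spec = scaffold_spec("none")) {
  n_max <- if (is.null(cell$n_max)) 100 else cell$n_max
  fs <- if (is.null(cell$fs)) 0 else cell$fs
  occ <- cell$msc + cell$ob + cell$ch + cell$fb
  if (occ > n_max * (1 - fs) + 1e-9) stop("cell violates the capacity closure")
  bone <- bone_phenotype_property_choice(table)
  f_gran <- (n_max * (1 - fs) - cell$ob - cell$ch - cell$fb) / n_max
  f_b <- cell$ob / n_max; f_c <- cell$ch / n_max; f_f <- cell$fb / n_max
  sm <- spec$material
  Es <- if (fs > 0) cell$E_scaffold else 0
  mix <- function(prop, sprop) {
    f_gran * table["granulation", prop] + f_b * bone[[prop]] +
      f_c * table["cartilage", prop] + f_f * table["fibrous", prop] +
      fs * sprop
  }
  list(E = mix("E", Es), nu = mix("nu", sm$nu), k = mix("k", sm$k),
       e = mix("e", sm$e), Kg = mix("Kg", sm$Kg))
}

# Vectorized homogenization over the whole lattice; returns matrices.
homogenize_grid <- function(grid, table = tissue_property_table(),
                            spec = scaffold_spec("none"),
                            E_field = NULL) {
  check_closure(grid)
  nm <- grid$n_max
  bone <- bone_phenotype_property_choice(table)
  f_gran <- (nm * (1 - grid$fs) - grid$ob - grid$ch - grid$fb) / nm
  f_b <- grid$ob / nm; f_c <- grid$ch / nm; f_f <- grid$fb / nm
  sm <- spec$material
  Es <- matrix(0, nrow(grid$fs), ncol(grid$fs))
  if (!is.null(E_field)) Es[!is.na(E_field)] <- E_field[!is.na(E_field)]
  mix <- function(prop, sprop) {
    f_gran * table["granulation", prop] + f_b * bone[[prop]] +
      f_c * table["cartilage", prop] + f_f * table["fibrous", prop] +
      grid$fs * sprop
  }
  list(E = f_gran * table["granulation", "E"] + f_b * bone$E +
         f_c * table["cartilage", "E"] + f_f * table["fibrous", "E"] +
         grid$fs * Es,
       nu = mix("nu", sm$nu), k = mix("k", sm$k), e = mix("e", sm$e),
       Kg = mix("Kg", sm$Kg))
}

#' Update defect material properties from the cell grid
#'
#' Writes the homogenized per-lattice-cell properties into the defect rows of
#' a [material_state()].
#'
#' @param ms a `material_state`.
#' @param mesh the mesh the state belongs to.
#' @param grid current `cell_grid`.
#' @param table a [tissue_property_table()].
#' @param spec a [scaffold_spec()].
#' @param E_field per-cell scaffold modulus field (from [embed_scaffold()]).
#' @return the updated `material_state`.
#' @export
update_defect_materials <- function(ms, mesh, grid,
                                    table = tissue_property_table(),
                                    spec = scaffold_spec("none"),
                                    E_field = NULL) {
  if (is.null(E_field) && !is.null(grid$E_field)) E_field <- grid$E_field
  hp <- homogenize_grid(grid, table, spec, E_field)
  ide <- as.vector(mesh$defect_elems)
  ms$E[ide] <- as.vector(hp$E)
  ms$nu[ide] <- as.vector(hp$nu)
  ms$k[ide] <- as.vector(hp$k)
  ms$e[ide] <- as.vector(hp$e)
  ms$Kg[ide] <- as.vector(hp$Kg)
  ms
}
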