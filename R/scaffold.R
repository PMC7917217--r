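# Scaffold architectures: strut layout on the defect lattice, porous strut
# cell capacity, and standalone axial stiffness of the scaffold structure.

#' Scaffold specification
#'
#' Describes a scaffold implanted in the osteochondral defect. In the
#' axisymmetric representation the `vertical_rings` architecture is three
#' vertical struts (concentric rings in 3D); `grid` adds two horizontal
#' annular struts. Strut edges snap to the defect lattice (0.125 mm lines),
#' so struts are unions of whole lattice elements. The strut material porosity
#' P sets both the fraction of each strut element accessible to cells and the
#' day-1 blended properties.
#'
#' @param architecture `"none"`, `"vertical_rings"` or `"grid"`.
#' @param E_scaffold elastic modulus of the scaffold material (MPa); ignored
#'   if `biphasic`.
#' @param porosity strut material porosity P in percent.
#' @param ring_radii radial centre positions of the vertical struts (mm).
#' @param strut_width width of the vertical struts (mm).
#' @param horiz_heights centre heights of the horizontal struts above the
#'   defect base (mm), grid architecture only.
#' @param horiz_thickness thickness of the horizontal struts (mm).
#' @param biphasic logical; use a proximal/distal modulus split.
#' @param E_proximal,E_distal moduli of the proximal (bone-targeted) and
#'   distal (cartilage-targeted) zones (MPa).
#' @param transition_height height above the defect base of the sharp
#'   modulus transition (mm).
#' @return object of class `scaffold_spec`.
#' @export
scaffold_spec <- function(architecture = c("none", "vertical_rings", "grid"),
                          E_scaffold = 1000, porosity = 50,
                          ring_radii = c(1.5, 2.625, 3.875),
                          strut_width = 0.25,
                          horiz_heights = c(1.25, 3.75),
                          horiz_thickness = 0.25,
                          biphasic = FALSE, E_proximal = 1000, E_distal = 10,
                          transition_height = 2.5) {
  architecture <- match.arg(architecture)
  if (porosity < 0 || porosity > 100) stop("porosity must be in [0, 100]")
  if (E_scaffold < 0) stop("E_scaffold must be >= 0")
  spec <- list(architecture = architecture, E_scaffold = E_scaffold,
               porosity = porosity, ring_radii = ring_radii,
               strut_width = strut_width, horiz_heights = horiz_heights,
               horiz_thickness = horiz_thickness, biphasic = biphasic,
               E_proximal = E_proximal, E_distal = E_distal,
               transition_height = transition_height,
               material = scaffold_material())
  class(spec) <- "scaffold_spec"
  spec
}

# lattice masks of strut occupancy; rows = proximal layers, cols = radial.
# Checks that strut edges snap to lattice lines and lie inside the defect.
scaffold_masks <- function(spec, n = 40L, seed = 0.125, depth = n * seed) {
  vert <- matrix(FALSE, n, n)
  horiz <- matrix(FALSE, n, n)
  snap <- function(x, what) {
    if (any(abs(x / seed - round(x / seed)) > 1e-9))
      stop(what, " does not snap to the lattice (multiple of ", seed, " mm)")
    as.integer(round(x / seed))
  }
  if (spec$architecture %in% c("vertical_rings", "grid")) {
    for (rc in spec$ring_radii) {
      lo <- rc - spec$strut_width / 2
      hi <- rc + spec$strut_width / 2
      if (lo < 0 || hi > n * seed) stop("strut outside the defect")
      cols <- (snap(lo, "strut edge") + 1L):snap(hi, "strut edge")
      vert[, cols] <- TRUE
    }
  }
  if (spec$architecture == "grid") {
    for (zc in spec$horiz_heights) {
      lo <- zc - spec$horiz_thickness / 2
      hi <- zc + spec$horiz_thickness / 2
      if (lo < 0 || hi > depth) stop("horizontal strut outside the defect")
      rows <- (snap(lo, "strut edge") + 1L):snap(hi, "strut edge")
      horiz[rows, ] <- TRUE
    }
  }
  list(vert = vert, horiz = horiz, any = vert | horiz)
}

# per-strut-element scaffold modulus (NA off-strut); biphasic split by the
# element centre height above the defect base
scaffold_E_field <- function(spec, n = 40L, seed = 0.125) {
  masks <- scaffold_masks(spec, n, seed)
  Ef <- matrix(NA_real_, n, n)
  if (!any(masks$any)) return(Ef)
  if (spec$biphasic) {
    hc <- matrix((seq_len(n) - 0.5) * seed, n, n)  # row centre heights
    Ef[masks$any] <- ifelse(hc[masks$any] < spec$transition_height,
                            spec$E_proximal, spec$E_distal)
  } else {
    Ef[masks$any] <- spec$E_scaffold
  }
  Ef
}

#' Embed a scaffold into the defect lattice
#'
#' Computes the element-wise scaffold occupancy fraction
#' f_s = (100 - P)/100 on strut elements (0 elsewhere) and reports the total
#' strut cross-sectional (annular) area.
#'
#' @param mesh a [mesh_geometry()] mesh (only the lattice dimensions are used).
#' @param spec a [scaffold_spec()].
#' @return list with `fs` (occupancy matrix), `E_field` (per-element scaffold
#'   modulus), and `strut_area` (mm^2, vertical struts).
#' @export
embed_scaffold <- function(mesh, spec = scaffold_spec("none")) {
  n <- mesh$nlat
  masks <- scaffold_masks(spec, n, mesh$seed)
  fs <- matrix(0, mesh$nlat_z, n)
  fs[masks$any] <- (100 - spec$porosity) / 100
  area <- if (spec$architecture == "none") 0 else
    sum(2 * pi * spec$ring_radii * spec$strut_width)
  list(fs = fs, E_field = scaffold_E_field(spec, n, mesh$seed),
       strut_area = area, masks = masks)
}

#' Strut cell capacity
#'
#' Maximum number of cells that can populate a scaffold strut element, set by
#' the strut material porosity: N_max^strut = N_max * P / 100.
#'
#' @param spec a [scaffold_spec()] (or a porosity value in percent).
#' @param n_max lattice element capacity (cells/element).
#' @return cells per strut element.
#' @export
strut_capacity <- function(spec, n_max = 100) {
  P <- if (inherits(spec, "scaffold_spec")) spec$porosity else spec
  if (P < 0 || P > 100) stop("porosity must be in [0, 100]")
  n_max * P / 100
}

#' Axial stiffness of a scaffold architecture
#'
#' Overall force per unit axial displacement of the scaffold structure alone
#' (scaffold material only, no tissue, no porosity blending), compressed
#' between rigid frictionless platens.
#'
#' `method = "spring"` uses the series/parallel closed form: each vertical
#' ring contributes E*A/L with A = 2*pi*r*w; biphasic struts are two springs
#' in series; the horizontal struts of the grid architecture act as rigid
#' couplers (their own compliance is negligible at equal modulus).
#' `method = "fe"` compresses an axisymmetric elastic FE model of the strut
#' elements between platens and returns reaction force / displacement.
#'
#' @param spec a [scaffold_spec()].
#' @param method `"fe"` or `"spring"`.
#' @param seed lattice seed used for the FE discretization (mm).
#' @return stiffness in N/mm.
#' @export
axial_stiffness <- function(spec, method = c("fe", "spring"), seed = 0.125) {
  method <- match.arg(method)
  if (spec$architecture == "none") {
    warning("empty architecture has zero stiffness")
    return(0)
  }
  L <- 5
  A <- sum(2 * pi * spec$ring_radii * spec$strut_width)
  if (method == "spring") {
    seg_comp <- function(z0, z1) {   # compliance of a vertical segment [z0,z1]
      if (spec$biphasic) {
        t <- spec$transition_height
        lp <- max(0, min(z1, t) - min(z0, t))
        ld <- (z1 - z0) - lp
        lp / spec$E_proximal + ld / spec$E_distal
      } else (z1 - z0) / spec$E_scaffold
    }
    if (spec$architecture == "vertical_rings") {
      return(A / seg_comp(0, L))
    }
    # grid: horizontal struts rigidly couple the rings; drop their thickness
    # from the compliant length
    cuts <- sort(unique(c(0, L, unlist(lapply(spec$horiz_heights, function(z)
      c(z - spec$horiz_thickness / 2, z + spec$horiz_thickness / 2))))))
    comp <- 0
    for (i in seq_len(length(cuts) - 1)) {
      z0 <- cuts[i]; z1 <- cuts[i + 1]
      zc <- (z0 + z1) / 2
      in_plate <- any(abs(zc - spec$horiz_heights) < spec$horiz_thickness / 2)
      if (!in_plate) comp <- comp + seg_comp(z0, z1)
    }
    return(A / comp)
  }
  scaffold_stiffness_fe(spec, seed)
}
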