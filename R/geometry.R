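# Axisymmetric condyle geometry and structured Q8 meshing.
#
# Coordinates: (r, z) in mm, symmetry axis at r = 0, z increasing distally
# (z = 0 is the loaded proximal surface of the cancellous bone, z = height is
# the articular surface / tibial plateau plane). The osteochondral defect is
# an exact defect_radius x defect_depth rectangle abutting the axis at the
# articular surface. Lattice indices are 1-based: row = z-layer counted from
# the proximal defect base, col = radial position from the axis.

#' Condyle geometry configuration
#'
#' Parametrizes the axisymmetric femoral-condyle model. The printed anchors
#' are the defect size (5 mm radius and depth) and the load calibration
#' (0.637 MPa over the top surface corresponding to 800 N, which fixes the
#' top radius at 20 mm). The remaining extents (layer thicknesses, the
#' articular recess that shapes the contact patch and seats the meniscus) are
#' calibrated defaults, documented in the methods vignette.
#'
#' @param r_top radius of the loaded top surface (mm).
#' @param height total condyle height from loaded surface to articular
#'   surface (mm).
#' @param cartilage,subchondral thicknesses of the articular cartilage layer
#'   and the subchondral bone plate (mm).
#' @param defect_radius,defect_depth radius and depth of the osteochondral
#'   defect rectangle (mm).
#' @param recess_start radial position where the articular surface starts to
#'   recede from the tibial plateau plane (mm).
#' @param recess_drop total rise of the articular surface at the lateral rim
#'   (mm); the meniscus occupies this recess.
#' @param mouth_gap contact conformity gap over the defect mouth (mm): the
#'   soft granulation filling the fresh defect is not load-bearing against
#'   the plateau until the surface closes this gap.
#' @param meniscus_inner,meniscus_outer radial extent of the meniscus ring (mm).
#' @param pressure applied surface pressure (MPa).
#' @param seed_max maximum mesh seed away from the defect (mm).
#' @param grade_ratio geometric growth ratio of the mesh grading.
#' @param contact_seed mesh seed along the condyle-meniscus interface (mm).
#' @param meniscus_layers number of element layers through the meniscus.
#' @return a list of class `condyle_config`.
#' @export
condyle_config <- function(r_top = 20, height = 25,
                           cartilage = 4.25, subchondral = 0.5,
                           defect_radius = 5, defect_depth = 5,
                           recess_start = 12, recess_drop = 1,
                           mouth_gap = 0.1,
                           meniscus_inner = 17, meniscus_outer = 23,
                           pressure = 0.637,
                           seed_max = 0.8, grade_ratio = 1.3,
                           contact_seed = 0.5, meniscus_layers = 3) {
  cfg <- list(r_top = r_top, height = height, cartilage = cartilage,
              subchondral = subchondral, defect_radius = defect_radius,
              defect_depth = defect_depth, recess_start = recess_start,
              recess_drop = recess_drop, mouth_gap = mouth_gap,
              meniscus_inner = meniscus_inner,
              meniscus_outer = meniscus_outer, pressure = pressure,
              seed_max = seed_max, grade_ratio = grade_ratio,
              contact_seed = contact_seed, meniscus_layers = meniscus_layers)
  class(cfg) <- "condyle_config"
  cfg
}

# articular surface height z_b(r): flat at `height` up to recess_start, then a
# cosine recess rising (receding from the tibia) by recess_drop at r_top.
articular_surface <- function(cfg) {
  force(cfg)
  function(r) {
    z <- rep(cfg$height, length(r))
    i <- r > cfg$recess_start
    if (any(i)) {
      th <- pi * (r[i] - cfg$recess_start) / (cfg$r_top - cfg$recess_start)
      z[i] <- cfg$height - cfg$recess_drop * (1 - cos(th)) / 2
    }
    z
  }
}

#' Build the condyle geometry
#'
#' Validates the configuration and assembles the region decomposition
#' (cartilage, subchondral bone, cancellous bone, defect, meniscus) together
#' with the named boundary sets used by the mechanics module. Regions are
#' described in the unscaled (r, z-hat) plane; the articular recess is applied
#' as a per-column vertical scaling at meshing time.
#'
#' @param config a [condyle_config()].
#' @return an object of class `condyle_geometry`.
#' @export
build_condyle_geometry <- function(config = condyle_config()) {
  cfg <- config
  if (cfg$defect_depth <= 0 || cfg$defect_radius <= 0)
    stop("defect must have positive radius and depth")
  if (cfg$defect_radius >= cfg$recess_start)
    stop("defect must lie inside the flat articular region")
  if (cfg$cartilage + cfg$subchondral >= cfg$defect_depth)
    stop("defect must penetrate into cancellous bone")
  if (cfg$cartilage + cfg$subchondral >= cfg$height)
    stop("layer thicknesses exceed condyle height")
  if (cfg$meniscus_inner <= cfg$recess_start || cfg$meniscus_inner >= cfg$r_top)
    stop("meniscus inner radius must lie within the articular recess")

  H <- cfg$height
  rects <- list(
    defect      = c(0, H - cfg$defect_depth, cfg$defect_radius, H),
    cartilage   = c(0, H - cfg$cartilage, cfg$r_top, H),
    subchondral = c(0, H - cfg$cartilage - cfg$subchondral, cfg$r_top,
                    H - cfg$cartilage),
    cancellous  = c(0, 0, cfg$r_top, H - cfg$cartilage - cfg$subchondral))
  # region of a point = defect wins over layer rectangles
  load_force <- cfg$pressure * pi * cfg$r_top^2

  geom <- list(config = cfg, rects = rects, surface = articular_surface(cfg),
               load_force = load_force,
               boundary_sets = c("load_top", "axis", "condyle_bottom",
                                 "meniscus_top", "meniscus_bottom",
                                 "defect_mouth"))
  class(geom) <- "condyle_geometry"
  geom
}

#' @export
print.condyle_geometry <- function(x, ...) {
  cfg <- x$config
  cat("Axisymmetric condyle geometry\n")
  cat(sprintf("  top radius %.1f mm, height %.1f mm; defect %.3g x %.3g mm\n",
              cfg$r_top, cfg$height, cfg$defect_radius, cfg$defect_depth))
  cat(sprintf("  layers: cartilage %.2f mm, subchondral %.2f mm\n",
              cfg$cartilage, cfg$subchondral))
  cat(sprintf("  load: %.3f MPa over top surface = %.1f N\n",
              cfg$pressure, x$load_force))
  invisible(x)
}

# graded cell sizes spanning L, starting near h0*ratio and capped at hmax,
# scaled (down) to fit L exactly
grade_sizes <- function(L, h0, hmax, ratio) {
  stopifnot(L > 0)
  sizes <- c()
  h <- h0 * ratio
  while (sum(sizes) < L) {
    sizes <- c(sizes, min(h, hmax))
    h <- h * ratio
  }
  sizes * (L / sum(sizes))
}

stations_from_sizes <- function(a, sizes) a + c(0, cumsum(sizes))

# Structured Q8 block on tensor stations with a vertical mapping
# zmap(r, zhat) -> z. Returns nodes, elems (ne x 8), and index grids.
q8_block <- function(rs, zhs, zmap) {
  nr <- length(rs) - 1L
  nz <- length(zhs) - 1L
  rmid <- (rs[-1] + rs[-length(rs)]) / 2
  zhmid <- (zhs[-1] + zhs[-length(zhs)]) / 2

  idC <- matrix(seq_len((nr + 1L) * (nz + 1L)), nr + 1L, nz + 1L)
  off <- (nr + 1L) * (nz + 1L)
  idH <- matrix(off + seq_len(nr * (nz + 1L)), nr, nz + 1L)
  off <- off + nr * (nz + 1L)
  idV <- matrix(off + seq_len((nr + 1L) * nz), nr + 1L, nz)
  nn <- off + (nr + 1L) * nz

  nodes <- matrix(0, nn, 2)
  for (j in seq_len(nz + 1)) {
    nodes[idC[, j], 1] <- rs
    nodes[idC[, j], 2] <- zmap(rs, zhs[j])
    nodes[idH[, j], 1] <- rmid
    nodes[idH[, j], 2] <- zmap(rmid, zhs[j])
  }
  for (j in seq_len(nz)) {
    nodes[idV[, j], 1] <- rs
    nodes[idV[, j], 2] <- zmap(rs, zhmid[j])
  }

  elems <- matrix(0L, nr * nz, 8)
  k <- 0L
  for (j in seq_len(nz)) for (i in seq_len(nr)) {
    k <- k + 1L
    elems[k, ] <- c(idC[i, j], idC[i + 1, j], idC[i + 1, j + 1], idC[i, j + 1],
                    idH[i, j], idV[i + 1, j], idH[i, j + 1], idV[i, j])
  }
  list(nodes = nodes, elems = elems, nr = nr, nz = nz,
       idC = idC, idH = idH, idV = idV, rs = rs, zhs = zhs)
}

# ordered surface nodes (corner/mid alternating) along a horizontal block face
face_nodes_bottom <- function(blk, j) {
  n <- integer(0)
  for (i in seq_len(blk$nr)) n <- c(n, blk$idC[i, j], blk$idH[i, j])
  c(n, blk$idC[blk$nr + 1, j])
}

# edges (3-node) along a horizontal face, as a matrix with one row per element edge
face_edges <- function(blk, j) {
  t(vapply(seq_len(blk$nr), function(i)
    c(blk$idC[i, j], blk$idH[i, j], blk$idC[i + 1, j]), integer(3)))
}

#' Mesh the condyle geometry
#'
#' Builds the structured 8-node quadrilateral mesh: the defect is meshed as an
#' exact structured lattice with the given seed (40 x 40 elements at the
#' default 0.125 mm), grading geometrically away from it up to `seed_max`.
#' The meniscus is meshed as a separate conforming block seated in the
#' articular recess.
#'
#' @param geometry a [build_condyle_geometry()] result.
#' @param seed defect seed size in mm; must divide the defect extents exactly.
#' @param meniscus include the meniscus block (needed by the full backend).
#' @return an object of class `fem_mesh` with nodes, elements, element region
#'   labels, the defect element index matrix (`defect_elems`), and named
#'   boundary sets.
#' @export
mesh_geometry <- function(geometry, seed = 0.125, meniscus = TRUE) {
  cfg <- geometry$config
  nlat <- cfg$defect_radius / seed
  if (abs(nlat - round(nlat)) > 1e-9 ||
      abs(cfg$defect_depth / seed - round(cfg$defect_depth / seed)) > 1e-9)
    stop("seed must divide the defect radius and depth exactly")
  nlat <- as.integer(round(nlat))
  nlat_z <- as.integer(round(cfg$defect_depth / seed))
  H <- cfg$height
  zb <- geometry$surface

  # radial stations: uniform through the defect, graded beyond, with
  # breakpoints at the recess start, the meniscus inner radius and the rim.
  # The grading outside the defect starts from the production lattice seed
  # regardless of `seed`, so refining the defect leaves the surround fixed.
  h0 <- 0.125
  rs <- seq(0, cfg$defect_radius, by = seed)
  rs <- c(rs, stations_from_sizes(cfg$defect_radius,
            grade_sizes(cfg$recess_start - cfg$defect_radius, h0,
                        cfg$seed_max, cfg$grade_ratio))[-1])
  rs <- c(rs, stations_from_sizes(cfg$recess_start,
            grade_sizes(cfg$meniscus_inner - cfg$recess_start,
                        cfg$seed_max / cfg$grade_ratio, cfg$seed_max,
                        cfg$grade_ratio))[-1])
  n_c <- max(2L, ceiling((cfg$r_top - cfg$meniscus_inner) / cfg$contact_seed))
  rs <- c(rs, seq(cfg$meniscus_inner, cfg$r_top, length.out = n_c + 1)[-1])

  # vertical stations (unscaled): uniform through the defect band, graded below
  zdeep <- H - cfg$defect_depth
  sz <- rev(grade_sizes(zdeep, h0, cfg$seed_max, cfg$grade_ratio))
  zhs <- c(stations_from_sizes(0, sz), seq(zdeep + seed, H, by = seed))
  zhs[length(zhs)] <- H

  scale_fun <- function(r) zb(r) / H
  blk <- q8_block(rs, zhs, function(r, zh) zh * scale_fun(r))

  nr <- blk$nr; nz <- blk$nz
  rmid <- (rs[-1] + rs[-length(rs)]) / 2
  zhmid <- (zhs[-1] + zhs[-length(zhs)]) / 2
  cen_r <- matrix(rmid, nr, nz)
  cen_z <- matrix(zhmid, nr, nz, byrow = TRUE)
  region <- matrix("cancellous", nr, nz)
  region[cen_z > H - cfg$cartilage - cfg$subchondral] <- "subchondral"
  region[cen_z > H - cfg$cartilage] <- "cartilage"
  region[cen_r < cfg$defect_radius & cen_z > H - cfg$defect_depth] <- "defect"
  region <- as.vector(region)   # element order: i fastest, j outer

  # defect lattice -> element id map (row 1 = proximal base layer)
  jz0 <- which(abs(zhs - (H - cfg$defect_depth)) < 1e-9)
  ic <- seq_len(nlat)
  defect_elems <- matrix(0L, nlat_z, nlat)
  for (row in seq_len(nlat_z))
    defect_elems[row, ] <- (jz0 - 2L + row) * nr + ic
  stopifnot(all(region[defect_elems] == "defect"))

  nodes <- blk$nodes
  elems <- blk$elems
  sets <- list(
    load_top_edges = face_edges(blk, 1L),
    condyle_bottom = face_nodes_bottom(blk, nz + 1L),
    condyle_bottom_edges = face_edges(blk, nz + 1L),
    axis = which(nodes[, 1] < 1e-9),
    defect_mouth = blk$idC[which(rs <= cfg$defect_radius + 1e-9), nz + 1L])

  meniscus_pairs <- NULL
  if (meniscus) {
    im0 <- which(abs(rs - cfg$meniscus_inner) < 1e-9)
    rms <- c(rs[im0:length(rs)],
             seq(cfg$r_top, cfg$meniscus_outer, length.out = n_c + 1)[-1])
    ztop <- function(r) ifelse(r <= cfg$r_top, zb(r), zb(cfg$r_top))
    mlay <- cfg$meniscus_layers
    mb <- q8_block(rms, seq(0, 1, length.out = mlay + 1),
                   function(r, zh) ztop(r) + zh * (H - ztop(r)))
    offn <- nrow(nodes)
    mb$nodes_off <- mb$nodes
    elems <- rbind(elems, mb$elems + offn)
    nodes <- rbind(nodes, mb$nodes)
    region <- c(region, rep("meniscus", nrow(mb$elems)))
    # contact pairing: condyle bottom nodes over [meniscus_inner, r_top]
    # match meniscus top nodes at identical r
    cb <- sets$condyle_bottom
    cb_r <- blk$nodes[cb, 1]
    sl <- cb[cb_r >= cfg$meniscus_inner - 1e-9 & cb_r <= cfg$r_top + 1e-9]
    mt <- face_nodes_bottom(mb, 1L) + offn
    mt_r <- nodes[mt, 1]
    mi <- match(round(nodes[sl, 1], 9), round(mt_r, 9))
    stopifnot(!anyNA(mi))
    meniscus_pairs <- cbind(slave = sl, master = mt[mi])
    sets$meniscus_bottom <- face_nodes_bottom(mb, mlay + 1L) + offn
    sets$meniscus_bottom_edges <- face_edges(mb, mlay + 1L) + offn
    sets$meniscus_top_edges <- face_edges(mb, 1L) + offn
    sets$contact_pairs <- meniscus_pairs
  }

  mesh <- list(nodes = nodes, elems = elems, region = region,
               defect_elems = defect_elems, nlat = nlat, nlat_z = nlat_z,
               seed = seed, sets = sets, geometry = geometry,
               n_defect = length(defect_elems))
  class(mesh) <- "fem_mesh"
  mesh
}

#' @export
print.fem_mesh <- function(x, ...) {
  cat(sprintf("fem_mesh: %d nodes, %d elements (%d defect lattice cells %dx%d)\n",
              nrow(x$nodes), nrow(x$elems), x$n_defect, x$nlat_z, x$nlat))
  print(table(x$region))
  invisible(x)
}

#' Lattice source mask for marrow invasion
#'
#' Identifies the defect lattice cells that abut cancellous bone (the whole
#' proximal base layer, plus the lateral border up to the level where the
#' subchondral plate starts), i.e. the cells replenished daily by the
#' bone-marrow MSC supply.
#'
#' @param geometry a [build_condyle_geometry()] result (defaults used if missing).
#' @param seed lattice seed (mm).
#' @return logical matrix (rows = proximal-to-distal layers).
#' @export
lattice_source_mask <- function(geometry = build_condyle_geometry(),
                                seed = 0.125) {
  cfg <- geometry$config
  n <- as.integer(round(cfg$defect_radius / seed))
  nz <- as.integer(round(cfg$defect_depth / seed))
  m <- matrix(FALSE, nz, n)
  m[1, ] <- TRUE
  lateral_cancellous <- cfg$defect_depth - cfg$cartilage - cfg$subchondral
  rows <- seq_len(min(nz, as.integer(round(lateral_cancellous / seed))))
  m[rows, n] <- TRUE
  m
}

# lattice cell centre coordinates (r, and height above the defect base)
lattice_centres <- function(n = 40L, seed = 0.125) {
  r <- (seq_len(n) - 0.5) * seed
  list(r = r, depth = r)  # same spacing both directions
}
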