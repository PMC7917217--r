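# Lattice cell-population dynamics on the 40 x 40 defect grid: MSC source
# replenishment, MSC diffusion (bilinear FE), stimulus-dependent
# differentiation, mitosis/apoptosis, and osteoblast resorption.
#
# All counts are continuous (the rates are deterministic fractions); the whole
# day step is RNG-free.

#' Cell rate parameters
#'
#' Daily rates of the cellular activities and the tissue diffusion
#' coefficients (mm^2/day) used for MSC migration.
#'
#' @param msc_proliferation constant MSC proliferation rate per day.
#' @param mitosis favored-phenotype mitosis rate per day.
#' @param apoptosis disfavored-phenotype apoptosis rate per day.
#' @param differentiation MSC differentiation rate per day.
#' @param resorption osteoblast loss rate per day under the resorption fate.
#' @param D diffusion coefficients, mm^2/day (granulation, cartilage,
#'   fibrous, bone, scaffold).
#' @return list of class `rate_params`.
#' @export
rate_params <- function(msc_proliferation = 0.15, mitosis = 0.05,
                        apoptosis = 0.15, differentiation = 0.05,
                        resorption = 0.10,
                        D = c(granulation = 0.80, cartilage = 0.05,
                              fibrous = 0.10, bone = 0.01, scaffold = 0.01)) {
  r <- c(msc_proliferation, mitosis, apoptosis, differentiation, resorption)
  if (any(r < 0 | r > 1)) stop("rates must lie in [0, 1]")
  if (any(D <= 0)) stop("diffusion coefficients must be positive")
  out <- list(msc_proliferation = msc_proliferation, mitosis = mitosis,
              apoptosis = apoptosis, differentiation = differentiation,
              resorption = resorption, D = D)
  class(out) <- "rate_params"
  out
}

#' Initialize the defect cell grid
#'
#' `marrow_invasion`: the defect is empty except the elements neighboring
#' cancellous bone, which are filled to capacity with MSCs and replenished
#' daily (continuous marrow supply). `uniform`: every element starts filled
#' to capacity with MSCs.
#'
#' @param mode `"marrow_invasion"` or `"uniform"`.
#' @param fs scaffold occupancy fraction matrix from [embed_scaffold()]
#'   (zeros for no scaffold).
#' @param source logical source-element mask (see [lattice_source_mask()]);
#'   required for marrow invasion.
#' @param n_max element capacity, cells/element.
#' @return object of class `cell_grid`.
#' @export
initialize_grid <- function(mode = c("marrow_invasion", "uniform"),
                            fs = matrix(0, 40, 40),
                            source = lattice_source_mask(),
                            n_max = 100) {
  mode <- match.arg(mode)
  n <- nrow(fs)
  zero <- matrix(0, n, ncol(fs))
  cap <- n_max * (1 - fs)
  msc <- zero
  if (mode == "uniform") {
    msc <- cap
  } else {
    msc[source] <- cap[source]
  }
  g <- list(msc = msc, ob = zero, ch = zero, fb = zero, fs = fs,
            n_max = n_max, source = source, mode = mode)
  class(g) <- "cell_grid"
  g
}

#' @export
print.cell_grid <- function(x, ...) {
  comp <- quantify_tissues(x)
  cat(sprintf("cell_grid %dx%d (%s): gran %.1f%%, bone %.1f%%, cart %.1f%%, fibrous %.1f%%\n",
              nrow(x$msc), ncol(x$msc), x$mode,
              comp$granulation, comp$bone, comp$cartilage, comp$fibrous))
  invisible(x)
}

grid_capacity <- function(grid) grid$n_max * (1 - grid$fs)

grid_occupied <- function(grid) grid$msc + grid$ob + grid$ch + grid$fb

check_closure <- function(grid, tol = 1e-9) {
  cap <- grid_capacity(grid)
  occ <- grid_occupied(grid)
  if (any(occ < -tol) || any(occ > cap + tol * grid$n_max))
    stop("cell grid violates the capacity invariant")
  invisible(TRUE)
}

#' Effective MSC diffusivity of a grid
#'
#' Weighted average of the tissue diffusion coefficients by the space
#' fractions in each element; empty space and MSC-occupied space take the
#' granulation coefficient, the scaffold fraction takes the scaffold
#' coefficient.
#'
#' @param grid a `cell_grid`.
#' @param rates a [rate_params()].
#' @return matrix of diffusion coefficients (mm^2/day).
#' @export
effective_diffusivity <- function(grid, rates = rate_params()) {
  check_closure(grid)
  D <- rates$D
  nm <- grid$n_max
  gran <- (nm * (1 - grid$fs) - grid$ob - grid$ch - grid$fb) / nm
  (gran * D[["granulation"]] + grid$ob / nm * D[["bone"]] +
   grid$ch / nm * D[["cartilage"]] + grid$fb / nm * D[["fibrous"]] +
   grid$fs * D[["scaffold"]])
}

# Bilinear Q4 diffusion step on the defect rectangle (planar, element size h),
# zero-flux boundaries, backward Euler with nsub sub-steps and a lumped mass
# matrix (the system is then an M-matrix: positivity-preserving and free of
# the checkerboard oscillations a consistent mass matrix produces for sharp
# fronts). The per-element counts are scattered to nodes (lumped-mass
# projection), advanced, and the nodal increment is gathered back, which
# conserves total cell number exactly.
diffusion_step <- function(N, Dfield, h = 0.125, dt = 1, nsub = 10) {
  nz <- nrow(N); nr <- ncol(N)
  nnod <- (nz + 1) * (nr + 1)
  idx <- function(i, j) (j - 1L) * (nz + 1L) + i   # i = z index, j = r index
  # element connectivity (4 corners per cell)
  ii <- rep(seq_len(nz), nr); jj <- rep(seq_len(nr), each = nz)
  n1 <- idx(ii, jj); n2 <- idx(ii + 1, jj); n3 <- idx(ii + 1, jj + 1)
  n4 <- idx(ii, jj + 1)
  conn <- cbind(n1, n2, n3, n4)
  # reference matrices for a square bilinear element
  Kref <- matrix(c(4, -1, -2, -1,
                   -1, 4, -1, -2,
                   -2, -1, 4, -1,
                   -1, -2, -1, 4), 4, 4) / 6
  De <- as.vector(Dfield)   # column-major matches (ii, jj) ordering
  ivec <- as.vector(conn[, rep(1:4, each = 4)])
  jvec <- as.vector(conn[, rep(1:4, times = 4)])
  kx <- as.vector(outer(De, as.vector(t(Kref))))
  K <- Matrix::sparseMatrix(i = ivec, j = jvec, x = kx, dims = c(nnod, nnod))
  # lumped projection element counts -> nodal concentrations
  w <- h^2 / 4
  acc <- function(vals) {
    out <- numeric(nnod)
    for (k in 1:4) {
      a <- tapply(vals, conn[, k], sum)
      out[as.integer(names(a))] <- out[as.integer(names(a))] + a
    }
    out
  }
  b <- acc(as.vector(N) * w)
  mlump <- acc(rep(w, length(De)))
  c0 <- b / mlump
  dts <- dt / nsub
  M <- Matrix::Diagonal(x = mlump)
  A <- M + dts * K
  fac <- Matrix::lu(A)
  cc <- c0
  for (s in seq_len(nsub)) cc <- as.numeric(Matrix::solve(fac, mlump * cc))
  # adjoint gather: conserves total count exactly and keeps counts >= 0
  matrix((cc[n1] + cc[n2] + cc[n3] + cc[n4]) / 4, nz, nr)
}

#' Advance MSC migration by diffusion
#'
#' Solves the heterogeneous diffusion equation for the MSC concentration on
#' the defect rectangle (bilinear 4-node elements, zero-flux boundaries,
#' implicit time stepping) over `dt` days, then clips the updated counts to
#' each element's remaining capacity. Non-MSC counts are untouched.
#'
#' @param grid a `cell_grid`.
#' @param dt time step in days.
#' @param rates a [rate_params()].
#' @param nsub implicit sub-steps per day.
#' @param h lattice element size (mm).
#' @return the advanced `cell_grid`.
#' @export
diffuse_mscs <- function(grid, dt = 1, rates = rate_params(), nsub = 10,
                         h = 0.125) {
  Df <- effective_diffusivity(grid, rates)
  if (all(Df == 0)) return(grid)
  msc <- diffusion_step(grid$msc, Df, h = h, dt = dt, nsub = nsub)
  room <- grid_capacity(grid) - (grid$ob + grid$ch + grid$fb)
  grid$msc <- pmin(pmax(msc, 0), room)
  grid
}

#' Replenish the marrow source elements
#'
#' Raises the MSC count of every source element to full remaining capacity
#' (given its current differentiated occupants); never lowers any count.
#'
#' @param grid a `cell_grid` (marrow-invasion mode).
#' @return the replenished grid.
#' @export
replenish_source <- function(grid) {
  room <- grid_capacity(grid) - (grid$ob + grid$ch + grid$fb)
  grid$msc[grid$source] <- pmax(grid$msc[grid$source], room[grid$source])
  grid
}

#' Stimulus-dependent MSC differentiation
#'
#' In elements whose fate is bone, cartilage or fibrous tissue, 5% of the
#' MSCs differentiate into the matching phenotype. The resorption fate causes
#' no differentiation.
#'
#' @param grid a `cell_grid`.
#' @param fates character fate matrix from [classify_stimulus()].
#' @param rates a [rate_params()].
#' @return the updated grid.
#' @export
differentiate <- function(grid, fates, rates = rate_params()) {
  d <- rates$differentiation
  for (ph in c("bone", "cartilage", "fibrous")) {
    sel <- fates == ph
    dn <- d * grid$msc[sel]
    grid$msc[sel] <- grid$msc[sel] - dn
    slot <- switch(ph, bone = "ob", cartilage = "ch", fibrous = "fb")
    grid[[slot]][sel] <- grid[[slot]][sel] + dn
  }
  grid
}

#' Mitosis, apoptosis and resorption
#'
#' The favored phenotype (matching the element fate) performs mitosis (+5%);
#' the other differentiated phenotypes apoptose (-15%). MSCs proliferate at a
#' constant 15% regardless of fate, clipped to the remaining capacity. Under
#' the resorption fate, osteoblasts lose 10% and no phenotype is favored.
#'
#' @inheritParams differentiate
#' @return the updated grid.
#' @export
proliferate_and_apoptose <- function(grid, fates, rates = rate_params()) {
  up <- 1 + rates$mitosis
  down <- 1 - rates$apoptosis
  mult <- function(ph_fate) {
    m <- matrix(down, nrow(fates), ncol(fates))
    m[fates == ph_fate] <- up
    m[fates == "resorption"] <- 1
    m
  }
  mob <- mult("bone")
  mob[fates == "resorption"] <- 1 - rates$resorption
  grid$ob <- grid$ob * mob
  grid$ch <- grid$ch * mult("cartilage")
  grid$fb <- grid$fb * mult("fibrous")
  # mitosis in a (nearly) full element is capacity-limited: the favored
  # phenotype keeps only what fits
  cap <- grid_capacity(grid)
  over <- pmax(grid$ob + grid$ch + grid$fb - cap, 0)
  if (any(over > 0)) {
    for (ph in c("bone", "cartilage", "fibrous")) {
      slot <- switch(ph, bone = "ob", cartilage = "ch", fibrous = "fb")
      sel <- fates == ph & over > 0
      grid[[slot]][sel] <- grid[[slot]][sel] - over[sel]
    }
  }
  room <- cap - (grid$ob + grid$ch + grid$fb)
  grid$msc <- pmin(grid$msc * (1 + rates$msc_proliferation), pmax(room, 0))
  grid
}

#' Advance the cell grid by one day
#'
#' Applies, in order: MSC diffusion, differentiation, mitosis/apoptosis,
#' and source replenishment. The intra-day ordering is configurable.
#'
#' @param grid a `cell_grid`.
#' @param fates fate matrix for the current day's mechanical state.
#' @param rates a [rate_params()].
#' @param order character vector naming the sub-steps in execution order.
#' @param h lattice element size (mm).
#' @return the day-advanced grid.
#' @export
step_day <- function(grid, fates,
                     rates = rate_params(),
                     order = c("diffuse", "differentiate", "proliferate",
                               "replenish"),
                     h = 0.125) {
  for (op in order) {
    grid <- switch(op,
      diffuse = diffuse_mscs(grid, dt = 1, rates = rates, h = h),
      differentiate = differentiate(grid, fates, rates),
      proliferate = proliferate_and_apoptose(grid, fates, rates),
      replenish = if (grid$mode == "marrow_invasion")
        replenish_source(grid) else grid,
      stop("unknown day sub-step: ", op))
  }
  check_closure(grid)
  grid
}
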