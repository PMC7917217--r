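# Axisymmetric poroelastic mechanics: model building, load/contact handling,
# and the staged transient solve (soil loading step + consolidation step).
#
# The discrete system couples 8-node displacement elements with bilinear
# corner pore pressures (backward Euler in time). The Newton loop keeps a
# lazily refreshed sparse LU factorization (Matrix::lu); contact against the
# rigid tibial plateau and the conforming condyle-meniscus interface is a
# frictionless normal penalty applied nodally with consistent tributary areas.

#' Octahedral shear strain
#'
#' gamma_oct = 2/3 sqrt((e1-e2)^2 + (e2-e3)^2 + (e3-e1)^2) over principal
#' strains, reported in percent. Input is a symmetric small-strain tensor in
#' axisymmetric storage `c(err, ezz, ethh, grz)` (engineering shear), or a
#' full symmetric 3x3 matrix.
#'
#' @param strain strain tensor (length-4 vector or 3x3 symmetric matrix).
#' @return octahedral shear strain in percent.
#' @export
octahedral_shear_strain <- function(strain) {
  if (is.matrix(strain)) {
    if (!isTRUE(all.equal(strain, t(strain), tolerance = 1e-8)))
      stop("strain tensor must be symmetric")
    ev <- eigen(strain, symmetric = TRUE, only.values = TRUE)$values
  } else {
    stopifnot(length(strain) == 4)
    cc <- (strain[1] + strain[2]) / 2
    rr <- sqrt(((strain[1] - strain[2]) / 2)^2 + (strain[4] / 2)^2)
    ev <- c(cc + rr, cc - rr, strain[3])
  }
  100 * (2 / 3) * sqrt((ev[1] - ev[2])^2 + (ev[2] - ev[3])^2 +
                         (ev[3] - ev[1])^2)
}

#' Fluid speed from a seepage velocity vector
#'
#' Euclidean norm of the (r, z) seepage velocity, mm/s.
#' @param v length-2 numeric vector.
#' @return non-negative scalar.
#' @export
fluid_speed <- function(v) {
  stopifnot(length(v) == 2)
  sqrt(sum(v^2))
}

#' Mechanics control parameters
#'
#' @param backend `"full"` (condyle + meniscus + rigid tibial plateau with
#'   frictionless penalty contact), `"reduced"` (condyle only, vertical
#'   rollers under the flat contact footprint) or `"surrogate"`.
#' @param penalty contact penalty stiffness (MPa/mm of penetration).
#' @param t_ramp,t_consol durations of the soil loading and consolidation
#'   steps (s).
#' @param n_ramp,n_consol implicit sub-increments per step.
#' @param sampling instant at which gamma and v are sampled: element-wise
#'   `"max"` over the consolidation increments (default), `"end_load"`, or
#'   `"end_consol"`.
#' @param tol_u,tol_p Newton increment tolerances (mm, MPa).
#' @param max_it Newton iteration cap per sub-increment.
#' @param refresh Jacobian refresh interval (iterations).
#' @param dx_max Newton step limiter: displacement updates are scaled so no
#'   DOF moves more than this per iteration (mm); guards the contact search
#'   and the hyperelastic elements against overshoot.
#' @param footprint_radius reduced backend: radial extent of the vertical
#'   roller supports under the articular surface (`NULL`: up to the meniscus
#'   inner radius).
#' @return list of class `mech_control`.
#' @export
mech_control <- function(backend = c("full", "reduced", "surrogate"),
                         penalty = 1e5,
                         t_ramp = 1, t_consol = 0.5,
                         n_ramp = 4, n_consol = 10,
                         sampling = c("max", "end_load", "end_consol"),
                         tol_u = 1e-7, tol_p = 1e-7,
                         max_it = 60, refresh = 4, dx_max = 0.5,
                         footprint_radius = NULL) {
  out <- list(backend = match.arg(backend), penalty = penalty,
              t_ramp = t_ramp, t_consol = t_consol,
              n_ramp = n_ramp, n_consol = n_consol,
              sampling = match.arg(sampling),
              tol_u = tol_u, tol_p = tol_p, max_it = max_it,
              refresh = refresh, dx_max = dx_max,
              footprint_radius = footprint_radius)
  class(out) <- "mech_control"
  out
}

#' Load case
#'
#' Surface pressure on the proximal cancellous-bone surface, with the step
#' durations of the staged analysis. The product pressure x loaded area is
#' the applied joint force.
#'
#' @param pressure surface pressure (MPa).
#' @param t_ramp,t_consol step durations (s).
#' @return list of class `load_case`.
#' @export
load_case <- function(pressure = 0.637, t_ramp = 1, t_consol = 0.5) {
  structure(list(pressure = pressure, t_ramp = t_ramp, t_consol = t_consol),
            class = "load_case")
}

# per-node integration weights \int N_a 2 pi r ds over a set of 3-node edges
edge_node_weights <- function(nodes, edges, nn = nrow(nodes)) {
  w <- numeric(nn)
  gp <- c(-sqrt(3 / 5), 0, sqrt(3 / 5))
  gw <- c(5 / 9, 8 / 9, 5 / 9)
  for (k in seq_len(nrow(edges))) {
    id <- edges[k, ]
    x <- nodes[id, 1]; y <- nodes[id, 2]
    for (g in seq_along(gp)) {
      xi <- gp[g]
      N <- c(0.5 * xi * (xi - 1), 1 - xi^2, 0.5 * xi * (xi + 1))
      dN <- c(xi - 0.5, -2 * xi, xi + 0.5)
      tr <- sum(dN * x); tz <- sum(dN * y)
      ds <- sqrt(tr^2 + tz^2)
      r <- sum(N * x)
      w[id] <- w[id] + gw[g] * N * 2 * pi * r * ds
    }
  }
  w
}

#' Build the mechanical model for a meshed condyle
#'
#' Precomputes everything the daily solve needs: consistent load vector,
#' constrained DOFs, pore-pressure DOF numbering, contact sets and the
#' meniscus stiffness. The returned model is reused across iterations with
#' changing defect materials.
#'
#' @param mesh a [mesh_geometry()] mesh.
#' @param load a [load_case()].
#' @param control a [mech_control()].
#' @return object of class `mech_model`.
#' @export
build_mech_model <- function(mesh, load = load_case(),
                             control = mech_control()) {
  cfg <- mesh$geometry$config
  nn <- nrow(mesh$nodes)
  law <- element_laws(mesh)
  poro <- law %in% c(0L, 3L)
  pnodes <- sort(unique(as.vector(mesh$elems[poro, 1:4])))
  pidx <- rep(-1L, nn)
  pidx[pnodes] <- seq_along(pnodes) - 1L
  np <- length(pnodes)

  matD <- matrix(0, nrow(mesh$elems), 10)
  if (any(law == 3L))
    matD[law == 3L, ] <- matrix(pack_sym4(meniscus_stiffness()),
                                sum(law == 3L), 10, byrow = TRUE)

  # consistent load on the proximal surface, acting in +z (toward the tibia)
  wtop <- edge_node_weights(mesh$nodes, mesh$sets$load_top_edges, nn)
  F_load <- numeric(2 * nn + np)
  F_load[2 * seq_len(nn)] <- load$pressure * wtop

  fixed <- 2 * mesh$sets$axis - 1   # u_r = 0 on the symmetry axis
  contact <- NULL
  if (control$backend == "full") {
    if (is.null(mesh$sets$meniscus_bottom))
      stop("full backend requires a mesh with the meniscus block")
    H <- cfg$height
    wbot <- edge_node_weights(mesh$nodes, mesh$sets$condyle_bottom_edges, nn)
    wmen <- edge_node_weights(mesh$nodes, mesh$sets$meniscus_bottom_edges, nn)
    cb <- mesh$sets$condyle_bottom
    rigid_nodes <- c(cb[mesh$nodes[cb, 1] < cfg$meniscus_inner - 1e-9],
                     mesh$sets$meniscus_bottom)
    gap0 <- H - mesh$nodes[rigid_nodes, 2]
    # the fresh granulation surface does not conform to the plateau
    gap0[mesh$nodes[rigid_nodes, 1] <= cfg$defect_radius + 1e-9] <-
      gap0[mesh$nodes[rigid_nodes, 1] <= cfg$defect_radius + 1e-9] +
      cfg$mouth_gap
    rigid <- list(nodes = rigid_nodes, gap0 = gap0,
                  area = (wbot + wmen)[rigid_nodes])
    pairs <- NULL
    if (!is.null(mesh$sets$contact_pairs)) {
      pr <- mesh$sets$contact_pairs
      wint <- edge_node_weights(mesh$nodes, mesh$sets$meniscus_top_edges, nn)
      rr <- mesh$nodes[pr[, 1], 1]
      eps <- 1e-5
      zb <- mesh$geometry$surface
      slope <- (zb(rr + eps) - zb(pmax(rr - eps, 0))) /
        (rr + eps - pmax(rr - eps, 0))
      nrm <- cbind(-slope, 1) / sqrt(1 + slope^2)
      pairs <- list(slave = pr[, 1], master = pr[, 2], normal = nrm,
                    area = wint[pr[, 2]])
    }
    contact <- list(rigid = rigid, pairs = pairs, kappa = control$penalty,
                    plane = H)
  } else if (control$backend == "reduced") {
    cb <- mesh$sets$condyle_bottom
    rf <- if (is.null(control$footprint_radius)) cfg$meniscus_inner else
      control$footprint_radius
    rr <- mesh$nodes[cb, 1]
    keep <- rr <= rf + 1e-9
    if (cfg$mouth_gap > 0) keep <- keep & rr > cfg$defect_radius + 1e-9
    fixed <- c(fixed, 2 * cb[keep])
  } else stop("surrogate backend has no FE model; use surrogate_field()")

  pdir <- pidx[mesh$sets$defect_mouth]
  pdir <- pdir[pdir >= 0] + 2L * nn + 1L   # global dof ids, 1-based

  model <- list(mesh = mesh, law = law, pidx = pidx, np = np,
                F_load = F_load, fixed = sort(unique(fixed)),
                contact = contact, pdir_dofs = pdir, matD = matD,
                load = load, control = control)
  class(model) <- "mech_model"
  model
}

# penalty contact residual force and Jacobian triplets at displacement u
contact_eval <- function(contact, u, nn) {
  f <- numeric(length(u))
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  if (is.null(contact)) return(list(f = f, ti = ti, tj = tj, tx = tx, n_active = 0L))
  kap <- contact$kappa
  nact <- 0L
  rg <- contact$rigid
  if (!is.null(rg)) {
    dz <- 2 * rg$nodes
    pen <- u[dz] - rg$gap0
    act <- pen > -1e-12
    nact <- nact + sum(act)
    if (any(act)) {
      f[dz[act]] <- f[dz[act]] - kap * rg$area[act] * pen[act]
      ti <- c(ti, dz[act]); tj <- c(tj, dz[act])
      tx <- c(tx, kap * rg$area[act])
    }
  }
  pr <- contact$pairs
  if (!is.null(pr)) {
    sdr <- 2 * pr$slave - 1; sdz <- 2 * pr$slave
    mdr <- 2 * pr$master - 1; mdz <- 2 * pr$master
    pen <- (u[sdr] - u[mdr]) * pr$normal[, 1] +
           (u[sdz] - u[mdz]) * pr$normal[, 2]
    act <- pen > -1e-12
    nact <- nact + sum(act)
    if (any(act)) {
      ka <- kap * pr$area[act]
      nr1 <- pr$normal[act, 1]; nz1 <- pr$normal[act, 2]
      fmag <- ka * pen[act]
      f[sdr[act]] <- f[sdr[act]] - fmag * nr1
      f[sdz[act]] <- f[sdz[act]] - fmag * nz1
      f[mdr[act]] <- f[mdr[act]] + fmag * nr1
      f[mdz[act]] <- f[mdz[act]] + fmag * nz1
      dofs <- list(sdr[act], sdz[act], mdr[act], mdz[act])
      comp <- list(nr1, nz1, -nr1, -nz1)
      for (a in 1:4) for (b in 1:4) {
        ti <- c(ti, dofs[[a]]); tj <- c(tj, dofs[[b]])
        tx <- c(tx, ka * comp[[a]] * comp[[b]])
      }
    }
  }
  list(f = f, ti = ti, tj = tj, tx = tx, n_active = nact)
}

# Low-level staged transient solve. `sys` bundles the arrays; `schedule` is a
# data.frame with columns dt, factor (load multiplier), drained (logical),
# record (logical). Returns final state, recorded element fields and
# diagnostics. `warm` supplies initial guesses per sub-increment.
fem_run <- function(sys, schedule, control, warm = NULL,
                    record_p_nodes = NULL) {
  nn <- nrow(sys$nodes)
  ndof <- 2 * nn + sys$np
  u <- numeric(ndof)
  if (!is.null(sys$fixed_vals)) u[sys$fixed] <- sys$fixed_vals
  un <- u
  fields <- list(); phist <- list()
  warm_out <- vector("list", nrow(schedule))
  fac <- NULL; fac_key <- ""; fac_act <- NULL
  total_it <- 0L
  matp <- sys$matp

  asm <- function(u, un, dt, want_jac) {
    fem_assemble_cpp(sys$nodes, sys$elems, sys$law, matp, sys$matD,
                     u[seq_len(2 * nn)], u[-seq_len(2 * nn)], sys$pidx,
                     un[seq_len(2 * nn)], un[-seq_len(2 * nn)], dt, want_jac)
  }

  residual <- function(u, un, dt, targetF) {
    a <- asm(u, un, dt, FALSE)
    ce <- contact_eval(sys$contact, u, nn)
    R <- a$res - targetF - ce$f
    if (sys$np > 0) R[(2 * nn + 1):ndof] <- -R[(2 * nn + 1):ndof]
    list(R = R, ce = ce)
  }

  # one sub-increment with modified Newton (lazy symmetric quasi-definite
  # LDL' refactorization) and a backtracking line search
  newton_substep <- function(u, un, dt, fct, drained) {
    fixed <- sys$fixed
    if (drained && length(sys$pdir_dofs)) fixed <- c(fixed, sys$pdir_dofs)
    free <- setdiff(seq_len(ndof), fixed)
    key <- paste0(dt, "_", drained)
    if (drained) u[sys$pdir_dofs] <- 0
    targetF <- fct * sys$F_load
    it <- 0L
    need_jac <- (fac_key != key)
    rr <- residual(u, un, dt, targetF)
    repeat {
      it <- it + 1L; total_it <<- total_it + 1L
      if (!need_jac && !identical(rr$ce$ti, fac_act)) need_jac <- TRUE
      if (need_jac) {
        a <- asm(u, un, dt, TRUE)
        tx <- a$tx
        if (sys$np > 0) {
          flip <- a$ti >= 2L * nn
          tx[flip] <- -tx[flip]
        }
        ti <- a$ti + 1L; tj <- a$tj + 1L
        ce <- rr$ce
        if (length(ce$ti)) { ti <- c(ti, ce$ti); tj <- c(tj, ce$tj); tx <- c(tx, ce$tx) }
        J <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(ndof, ndof))
        Jf <- Matrix::forceSymmetric(J[free, free, drop = FALSE])
        fac <<- Matrix::Cholesky(Jf, LDL = TRUE, super = FALSE, perm = TRUE)
        fac_key <<- key
        fac_act <<- rr$ce$ti
        need_jac <- FALSE
      }
      dx <- as.numeric(Matrix::solve(fac, -rr$R[free]))
      if (any(!is.finite(dx))) return(list(ok = FALSE, u = u))
      dmax <- max(abs(dx[free <= 2 * nn]), 0)
      if (dmax > control$dx_max) dx <- dx * (control$dx_max / dmax)
      # backtracking on the residual norm
      n0 <- sqrt(sum(rr$R[free]^2))
      sc <- 1
      repeat {
        ut <- u; ut[free] <- u[free] + sc * dx
        rt <- residual(ut, un, dt, targetF)
        if (sqrt(sum(rt$R[free]^2)) <= n0 * (1 + 1e-8) || sc <= 1 / 16) break
        sc <- sc / 2
      }
      u <- ut; rr <- rt
      dxu <- sc * max(abs(dx[free <= 2 * nn]), 0)
      dxp <- if (any(free > 2 * nn)) sc * max(abs(dx[free > 2 * nn])) else 0
      if (dxu < control$tol_u && dxp < control$tol_p)
        return(list(ok = TRUE, u = u, its = it))
      if (it >= control$max_it) return(list(ok = FALSE, u = u))
      if (sc < 1 || it %% control$refresh == 0) need_jac <- TRUE
    }
  }

  for (s in seq_len(nrow(schedule))) {
    dt <- schedule$dt[s]; fct <- schedule$factor[s]
    drained <- schedule$drained[s]
    f_prev <- if (s > 1) schedule$factor[s - 1] else 0
    guess <- if (!is.null(warm) && length(warm) >= s) warm[[s]] else NULL
    if (!is.null(guess)) {
      fixed <- sys$fixed
      free <- setdiff(seq_len(ndof), fixed)
      u[free] <- guess[free]
    }
    res <- newton_substep(u, un, dt, fct, drained)
    if (!res$ok) {
      # bisect the sub-increment (up to 4 levels)
      u_save <- un
      stack <- list(list(dt = dt, f0 = f_prev, f1 = fct, depth = 0L))
      u <- un
      while (length(stack)) {
        sp <- stack[[1]]; stack <- stack[-1]
        fm <- (sp$f0 + sp$f1) / 2
        res2 <- newton_substep(u, un, sp$dt / 2, fm, drained)
        res3 <- if (res2$ok) {
          u <- res2$u; un <- u
          newton_substep(u, un, sp$dt / 2, sp$f1, drained)
        } else NULL
        if (!res2$ok || !res3$ok) {
          if (sp$depth >= 4L)
            stop(sprintf("mechanics solve did not converge (substep %d)", s))
          if (!res2$ok) {
            u <- un
            stack <- c(list(list(dt = sp$dt / 2, f0 = sp$f0, f1 = fm,
                                 depth = sp$depth + 1L),
                            list(dt = sp$dt / 2, f0 = fm, f1 = sp$f1,
                                 depth = sp$depth + 1L)), stack)
          } else {
            stack <- c(list(list(dt = sp$dt / 2, f0 = fm, f1 = sp$f1,
                                 depth = sp$depth + 1L)), stack)
          }
        } else {
          u <- res3$u; un <- u
        }
      }
      res <- list(ok = TRUE, u = u)
    }
    u <- res$u
    un <- u
    warm_out[[s]] <- u
    if (schedule$record[s]) {
      fields[[length(fields) + 1L]] <-
        fem_fields_cpp(sys$nodes, sys$elems, sys$law, matp,
                       u[seq_len(2 * nn)], u[-seq_len(2 * nn)], sys$pidx)
      if (!is.null(record_p_nodes))
        phist[[length(phist) + 1L]] <-
          u[2 * nn + sys$pidx[record_p_nodes] + 1L]
    }
  }
  list(u = u[seq_len(2 * nn)], p = u[-seq_len(2 * nn)], fields = fields,
       phist = phist, warm = warm_out, iterations = total_it)
}

sys_from_model <- function(model, ms) {
  mesh <- model$mesh
  list(nodes = mesh$nodes, elems = mesh$elems, law = attr(ms, "law"),
       matp = as.matrix(ms[, c("E", "nu", "k", "e", "Kg", "C10", "D1")]),
       matD = model$matD,
       pidx = model$pidx, np = model$np, F_load = model$F_load,
       fixed = model$fixed, fixed_vals = NULL, contact = model$contact,
       pdir_dofs = model$pdir_dofs)
}

standard_schedule <- function(control) {
  rbind(
    data.frame(dt = control$t_ramp / control$n_ramp,
               factor = seq_len(control$n_ramp) / control$n_ramp,
               drained = FALSE,
               record = FALSE),
    data.frame(dt = control$t_consol / control$n_consol, factor = 1,
               drained = TRUE, record = TRUE))
}

#' Solve one day's mechanical state
#'
#' Runs the staged transient analysis (1 s soil loading step in `n_ramp`
#' sub-increments, then 0.5 s consolidation in `n_consol` sub-increments with
#' zero pore pressure on the defect mouth) and returns the defect lattice
#' fields: octahedral shear strain gamma (percent) and seepage fluid speed v
#' (mm/s), sampled per element according to `control$sampling` (element-wise
#' maximum over the consolidation increments by default).
#'
#' @param model a [build_mech_model()] model.
#' @param materials a [material_state()] for the current day.
#' @param warm optional warm-start state from the previous day's solve.
#' @return object of class `mechano_state`: matrices `gamma`, `v`, plus
#'   solver diagnostics and the warm-start payload.
#' @export
solve_step <- function(model, materials, warm = NULL) {
  control <- model$control
  if (control$backend == "surrogate")
    stop("surrogate backend: use surrogate_field()")
  validate_material_state(materials)
  sys <- sys_from_model(model, materials)
  sch <- standard_schedule(control)
  if (control$sampling == "end_load") {
    sch$record <- FALSE
    sch$record[control$n_ramp] <- TRUE
  } else if (control$sampling == "end_consol") {
    sch$record <- FALSE
    sch$record[nrow(sch)] <- TRUE
  }
  out <- fem_run(sys, sch, control, warm)
  ide <- as.vector(model$mesh$defect_elems)
  nlz <- model$mesh$nlat_z; nl <- model$mesh$nlat
  gmax <- matrix(0, nlz, nl); vmax <- matrix(0, nlz, nl)
  poros <- materials$e[ide] / (1 + materials$e[ide])
  for (fl in out$fields) {
    g <- matrix(fl[ide, 5], nlz, nl)
    v <- matrix(fl[ide, 8] / poros, nlz, nl)
    gmax <- pmax(gmax, g); vmax <- pmax(vmax, v)
  }
  st <- list(gamma = gmax, v = vmax,
             diagnostics = list(iterations = out$iterations,
                                n_recorded = length(out$fields)),
             u = out$u, p = out$p, warm = out$warm)
  class(st) <- "mechano_state"
  st
}

#' Analytic surrogate mechanical fields
#'
#' Produces a `mechano_state` on the defect lattice from analytic
#' expressions or constants, without any FE solve; used to exercise the
#' downstream mechanoregulation and cell modules in isolation.
#'
#' @param gamma constant (percent) or `function(r, depth)` evaluated at the
#'   lattice cell centres (`depth` = height above the defect base, mm).
#' @param v constant (mm/s) or `function(r, depth)`.
#' @param n lattice size.
#' @param seed lattice element size (mm).
#' @return a `mechano_state` with `gamma` and `v` matrices.
#' @export
surrogate_field <- function(gamma = 0, v = 0, n = 40L, seed = 0.125) {
  cen <- lattice_centres(n, seed)
  evalf <- function(x) {
    if (is.function(x)) {
      m <- outer(cen$depth, cen$r, function(d, r) x(r, d))
    } else m <- matrix(x, n, n)
    if (any(m < 0)) stop("surrogate field values must be non-negative")
    m
  }
  st <- list(gamma = evalf(gamma), v = evalf(v),
             diagnostics = list(backend = "surrogate"))
  class(st) <- "mechano_state"
  st
}

# ---- verification / standalone meshes -------------------------------------

# structured Q8 rectangle [r0,r1] x [z0,z1]; law/materials uniform
rect_sys <- function(r0, r1, z0, z1, nx, nz, mat_row, law = 0L,
                     pressure = 0, confined = FALSE, drain_top = FALSE) {
  blk <- q8_block(seq(r0, r1, length.out = nx + 1),
                  seq(z0, z1, length.out = nz + 1), function(r, zh) zh)
  ne <- nrow(blk$elems)
  nn <- nrow(blk$nodes)
  lawv <- rep(law, ne)
  matp <- matrix(rep(c(mat_row$E, mat_row$nu, mat_row$k, mat_row$e,
                       mat_row$Kg, 0, 0), each = ne), ne, 7)
  pidx <- rep(-1L, nn); np <- 0L
  if (law %in% c(0L, 3L)) {
    pn <- sort(unique(as.vector(blk$elems[, 1:4])))
    pidx[pn] <- seq_along(pn) - 1L
    np <- length(pn)
  }
  # load on top (z = z1) acting in -z (compression), consistent
  wtop <- edge_node_weights(blk$nodes, face_edges(blk, nz + 1L), nn)
  F_load <- numeric(2 * nn + np)
  F_load[2 * seq_len(nn)] <- -pressure * wtop
  fixed <- 2L * face_nodes_bottom(blk, 1L)           # u_z = 0 at base
  ax <- which(blk$nodes[, 1] < r0 + 1e-12)
  fixed <- c(fixed, 2L * ax - 1L)
  if (confined) {
    side <- which(blk$nodes[, 1] > r1 - 1e-12)
    fixed <- c(fixed, 2L * side - 1L)
  }
  pdir <- integer(0)
  if (drain_top && np > 0) {
    topn <- blk$idC[, nz + 1L]
    pdir <- pidx[topn] + 2L * nn + 1L
  }
  list(nodes = blk$nodes, elems = blk$elems, law = lawv, matp = matp,
       matD = matrix(0, ne, 10), pidx = pidx, np = np, F_load = F_load,
       fixed = sort(unique(fixed)), fixed_vals = NULL, contact = NULL,
       pdir_dofs = pdir, blk = blk)
}

# axisymmetric FE compression of the scaffold structure between rigid
# frictionless platens; returns N/mm
scaffold_stiffness_fe <- function(spec, seed = 0.125) {
  n <- 40L
  masks <- scaffold_masks(spec, n, seed)
  if (!any(masks$any)) return(0)
  Ef <- scaffold_E_field(spec, n, seed)
  blk <- q8_block(seq(0, n * seed, by = seed), seq(0, n * seed, by = seed),
                  function(r, zh) zh)
  # q8_block orders elements r fastest within each z row; masks are [row, col]
  keep <- which(as.vector(t(masks$any)))
  elems <- blk$elems[keep, , drop = FALSE]
  Ee <- as.vector(t(Ef))[keep]
  used <- sort(unique(as.vector(elems)))
  remap <- integer(nrow(blk$nodes)); remap[used] <- seq_along(used)
  nodes <- blk$nodes[used, , drop = FALSE]
  elems <- matrix(remap[elems], nrow(elems), 8)
  nn <- nrow(nodes); ne <- nrow(elems)
  matp <- cbind(Ee, spec$material$nu, 0, 4, 0, 0, 0)
  law <- rep(1L, ne)
  H <- n * seed
  bot <- which(abs(nodes[, 2]) < 1e-9)
  top <- which(abs(nodes[, 2] - H) < 1e-9)
  ax <- which(nodes[, 1] < 1e-9)
  delta <- 0.01
  fixed <- c(2L * bot, 2L * top, 2L * ax - 1L)
  vals <- c(rep(0, length(bot)), rep(-delta, length(top)),
            rep(0, length(ax)))
  o <- order(fixed); fixed <- fixed[o]; vals <- vals[o]
  du <- !duplicated(fixed); fixed <- fixed[du]; vals <- vals[du]
  sys <- list(nodes = nodes, elems = elems, law = law, matp = matp,
              matD = matrix(0, ne, 10), pidx = rep(-1L, nn), np = 0L,
              F_load = numeric(2 * nn), fixed = fixed, fixed_vals = vals,
              contact = NULL, pdir_dofs = integer(0))
  ctl <- mech_control(backend = "reduced")
  sch <- data.frame(dt = 1, factor = 0, drained = FALSE, record = FALSE)
  out <- fem_run(sys, sch, ctl)
  a <- fem_assemble_cpp(nodes, elems, law, matp, sys$matD, out$u,
                        numeric(0), sys$pidx, out$u * 0, numeric(0), 1, FALSE)
  Freac <- -sum(a$res[2L * top])
  Freac / delta
}
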