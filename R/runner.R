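# Orchestration of the iterative healing loop: one mechanics solve per day,
# stimulus classification, cell-activity step, material update; collects the
# tissue time series and snapshots.

#' Simulation configuration
#'
#' @param scenario `"empty_marrow"` (empty defect, MSC invasion from the bone
#'   marrow), `"empty_uniform"` (all defect elements initially filled with
#'   MSCs), or `"scaffold"` (marrow invasion plus the given scaffold).
#' @param scaffold a [scaffold_spec()]; implies marrow invasion.
#' @param days number of iterations (1 iteration = 1 day).
#' @param geometry a [condyle_config()].
#' @param control a [mech_control()]; `backend = "surrogate"` runs the cell
#'   model against [surrogate_field()] values given in `surrogate`.
#' @param load a [load_case()].
#' @param rates a [rate_params()].
#' @param stimulus a [stimulus_params()].
#' @param table a [tissue_property_table()].
#' @param surrogate list with `gamma`, `v` passed to [surrogate_field()]
#'   (surrogate backend only).
#' @param snapshot_days iterations at which field snapshots are kept.
#' @param out_dir directory for CSV/VTU output (`NULL`: keep in memory only).
#' @param quantify_weighting `"none"` (plain element average) or `"volume"`
#'   (axisymmetric 2*pi*r weighting).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(scenario = c("empty_marrow", "empty_uniform",
                                           "scaffold"),
                              scaffold = scaffold_spec("none"),
                              days = 50,
                              geometry = condyle_config(),
                              control = mech_control(),
                              load = load_case(),
                              rates = rate_params(),
                              stimulus = stimulus_params(),
                              table = tissue_property_table(),
                              surrogate = list(gamma = 0, v = 0),
                              snapshot_days = c(5, 20, 50),
                              out_dir = NULL,
                              quantify_weighting = c("none", "volume")) {
  scenario <- match.arg(scenario)
  if (days < 1) stop("iteration count must be >= 1")
  if (scenario == "scaffold" && scaffold$architecture == "none")
    stop("scaffold scenario needs a scaffold architecture")
  cfgl <- list(scenario = scenario, scaffold = scaffold, days = days,
               geometry = geometry, control = control, load = load,
               rates = rates, stimulus = stimulus, table = table,
               surrogate = surrogate, snapshot_days = snapshot_days,
               out_dir = out_dir,
               quantify_weighting = match.arg(quantify_weighting))
  class(cfgl) <- "simulation_config"
  cfgl
}

#' Quantify the defect tissue composition
#'
#' Fractions (percent of the defect) of granulation tissue (empty + MSC
#' space), bone, cartilage and fibrous tissue, as the unweighted mean of the
#' per-element space fractions over the lattice; optionally axisymmetric
#' (2*pi*r) volume weighting. The four fractions sum to 100% minus the
#' scaffold occupancy.
#'
#' @param grid a `cell_grid`.
#' @param weighting `"none"` or `"volume"`.
#' @param seed lattice element size (mm), for volume weighting.
#' @return data.frame with one row: granulation, bone, cartilage, fibrous,
#'   scaffold (all percent).
#' @export
quantify_tissues <- function(grid, weighting = c("none", "volume"),
                             seed = 0.125) {
  weighting <- match.arg(weighting)
  nm <- grid$n_max
  w <- if (weighting == "none") {
    matrix(1, nrow(grid$msc), ncol(grid$msc))
  } else {
    r <- (seq_len(ncol(grid$msc)) - 0.5) * seed
    matrix(r, nrow(grid$msc), ncol(grid$msc), byrow = TRUE)
  }
  w <- w / sum(w)
  gran <- (nm * (1 - grid$fs) - grid$ob - grid$ch - grid$fb) / nm
  data.frame(granulation = 100 * sum(w * gran),
             bone = 100 * sum(w * grid$ob) / nm,
             cartilage = 100 * sum(w * grid$ch) / nm,
             fibrous = 100 * sum(w * grid$fb) / nm,
             scaffold = 100 * sum(w * grid$fs))
}

#' Convergence check of the healing process
#'
#' Maximum over the formed tissues (bone, cartilage, fibrous) of the relative
#' change between the reference iteration and the given horizon:
#' |amount(horizon) - amount(ref)| / amount(ref) x 100.
#'
#' @param series a tissue time series (data.frame with a `day` column, as
#'   returned by [run_healing()]).
#' @param horizon iteration to compare against the reference.
#' @param ref reference iteration.
#' @return list with `max_change` (percent) and the per-tissue table; tissues
#'   with zero reference amount are flagged and excluded from the maximum.
#' @export
convergence_check <- function(series, horizon = 100, ref = 50) {
  if (max(series$day) < horizon || !ref %in% series$day)
    stop("series does not cover the requested horizon")
  a50 <- series[series$day == ref, c("bone", "cartilage", "fibrous")]
  ah <- series[series$day == horizon, c("bone", "cartilage", "fibrous")]
  zero <- unlist(a50) == 0
  chg <- 100 * abs(unlist(ah) - unlist(a50)) / ifelse(zero, NA, unlist(a50))
  list(max_change = max(chg[!zero]),
       per_tissue = data.frame(tissue = names(chg), change_pct = unname(chg),
                               zero_reference = unname(zero)))
}

#' Run the coupled healing simulation
#'
#' Executes the daily loop: mechanical solve (or surrogate fields) ->
#' stimulus + fate classification -> cell activity step -> material property
#' update; exactly one mechanics solve per day. The run is deterministic and
#' RNG-free.
#'
#' @param config a [simulation_config()].
#' @param init_state optional checkpoint (the `state` element of a previous
#'   result) to resume from.
#' @return list of class `healing_result`: `series` (per-day composition),
#'   `grid` (final cell grid), `fate` (final fate map), `S`, `gamma`, `v`
#'   (final-day fields), `snapshots`, and `state` (checkpoint for resuming).
#' @export
run_healing <- function(config, init_state = NULL) {
  ctl <- config$control
  surrogate <- ctl$backend == "surrogate"
  geom <- build_condyle_geometry(config$geometry)
  spec <- config$scaffold
  mode <- if (config$scenario == "empty_uniform") "uniform" else
    "marrow_invasion"

  if (!surrogate) {
    mesh <- mesh_geometry(geom, meniscus = (ctl$backend == "full"))
    emb <- embed_scaffold(mesh, spec)
    model <- build_mech_model(mesh, config$load, ctl)
  } else {
    mesh <- NULL
    emb <- list(fs = matrix(0, 40, 40) + 0,
                E_field = scaffold_E_field(spec))
    if (spec$architecture != "none")
      emb$fs[!is.na(emb$E_field)] <- (100 - spec$porosity) / 100
  }

  if (is.null(init_state)) {
    grid <- initialize_grid(mode, fs = emb$fs,
                            source = lattice_source_mask(geom))
    grid$E_field <- emb$E_field
    ms <- if (!surrogate)
      material_state(mesh, config$table, grid, spec) else NULL
    day0 <- 0L
    series <- NULL
    warm <- NULL
  } else {
    grid <- init_state$grid
    ms <- init_state$ms
    day0 <- init_state$day
    series <- init_state$series
    warm <- init_state$warm
  }

  snapshots <- if (is.null(init_state)) list() else init_state$snapshots
  last <- NULL

  for (day in (day0 + 1L):config$days) {
    if (surrogate) {
      mech <- surrogate_field(config$surrogate$gamma, config$surrogate$v)
    } else {
      mech <- solve_step(model, ms, warm)
      warm <- mech$warm
    }
    S <- compute_stimulus(mech, config$stimulus)
    fate <- classify_stimulus(S, config$stimulus)
    grid <- step_day(grid, fate, config$rates)
    if (!surrogate)
      ms <- update_defect_materials(ms, mesh, grid, config$table, spec,
                                    emb$E_field)
    comp <- cbind(day = day, quantify_tissues(grid, config$quantify_weighting))
    series <- rbind(series, comp)
    last <- list(S = S, fate = fate, gamma = mech$gamma, v = mech$v)
    if (day %in% config$snapshot_days)
      snapshots[[as.character(day)]] <-
        c(last, list(grid = grid, composition = comp))
    if (!is.null(config$out_dir))
      write_day_outputs(config$out_dir, day, grid, last, mesh, ms)
  }

  res <- list(series = series, grid = grid, fate = last$fate, S = last$S,
              gamma = last$gamma, v = last$v, snapshots = snapshots,
              state = list(grid = grid, ms = ms, day = config$days,
                           series = series, warm = warm,
                           snapshots = snapshots),
              config = config)
  class(res) <- "healing_result"
  if (!is.null(config$out_dir)) write_run_manifest(config, res)
  res
}

#' @export
print.healing_result <- function(x, ...) {
  n <- nrow(x$series)
  cat(sprintf("healing_result: %d iterations (%s, %s backend)\n",
              n, x$config$scenario, x$config$control$backend))
  cat("final composition (% of defect):\n")
  print(round(x$series[n, -1], 1), row.names = FALSE)
  invisible(x)
}
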