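# The tissue time loop: stimulus protocol handling, reaction-diffusion
# Euler stepping over the grid, and the interchangeable compute backends.

.cw_backends <- c("reference", "gather", "scatter", "tiled", "parallel")

#' Stimulation event
#'
#' A timed rectangular current injection.  Node coordinates are
#' zero-based and the region is half-open: `[x0, x1) x [y0, y1)`.
#' Fixed-time events fire during `[t_start, t_end)`.  Auto-triggered
#' events latch their start time on the first step at which the monitor
#' node's `Vm` falls through `threshold` during repolarization (downward
#' crossing); they then fire for `duration` ms.  Overlapping events sum.
#'
#' @param region `c(x0, x1, y0, y1)`, zero-based half-open node indices.
#' @param amplitude injected current density, uA/cm^2 (depolarizing
#'   positive).
#' @param t_start,t_end window, ms (fixed-trigger events).
#' @param trigger `"fixed"` or `"auto"`.
#' @param monitor `c(x, y)` zero-based monitor node (auto events).
#' @param threshold repolarization threshold, mV (auto events).
#' @param duration pulse length after the trigger, ms (auto events).
#' @return object of class `cw_stim`.
#' @export
stim_event <- function(region, amplitude, t_start = NULL, t_end = NULL,
                       trigger = c("fixed", "auto"), monitor = NULL,
                       threshold = -50, duration = NULL) {
  trigger <- match.arg(trigger)
  region <- as.numeric(region)
  if (length(region) != 4 || region[2] <= region[1] || region[4] <= region[3])
    stop("region must be c(x0, x1, y0, y1) with x1 > x0 and y1 > y0")
  if (trigger == "fixed") {
    if (is.null(t_start) || is.null(t_end) || t_end <= t_start)
      stop("fixed events need t_end > t_start")
  } else {
    if (is.null(monitor) || length(monitor) != 2)
      stop("auto events need a monitor node c(x, y)")
    if (is.null(duration) || duration <= 0)
      stop("auto events need a positive duration")
  }
  structure(list(trigger = trigger, t_start = t_start, t_end = t_end,
                 region = region, amplitude = amplitude,
                 monitor = monitor, threshold = threshold,
                 duration = duration),
            class = "cw_stim")
}

# events -> 12-column matrix for the C++ kernel (see kernels.cpp header)
.pack_stim <- function(stimuli, grid) {
  if (length(stimuli) == 0) return(matrix(0, 0, 12))
  rows <- lapply(stimuli, function(e) {
    auto <- e$trigger == "auto"
    if (e$region[2] > grid$nx || e$region[4] > grid$ny ||
        e$region[1] < 0 || e$region[3] < 0)
      stop("stimulus region outside the grid")
    c(as.numeric(auto),
      if (auto) -1 else e$t_start, if (auto) -1 else e$t_end,
      e$region,
      e$amplitude,
      if (auto) e$monitor[1] * grid$ny + e$monitor[2] else 0,
      if (auto) e$threshold else 0,
      if (auto) e$duration else 0,
      0)
  })
  do.call(rbind, rows)
}

#' Per-node stimulus current at a time point
#'
#' Sums the amplitudes of all events whose window contains `t` over their
#' regions.  Auto-triggered events contribute only once latched (their
#' `t_start`/`t_end` resolved by [run_sim()]); unresolved auto events are
#' silent here.
#'
#' @param stimuli list of [stim_event()]s.
#' @param t time, ms.
#' @param grid a [grid2d()].
#' @return `ny x nx` matrix of injected current, uA/cm^2.
#' @export
apply_stimulus <- function(stimuli, t, grid) {
  out <- matrix(0, grid$ny, grid$nx)
  for (e in stimuli) {
    if (is.null(e$t_start) || is.null(e$t_end)) next
    if (t >= e$t_start && t < e$t_end) {
      xs <- (e$region[1] + 1):e$region[2]
      ys <- (e$region[3] + 1):e$region[4]
      out[ys, xs] <- out[ys, xs] + e$amplitude
    }
  }
  out
}

#' Simulation configuration
#'
#' Bundles grid, fiber field, membrane parameters, time stepping,
#' stimulus protocol and backend selection, and validates the stability
#' invariants: `dt` must stay below `safety_factor` times both the
#' diffusion CFL bound ([cfl_max_dt()]) and the gate-kinetics stiffness
#' cap (the largest `dt` for which one Euler gate update is a contraction,
#' `dt * max(alpha + beta) < 2` over the potentials an action potential
#' traverses).
#'
#' @param grid a [grid2d()].
#' @param fibers a [fiber_field()].
#' @param ionic an [ionic_params()].
#' @param dt time step, ms.
#' @param duration simulated time, ms.
#' @param stimuli list of [stim_event()]s.
#' @param backend one of `"reference"`, `"gather"`, `"scatter"`,
#'   `"tiled"`, `"parallel"`.
#' @param tile_x,tile_y tile extent in nodes (tiled backend).
#' @param workers worker count (parallel backend).
#' @param probe zero-based `c(x, y)` probe node; default domain center.
#' @param snapshot_every snapshot cadence, ms of simulated time.
#' @param record_snapshots keep full Vm snapshots?  Excited-node counts
#'   are recorded at the snapshot cadence either way.
#' @param excite_threshold threshold for the excited-node count, mV.
#' @param safety_factor fraction of the stability bounds `dt` may use.
#' @param seed reserved; all shipped functionality is deterministic.
#' @param validate check invariants (disable only for deliberate
#'   stability experiments).
#' @return object of class `cw_config`.
#' @export
sim_config <- function(grid, fibers = fiber_field(), ionic = ionic_params(),
                       dt = 0.01, duration = 100, stimuli = list(),
                       backend = "gather", tile_x = 16L, tile_y = 16L,
                       workers = 1L, probe = NULL, snapshot_every = 1,
                       record_snapshots = TRUE, excite_threshold = -30,
                       safety_factor = 0.9, seed = NULL, validate = TRUE) {
  if (is.null(probe)) probe <- c(grid$nx %/% 2, grid$ny %/% 2)
  cfg <- structure(list(
    grid = grid, fibers = fibers, ionic = ionic, dt = dt,
    duration = duration, stimuli = stimuli, backend = backend,
    tile_x = as.integer(tile_x), tile_y = as.integer(tile_y),
    workers = as.integer(workers), probe = as.integer(probe),
    snapshot_every = snapshot_every,
    record_snapshots = isTRUE(record_snapshots),
    excite_threshold = excite_threshold,
    safety_factor = safety_factor, seed = seed
  ), class = "cw_config")
  if (validate) validate_config(cfg)
  cfg
}

# largest stable dt for the gate kinetics: one Euler gate update is a
# contraction iff dt * (alpha + beta) < 2; scanned over the potential
# range an action potential actually traverses (the sanity bounds are
# wider on purpose -- they detect blow-up, they are not visited states)
gate_max_dt <- function(ionic, v_range = c(-95, 60)) {
  v <- seq(v_range[1], v_range[2], by = 0.5)
  gates <- if (ionic$use_j_gate) .cw_gates else setdiff(.cw_gates, "j")
  worst <- max(vapply(gates, function(g) {
    r <- .gate_rates(g, v, ionic)
    max(r$alpha + r$beta)
  }, 0))
  2 / worst
}

#' Validate a simulation configuration
#'
#' @param config a [sim_config()].
#' @return the config, invisibly; errors name the offending field.
#' @export
validate_config <- function(config) {
  g <- config$grid
  if (!config$backend %in% .cw_backends)
    stop("backend must be one of: ", paste(.cw_backends, collapse = ", "))
  if (config$duration <= 0) stop("duration must be positive")
  if (config$dt <= 0) stop("dt must be positive")
  if (config$tile_x < 1 || config$tile_y < 1)
    stop("tile sizes must be at least 1")
  if (config$workers < 1) stop("workers must be at least 1")
  if (any(config$probe < 0) || config$probe[1] >= g$nx ||
      config$probe[2] >= g$ny)
    stop("probe node outside the grid")
  if (config$snapshot_every <= 0) stop("snapshot_every must be positive")
  dt_cfl <- cfl_max_dt(config$fibers, g)
  dt_gate <- gate_max_dt(config$ionic)
  cap <- config$safety_factor * min(dt_cfl, dt_gate)
  if (config$dt > cap)
    stop(sprintf(paste0("dt = %g ms violates the stability bound: must be ",
                        "<= %g ms (%g x min(CFL %g ms, gate cap %g ms))"),
                 config$dt, cap, config$safety_factor, dt_cfl, dt_gate))
  for (e in config$stimuli) {
    if (!inherits(e, "cw_stim")) stop("stimuli must be stim_event objects")
    if (e$region[2] > g$nx || e$region[4] > g$ny)
      stop("stimulus region outside the grid")
  }
  invisible(config)
}

#' Initialize quiescent tissue
#'
#' Broadcasts the single-cell rest state ([find_rest_state()]) to every
#' node.
#'
#' @param config a [sim_config()].
#' @return object of class `cw_state`: one `ny x nx` matrix per state
#'   variable (structure-of-arrays layout), plus `time` and `step`.
#' @export
init_tissue <- function(config) {
  rest <- find_rest_state(config$ionic)
  g <- config$grid
  grids <- lapply(c("Vm", .cw_gates, "Cai"), function(v)
    matrix(rest[[v]], g$ny, g$nx))
  names(grids) <- c("vm", .cw_gates, "cai")
  structure(c(grids, list(time = 0, step = 0L, grid = g)),
            class = "cw_state")
}

.backend_code <- function(backend) {
  match(backend, .cw_backends) - 1L
}

.state_pack <- function(state) {
  list(vm = as.numeric(state$vm), m = as.numeric(state$m),
       h = as.numeric(state$h), j = as.numeric(state$j),
       d = as.numeric(state$d), f = as.numeric(state$f),
       x1 = as.numeric(state$x1), cai = as.numeric(state$cai))
}

.state_unpack <- function(res, grid, time, step) {
  grids <- lapply(c("vm", "m", "h", "j", "d", "f", "x1", "cai"),
                  function(v) matrix(res[[v]], grid$ny, grid$nx))
  names(grids) <- c("vm", .cw_gates, "cai")
  structure(c(grids, list(time = time, step = step, grid = grid)),
            class = "cw_state")
}

# resolved-auto-event bookkeeping: rebuild the stimulus list with latched
# windows turned into fixed events
.resolve_stimuli <- function(stimuli, sm) {
  if (length(stimuli) == 0) return(stimuli)
  for (i in seq_along(stimuli)) {
    if (sm[i, 1] == 1 && sm[i, 12] == 1) {
      stimuli[[i]]$t_start <- sm[i, 2]
      stimuli[[i]]$t_end <- sm[i, 3]
      stimuli[[i]]$latched <- TRUE
    }
  }
  stimuli
}

#' Run a tissue simulation
#'
#' Executes `floor(duration / dt)` explicit Euler steps with the selected
#' backend.  Each step refreshes the no-flux ghost frame (serialized),
#' evaluates the diffusion stencil, and advances every node's membrane
#' state in the canonical order (gates, currents, calcium, potential).
#' The probe trace is recorded at every step; Vm snapshots and
#' excited-node counts at the snapshot cadence.  All read-only backends
#' (`reference`, `gather`, `tiled`, `parallel`) produce identical
#' trajectories for a given config; `scatter` agrees to within
#' accumulation-order rounding.
#'
#' @param config a [sim_config()].
#' @param state optional initial [init_tissue()] state (default: rest).
#' @param out_dir optional directory; when given, the probe trace (CSV),
#'   final-state snapshot and a JSON run manifest are written there.
#' @return object of class `cw_result`: `trace` (data.frame `time_ms`,
#'   `vm_mV`), `snapshots` (node x snapshot matrix or `NULL`),
#'   `snapshot_times`, `excited_counts`, `final_state`, resolved `config`,
#'   and `perf` (node updates, elapsed seconds, nodes per second).  A
#'   numerical instability aborts with a condition of class
#'   `cw_instability` naming the step and node and carrying the last
#'   valid snapshot.
#' @export
run_sim <- function(config, state = NULL, out_dir = NULL) {
  validate_config(config)
  if (is.null(state)) state <- init_tissue(config)
  g <- config$grid
  nsteps <- as.integer(floor(config$duration / config$dt + 1e-9))
  snap_stride <- max(1L, as.integer(round(config$snapshot_every / config$dt)))
  probe_idx <- config$probe[1] * g$ny + config$probe[2]
  res <- cpp_run(.state_pack(state), g$nx, g$ny,
                 .pack_rates(config$ionic), .pack_memconst(config$ionic),
                 .stencil_pack(config$fibers, g),
                 .pack_stim(config$stimuli, g),
                 .backend_code(config$backend),
                 config$tile_x, config$tile_y, config$workers,
                 config$dt, nsteps, state$time, as.integer(state$step),
                 as.integer(probe_idx), snap_stride,
                 config$record_snapshots, config$excite_threshold,
                 -120, 80)
  ndone <- res$nsnap_done
  snaps <- if (config$record_snapshots) res$snaps[, seq_len(ndone),
                                                  drop = FALSE]
  final <- .state_unpack(res, g, res$time, res$step)
  config$stimuli <- .resolve_stimuli(config$stimuli, res$stim_resolved)
  out <- structure(list(
    trace = data.frame(time_ms = res$trace[seq_len(res$completed + 1), 1],
                       vm_mV = res$trace[seq_len(res$completed + 1), 2]),
    snapshots = snaps,
    snapshot_times = res$snap_times[seq_len(ndone)],
    excited_counts = res$excited[seq_len(ndone)],
    final_state = final,
    config = config,
    perf = list(node_updates = res$node_updates,
                elapsed_s = res$elapsed_s,
                nodes_per_second = res$node_updates / max(res$elapsed_s,
                                                          .Machine$double.eps),
                steps = res$completed)
  ), class = "cw_result")
  if (res$instab_step >= 0) {
    node <- res$instab_node
    xy <- c(node %/% g$ny, node %% g$ny)
    cond <- structure(class = c("cw_instability", "error", "condition"),
                      list(message = sprintf(
                        paste0("numerical instability at step %d, node ",
                               "(x = %d, y = %d): Vm left [-120, 80] mV"),
                        res$instab_step, xy[1], xy[2]),
                        call = NULL,
                        result = out,
                        last_snapshot = if (ndone > 0 &&
                                            config$record_snapshots)
                          matrix(snaps[, ndone], g$ny, g$nx)))
    stop(cond)
  }
  if (!is.null(out_dir)) .write_run_outputs(out, out_dir)
  out
}

#' Advance a tissue state by a fixed number of steps
#'
#' Convenience wrapper over [run_sim()] for step-wise use; auto-triggered
#' events latched during the call are resolved into fixed events on the
#' returned state's `config` attribute so that repeated stepping matches
#' a single longer run.
#'
#' @param state a `cw_state`.
#' @param config a [sim_config()].
#' @param n number of steps.
#' @return updated `cw_state` with attribute `"config"` (resolved).
#' @export
step_tissue <- function(state, config, n = 1L) {
  config$duration <- n * config$dt
  config$record_snapshots <- FALSE
  res <- run_sim(config, state = state)
  out <- res$final_state
  attr(out, "config") <- res$config
  out
}

#' Backend equivalence report
#'
#' Runs the same configuration under several backends and reports the
#' pairwise sup-norm difference of the full Vm trajectory (every node,
#' every step).  Read-only backends must agree within `tol_readonly`;
#' pairs involving the scatter backend within `tol_scatter`.
#'
#' @param config a [sim_config()]; its `duration` is simulated per
#'   backend with a snapshot every step.
#' @param backends character vector of backend names, or a list whose
#'   elements are either names or lists with fields `backend` and
#'   optionally `tile_x`, `tile_y`, `workers` (e.g.
#'   `list(backend = "tiled", tile_x = 8, tile_y = 8)`).
#' @param tol_readonly,tol_scatter pass thresholds, mV.
#' @return object of class `cw_equivalence`: data.frame of pairwise
#'   sup-norm differences with pass flags.
#' @export
run_equivalence <- function(config,
                            backends = c("reference", "gather", "scatter",
                                         "tiled", "parallel"),
                            tol_readonly = 1e-10, tol_scatter = 1e-9) {
  if (length(backends) < 2) stop("need at least two backends")
  specs <- lapply(backends, function(b) {
    if (is.character(b)) list(backend = b) else b
  })
  labels <- vapply(specs, function(s) {
    lab <- s$backend
    if (s$backend == "tiled" && !is.null(s$tile_x))
      lab <- sprintf("tiled(%dx%d)", s$tile_x, s$tile_y)
    if (s$backend == "parallel" && !is.null(s$workers))
      lab <- sprintf("parallel(%d)", s$workers)
    lab
  }, "")
  state <- init_tissue(config)
  config$record_snapshots <- TRUE
  config$snapshot_every <- config$dt / 2   # every step
  trajs <- lapply(specs, function(s) {
    cfg <- config
    cfg$backend <- s$backend
    for (f in c("tile_x", "tile_y", "workers"))
      if (!is.null(s[[f]])) cfg[[f]] <- as.integer(s[[f]])
    run_sim(cfg, state = state)$snapshots
  })
  pairs <- utils::combn(length(specs), 2)
  rows <- apply(pairs, 2, function(p) {
    d <- max(abs(trajs[[p[1]]] - trajs[[p[2]]]))
    scat <- any(c(specs[[p[1]]]$backend, specs[[p[2]]]$backend) == "scatter")
    tol <- if (scat) tol_scatter else tol_readonly
    data.frame(backend_a = labels[p[1]], backend_b = labels[p[2]],
               max_abs_diff_mV = d, tol_mV = tol, pass = d < tol)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cw_equivalence", "data.frame")
  out
}

#' Tile-size autotuner for the tiled backend
#'
#' Asserts trajectory equivalence of every candidate tile shape against
#' the gather backend first, then times a fixed-step workload per
#' candidate (after one warm-up) and returns the fastest along with the
#' full timing table.
#'
#' @param config a [sim_config()].
#' @param candidates list of `c(tile_x, tile_y)` pairs.
#' @param steps timed steps per candidate.
#' @param check_steps steps used for the correctness check.
#' @return list with `best` (`c(tile_x, tile_y)`) and `table`
#'   (data.frame: tile_x, tile_y, elapsed_s, nodes_per_second).
#' @export
autotune_tiles <- function(config, candidates, steps = 200L,
                           check_steps = 50L) {
  if (length(candidates) == 0) stop("no tile candidates")
  eqcfg <- config
  eqcfg$duration <- check_steps * config$dt
  eq <- run_equivalence(eqcfg, c(list("gather"),
                                 lapply(candidates, function(tc)
                                   list(backend = "tiled", tile_x = tc[1],
                                        tile_y = tc[2]))))
  if (!all(eq$pass))
    stop("tile candidate failed the equivalence check")
  timed <- config
  timed$duration <- steps * config$dt
  timed$record_snapshots <- FALSE
  timed$backend <- "tiled"
  state <- init_tissue(config)
  rows <- lapply(candidates, function(tc) {
    cfg <- timed
    cfg$tile_x <- as.integer(tc[1]); cfg$tile_y <- as.integer(tc[2])
    run_sim(cfg, state = state)          # warm-up
    r <- run_sim(cfg, state = state)
    data.frame(tile_x = tc[1], tile_y = tc[2],
               elapsed_s = r$perf$elapsed_s,
               nodes_per_second = r$perf$nodes_per_second)
  })
  tab <- do.call(rbind, rows)
  best <- tab[which.min(tab$elapsed_s), c("tile_x", "tile_y")]
  list(best = as.integer(unlist(best)), table = tab, equivalence = eq)
}
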