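# Scalability harness: nodes-per-second throughput per grid size and
# backend, with I/O excluded from the timed region.

#' Throughput benchmark
#'
#' Runs a fixed number of steps for each configuration and reports one
#' performance record per run.  Snapshot and probe recording are excluded
#' from the timed region (only the kernel compute loop is timed);
#' `node_updates = steps * nx * ny` exactly and
#' `nodes_per_second = node_updates / elapsed`.  Timing values are
#' reported, never asserted: they are hardware-dependent.
#'
#' @param configs list of [sim_config()]s.
#' @param steps steps to time per config.
#' @param warmup run an untimed warm-up first?
#' @param csv optional path for a machine-readable CSV report.
#' @return data.frame with columns `nx`, `ny`, `backend`, `tile_x`,
#'   `tile_y`, `workers`, `steps`, `node_updates`, `elapsed_s`,
#'   `nodes_per_s`.
#' @export
benchmark_backends <- function(configs, steps = 100L, warmup = TRUE,
                               csv = NULL) {
  rows <- lapply(configs, function(cfg) {
    cfg$duration <- steps * cfg$dt
    cfg$record_snapshots <- FALSE
    state <- init_tissue(cfg)
    if (warmup) run_sim(cfg, state = state)
    r <- run_sim(cfg, state = state)
    data.frame(nx = cfg$grid$nx, ny = cfg$grid$ny, backend = cfg$backend,
               tile_x = cfg$tile_x, tile_y = cfg$tile_y,
               workers = cfg$workers, steps = r$perf$steps,
               node_updates = r$perf$node_updates,
               elapsed_s = r$perf$elapsed_s,
               nodes_per_s = r$perf$nodes_per_second)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(csv))
    write.table(out, csv, sep = ",", row.names = FALSE, quote = FALSE)
  out
}
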