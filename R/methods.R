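# print / summary / plot methods for the user-facing classes.

#' @export
print.cw_config <- function(x, ...) {
  g <- x$grid
  cat("cardiowave simulation config\n")
  print(g)
  print(x$fibers)
  cat(sprintf("  dt %.4g ms, duration %.5g ms (%d steps), backend %s",
              x$dt, x$duration, floor(x$duration / x$dt), x$backend))
  if (x$backend == "tiled")
    cat(sprintf(" (%d x %d tiles)", x$tile_x, x$tile_y))
  if (x$backend == "parallel")
    cat(sprintf(" (%d workers)", x$workers))
  cat("\n")
  cat(sprintf("  probe (%d, %d), snapshots every %.3g ms%s\n",
              x$probe[1], x$probe[2], x$snapshot_every,
              if (x$record_snapshots) "" else " (counts only)"))
  cat("  stimuli:", length(x$stimuli), "event(s)\n")
  dt_cfl <- cfl_max_dt(x$fibers, g)
  cat(sprintf("  stability: CFL bound %.4g ms, gate cap %.4g ms, margin %.2f\n",
              dt_cfl, gate_max_dt(x$ionic),
              x$dt / (x$safety_factor * min(dt_cfl, gate_max_dt(x$ionic)))))
  invisible(x)
}

#' @export
print.cw_state <- function(x, ...) {
  cat(sprintf("tissue state: %d x %d nodes at t = %.4g ms (step %d)\n",
              x$grid$nx, x$grid$ny, x$time, x$step))
  cat(sprintf("  Vm range [%.3f, %.3f] mV, excited (> -30 mV): %d nodes\n",
              min(x$vm), max(x$vm), count_excited(x$vm)))
  invisible(x)
}

#' Image of the transmembrane potential field
#'
#' @param x a `cw_state`.
#' @param ... passed to [graphics::image()].
#' @export
plot.cw_state <- function(x, ...) {
  g <- x$grid
  image(x = (0:(g$nx - 1)) * g$dx, y = (0:(g$ny - 1)) * g$dy,
        z = t(x$vm), xlab = "x (cm)", ylab = "y (cm)",
        col = hcl.colors(64, "viridis"), useRaster = TRUE,
        main = sprintf("Vm at t = %.1f ms", x$time), ...)
  invisible(x)
}

#' @export
print.cw_result <- function(x, ...) {
  g <- x$final_state$grid
  cat(sprintf("cardiowave run: %d x %d nodes, %d steps (dt %.4g ms), backend %s\n",
              g$nx, g$ny, x$perf$steps, x$config$dt, x$config$backend))
  cat(sprintf("  probe Vm range [%.2f, %.2f] mV over [%.4g, %.4g] ms\n",
              min(x$trace$vm_mV), max(x$trace$vm_mV),
              x$trace$time_ms[1], x$trace$time_ms[nrow(x$trace)]))
  cat(sprintf("  %.0f node updates in %.3f s (%.3g nodes/s)\n",
              x$perf$node_updates, x$perf$elapsed_s,
              x$perf$nodes_per_second))
  invisible(x)
}

#' @export
summary.cw_result <- function(object, ...) {
  x <- object
  re <- tryCatch(apd(x$trace), error = function(e) NA_real_)
  cat(sprintf("steps: %d, simulated: %.4g ms\n", x$perf$steps,
              x$perf$steps * x$config$dt))
  cat(sprintf("probe APD90: %s\n",
              if (is.na(re)) "no action potential at probe"
              else sprintf("%.1f ms", re)))
  cat(sprintf("excited-node count: min %d, max %d over %d snapshots\n",
              min(x$excited_counts), max(x$excited_counts),
              length(x$excited_counts)))
  cat(sprintf("throughput: %.3g node updates/s\n", x$perf$nodes_per_second))
  invisible(x)
}

#' Probe action-potential trace
#'
#' @param x a `cw_result`.
#' @param ... passed to [plot()].
#' @export
plot.cw_result <- function(x, ...) {
  plot(x$trace$time_ms, x$trace$vm_mV, type = "l",
       xlab = "time (ms)", ylab = "Vm (mV)",
       main = sprintf("probe (%d, %d)", x$config$probe[1],
                      x$config$probe[2]), ...)
  invisible(x)
}

#' @export
print.cw_equivalence <- function(x, ...) {
  cat("backend trajectory equivalence (sup-norm over all nodes and steps)\n")
  df <- as.data.frame(x)
  df$max_abs_diff_mV <- formatC(df$max_abs_diff_mV, format = "e", digits = 2)
  print(df, row.names = FALSE)
  cat(if (all(x$pass)) "all pairs within tolerance\n"
      else "EQUIVALENCE FAILURE\n")
  invisible(x)
}
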