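# Quantitative readouts: excited-node counts, activation maps,
# conduction velocity, action-potential duration.

#' Count excited nodes
#'
#' @param vm `ny x nx` matrix of potentials, mV.
#' @param threshold excitation threshold, mV.
#' @return number of nodes with `Vm > threshold`.
#' @export
count_excited <- function(vm, threshold = -30) {
  sum(vm > threshold)
}

#' First-activation map
#'
#' For every node, the time of the first upward crossing of the upstroke
#' threshold, linearly interpolated between consecutive snapshots.
#' Never-activated nodes carry the sentinel `NA`.
#'
#' @param result a [run_sim()] result with snapshots recorded.
#' @param threshold upstroke threshold, mV.
#' @return `ny x nx` matrix of class `cw_activation` (ms; `NA` sentinel).
#' @export
activation_map <- function(result, threshold = -50) {
  if (is.null(result$snapshots) || ncol(result$snapshots) < 2)
    stop("activation_map needs at least two recorded snapshots")
  snaps <- result$snapshots
  times <- result$snapshot_times
  g <- result$final_state$grid
  n <- nrow(snaps)
  tact <- rep(NA_real_, n)
  above_prev <- snaps[, 1] > threshold
  for (k in 2:ncol(snaps)) {
    above <- snaps[, k] > threshold
    newly <- above & !above_prev & is.na(tact)
    if (any(newly)) {
      v0 <- snaps[newly, k - 1]
      v1 <- snaps[newly, k]
      frac <- (threshold - v0) / (v1 - v0)
      tact[newly] <- times[k - 1] + frac * (times[k] - times[k - 1])
    }
    above_prev <- above
  }
  out <- matrix(tact, g$ny, g$nx)
  class(out) <- c("cw_activation", "matrix", "array")
  out
}

#' Conduction velocity along a row
#'
#' Distance over activation-time difference between the endpoints of an
#' x-range on one grid row.
#'
#' @param map an [activation_map()].
#' @param grid the [grid2d()] the map was computed on.
#' @param row zero-based y index of the row.
#' @param x_range `c(x0, x1)` zero-based column endpoints (inclusive).
#' @return conduction velocity, cm/ms.
#' @export
conduction_velocity <- function(map, grid, row, x_range) {
  t0 <- map[row + 1, x_range[1] + 1]
  t1 <- map[row + 1, x_range[2] + 1]
  if (is.na(t0) || is.na(t1))
    stop("node in x_range never activated")
  if (t1 <= t0)
    stop("activation times must increase over x_range")
  (x_range[2] - x_range[1]) * grid$dx / (t1 - t0)
}

#' Action-potential duration
#'
#' APD at a repolarization level, e.g. `level = 0.9` for APD90: the time
#' between the upstroke's upward crossing and repolarization's downward
#' crossing of `baseline + (1 - level) * amplitude`, with the baseline
#' taken as the first sample and the amplitude as `max(Vm) - baseline`.
#' Crossing times are linearly interpolated.  Both thresholds are
#' relative, so rescaling the trace amplitude leaves the APD unchanged.
#'
#' @param trace data.frame with columns `time`/`time_ms` and `Vm`/`vm_mV`
#'   (or a two-column matrix), containing a single upstroke and recovery.
#' @param level repolarization fraction in (0, 1).
#' @return duration, ms.
#' @export
apd <- function(trace, level = 0.9) {
  if (is.matrix(trace)) trace <- data.frame(time = trace[, 1],
                                            Vm = trace[, 2])
  tcol <- intersect(c("time", "time_ms"), names(trace))[1]
  vcol <- intersect(c("Vm", "vm_mV"), names(trace))[1]
  if (is.na(tcol) || is.na(vcol))
    stop("trace needs time and Vm columns")
  tt <- trace[[tcol]]; vv <- trace[[vcol]]
  base <- vv[1]
  amp <- max(vv) - base
  thr <- base + (1 - level) * amp
  up <- which(vv[-1] > thr & vv[-length(vv)] <= thr)
  if (amp <= 0 || length(up) == 0)
    stop("no action potential found in trace")
  i <- up[1]
  t_up <- tt[i] + (thr - vv[i]) / (vv[i + 1] - vv[i]) * (tt[i + 1] - tt[i])
  down <- which(vv[-1] <= thr & vv[-length(vv)] > thr)
  down <- down[down > i]
  if (length(down) == 0)
    stop("no repolarization to the requested level found")
  k <- down[1]
  t_dn <- tt[k] + (thr - vv[k]) / (vv[k + 1] - vv[k]) * (tt[k + 1] - tt[k])
  t_dn - t_up
}
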