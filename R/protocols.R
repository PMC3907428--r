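# Stimulation protocol presets: S1 plane wave, S1-S2 cross-field rotor
# initiation, and rotor breakup.

#' Protocol presets
#'
#' Builds a ready-to-run [sim_config()] for one of the standard
#' protocols:
#'
#' * `plane_wave` - a single S1 stimulus over a 5-column strip at the
#'   left edge (2 ms, suprathreshold), anisotropic fibers along x.
#'   Default grid 64 x 64, duration 60 ms.
#' * `single_rotor` - cross-field S1-S2: the S1 plane wave plus an
#'   auto-triggered S2 over the lower-left quadrant that fires when the
#'   domain-center node repolarizes through the S2 threshold, placing the
#'   premature beat inside the vulnerable window so that the wavebreak
#'   curls into a rotor.  Anisotropic preset (fibers at 45 degrees,
#'   D_par 0.001, D_perp 0.0002 cm^2/ms), repolarization kinetics
#'   (d, f, x1) sped up 4x to fit the excitation wavelength into the
#'   domain.  Default grid 192 x 192, duration 450 ms; the probe sits at
#'   (3nx/4, 3ny/4), off the expected core.
#' * `breakup` - isotropic preset (theta 0, D 0.001 cm^2/ms both axes)
#'   with milder 2x repolarization speed-up, whose steeper restitution
#'   regime lets the spiral fragment into fibrillatory wavelets.
#'   Default grid 256 x 256, duration 600 ms.
#'
#' Rotor and breakup presets skip full snapshot storage by default
#' (excited-node counts are still recorded every millisecond).
#'
#' @param name protocol name.
#' @param grid optional [grid2d()] overriding the preset default.
#' @param s2_threshold S2 auto-trigger repolarization threshold, mV
#'   (rotor/breakup; see [vulnerable_window_scan()]).
#' @param ... further [sim_config()] fields to override.
#' @return a validated [sim_config()].
#' @export
make_protocol <- function(name = c("plane_wave", "single_rotor", "breakup"),
                          grid = NULL, s2_threshold = -50, ...) {
  name <- match.arg(name)
  s1 <- function(g, amp = 50)
    stim_event(region = c(0, 5, 0, g$ny), amplitude = amp,
               t_start = 0, t_end = 2)
  s2 <- function(g, amp = 50)
    stim_event(region = c(0, g$nx %/% 2, 0, g$ny %/% 2), amplitude = amp,
               trigger = "auto", monitor = c(g$nx %/% 2, g$ny %/% 2),
               threshold = s2_threshold, duration = 2)
  args <- switch(name,
    plane_wave = {
      g <- if (is.null(grid)) grid2d(64, 64) else grid
      list(grid = g,
           fibers = fiber_field(theta = 0, D_par = 0.001, D_perp = 2e-4),
           ionic = ionic_params(),
           dt = 0.01, duration = 60, stimuli = list(s1(g)))
    },
    single_rotor = {
      g <- if (is.null(grid)) grid2d(192, 192) else grid
      list(grid = g,
           fibers = fiber_field(theta = pi / 4, D_par = 0.001,
                                D_perp = 2e-4),
           ionic = ionic_params(rate_scale = c(d = 4, f = 4, x1 = 4)),
           dt = 0.01, duration = 450, stimuli = list(s1(g), s2(g)),
           probe = c(3 * g$nx %/% 4, 3 * g$ny %/% 4),
           record_snapshots = FALSE)
    },
    breakup = {
      g <- if (is.null(grid)) grid2d(256, 256) else grid
      list(grid = g,
           fibers = fiber_field(theta = 0, D_par = 0.001, D_perp = 0.001),
           ionic = ionic_params(rate_scale = c(d = 2, f = 2, x1 = 2)),
           dt = 0.01, duration = 600, stimuli = list(s1(g), s2(g)),
           probe = c(3 * g$nx %/% 4, 3 * g$ny %/% 4),
           record_snapshots = FALSE)
    })
  do.call(sim_config, modifyList(args, list(...)))
}

#' Sustained-reentry criterion
#'
#' Reentry counts as sustained when, over the `window` ms following the
#' (resolved) S2 stimulus, (a) the excited-node count is positive at
#' every recorded snapshot instant and (b) the probe node shows at least
#' `min_activations` distinct activations (upward crossings of the
#' upstroke threshold).  Condition (b) rules out a single decaying wave.
#'
#' @param result a [run_sim()] result whose config contains a resolved
#'   auto-triggered (S2) event.
#' @param window observation window after S2, ms.
#' @param min_activations required probe activations.
#' @param upstroke_threshold probe activation threshold, mV.
#' @return list: `sustained` (logical), `s2_time` (ms or `NA`),
#'   `n_activations`, `min_excited` (minimum excited count in-window),
#'   `checked_window` (ms actually observed).
#' @export
sustained_reentry <- function(result, window = 300, min_activations = 3,
                              upstroke_threshold = -50) {
  auto <- Filter(function(e) e$trigger == "auto", result$config$stimuli)
  latched <- Filter(function(e) isTRUE(e$latched), auto)
  if (length(latched) == 0)
    return(list(sustained = FALSE, s2_time = NA_real_, n_activations = 0L,
                min_excited = 0L, checked_window = 0))
  s2 <- latched[[1]]$t_start
  tend <- result$trace$time_ms[nrow(result$trace)]
  checked <- min(window, tend - s2)
  inwin <- result$snapshot_times > s2 &
    result$snapshot_times <= s2 + window
  min_exc <- if (any(inwin)) min(result$excited_counts[inwin]) else 0L
  tr <- result$trace
  sel <- tr$time_ms > s2 & tr$time_ms <= s2 + window
  v <- tr$vm_mV[sel]
  ups <- sum(v[-1] >= upstroke_threshold & v[-length(v)] < upstroke_threshold)
  list(sustained = (min_exc > 0) && (ups >= min_activations) &&
         checked >= window,
       s2_time = s2, n_activations = as.integer(ups),
       min_excited = as.integer(min_exc), checked_window = checked)
}

#' Vulnerable-window scan over S2 trigger thresholds
#'
#' The repolarization level at which the premature S2 fires determines
#' whether the wavebreak falls inside the vulnerable window.  This scans
#' a small set of trigger thresholds, runs the protocol for each, and
#' evaluates [sustained_reentry()]; the run is extended automatically if
#' S2 fires too late for the full observation window.
#'
#' @param config a rotor-style [sim_config()] with an auto-triggered S2
#'   (e.g. from `make_protocol("single_rotor")`), or `NULL` to build that
#'   preset.
#' @param thresholds S2 trigger thresholds to scan, mV.
#' @param window observation window after S2, ms.
#' @param stop_at_first stop scanning after the first sustained hit?
#' @param ... passed to [make_protocol()] when `config` is `NULL`.
#' @return object of class `cw_vwscan`: list of per-threshold results
#'   (`threshold`, `reentry`, `result`) plus `any_sustained`.
#' @export
vulnerable_window_scan <- function(config = NULL,
                                   thresholds = c(-40, -50, -60),
                                   window = 300, stop_at_first = TRUE, ...) {
  runs <- list()
  any_s <- FALSE
  for (thr in thresholds) {
    cfg <- if (is.null(config)) {
      make_protocol("single_rotor", s2_threshold = thr, ...)
    } else {
      cc <- config
      for (i in seq_along(cc$stimuli))
        if (cc$stimuli[[i]]$trigger == "auto")
          cc$stimuli[[i]]$threshold <- thr
      cc
    }
    res <- run_sim(cfg)
    re <- sustained_reentry(res, window = window)
    # extend if S2 latched too late for the full observation window
    if (!is.na(re$s2_time) && re$checked_window < window) {
      cfg$duration <- re$s2_time + window + 10
      res <- run_sim(cfg)
      re <- sustained_reentry(res, window = window)
    }
    runs[[as.character(thr)]] <- list(threshold = thr, reentry = re,
                                      result = res)
    if (re$sustained) {
      any_s <- TRUE
      if (stop_at_first) break
    }
  }
  structure(list(runs = runs, any_sustained = any_s, window = window),
            class = "cw_vwscan")
}

#' @export
print.cw_vwscan <- function(x, ...) {
  cat("vulnerable-window scan (", x$window, "ms window after S2)\n")
  for (r in x$runs) {
    re <- r$reentry
    cat(sprintf(paste0("  S2 threshold %+.0f mV: %s (S2 at %s ms, %d probe ",
                       "activations, min excited %d)\n"),
                r$threshold,
                if (re$sustained) "sustained reentry" else "not sustained",
                if (is.na(re$s2_time)) "-" else sprintf("%.1f", re$s2_time),
                re$n_activations, re$min_excited))
  }
  invisible(x)
}
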