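# Single-cell electrophysiology: Beeler-Reuter membrane model with the
# Drouhard-Roberge sodium current.  Constants are loaded from a versioned
# plain-text table (see inst/extdata/brdr_constants_v1.txt); users may
# point `ionic_params()` at an alternative table with the same keys.

.cw_gates <- c("m", "h", "j", "d", "f", "x1")
.cw_rate_names <- as.vector(t(outer(c("alpha", "beta"), .cw_gates,
                                    function(a, g) paste(a, g, sep = "_"))))
# order used by the C++ kernels: alpha_m, beta_m, alpha_h, ..., beta_x1
.cw_rate_order <- as.vector(rbind(paste0("alpha_", .cw_gates),
                                  paste0("beta_", .cw_gates)))

#' Path of the shipped membrane constant table
#' @return file path of the default plain-text constants file.
#' @export
cw_constants_file <- function() {
  system.file("extdata", "brdr_constants_v1.txt", package = "cardiowave",
              mustWork = TRUE)
}

# parse "key = value" lines; '#' comments; returns named numeric vector
read_constants <- function(path) {
  if (!file.exists(path)) stop("constants file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(\\S+)$", lines))
  bad <- vapply(parts, length, 0L) != 3L
  if (any(bad))
    stop("malformed constants line: '", lines[which(bad)[1]], "'")
  keys <- vapply(parts, `[`, "", 2L)
  vals <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3L)))
  if (anyNA(vals))
    stop("non-numeric value for key '", keys[which(is.na(vals))[1]], "'")
  if (anyDuplicated(keys))
    stop("duplicate key in constants file: ", keys[anyDuplicated(keys)])
  stats::setNames(vals, keys)
}

# build the rate table (named list of cw_rate_spec) from a constants vector
.rate_table_from_constants <- function(k) {
  specs <- list()
  for (nm in .cw_rate_order) {
    co <- k[paste0(nm, ".C", 1:7)]
    if (anyNA(co))
      stop("constants file is missing coefficients for rate '", nm, "'")
    sv <- k[paste0(nm, ".singular_V")]
    sl <- k[paste0(nm, ".singular_limit")]
    specs[[nm]] <- rate_spec(co[1], co[2], co[3], co[4], co[5], co[6], co[7],
                             singular_V = if (!is.na(sv)) unname(sv),
                             singular_limit = if (!is.na(sl)) unname(sl))
  }
  specs
}

#' Membrane model parameters
#'
#' Loads the membrane constant table and assembles the full parameter set:
#' conductances, reversal potential, capacitance, the 12-entry rate table
#' (one [rate_spec()] per gate alpha/beta pair), the optional slow sodium
#' inactivation gate `j`, and per-gate rate multipliers.
#'
#' The `rate_scale` multipliers scale both the opening and closing rate of
#' a gate, shortening its time constant without moving its steady state.
#' Scaling the repolarizing gates (`d`, `f`, `x1`) shortens the action
#' potential; the rotor and breakup protocol presets use this to fit the
#' excitation wavelength into their domains.
#'
#' @param constants_file plain-text `key = value` constant table
#'   (default: the shipped Beeler-Reuter / Drouhard-Roberge table).
#' @param use_j_gate logical; retain the slow sodium inactivation gate
#'   `j`?  The Drouhard-Roberge sodium formulation drops it (default
#'   `FALSE`); its Beeler-Reuter kinetics stay in the table for
#'   `use_j_gate = TRUE`.
#' @param rate_scale named multipliers for gate kinetics, e.g.
#'   `c(d = 4, f = 4, x1 = 4)`; unnamed gates keep multiplier 1.
#' @param g_Na,E_Na,g_NaC,g_s,C_m optional scalar overrides of the file
#'   values (mS/cm^2, mV, mS/cm^2, mS/cm^2, uF/cm^2).
#' @return object of class `cw_ionic`.
#' @export
ionic_params <- function(constants_file = cw_constants_file(),
                         use_j_gate = FALSE,
                         rate_scale = NULL,
                         g_Na = NULL, E_Na = NULL, g_NaC = NULL,
                         g_s = NULL, C_m = NULL) {
  k <- read_constants(constants_file)
  pick <- function(override, key) {
    if (!is.null(override)) return(override)
    if (is.na(k[key])) stop("constants file is missing key '", key, "'")
    unname(k[key])
  }
  scale <- stats::setNames(rep(1, 6), .cw_gates)
  if (!is.null(rate_scale)) {
    if (is.null(names(rate_scale)) || !all(names(rate_scale) %in% .cw_gates))
      stop("rate_scale must be named with gates among: ",
           paste(.cw_gates, collapse = ", "))
    scale[names(rate_scale)] <- rate_scale
  }
  if (any(scale <= 0)) stop("rate_scale entries must be positive")
  p <- structure(list(
    g_Na = pick(g_Na, "g_Na"), E_Na = pick(E_Na, "E_Na"),
    g_NaC = pick(g_NaC, "g_NaC"), g_s = pick(g_s, "g_s"),
    C_m = pick(C_m, "C_m"),
    cai_floor = pick(NULL, "cai_floor"), cai_init = pick(NULL, "cai_init"),
    use_j_gate = isTRUE(use_j_gate),
    rate_scale = scale,
    rate_table = .rate_table_from_constants(k),
    constants_file = normalizePath(constants_file)
  ), class = "cw_ionic")
  if (p$g_Na < 0 || p$g_NaC < 0 || p$g_s < 0)
    stop("conductances must be non-negative")
  if (p$C_m <= 0) stop("C_m must be positive")
  p
}

# flatten the rate table to the 12 x 10 matrix the C++ kernels take:
# columns C1..C7, has_singular, singular_V, singular_limit
.pack_rates <- function(params) {
  rows <- lapply(params$rate_table[.cw_rate_order], function(sp) {
    c(sp$C,
      as.numeric(!is.null(sp$singular_V)),
      if (is.null(sp$singular_V)) 0 else sp$singular_V,
      if (is.null(sp$singular_limit)) 0 else sp$singular_limit)
  })
  do.call(rbind, rows)
}

.pack_memconst <- function(params) {
  c(params$g_Na, params$E_Na, params$g_NaC, params$g_s, params$C_m,
    params$cai_floor, as.numeric(params$use_j_gate),
    unname(params$rate_scale[.cw_gates]))
}

#' Single-cell membrane state
#'
#' @param Vm transmembrane potential, mV (sanity bounds \[-120, 80\]).
#' @param m,h,j,d,f,x1 gate variables, each in \[0, 1\].
#' @param Cai intracellular calcium, mol/L (positive).
#' @return named numeric vector of class `cw_membrane`.
#' @export
membrane_state <- function(Vm, m, h, j, d, f, x1, Cai) {
  s <- c(Vm = Vm, m = m, h = h, j = j, d = d, f = f, x1 = x1, Cai = Cai)
  validate_membrane_state(s)
  structure(s, class = "cw_membrane")
}

validate_membrane_state <- function(s) {
  g <- s[c("m", "h", "j", "d", "f", "x1")]
  if (any(!is.finite(s))) stop("membrane state must be finite")
  if (any(g < 0) || any(g > 1)) stop("gate variables must lie in [0, 1]")
  if (s[["Cai"]] <= 0) stop("Cai must be positive")
  if (s[["Vm"]] < -120 || s[["Vm"]] > 80)
    stop("Vm outside sanity bounds [-120, 80] mV (numerical instability?)")
  invisible(s)
}

# time-independent potassium current, uA/cm^2; removable singularity of
# the (V+23) factor at V = -23 handled with its analytic limit 1/0.04
.ik1 <- function(v) {
  t1 <- 4 * (exp(0.04 * (v + 85)) - 1) /
    (exp(0.08 * (v + 53)) + exp(0.04 * (v + 53)))
  x <- v + 23
  t2 <- ifelse(abs(x) < .cw_singular_halfwidth, 1 / 0.04,
               x / (1 - exp(-0.04 * x)))
  0.35 * (t1 + 0.2 * t2)
}

# time-activated outward current, uA/cm^2
.ix1 <- function(v, x1) {
  x1 * 0.8 * (exp(0.04 * (v + 77)) - 1) / exp(0.04 * (v + 35))
}

#' Ionic current densities at a membrane state
#'
#' `I_Na = (g_Na m^3 h (j) + g_NaC)(Vm - E_Na)`;
#' `I_s = g_s d f (Vm - E_s)` with `E_s = -82.3 - 13.0287 ln(Cai)`;
#' `I_K1` and `I_x1` follow the Beeler-Reuter closed forms with removable
#' singularities replaced by their analytic limits.  `I_total` is their
#' sum, in that order.
#'
#' @param state a [membrane_state()].
#' @param params an [ionic_params()].
#' @return list of class `cw_currents` with `I_Na`, `I_s`, `I_K1`, `I_x1`,
#'   `I_total` (uA/cm^2) and the reversal `E_s` (mV).
#' @export
compute_currents <- function(state, params) {
  v <- state[["Vm"]]
  if (state[["Cai"]] <= 0) stop("invalid state: Cai must be positive")
  jg <- if (params$use_j_gate) state[["j"]] else 1
  I_Na <- (params$g_Na * state[["m"]]^3 * state[["h"]] * jg + params$g_NaC) *
    (v - params$E_Na)
  E_s <- -82.3 - 13.0287 * log(state[["Cai"]])
  I_s <- params$g_s * state[["d"]] * state[["f"]] * (v - E_s)
  I_K1 <- .ik1(v)
  I_x1 <- .ix1(v, state[["x1"]])
  structure(list(I_Na = I_Na, I_s = I_s, I_K1 = I_K1, I_x1 = I_x1,
                 I_total = I_Na + I_s + I_K1 + I_x1, E_s = E_s),
            class = "cw_currents")
}

# alpha/beta for one gate at potential v, including the rate multiplier
.gate_rates <- function(gate, v, params) {
  sc <- params$rate_scale[[gate]]
  list(alpha = sc * evaluate_rate(v, params$rate_table[[paste0("alpha_", gate)]]),
       beta = sc * evaluate_rate(v, params$rate_table[[paste0("beta_", gate)]]))
}

#' One explicit Euler update of the gate variables
#'
#' Each gate moves by `dt * (alpha(Vm) (1 - g) - beta(Vm) g)` evaluated at
#' the pre-step `Vm`, then is clamped to \[0, 1\].  `Vm` and `Cai` are
#' unchanged.  When `use_j_gate` is `FALSE` the `j` gate is left untouched.
#'
#' @inheritParams compute_currents
#' @param dt time step, ms (positive).
#' @return updated `cw_membrane` state.
#' @export
update_gates_euler <- function(state, params, dt) {
  if (dt <= 0) stop("dt must be positive")
  v <- state[["Vm"]]
  out <- state
  gates <- if (params$use_j_gate) .cw_gates else setdiff(.cw_gates, "j")
  for (g in gates) {
    r <- .gate_rates(g, v, params)
    gv <- state[[g]] + dt * (r$alpha * (1 - state[[g]]) - r$beta * state[[g]])
    out[[g]] <- min(1, max(0, gv))
  }
  out
}

#' Intracellular calcium update
#'
#' `Cai' = Cai + dt (-1e-7 I_s + 0.07 (1e-7 - Cai))`, floored at a small
#' positive value so that `ln(Cai)` in the slow-inward reversal stays
#' finite.
#'
#' @param state a [membrane_state()] (only `Cai` is read).
#' @param I_s slow inward current, uA/cm^2.
#' @param dt time step, ms.
#' @param floor calcium floor, mol/L.
#' @return updated calcium concentration, mol/L.
#' @export
update_cai <- function(state, I_s, dt, floor = 1e-10) {
  if (dt <= 0) stop("dt must be positive")
  cai <- state[["Cai"]]
  if (cai <= 0) stop("Cai must be positive")
  max(floor, cai + dt * (-1e-7 * I_s + 0.07 * (1e-7 - cai)))
}

#' One explicit Euler step of the full membrane model
#'
#' Fixed update order shared by every tissue backend: (1) gates from the
#' pre-step `Vm`, (2) currents from the updated gates and pre-step `Vm`,
#' (3) calcium, (4) `Vm <- Vm + dt (-I_total + I_stim) / C_m`.  Runs the
#' same compiled update the tissue kernels use, so a zero-diffusion tissue
#' node and this function produce bit-identical trajectories.
#'
#' @inheritParams compute_currents
#' @param I_stim injected current density, uA/cm^2 (depolarizing positive).
#' @param dt time step, ms.
#' @return updated `cw_membrane` state.
#' @export
single_cell_step <- function(state, params, I_stim = 0, dt) {
  if (dt <= 0) stop("dt must be positive")
  out <- cpp_cell_step(unclass(state)[c("Vm", .cw_gates, "Cai")],
                       .pack_rates(params), .pack_memconst(params),
                       I_stim, dt)
  out <- stats::setNames(as.numeric(out), c("Vm", .cw_gates, "Cai"))
  if (!is.finite(out[["Vm"]]) || out[["Vm"]] < -120 || out[["Vm"]] > 80)
    stop("numerical instability: Vm left sanity bounds [-120, 80] mV")
  structure(out, class = "cw_membrane")
}

#' Run an isolated cell for a fixed duration
#'
#' @param params an [ionic_params()].
#' @param duration simulated time, ms.
#' @param dt time step, ms.
#' @param state initial state (default: the computed rest state).
#' @param stim `NULL` or a matrix/data.frame with columns `t_start`,
#'   `t_end`, `amplitude` (ms, ms, uA/cm^2) of rectangular current pulses.
#' @return data.frame with columns `time`, `Vm`, the six gates and `Cai`,
#'   one row per step (including the initial sample).
#' @export
run_single_cell <- function(params, duration, dt = 0.01,
                            state = find_rest_state(params), stim = NULL) {
  if (dt <= 0 || duration <= 0) stop("dt and duration must be positive")
  nsteps <- floor(duration / dt + 1e-9)
  sm <- if (is.null(stim)) matrix(0, 0, 3) else {
    sm <- as.matrix(as.data.frame(stim)[, c("t_start", "t_end", "amplitude")])
    storage.mode(sm) <- "double"
    sm
  }
  res <- cpp_run_single_cell(unclass(state)[c("Vm", .cw_gates, "Cai")],
                             .pack_rates(params), .pack_memconst(params),
                             sm, dt, as.integer(nsteps), 0)
  out <- data.frame(time = res$times, res$traj)
  names(out) <- c("time", "Vm", .cw_gates, "Cai")
  out
}

#' Quiescent (rest) state of the membrane model
#'
#' Sets every gate to its steady state `g_inf(V)`, solves the calcium
#' fixed point consistent with the resulting slow-inward current, and
#' finds the resting potential as the root of the total ionic current by
#' bisection on the bracket, to `|I_total| < tol`.
#'
#' @param params an [ionic_params()].
#' @param bracket search interval for the resting potential, mV.
#' @param tol tolerance on the residual total current, uA/cm^2.
#' @return `cw_membrane` rest state.
#' @export
find_rest_state <- function(params, bracket = c(-100, -60), tol = 1e-9) {
  gates_inf <- function(v) {
    vapply(.cw_gates, function(g) {
      r <- .gate_rates(g, v, params)
      gate_steady_state(r$alpha, r$beta)$g_inf
    }, 0)
  }
  cai_fixed_point <- function(v, gi) {
    cai <- params$cai_init
    for (i in 1:200) {
      E_s <- -82.3 - 13.0287 * log(cai)
      I_s <- params$g_s * gi[["d"]] * gi[["f"]] * (v - E_s)
      new <- max(params$cai_floor, 1e-7 - (1e-7 / 0.07) * I_s)
      if (abs(new - cai) < 1e-22) {
        cai <- new
        break
      }
      cai <- new
    }
    cai
  }
  resid <- function(v) {
    gi <- gates_inf(v)
    cai <- cai_fixed_point(v, gi)
    st <- structure(c(Vm = v, gi, Cai = cai), class = "cw_membrane")
    names(st) <- c("Vm", .cw_gates, "Cai")
    compute_currents(st, params)$I_total
  }
  lo <- bracket[1]; hi <- bracket[2]
  flo <- resid(lo); fhi <- resid(hi)
  if (sign(flo) == sign(fhi))
    stop("no rest state: I_total has no sign change on [", lo, ", ", hi,
         "] mV (check model constants)")
  mid <- lo
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- resid(mid)
    if (abs(fm) < tol && (hi - lo) < 1e-10) break
    if (sign(fm) == sign(flo)) {
      lo <- mid; flo <- fm
    } else {
      hi <- mid
    }
  }
  gi <- gates_inf(mid)
  cai <- cai_fixed_point(mid, gi)
  st <- structure(c(Vm = mid, gi, Cai = cai), class = "cw_membrane")
  names(st) <- c("Vm", .cw_gates, "Cai")
  validate_membrane_state(st)
  st
}

#' @export
print.cw_ionic <- function(x, ...) {
  cat("Beeler-Reuter / Drouhard-Roberge membrane parameters\n")
  cat(sprintf("  g_Na %.4g  E_Na %.4g  g_NaC %.4g  g_s %.4g  C_m %.4g\n",
              x$g_Na, x$E_Na, x$g_NaC, x$g_s, x$C_m))
  cat("  j gate:", if (x$use_j_gate) "retained" else "dropped (DR sodium)",
      "\n")
  sc <- x$rate_scale[x$rate_scale != 1]
  if (length(sc))
    cat("  rate multipliers:",
        paste(names(sc), sc, sep = " x", collapse = ", "), "\n")
  cat("  constants:", x$constants_file, "\n")
  invisible(x)
}

#' @export
print.cw_membrane <- function(x, ...) {
  cat(sprintf("membrane state: Vm %.4f mV, Cai %.4g mol/L\n",
              x[["Vm"]], x[["Cai"]]))
  cat("  gates:", paste(sprintf("%s=%.4f", .cw_gates, x[.cw_gates]),
                        collapse = " "), "\n")
  invisible(x)
}
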