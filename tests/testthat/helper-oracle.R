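# Shared fixtures and independent R oracles for the compiled kernels.

test_ionic <- ionic_params()
test_rest <- find_rest_state(test_ionic)

# Independent single-cell Euler step assembled from the package's R-level
# pieces (evaluate_rate / compute_currents / update_cai), i.e. a code path
# disjoint from the compiled cell update it checks.
r_cell_step <- function(state, params, I_stim = 0, dt, diff = 0) {
  st <- update_gates_euler(state, params, dt)
  cur <- compute_currents(st, params)
  cai <- update_cai(st, cur$I_s, dt, floor = params$cai_floor)
  vm <- st[["Vm"]] + dt * (diff + (I_stim - cur$I_total) / params$C_m)
  out <- st
  out[["Cai"]] <- cai
  out[["Vm"]] <- vm
  out
}

# Brute-force stencil application with explicit loops over the padded grid.
r_diffusion <- function(vm, w3, pad_type = "face") {
  p <- pad_noflux(vm, type = pad_type)
  ny <- nrow(vm); nx <- ncol(vm)
  out <- matrix(0, ny, nx)
  for (x in 1:nx) {
    for (y in 1:ny) {
      acc <- 0
      for (ox in -1:1)
        for (oy in -1:1)
          acc <- acc + w3[oy + 2, ox + 2] * p[y + 1 + oy, x + 1 + ox]
      out[y, x] <- acc
    }
  }
  out
}

# a random valid membrane state
random_membrane_state <- function() {
  membrane_state(Vm = runif(1, -100, 40),
                 m = runif(1), h = runif(1), j = runif(1),
                 d = runif(1), f = runif(1), x1 = runif(1),
                 Cai = 10^runif(1, -7.5, -6))
}

# small quiet tissue config for simulation tests
quick_config <- function(nx = 16, ny = 16, duration = 2, ...) {
  sim_config(grid2d(nx, ny), fiber_field(0, 0.001, 2e-4), test_ionic,
             dt = 0.01, duration = duration, ...)
}

# full-grid uniform stimulus event
uniform_stim <- function(grid, t_start = 0, t_end = 2, amplitude = 60)
  stim_event(region = c(0, grid$nx, 0, grid$ny), amplitude = amplitude,
             t_start = t_start, t_end = t_end)
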