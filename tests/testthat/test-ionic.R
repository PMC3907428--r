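# Membrane currents, gate/calcium updates, the full cell step, and the
# rest-state solver.

test_that("multiplicative gates switch their currents off", {
  st <- membrane_state(Vm = -20, m = 0.5, h = 0.5, j = 0.5, d = 0, f = 0.8,
                       x1 = 0.1, Cai = 1e-7)
  cur <- compute_currents(st, test_ionic)
  expect_identical(cur$I_s, 0)

  p0 <- ionic_params(g_NaC = 0)
  st2 <- membrane_state(Vm = -20, m = 0, h = 1, j = 1, d = 0.3, f = 0.8,
                        x1 = 0.1, Cai = 1e-7)
  expect_identical(compute_currents(st2, p0)$I_Na, 0)
})

test_that("I_total is the plain sum of the four currents", {
  set.seed(11)
  for (i in 1:20) {
    st <- random_membrane_state()
    cur <- compute_currents(st, test_ionic)
    expect_identical(cur$I_total, cur$I_Na + cur$I_s + cur$I_K1 + cur$I_x1)
  }
})

test_that("the potassium current is continuous at its singular point", {
  # isolate I_K1: all other currents gated/conducted to zero
  p0 <- ionic_params(g_NaC = 0)
  ik1_at <- function(v) {
    st <- membrane_state(Vm = v, m = 0, h = 1, j = 1, d = 0, f = 1, x1 = 0,
                         Cai = 1e-7)
    compute_currents(st, p0)$I_K1
  }
  at <- ik1_at(-23)
  expect_true(is.finite(at))
  expect_lt(abs(ik1_at(-23 + 2e-6) - at), 1e-6)
  expect_lt(abs(ik1_at(-23 - 2e-6) - at), 1e-6)
})

test_that("gate update follows the explicit Euler formula and fixed point", {
  # custom constant rates: alpha = 2, beta = 3 -> from g = 0, dt = 0.1,
  # g' = 0.2 (the 1 - g factor is 1)
  p <- test_ionic
  p$rate_table$alpha_m <- rate_spec(C1 = 2)
  p$rate_table$beta_m <- rate_spec(C1 = 3)
  st <- membrane_state(Vm = -80, m = 0, h = 0.5, j = 0.5, d = 0.5, f = 0.5,
                       x1 = 0.5, Cai = 1e-7)
  up <- update_gates_euler(st, p, dt = 0.1)
  expect_equal(up[["m"]], 0.2)
  expect_identical(up[["Vm"]], st[["Vm"]])
  expect_identical(up[["Cai"]], st[["Cai"]])

  # steady-state gates are a fixed point of the update
  v <- -60
  ginf <- vapply(c("m", "h", "j", "d", "f", "x1"), function(g) {
    a <- evaluate_rate(v, test_ionic$rate_table[[paste0("alpha_", g)]])
    b <- evaluate_rate(v, test_ionic$rate_table[[paste0("beta_", g)]])
    gate_steady_state(a, b)$g_inf
  }, 0)
  st2 <- membrane_state(Vm = v, m = ginf[["m"]], h = ginf[["h"]],
                        j = ginf[["j"]], d = ginf[["d"]], f = ginf[["f"]],
                        x1 = ginf[["x1"]], Cai = 1e-7)
  up2 <- update_gates_euler(st2, test_ionic, dt = 0.05)
  for (g in c("m", "h", "d", "f", "x1"))
    expect_lt(abs(up2[[g]] - st2[[g]]), 1e-14)
  expect_error(update_gates_euler(st2, test_ionic, dt = 0), "positive")
})

test_that("one Euler gate update maps [0,1] into [0,1] below the bounded-dt cap", {
  # dt <= 1 / max(alpha + beta) over the sanity range guarantees the
  # update never leaves [0,1] before clamping, from any admissible g
  v <- seq(-120, 80, by = 0.5)
  for (g in setdiff(c("m", "h", "j", "d", "f", "x1"), "j")) {
    a <- evaluate_rate(v, test_ionic$rate_table[[paste0("alpha_", g)]])
    b <- evaluate_rate(v, test_ionic$rate_table[[paste0("beta_", g)]])
    dt <- 1 / max(a + b)
    for (g0 in c(0, 0.5, 1)) {
      g1 <- g0 + dt * (a * (1 - g0) - b * g0)
      expect_true(all(g1 >= 0 & g1 <= 1))
    }
  }
})

test_that("calcium update: fixed point, arithmetic, floor", {
  st <- membrane_state(Vm = -80, m = 0, h = 1, j = 1, d = 0, f = 1, x1 = 0,
                       Cai = 1e-7)
  expect_equal(update_cai(st, I_s = 0, dt = 0.5), 1e-7)
  st2 <- st; st2[["Cai"]] <- 2e-7
  expect_equal(update_cai(st2, I_s = 0, dt = 1), 1.93e-7)
  # enormous outward I_s drives Cai to the floor, never below
  expect_equal(update_cai(st2, I_s = 1e6, dt = 1, floor = 1e-10), 1e-10)
})

test_that("compiled cell step matches the independent R oracle", {
  set.seed(42)
  for (i in 1:25) {
    st <- random_membrane_state()
    istim <- runif(1, -5, 60)
    dt <- 0.01
    a <- single_cell_step(st, test_ionic, I_stim = istim, dt = dt)
    b <- r_cell_step(st, test_ionic, I_stim = istim, dt = dt)
    expect_lt(max(abs(a - b)), 1e-12)
  }
  # with the j gate retained
  pj <- ionic_params(use_j_gate = TRUE)
  st <- random_membrane_state()
  expect_lt(max(abs(single_cell_step(st, pj, 0, 0.01) -
                      r_cell_step(st, pj, 0, 0.01))), 1e-12)
})

test_that("rest state is a fixed point and stays quiescent", {
  expect_gt(test_rest[["Vm"]], -90)
  expect_lt(test_rest[["Vm"]], -75)
  # gates solve the steady-state equation
  for (g in c("m", "h", "j", "d", "f", "x1")) {
    a <- evaluate_rate(test_rest[["Vm"]],
                       test_ionic$rate_table[[paste0("alpha_", g)]])
    b <- evaluate_rate(test_rest[["Vm"]],
                       test_ionic$rate_table[[paste0("beta_", g)]])
    expect_lt(abs(a * (1 - test_rest[[g]]) - b * test_rest[[g]]), 1e-12)
  }
  one <- single_cell_step(test_rest, test_ionic, 0, dt = 0.01)
  expect_lt(max(abs(one - test_rest)), 1e-9)
  tr <- run_single_cell(test_ionic, duration = 10, dt = 0.01,
                        state = test_rest)
  expect_lt(max(abs(tr$Vm - test_rest[["Vm"]])), 1e-3)
})

test_that("with sodium and calcium conductances off, rest is the K-current root", {
  p0 <- ionic_params(g_Na = 0, g_s = 0, g_NaC = 0)
  got <- find_rest_state(p0)[["Vm"]]
  # independent oracle: hand-written closed forms + uniroot
  ik1 <- function(v)
    0.35 * (4 * (exp(0.04 * (v + 85)) - 1) /
              (exp(0.08 * (v + 53)) + exp(0.04 * (v + 53))) +
              0.2 * (v + 23) / (1 - exp(-0.04 * (v + 23))))
  ix1 <- function(v) {
    ax <- 0.0005 * exp(0.083 * (v + 50)) / (exp(0.057 * (v + 50)) + 1)
    bx <- 0.0013 * exp(-0.06 * (v + 20)) / (exp(-0.04 * (v + 20)) + 1)
    x1inf <- ax / (ax + bx)
    x1inf * 0.8 * (exp(0.04 * (v + 77)) - 1) / exp(0.04 * (v + 35))
  }
  oracle <- stats::uniroot(function(v) ik1(v) + ix1(v), c(-100, -60),
                           tol = 1e-12)$root
  expect_lt(abs(got - oracle), 1e-6)
})

test_that("a suprathreshold pulse elicits an action potential that recovers", {
  # the last millivolt of recovery is slow: the x1 gate deactivates with
  # tau ~ 230 ms at rest, so full return takes ~2 APDs
  tr <- run_single_cell(test_ionic, duration = 600, dt = 0.01,
                        state = test_rest,
                        stim = data.frame(t_start = 2, t_end = 4,
                                          amplitude = 60))
  expect_gt(max(tr$Vm), 0)
  expect_lt(abs(tr$Vm[nrow(tr)] - test_rest[["Vm"]]), 1)
  expect_lt(abs(tr$Vm[which.min(abs(tr$time - 500))] - test_rest[["Vm"]]), 2)
  # gates never leave [0, 1] (and by construction were never clamped)
  for (g in c("m", "h", "d", "f", "x1"))
    expect_true(all(tr[[g]] >= 0 & tr[[g]] <= 1))
  # strictly increasing Vm while the strong stimulus is on
  during <- tr$Vm[tr$time >= 2 & tr$time <= 3]
  expect_true(all(diff(during) > 0))
})

test_that("determinism: identical inputs give bit-identical trajectories", {
  st <- membrane_state(Vm = -60, m = 0.1, h = 0.8, j = 0.9, d = 0.1,
                       f = 0.9, x1 = 0.05, Cai = 2e-7)
  t1 <- run_single_cell(test_ionic, duration = 5, dt = 0.01, state = st)
  t2 <- run_single_cell(test_ionic, duration = 5, dt = 0.01, state = st)
  expect_identical(t1, t2)
})

test_that("degenerate parameter sets are rejected", {
  st <- membrane_state(Vm = -80, m = 0, h = 1, j = 1, d = 0, f = 1, x1 = 0,
                       Cai = 1e-7)
  expect_error(single_cell_step(st, test_ionic, 0, dt = -1), "positive")
  expect_error(membrane_state(Vm = -80, m = 2, h = 1, j = 1, d = 0, f = 1,
                              x1 = 0, Cai = 1e-7), "\\[0, 1\\]")
  expect_error(membrane_state(Vm = -80, m = 1, h = 1, j = 1, d = 0, f = 1,
                              x1 = 0, Cai = 0), "Cai")
  expect_error(ionic_params(g_Na = -1), "non-negative")
})
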