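# Tissue time loop: initialization, stimulus semantics, backend
# equivalence, determinism, and protocol presets.

test_that("init_tissue broadcasts the single-cell rest state", {
  cfg <- quick_config()
  st <- init_tissue(cfg)
  expect_true(all(st$vm == test_rest[["Vm"]]))
  for (g in c("m", "h", "j", "d", "f", "x1"))
    expect_true(all(st[[g]] == test_rest[[g]]))
  expect_true(all(st$cai == test_rest[["Cai"]]))
  expect_identical(st$step, 0L)
})

test_that("resting tissue stays quiescent without stimulation", {
  cfg <- quick_config(duration = 10)
  res <- run_sim(cfg)
  expect_lt(max(abs(res$final_state$vm - test_rest[["Vm"]])), 1e-3)
  one <- step_tissue(init_tissue(cfg), cfg)
  expect_lt(max(abs(one$vm - test_rest[["Vm"]])), 1e-9)
})

test_that("run bookkeeping: steps, trace length, node updates", {
  cfg <- quick_config(duration = 1)
  res <- run_sim(cfg)
  expect_identical(res$perf$steps, 100L)
  expect_identical(nrow(res$trace), 101L)
  expect_identical(res$perf$node_updates, 100 * 16 * 16)
  expect_identical(length(res$snapshot_times), 2L)  # t = 0 and t = 1
})

test_that("zero-diffusion uniform tissue reproduces the single cell bit-for-bit", {
  g <- grid2d(6, 6)
  cfg <- sim_config(g, fiber_field(0, 0, 0), test_ionic, dt = 0.01,
                    duration = 20, stimuli = list(uniform_stim(g)),
                    record_snapshots = FALSE)
  res <- run_sim(cfg)
  cell <- run_single_cell(test_ionic, duration = 20, dt = 0.01,
                          state = test_rest,
                          stim = data.frame(t_start = 0, t_end = 2,
                                            amplitude = 60))
  expect_identical(res$trace$vm_mV, cell$Vm)
  # every node identical (tissue of independent cells)
  expect_identical(max(res$final_state$vm), min(res$final_state$vm))
  expect_identical(res$final_state$vm[1, 1], cell$Vm[nrow(cell)])
})

test_that("within one step, node updates depend only on pre-step values", {
  g <- grid2d(12, 12)
  cfg <- sim_config(g, fiber_field(0.5, 0.001, 2e-4), test_ionic,
                    dt = 0.01, duration = 1)
  pre <- make_fixture("random", g, seed = 21)
  post <- step_tissue(pre, cfg, n = 1L)
  w <- stencil_weights(tensor_from_fibers(0.5, 0.001, 2e-4), g)
  diff <- apply_diffusion_gather(pre$vm, w)
  for (node in list(c(1, 1), c(6, 7), c(12, 12), c(1, 12))) {
    y <- node[1]; x <- node[2]
    st <- membrane_state(Vm = pre$vm[y, x], m = pre$m[y, x], h = pre$h[y, x],
                         j = pre$j[y, x], d = pre$d[y, x], f = pre$f[y, x],
                         x1 = pre$x1[y, x], Cai = pre$cai[y, x])
    iso <- r_cell_step(st, test_ionic, I_stim = 0, dt = 0.01,
                       diff = diff[y, x])
    expect_lt(abs(post$vm[y, x] - iso[["Vm"]]), 1e-12)
    expect_lt(abs(post$cai[y, x] - iso[["Cai"]]), 1e-18)
  }
})

test_that("stimulus windows, regions and overlap follow the contract", {
  g <- grid2d(8, 8)
  e1 <- stim_event(region = c(0, 8, 0, 8), amplitude = 30, t_start = 1,
                   t_end = 3)
  e2 <- stim_event(region = c(0, 4, 0, 8), amplitude = 10, t_start = 2,
                   t_end = 4)
  expect_true(all(apply_stimulus(list(e1, e2), 0.5, g) == 0))
  expect_true(all(apply_stimulus(list(e1), 1, g) == 30))
  both <- apply_stimulus(list(e1, e2), 2.5, g)
  expect_true(all(both[, 1:4] == 40))
  expect_true(all(both[, 5:8] == 30))
  # half-open in time: t_end excluded
  expect_true(all(apply_stimulus(list(e1), 3, g) == 0))
  expect_error(stim_event(region = c(0, 0, 0, 8), amplitude = 1,
                          t_start = 0, t_end = 1), "region")
})

test_that("auto-triggered S2 latches exactly once, at repolarization", {
  g <- grid2d(16, 16)
  s1 <- stim_event(region = c(0, 16, 0, 16), amplitude = 60, t_start = 1,
                   t_end = 3)
  s2 <- stim_event(region = c(0, 8, 0, 8), amplitude = 40, trigger = "auto",
                   monitor = c(8, 8), threshold = -50, duration = 2)
  p4 <- ionic_params(rate_scale = c(d = 4, f = 4, x1 = 4))
  cfg <- sim_config(g, fiber_field(0, 0, 0), p4, dt = 0.01, duration = 250,
                    stimuli = list(s1, s2), probe = c(8, 8),
                    record_snapshots = FALSE)
  res <- run_sim(cfg)
  ev <- res$config$stimuli[[2]]
  expect_true(isTRUE(ev$latched))
  # latch time equals the probe trace's first downward crossing of -50 mV
  v <- res$trace$vm_mV
  below <- which(v[-1] <= -50 & v[-length(v)] > -50)
  expect_equal(ev$t_start, res$trace$time_ms[below[1] + 1],
               tolerance = 1e-9)
  expect_equal(ev$t_end, ev$t_start + 2, tolerance = 1e-12)
  # the S2 should re-excite the monitored half: later crossings exist but
  # the latched window must not move when the run is replayed
  res2 <- run_sim(cfg)
  expect_identical(res2$config$stimuli[[2]]$t_start, ev$t_start)
})

test_that("all read-only backends agree bitwise; scatter to rounding", {
  g <- grid2d(16, 16)
  cfg <- sim_config(g, fiber_field(pi / 6, 0.001, 2e-4), test_ionic,
                    dt = 0.01, duration = 3,
                    stimuli = list(stim_event(region = c(0, 3, 0, 16),
                                              amplitude = 60, t_start = 0,
                                              t_end = 2)))
  eq <- run_equivalence(cfg, list("reference", "gather", "scatter",
                                  list(backend = "tiled", tile_x = 5,
                                       tile_y = 3),
                                  list(backend = "tiled", tile_x = 16,
                                       tile_y = 2),
                                  list(backend = "parallel", workers = 2),
                                  list(backend = "parallel", workers = 4)))
  expect_true(all(eq$pass))
  ro <- !grepl("scatter", paste(eq$backend_a, eq$backend_b))
  expect_true(all(eq$max_abs_diff_mV[ro] == 0))
  expect_true(all(eq$max_abs_diff_mV < 1e-9))
})

test_that("a tissue of uncoupled nodes runs nine independent cells", {
  g <- grid2d(3, 3)
  cfg <- sim_config(g, fiber_field(0, 0, 0), test_ionic, dt = 0.01,
                    duration = 5, stimuli = list(uniform_stim(g)),
                    probe = c(1, 1), record_snapshots = FALSE)
  res <- run_sim(cfg)
  cell <- run_single_cell(test_ionic, duration = 5, dt = 0.01,
                          state = test_rest,
                          stim = data.frame(t_start = 0, t_end = 2,
                                            amplitude = 60))
  expect_identical(res$trace$vm_mV, cell$Vm)
  expect_true(all(res$final_state$vm == cell$Vm[nrow(cell)]))
})

test_that("halving dt moves the far-edge activation time only slightly", {
  run_at <- function(dt) {
    cfg <- make_protocol("plane_wave", grid = grid2d(32, 16),
                         dt = dt, duration = 25)
    m <- activation_map(run_sim(cfg))
    m[8, 32]
  }
  t1 <- run_at(0.01)
  t2 <- run_at(0.005)
  expect_false(is.na(t1) || is.na(t2))
  expect_lt(abs(t1 - t2), 1)   # first-order trend, loose bound
})

test_that("protocol presets build valid configs with the documented differences", {
  pw <- make_protocol("plane_wave")
  expect_s3_class(validate_config(pw), "cw_config")
  expect_length(pw$stimuli, 1)
  rot <- make_protocol("single_rotor", grid = grid2d(48, 48),
                       duration = 50)
  brk <- make_protocol("breakup", grid = grid2d(48, 48), duration = 50)
  expect_identical(rot$grid, brk$grid)
  expect_identical(lapply(rot$stimuli, `[[`, "region"),
                   lapply(brk$stimuli, `[[`, "region"))
  # differ in fibers/diffusion and kinetics speed-up only
  expect_false(isTRUE(all.equal(rot$fibers, brk$fibers)))
  expect_identical(unname(rot$ionic$rate_scale[c("d", "f", "x1")]),
                   c(4, 4, 4))
  expect_identical(unname(brk$ionic$rate_scale[c("d", "f", "x1")]),
                   c(2, 2, 2))
  expect_error(make_protocol("spiral"), "arg")
})

test_that("the autotuner checks correctness first and keeps its books", {
  cfg <- quick_config(duration = 1)
  tuned <- autotune_tiles(cfg, list(c(4, 4)), steps = 20, check_steps = 10)
  expect_identical(tuned$best, c(4L, 4L))
  expect_identical(nrow(tuned$table), 1L)
  tuned2 <- autotune_tiles(cfg, list(c(4, 4), c(16, 2), c(2, 16)),
                           steps = 20, check_steps = 10)
  expect_identical(nrow(tuned2$table), 3L)
  expect_true(all(tuned2$equivalence$pass))
  expect_true(all(tuned2$equivalence$max_abs_diff_mV == 0))
})

test_that("instability is reported with step, node and last snapshot", {
  g <- grid2d(8, 8)
  cfg <- sim_config(g, fiber_field(0, 0.001, 2e-4), test_ionic, dt = 0.01,
                    duration = 5,
                    stimuli = list(stim_event(region = c(0, 8, 0, 8),
                                              amplitude = 1e5,
                                              t_start = 0, t_end = 5)))
  err <- tryCatch(run_sim(cfg), cw_instability = function(e) e)
  expect_s3_class(err, "cw_instability")
  expect_match(conditionMessage(err), "step")
  expect_match(conditionMessage(err), "node")
  expect_false(is.null(err$result))
})

test_that("config invariants are enforced with named errors", {
  g <- grid2d(8, 8)
  expect_error(sim_config(g, dt = 1), "dt")
  expect_error(sim_config(g, backend = "cuda"), "backend")
  expect_error(sim_config(g, probe = c(20, 2)), "probe")
  expect_error(sim_config(g, duration = -1), "duration")
  expect_error(grid2d(2, 8), "3 x 3")
})
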