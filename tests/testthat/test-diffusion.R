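# Fiber-rotated tensor, 9-point stencil, no-flux padding, gather/scatter
# kernels, and the explicit-Euler stability bound.

test_that("fiber rotation produces the expected tensors", {
  t0 <- tensor_from_fibers(0, 1, 0.2)
  expect_equal(c(t0$Dxx, t0$Dyy, t0$Dxy), c(1, 0.2, 0))
  t90 <- tensor_from_fibers(pi / 2, 1, 0.2)
  expect_equal(c(t90$Dxx, t90$Dyy), c(0.2, 1), tolerance = 1e-12)
  t45 <- tensor_from_fibers(pi / 4, 1, 0.2)
  expect_equal(c(t45$Dxx, t45$Dyy, t45$Dxy), c(0.6, 0.6, 0.4),
               tolerance = 1e-12)
  # trace preserved under any rotation
  for (th in seq(0, pi, length.out = 11)) {
    tt <- tensor_from_fibers(th, 1, 0.2)
    expect_equal(tt$Dxx + tt$Dyy, 1.2, tolerance = 1e-12)
    expect_gte(tt$Dxx * tt$Dyy - tt$Dxy^2, -1e-15)
  }
  expect_error(tensor_from_fibers(0, 0.2, 1), "anisotropy")
})

test_that("stencil weights: classic Laplacian, zero sum, cross-derivative corners", {
  g1 <- grid2d(8, 8, dx = 1, dy = 1)
  w <- stencil_weights(tensor_from_fibers(0, 1, 1), g1)
  expect_equal(as.numeric(w), c(0, 1, 0, 1, -4, 1, 0, 1, 0))

  wc <- stencil_weights(structure(list(Dxx = 1, Dyy = 1, Dxy = 0.4),
                                  class = "cw_tensor"), g1)
  # NE and SW corners +0.2, NW and SE -0.2
  expect_equal(wc[3, 3], 0.2); expect_equal(wc[1, 1], 0.2)
  expect_equal(wc[3, 1], -0.2); expect_equal(wc[1, 3], -0.2)

  set.seed(5)
  for (i in 1:20) {
    th <- runif(1, 0, pi); dpar <- runif(1, 1e-4, 2e-3)
    dperp <- runif(1, 0, 1) * dpar
    grid <- grid2d(8, 8, dx = runif(1, 0.01, 0.05), dy = runif(1, 0.01, 0.05))
    ww <- stencil_weights(tensor_from_fibers(th, dpar, dperp), grid)
    expect_lt(abs(sum(ww)) / max(abs(ww)), 1e-12)
    # 180-degree rotation symmetry
    expect_identical(as.numeric(ww), rev(as.numeric(ww)))
  }
})

test_that("no-flux padding follows its reflection conventions", {
  m <- matrix(as.numeric(1:9), 3, 3)
  pf <- pad_noflux(m, type = "face")
  expect_equal(pf[2:4, 1], m[, 1])        # ghost west = edge column
  expect_equal(pf[1, 2:4], m[1, ])
  expect_equal(pf[1, 1], m[1, 1])         # diagonal corner mirror
  pn <- pad_noflux(m, type = "node")
  expect_equal(pn[2:4, 1], m[, 2])        # ghost west = interior column 1
  expect_equal(pn[1, 1], m[2, 2])
  # constant field pads to a constant, interior untouched either way
  cm <- matrix(7, 4, 5)
  for (ty in c("face", "node")) {
    p <- pad_noflux(cm, type = ty)
    expect_true(all(p == 7))
    expect_identical(p[2:5, 2:6], cm)
  }
})

test_that("gather: zero on uniform fields, impulse response, matches R oracle", {
  g1 <- grid2d(7, 7, dx = 1, dy = 1)
  w <- stencil_weights(tensor_from_fibers(0, 1, 1), g1)
  u <- matrix(-84, 7, 7)
  expect_true(all(apply_diffusion_gather(u, w) == 0))

  imp <- matrix(0, 7, 7); imp[4, 4] <- 1
  out <- apply_diffusion_gather(imp, w)
  expect_equal(out[4, 4], -4)
  expect_equal(out[4, 3] + out[4, 5] + out[3, 4] + out[5, 4], 4)
  expect_equal(sum(out != 0), 5)

  set.seed(7)
  wa <- stencil_weights(tensor_from_fibers(0.6, 0.001, 2e-4),
                        grid2d(6, 9, dx = 0.025, dy = 0.03))
  vm <- matrix(runif(54, -90, 20), 9, 6)
  expect_lt(max(abs(apply_diffusion_gather(vm, wa) - r_diffusion(vm, wa))),
            1e-12)
  expect_lt(max(abs(apply_diffusion_gather(vm, wa, pad_type = "node") -
                      r_diffusion(vm, wa, pad_type = "node"))), 1e-12)
})

test_that("scatter equals gather to accumulation-order rounding on seeded grids", {
  g <- grid2d(24, 24)
  w <- stencil_weights(tensor_from_fibers(pi / 5, 0.001, 2e-4), g)
  scale <- max(abs(w))
  for (seed in 1:100) {
    set.seed(seed)
    vm <- matrix(runif(24 * 24, -90, 20), 24, 24)
    d <- max(abs(apply_diffusion_gather(vm, w) -
                   apply_diffusion_scatter(vm, w)))
    expect_lt(d, 1e-9)
  }
  # impulse pattern identical between formulations
  imp <- matrix(0, 24, 24); imp[12, 12] <- 1
  expect_equal(apply_diffusion_scatter(imp, w),
               apply_diffusion_gather(imp, w), tolerance = 1e-14)
})

test_that("axis-aligned diffusion with face padding conserves the total", {
  g <- grid2d(20, 20)
  w <- stencil_weights(tensor_from_fibers(0, 0.001, 2e-4), g)
  for (seed in 1:25) {
    set.seed(seed)
    vm <- matrix(runif(400, -90, 20), 20, 20)
    out <- apply_diffusion_gather(vm, w)
    expect_lt(abs(sum(out)) / sum(abs(out)), 1e-9)
  }
})

test_that("maximum principle holds for a stable axis-aligned Euler step", {
  g <- grid2d(16, 16)
  tn <- tensor_from_fibers(0, 0.001, 2e-4)
  w <- stencil_weights(tn, g)
  dt <- 0.95 * cfl_max_dt(tn, g)
  set.seed(3)
  vm <- matrix(runif(256, -90, 20), 16, 16)
  out <- run_diffusion_euler(vm, w, dt, steps = 20)
  expect_gte(min(out), min(vm))
  expect_lte(max(out), max(vm))
})

test_that("rotating fibers by 90 degrees transposes the operator", {
  gx <- grid2d(10, 6, dx = 0.025, dy = 0.025)
  gy <- grid2d(6, 10, dx = 0.025, dy = 0.025)
  w0 <- stencil_weights(tensor_from_fibers(0, 0.001, 2e-4), gx)
  w90 <- stencil_weights(tensor_from_fibers(pi / 2, 0.001, 2e-4), gy)
  set.seed(9)
  vm <- matrix(runif(60, -90, 20), 6, 10)   # ny = 6, nx = 10
  a <- apply_diffusion_gather(vm, w0)
  b <- apply_diffusion_gather(t(vm), w90)
  expect_lt(max(abs(t(b) - a)), 1e-12)
})

test_that("left-right symmetric fields stay symmetric under isotropic diffusion", {
  g <- grid2d(12, 12)
  w <- stencil_weights(tensor_from_fibers(0, 0.001, 0.001), g)
  vm <- make_fixture("symmetric", g, seed = 4)$vm
  cur <- vm
  for (i in 1:50) {
    cur <- cur + 0.01 * apply_diffusion_gather(cur, w)
    expect_identical(cur, cur[, ncol(cur):1])
  }
})

test_that("the stability bound follows its closed form", {
  g1 <- grid2d(8, 8, dx = 1, dy = 1)
  expect_equal(cfl_max_dt(tensor_from_fibers(0, 1, 1), g1), 0.25)
  expect_equal(cfl_max_dt(structure(list(Dxx = 1, Dyy = 1, Dxy = 0.5),
                                    class = "cw_tensor"), g1), 0.2)
  # doubling dx relaxes the bound
  tn <- tensor_from_fibers(0.3, 0.001, 2e-4)
  expect_gt(cfl_max_dt(tn, grid2d(8, 8, dx = 0.05, dy = 0.025)),
            cfl_max_dt(tn, grid2d(8, 8, dx = 0.025, dy = 0.025)))
  expect_identical(cfl_max_dt(tensor_from_fibers(0, 0, 0), g1), Inf)
})
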