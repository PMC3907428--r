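# Anisotropic diffusion on a rectilinear grid: fiber-rotated tensor,
# 9-point stencil, no-flux ghost frame, explicit-Euler stability bound.

#' Rectilinear 2D grid
#'
#' @param nx,ny node counts (each at least 3).
#' @param dx,dy node spacing, cm.
#' @return object of class `cw_grid`.
#' @export
grid2d <- function(nx, ny, dx = 0.025, dy = dx) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 3 || ny < 3) stop("grid must be at least 3 x 3 nodes")
  if (dx <= 0 || dy <= 0) stop("node spacing must be positive")
  structure(list(nx = nx, ny = ny, dx = dx, dy = dy), class = "cw_grid")
}

#' Fiber field
#'
#' Uniform or per-node fiber orientation with along/across-fiber diffusion
#' coefficients.
#'
#' @param theta fiber angle, radians, measured from the x axis; a scalar
#'   or an `ny x nx` matrix for per-node orientation.
#' @param D_par,D_perp diffusion coefficients along and across fibers,
#'   cm^2/ms; must satisfy `D_par >= D_perp >= 0`.
#' @return object of class `cw_fibers`.
#' @export
fiber_field <- function(theta = 0, D_par = 0.001, D_perp = D_par) {
  if (D_perp > D_par)
    stop("invalid anisotropy: D_perp must not exceed D_par")
  if (D_perp < 0) stop("diffusion coefficients must be non-negative")
  structure(list(theta = theta, D_par = D_par, D_perp = D_perp),
            class = "cw_fibers")
}

#' Fiber-rotated diffusion tensor
#'
#' Rotates the diagonal tensor `diag(D_par, D_perp)` by the fiber angle:
#' `Dxx = D_par cos^2(t) + D_perp sin^2(t)`,
#' `Dyy = D_par sin^2(t) + D_perp cos^2(t)`,
#' `Dxy = (D_par - D_perp) sin(t) cos(t)`.  The trace `Dxx + Dyy`
#' equals `D_par + D_perp` and the tensor is positive semidefinite.
#'
#' @param theta fiber angle, radians (scalar or matrix).
#' @param D_par,D_perp along/across-fiber coefficients, cm^2/ms.
#' @return list of class `cw_tensor` with fields `Dxx`, `Dyy`, `Dxy`
#'   (scalars, or matrices when `theta` is a matrix).
#' @export
tensor_from_fibers <- function(theta, D_par, D_perp) {
  if (D_perp > D_par)
    stop("invalid anisotropy: D_perp must not exceed D_par")
  if (D_perp < 0) stop("diffusion coefficients must be non-negative")
  ct <- cos(theta); st <- sin(theta)
  structure(list(Dxx = D_par * ct^2 + D_perp * st^2,
                 Dyy = D_par * st^2 + D_perp * ct^2,
                 Dxy = (D_par - D_perp) * st * ct),
            class = "cw_tensor")
}

as_tensor <- function(x) {
  if (inherits(x, "cw_tensor")) return(x)
  if (inherits(x, "cw_fibers"))
    return(tensor_from_fibers(x$theta, x$D_par, x$D_perp))
  stop("expected a cw_tensor or cw_fibers object")
}

#' 9-point stencil weights for an anisotropic diffusion tensor
#'
#' Centered second differences for the axis terms and the standard
#' 4-corner centered cross-derivative: east/west weights `Dxx/dx^2`,
#' north/south `Dyy/dy^2`, corners `+Dxy/(2 dx dy)` on NE/SW and
#' `-Dxy/(2 dx dy)` on NW/SE, center `-2 Dxx/dx^2 - 2 Dyy/dy^2`.  The
#' weights sum to zero and are symmetric under 180-degree rotation.
#'
#' @param tensor a scalar-field [tensor_from_fibers()] (or a
#'   [fiber_field()] with scalar `theta`).
#' @param grid a [grid2d()].
#' @return 3 x 3 matrix of class `cw_stencil`; rows index the y offset
#'   (-1, 0, +1), columns the x offset.  Units: ms^-1 when applied to mV.
#' @export
stencil_weights <- function(tensor, grid) {
  tensor <- as_tensor(tensor)
  if (length(tensor$Dxx) != 1)
    stop("stencil_weights expects a uniform tensor; per-node fields are ",
         "expanded internally by the simulator")
  wx <- tensor$Dxx / grid$dx^2
  wy <- tensor$Dyy / grid$dy^2
  wc <- tensor$Dxy / (2 * grid$dx * grid$dy)
  w <- matrix(c(wc,  wx, -wc,   # x offset -1: SW, W, NW
                wy, -2 * wx - 2 * wy, wy,  # x offset 0: S, C, N
                -wc, wx,  wc),  # x offset +1: SE, E, NE
              nrow = 3, ncol = 3)
  dimnames(w) <- list(y_offset = c("-1", "0", "+1"),
                      x_offset = c("-1", "0", "+1"))
  class(w) <- c("cw_stencil", "matrix", "array")
  w
}

# 9 x 1 (uniform) or 9 x (nx*ny) weight pack for the C++ kernels
.stencil_pack <- function(fibers, grid) {
  if (length(fibers$theta) == 1) {
    w <- stencil_weights(fibers, grid)
    return(matrix(as.numeric(w), 9, 1))
  }
  th <- fibers$theta
  if (!is.matrix(th) || nrow(th) != grid$ny || ncol(th) != grid$nx)
    stop("per-node theta must be an ny x nx matrix")
  out <- matrix(0, 9, grid$nx * grid$ny)
  for (x in seq_len(grid$nx)) {
    for (y in seq_len(grid$ny)) {
      tn <- tensor_from_fibers(th[y, x], fibers$D_par, fibers$D_perp)
      out[, (x - 1) * grid$ny + y] <-
        as.numeric(stencil_weights(tn, grid))
    }
  }
  out
}

.weights_arg <- function(w) {
  if (is.matrix(w) && nrow(w) == 3 && ncol(w) == 3)
    return(matrix(as.numeric(w), 9, 1))
  if (is.matrix(w) && nrow(w) == 9) return(w)
  stop("weights must be a 3 x 3 stencil or a 9 x n weight pack")
}

#' Ghost-cell padding implementing no-flux boundaries
#'
#' Surrounds an `ny x nx` grid with a one-cell ghost frame.  `type
#' "face"` reflects about the boundary face (ghost = edge value), which
#' makes the discrete diffusion operator conserve the plain sum of the
#' field exactly and is what the simulator uses.  `type "node"` reflects
#' about the boundary node (ghost = first interior neighbour), the
#' textbook centered zero-gradient closure.  Corner ghosts mirror
#' diagonally; the interior is untouched.
#'
#' @param vm `ny x nx` numeric matrix (mV).
#' @param type ghost reflection convention.
#' @return `(ny+2) x (nx+2)` matrix.
#' @export
pad_noflux <- function(vm, type = c("face", "node")) {
  type <- match.arg(type)
  ny <- nrow(vm); nx <- ncol(vm)
  out <- matrix(0, ny + 2, nx + 2)
  out[2:(ny + 1), 2:(nx + 1)] <- vm
  k <- if (type == "face") 1L else 2L
  out[1, 2:(nx + 1)] <- vm[k, ]
  out[ny + 2, 2:(nx + 1)] <- vm[ny + 1 - k, ]
  out[2:(ny + 1), 1] <- vm[, k]
  out[2:(ny + 1), nx + 2] <- vm[, nx + 1 - k]
  out[1, 1] <- vm[k, k]
  out[1, nx + 2] <- vm[k, nx + 1 - k]
  out[ny + 2, 1] <- vm[ny + 1 - k, k]
  out[ny + 2, nx + 2] <- vm[ny + 1 - k, nx + 1 - k]
  out
}

#' Apply the diffusion operator (gather formulation)
#'
#' Each node reads its padded 3 x 3 neighbourhood and accumulates the
#' weighted sum; no cross-node writes, so the result is independent of
#' traversal order.
#'
#' @param vm `ny x nx` matrix of potentials, mV.
#' @param w stencil weights ([stencil_weights()] or a 9 x n pack).
#' @param pad_type ghost reflection convention (see [pad_noflux()]).
#' @return `ny x nx` matrix of `dVm/dt` contributions, mV/ms.
#' @export
apply_diffusion_gather <- function(vm, w, pad_type = c("face", "node")) {
  pad_type <- match.arg(pad_type)
  cpp_apply_diffusion(vm, .weights_arg(w), 0L,
                      if (pad_type == "face") 0L else 1L)
}

#' Apply the diffusion operator (scatter formulation)
#'
#' Each node (including ghosts) accumulates its contribution into itself
#' and its 8 neighbours in fixed column-major source order.
#' Mathematically equal to [apply_diffusion_gather()]; kept as the
#' cross-check oracle for the neighbour-update-free gather transformation
#' (differences are accumulation-order rounding only).
#'
#' @inheritParams apply_diffusion_gather
#' @return `ny x nx` matrix of `dVm/dt` contributions, mV/ms.
#' @export
apply_diffusion_scatter <- function(vm, w, pad_type = c("face", "node")) {
  pad_type <- match.arg(pad_type)
  cpp_apply_diffusion(vm, .weights_arg(w), 1L,
                      if (pad_type == "face") 0L else 1L)
}

#' Explicit-Euler stability bound for the 9-point scheme
#'
#' Conservative CFL-type bound
#' `dt_max = 1 / (2 (Dxx/dx^2 + Dyy/dy^2 + |Dxy|/(dx dy)))`; for a
#' per-node tensor the minimum over nodes is returned.  An all-zero
#' tensor yields `Inf`.
#'
#' @param tensor a [tensor_from_fibers()] or [fiber_field()].
#' @param grid a [grid2d()].
#' @return maximum stable time step, ms.
#' @export
cfl_max_dt <- function(tensor, grid) {
  tensor <- as_tensor(tensor)
  den <- 2 * (tensor$Dxx / grid$dx^2 + tensor$Dyy / grid$dy^2 +
                abs(tensor$Dxy) / (grid$dx * grid$dy))
  den <- max(den)
  if (den == 0) return(Inf)
  1 / den
}

#' Euler integration of the diffusion operator alone
#'
#' Advances `vm' = vm + dt * L(vm)` for a fixed number of steps with no
#' membrane kinetics; used for stability and maximum-principle checks.
#'
#' @inheritParams apply_diffusion_gather
#' @param dt time step, ms.
#' @param steps number of Euler steps.
#' @return `ny x nx` matrix after `steps` steps.
#' @export
run_diffusion_euler <- function(vm, w, dt, steps,
                                pad_type = c("face", "node")) {
  pad_type <- match.arg(pad_type)
  wp <- .weights_arg(w)
  pt <- if (pad_type == "face") 0L else 1L
  for (i in seq_len(steps))
    vm <- vm + dt * cpp_apply_diffusion(vm, wp, 0L, pt)
  vm
}

#' @export
print.cw_grid <- function(x, ...) {
  cat(sprintf("grid: %d x %d nodes, dx %.4g cm, dy %.4g cm (%.3g x %.3g cm)\n",
              x$nx, x$ny, x$dx, x$dy, x$nx * x$dx, x$ny * x$dy))
  invisible(x)
}

#' @export
print.cw_fibers <- function(x, ...) {
  th <- if (length(x$theta) == 1)
    sprintf("%.4g rad (%.1f deg)", x$theta, x$theta * 180 / pi)
  else "per-node field"
  cat(sprintf("fibers: theta %s, D_par %.4g, D_perp %.4g cm^2/ms\n",
              th, x$D_par, x$D_perp))
  invisible(x)
}
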