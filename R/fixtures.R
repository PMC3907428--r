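# Deterministic test-surface generators: tissue states with controlled
# structure (impulse, excited strip, seeded random, mirrored random).

#' Generate a deterministic tissue fixture
#'
#' All fixtures start from the broadcast rest state and perturb only
#' `Vm`; gates and calcium stay at rest.  The generator is deterministic
#' for a given `(kind, grid, seed)` and restores the caller's RNG state.
#'
#' * `impulse` - one node (domain center) set to 0 mV.
#' * `plane` - an excited 5-column strip (0 mV) at the left edge.
#' * `random` - `Vm` drawn uniformly from \[-90, 20\] mV.
#' * `symmetric` - `random`, mirrored left-right (columns `x` and
#'   `nx-1-x` equal).
#'
#' @param kind fixture kind.
#' @param grid a [grid2d()].
#' @param seed RNG seed for the random kinds.
#' @param ionic an [ionic_params()] for the rest state.
#' @return a `cw_state`.
#' @export
make_fixture <- function(kind = c("impulse", "plane", "random", "symmetric"),
                         grid, seed = 1L, ionic = ionic_params()) {
  kind <- match.arg(kind)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  rest <- find_rest_state(ionic)
  grids <- lapply(c("Vm", .cw_gates, "Cai"), function(v)
    matrix(rest[[v]], grid$ny, grid$nx))
  names(grids) <- c("vm", .cw_gates, "cai")
  nx <- grid$nx; ny <- grid$ny
  grids$vm <- switch(kind,
    impulse = {
      v <- grids$vm
      v[ny %/% 2 + 1, nx %/% 2 + 1] <- 0
      v
    },
    plane = {
      v <- grids$vm
      v[, 1:min(5, nx)] <- 0
      v
    },
    random = matrix(runif(nx * ny, -90, 20), ny, nx),
    symmetric = {
      half <- ceiling(nx / 2)
      left <- matrix(runif(half * ny, -90, 20), ny, half)
      v <- matrix(0, ny, nx)
      v[, 1:half] <- left
      v[, nx:(nx - half + 1)] <- left
      v
    })
  structure(c(grids, list(time = 0, step = 0L, grid = grid)),
            class = "cw_state")
}
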