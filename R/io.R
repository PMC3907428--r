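# Configuration files (flat key = value text), binary snapshot format,
# probe-trace CSV, and run manifests.

.cw_scalar_keys <- c(
  "nx", "ny", "dx", "dy", "theta", "d_par", "d_perp", "dt", "duration",
  "backend", "tile_x", "tile_y", "workers", "probe_x", "probe_y",
  "snapshot_every", "record_snapshots", "excite_threshold", "safety_factor",
  "constants_file", "use_j_gate", "scale_m", "scale_h", "scale_j",
  "scale_d", "scale_f", "scale_x1", "g_na", "e_na", "g_nac", "g_s", "c_m",
  "protocol", "s2_threshold", "seed")
.cw_stim_keys <- c("type", "t_start", "t_end", "x0", "x1", "y0", "y1",
                   "amplitude", "monitor_x", "monitor_y", "threshold",
                   "duration")

.parse_kv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  stripped <- trimws(sub("#.*$", "", lines))
  keep <- which(nzchar(stripped))
  kv <- list()
  for (i in keep) {
    m <- regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", stripped[i])[[1]]
    if (m[1] == -1)
      stop("config parse error at line ", i, ": '", lines[i], "'")
    key <- regmatches(stripped[i], list(m))[[1]][2]
    val <- trimws(regmatches(stripped[i], list(m))[[1]][3])
    if (!nzchar(val))
      stop("config parse error at line ", i, ": empty value for '", key, "'")
    if (!is.null(kv[[key]]))
      stop("duplicate config key at line ", i, ": '", key, "'")
    kv[[key]] <- val
  }
  kv
}

.num <- function(kv, key, default = NULL) {
  if (is.null(kv[[key]])) return(default)
  x <- suppressWarnings(as.numeric(kv[[key]]))
  if (is.na(x)) stop("config value for '", key, "' is not numeric: '",
                     kv[[key]], "'")
  x
}

.bool <- function(kv, key, default = NULL) {
  if (is.null(kv[[key]])) return(default)
  v <- tolower(kv[[key]])
  if (!v %in% c("true", "false", "yes", "no", "1", "0"))
    stop("config value for '", key, "' is not logical: '", kv[[key]], "'")
  v %in% c("true", "yes", "1")
}

# angles accepted in radians (bare number) or degrees ("45 deg")
.angle <- function(kv, key, default = NULL) {
  raw <- kv[[key]]
  if (is.null(raw)) return(default)
  m <- regexec("^(-?[0-9.eE+-]+)\\s*(deg|rad)?$", raw)[[1]]
  if (m[1] == -1) stop("config value for '", key, "' is not an angle: '",
                       raw, "'")
  parts <- regmatches(raw, list(m))[[1]]
  x <- suppressWarnings(as.numeric(parts[2]))
  if (is.na(x)) stop("config value for '", key, "' is not an angle: '",
                     raw, "'")
  if (identical(parts[3], "deg")) x * pi / 180 else x
}

#' Load a simulation configuration from a flat text file
#'
#' The format is `key = value`, one per line, `#` comments.  Unknown keys
#' are an error (no silent typos); missing keys take the documented
#' defaults; the assembled configuration is validated, so e.g. a `dt`
#' violating the stability bound is rejected at load time.  Stimuli are
#' given as `stim1.type = fixed`, `stim1.t_start = 0`, ... blocks;
#' angles accept a `deg` suffix.  A `protocol` key starts from the named
#' [make_protocol()] preset before applying overrides.
#'
#' @param path config file path.
#' @return a validated [sim_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  kv <- .parse_kv(path)
  keys <- names(kv)
  stim_key <- grepl("^stim[0-9]+\\.", keys)
  bad <- !(keys %in% .cw_scalar_keys) & !stim_key
  if (any(bad))
    stop("unknown config key: '", keys[bad][1], "'")
  sub_bad <- stim_key &
    !(sub("^stim[0-9]+\\.", "", keys) %in% .cw_stim_keys)
  if (any(sub_bad))
    stop("unknown config key: '", keys[sub_bad][1], "'")

  proto <- kv[["protocol"]]
  base <- if (!is.null(proto))
    make_protocol(proto,
                  s2_threshold = .num(kv, "s2_threshold", -50))
  else
    sim_config(grid2d(64, 64), validate = FALSE)

  g0 <- base$grid
  grid <- grid2d(.num(kv, "nx", g0$nx), .num(kv, "ny", g0$ny),
                 .num(kv, "dx", g0$dx), .num(kv, "dy", g0$dy))
  f0 <- base$fibers
  fibers <- fiber_field(.angle(kv, "theta", f0$theta),
                        .num(kv, "d_par", f0$D_par),
                        .num(kv, "d_perp", f0$D_perp))
  i0 <- base$ionic
  scale <- i0$rate_scale
  for (gname in .cw_gates) {
    v <- .num(kv, paste0("scale_", gname))
    if (!is.null(v)) scale[gname] <- v
  }
  ionic <- ionic_params(
    constants_file = if (!is.null(kv[["constants_file"]]))
      kv[["constants_file"]] else i0$constants_file,
    use_j_gate = .bool(kv, "use_j_gate", i0$use_j_gate),
    rate_scale = scale,
    g_Na = .num(kv, "g_na", i0$g_Na), E_Na = .num(kv, "e_na", i0$E_Na),
    g_NaC = .num(kv, "g_nac", i0$g_NaC), g_s = .num(kv, "g_s", i0$g_s),
    C_m = .num(kv, "c_m", i0$C_m))

  stim_ids <- unique(sub("\\..*$", "", keys[stim_key]))
  stimuli <- if (length(stim_ids)) {
    lapply(stim_ids[order(as.integer(sub("^stim", "", stim_ids)))],
           function(id) {
      sk <- function(f) kv[[paste0(id, ".", f)]]
      skn <- function(f) .num(kv, paste0(id, ".", f))
      type <- if (is.null(sk("type"))) "fixed" else sk("type")
      region <- c(skn("x0"), skn("x1"), skn("y0"), skn("y1"))
      if (any(vapply(region, is.null, TRUE)))
        stop("stimulus '", id, "' needs x0, x1, y0, y1")
      if (type == "fixed")
        stim_event(region = region, amplitude = skn("amplitude"),
                   t_start = skn("t_start"), t_end = skn("t_end"))
      else
        stim_event(region = region, amplitude = skn("amplitude"),
                   trigger = "auto",
                   monitor = c(skn("monitor_x"), skn("monitor_y")),
                   threshold = skn("threshold"),
                   duration = skn("duration"))
    })
  } else base$stimuli

  probe0 <- base$probe
  sim_config(
    grid = grid, fibers = fibers, ionic = ionic,
    dt = .num(kv, "dt", base$dt),
    duration = .num(kv, "duration", base$duration),
    stimuli = stimuli,
    backend = if (!is.null(kv[["backend"]])) kv[["backend"]] else
      base$backend,
    tile_x = .num(kv, "tile_x", base$tile_x),
    tile_y = .num(kv, "tile_y", base$tile_y),
    workers = .num(kv, "workers", base$workers),
    probe = c(.num(kv, "probe_x", probe0[1]),
              .num(kv, "probe_y", probe0[2])),
    snapshot_every = .num(kv, "snapshot_every", base$snapshot_every),
    record_snapshots = .bool(kv, "record_snapshots",
                             base$record_snapshots),
    excite_threshold = .num(kv, "excite_threshold",
                            base$excite_threshold),
    safety_factor = .num(kv, "safety_factor", base$safety_factor),
    seed = .num(kv, "seed", base$seed))
}

.fmt_num <- function(x) sprintf("%.17g", x)

#' Write a configuration back to the flat text format
#'
#' `load_config(dump_config(cfg))` reproduces an equal configuration.
#'
#' @param config a [sim_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  g <- config$grid; f <- config$fibers; i <- config$ionic
  ln <- c(
    "# cardiowave configuration",
    paste("nx =", g$nx), paste("ny =", g$ny),
    paste("dx =", .fmt_num(g$dx)), paste("dy =", .fmt_num(g$dy)),
    paste("theta =", .fmt_num(f$theta)),
    paste("d_par =", .fmt_num(f$D_par)),
    paste("d_perp =", .fmt_num(f$D_perp)),
    paste("dt =", .fmt_num(config$dt)),
    paste("duration =", .fmt_num(config$duration)),
    paste("backend =", config$backend),
    paste("tile_x =", config$tile_x), paste("tile_y =", config$tile_y),
    paste("workers =", config$workers),
    paste("probe_x =", config$probe[1]),
    paste("probe_y =", config$probe[2]),
    paste("snapshot_every =", .fmt_num(config$snapshot_every)),
    paste("record_snapshots =",
          tolower(as.character(config$record_snapshots))),
    paste("excite_threshold =", .fmt_num(config$excite_threshold)),
    paste("safety_factor =", .fmt_num(config$safety_factor)),
    paste("constants_file =", i$constants_file),
    paste("use_j_gate =", tolower(as.character(i$use_j_gate))),
    unlist(lapply(.cw_gates, function(gn)
      paste0("scale_", gn, " = ", .fmt_num(i$rate_scale[[gn]])))),
    paste("g_na =", .fmt_num(i$g_Na)), paste("e_na =", .fmt_num(i$E_Na)),
    paste("g_nac =", .fmt_num(i$g_NaC)), paste("g_s =", .fmt_num(i$g_s)),
    paste("c_m =", .fmt_num(i$C_m)))
  if (!is.null(config$seed)) ln <- c(ln, paste("seed =", config$seed))
  for (k in seq_along(config$stimuli)) {
    e <- config$stimuli[[k]]
    p <- sprintf("stim%d.", k)
    ln <- c(ln, paste0(p, "type = ", e$trigger),
            paste0(p, "x0 = ", e$region[1]), paste0(p, "x1 = ", e$region[2]),
            paste0(p, "y0 = ", e$region[3]), paste0(p, "y1 = ", e$region[4]),
            paste0(p, "amplitude = ", .fmt_num(e$amplitude)))
    if (e$trigger == "fixed") {
      ln <- c(ln, paste0(p, "t_start = ", .fmt_num(e$t_start)),
              paste0(p, "t_end = ", .fmt_num(e$t_end)))
    } else {
      ln <- c(ln, paste0(p, "monitor_x = ", e$monitor[1]),
              paste0(p, "monitor_y = ", e$monitor[2]),
              paste0(p, "threshold = ", .fmt_num(e$threshold)),
              paste0(p, "duration = ", .fmt_num(e$duration)))
    }
  }
  writeLines(ln, path)
  invisible(path)
}

# --- binary snapshot format -----------------------------------------------
# little-endian: magic "CWSNAP01" (8 bytes), int32 version, int32 nx,
# int32 ny, double dx, double dy, double time_ms, int32 name length, name
# bytes, then ny*nx float64 payload in row-major order (x fastest).

.cw_snap_magic <- charToRaw("CWSNAP01")

#' Write a grid snapshot
#'
#' Documented little-endian binary format with a self-describing header;
#' `read_snapshot(write_snapshot(...))` is bit-exact.
#'
#' @param vm `ny x nx` numeric matrix.
#' @param path output path.
#' @param grid the [grid2d()] the field lives on.
#' @param time simulation time, ms.
#' @param var variable name stored in the header.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(vm, path, grid, time = 0, var = "vm") {
  stopifnot(nrow(vm) == grid$ny, ncol(vm) == grid$nx)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(.cw_snap_magic, con)
  writeBin(1L, con, size = 4, endian = "little")
  writeBin(c(grid$nx, grid$ny), con, size = 4, endian = "little")
  writeBin(c(grid$dx, grid$dy, as.numeric(time)), con, size = 8,
           endian = "little")
  nm <- charToRaw(var)
  writeBin(length(nm), con, size = 4, endian = "little")
  writeBin(nm, con)
  writeBin(as.numeric(t(vm)), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a grid snapshot
#'
#' @param path snapshot file.
#' @return list with `data` (`ny x nx` matrix), `grid`, `time`, `var`.
#' @export
read_snapshot <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 8)
  if (length(magic) < 8 || !identical(magic, .cw_snap_magic))
    stop("snapshot format error: bad magic (not a cardiowave snapshot)")
  version <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (!identical(version, 1L))
    stop("snapshot format error: unsupported version ", version)
  dims <- readBin(con, "integer", n = 2, size = 4, endian = "little")
  meta <- readBin(con, "double", n = 3, size = 8, endian = "little")
  nlen <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  var <- rawToChar(readBin(con, "raw", n = nlen))
  n <- dims[1] * dims[2]
  payload <- readBin(con, "double", n = n, size = 8, endian = "little")
  if (length(payload) != n)
    stop("snapshot format error: truncated payload (", length(payload),
         " of ", n, " values)")
  list(data = t(matrix(payload, nrow = dims[1], ncol = dims[2])),
       grid = grid2d(dims[1], dims[2], meta[1], meta[2]),
       time = meta[3], var = var)
}

#' Write a probe trace as CSV
#'
#' Two columns `time_ms`, `vm_mV` at full double precision (17
#' significant digits), one row per step sample.
#'
#' @param trace data.frame with columns `time_ms`, `vm_mV` (a
#'   [run_sim()] result's `trace`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_probe_trace <- function(trace, path) {
  ln <- "time_ms,vm_mV"
  if (nrow(trace) > 0)
    ln <- c(ln, paste(.fmt_num(trace$time_ms), .fmt_num(trace$vm_mV),
                      sep = ","))
  writeLines(ln, path)
  invisible(path)
}

#' Write a run manifest
#'
#' JSON record sufficient to reproduce the run: the fully resolved
#' configuration (as the flat key = value pairs of [dump_config()]), the
#' md5 checksum of the constants table, the package version, timestamps
#' and the list of produced files (all of which must exist).
#'
#' @param path manifest path.
#' @param config the resolved [sim_config()].
#' @param files character vector of output files.
#' @param started,finished POSIXct timestamps.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, files,
                           started = Sys.time(), finished = Sys.time()) {
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("manifest refers to missing output file: ", missing[1])
  cfg_file <- tempfile(fileext = ".cfg")
  dump_config(config, cfg_file)
  cfg_lines <- readLines(cfg_file)
  unlink(cfg_file)
  obj <- list(
    format = "cardiowave-manifest",
    version = as.character(packageVersion("cardiowave")),
    constants_md5 = unname(tools::md5sum(config$ionic$constants_file)),
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(finished, "%Y-%m-%dT%H:%M:%S%z"),
    config = cfg_lines,
    outputs = basename(files))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# standard output set for run_sim(out_dir = ...): probe trace CSV, final
# Vm snapshot, manifest
.write_run_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  started <- Sys.time()
  trace_path <- file.path(out_dir, "probe_trace.csv")
  write_probe_trace(result$trace, trace_path)
  snap_path <- file.path(out_dir, "vm_final.snap")
  write_snapshot(result$final_state$vm, snap_path,
                 result$final_state$grid,
                 time = result$final_state$time, var = "vm")
  write_manifest(file.path(out_dir, "manifest.json"), result$config,
                 c(trace_path, snap_path), started = started)
  invisible(out_dir)
}
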