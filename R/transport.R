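# Finite-difference solver for Fick's second law on the heterogeneous device
# plan view:
#
#   dC/dt = div( D(x,y) grad C ) + S(x,y)
#
# on a uniform grid, with zero-flux outer boundaries, harmonic-mean face
# diffusivities (the conservative choice for piecewise-constant D), the
# endothelial monolayer as a membrane conductance K = D_b/h_b in series on
# the scaffold/bEC interface faces, distributed constant sources, and
# scheduled instantaneous medium-replacement events. Two time integrators:
# explicit FTCS (dt <= dx^2 / (4 D_max)) and implicit backward Euler
# (unconditionally stable; sparse Cholesky factorised once per step size).

#' Discretize a device layout onto a uniform grid
#'
#' Each cell takes the material of the region containing its centre. The
#' endothelial barrier is handled either as a membrane conductance on the
#' interface faces (`barrier_mode = "interface"`, default; works at any dx)
#' or as an explicit thin strip of barrier material
#' (`barrier_mode = "thin_region"`, requires `dx_um <=` barrier thickness).
#'
#' @param layout A `bbb_layout`.
#' @param dx_um Uniform grid spacing in micrometres; must be positive and
#'   no larger than the thinnest region.
#' @param barrier_mode `"interface"` or `"thin_region"`.
#' @param membrane_conductance Optional override of the membrane
#'   conductance in m/s (default `barrier_conductance(layout)`).
#' @return An object of class `bbb_grid` with `nx`, `ny`, `dx_um`,
#'   `material_map` and `region_map` (ny x nx integer matrices),
#'   `material_names`, `region_names`, and membrane bookkeeping.
#' @export
discretize <- function(layout, dx_um,
                       barrier_mode = c("interface", "thin_region"),
                       membrane_conductance = NULL) {
  barrier_mode <- match.arg(barrier_mode)
  cfg_error <- function(msg)
    stop(structure(class = c("bbb_config_error", "error", "condition"),
                   list(message = msg, call = NULL)))
  if (!is.numeric(dx_um) || length(dx_um) != 1L || dx_um <= 0)
    cfg_error("dx_um must be a single positive number")
  widths <- vapply(layout$regions, function(r) diff(r$x_range), numeric(1))
  if (dx_um > min(widths))
    cfg_error(sprintf("dx_um = %g exceeds the thinnest region (%g um)",
                      dx_um, min(widths)))
  if (barrier_mode == "thin_region" && dx_um > layout$barrier_thickness_um)
    cfg_error(sprintf(
      "dx_um = %g exceeds the barrier thickness (%g um); use barrier_mode = 'interface'",
      dx_um, layout$barrier_thickness_um))

  x0 <- layout$regions[[1]]$x_range[1]
  x1 <- layout$regions[[length(layout$regions)]]$x_range[2]
  yr <- layout$regions[[1]]$y_range
  nx <- as.integer(ceiling((x1 - x0) / dx_um))
  ny <- as.integer(ceiling(diff(yr) / dx_um))
  xc <- x0 + (seq_len(nx) - 0.5) * dx_um

  material_names <- names(layout$materials)
  region_names <- vapply(layout$regions, `[[`, character(1), "role")
  mat_col <- integer(nx)
  reg_col <- integer(nx)
  for (j in seq_len(nx)) {
    hit <- which(vapply(layout$regions, function(r)
      xc[j] >= r$x_range[1] && xc[j] < r$x_range[2], logical(1)))
    if (length(hit) == 0L) hit <- length(layout$regions)  # right edge cell
    reg_col[j] <- hit[1]
    mat_col[j] <- match(layout$regions[[hit[1]]]$material, material_names)
  }
  if (barrier_mode == "thin_region") {
    xb <- layout$barrier_interface
    in_barrier <- xc >= (xb - layout$barrier_thickness_um) & xc < xb
    mat_col[in_barrier] <- match("barrier", material_names)
  }
  material_map <- matrix(rep(mat_col, each = ny), nrow = ny)
  region_map <- matrix(rep(reg_col, each = ny), nrow = ny)

  membrane_face <- NA_integer_
  if (barrier_mode == "interface") {
    # face index j separates columns j and j+1; face x position = x0 + j*dx
    membrane_face <- as.integer(round((layout$barrier_interface - x0) / dx_um))
    if (membrane_face < 1L || membrane_face > nx - 1L)
      cfg_error("barrier interface does not fall between grid columns")
  }
  structure(list(
    dx_um = dx_um, nx = nx, ny = ny, x0_um = x0, y0_um = yr[1],
    material_map = material_map, region_map = region_map,
    material_names = material_names, region_names = region_names,
    layout = layout, barrier_mode = barrier_mode,
    membrane_face = membrane_face,
    membrane_conductance = membrane_conductance %||%
      barrier_conductance(layout)
  ), class = "bbb_grid")
}

#' @export
print.bbb_grid <- function(x, ...) {
  cat(sprintf("bbb_grid: %d x %d cells, dx = %g um, barrier mode '%s'",
              x$ny, x$nx, x$dx_um, x$barrier_mode))
  if (x$barrier_mode == "interface")
    cat(sprintf(" (K = %.3g m/s)", x$membrane_conductance))
  cat("\n")
  invisible(x)
}

#' Create a concentration field on a grid
#'
#' @param grid A `bbb_grid`.
#' @param initial_values Either a single value, a named vector/list of
#'   region role -> mol m^-3 (unlisted regions start at 0), or a full
#'   ny x nx matrix.
#' @param time Field time in seconds (default 0).
#' @return An object of class `bbb_field` (grid, values, time).
#' @export
concentration_field <- function(grid, initial_values = 0, time = 0) {
  v <- matrix(0, grid$ny, grid$nx)
  if (is.matrix(initial_values)) {
    stopifnot(all(dim(initial_values) == dim(v)))
    v[] <- initial_values
  } else if (!is.null(names(initial_values))) {
    for (role in names(initial_values)) {
      idx <- .region_cells(grid, role)
      v[idx] <- as.numeric(initial_values[[role]])
    }
  } else if (length(initial_values)) {
    v[] <- as.numeric(initial_values)
  }
  if (any(!is.finite(v)) || any(v < 0))
    stop("concentrations must be finite and non-negative", call. = FALSE)
  structure(list(grid = grid, values = v, time = time), class = "bbb_field")
}

.region_cells <- function(grid, role) {
  k <- match(role, grid$region_names)
  if (is.na(k))
    stop(sprintf("unknown region role '%s'", role), call. = FALSE)
  idx <- which(grid$region_map == k)
  if (length(idx) == 0L)
    stop(sprintf("region '%s' contains no grid cells", role), call. = FALSE)
  idx
}

# Face conductances (units 1/s: conductance-per-area / dx) for a solute.
.face_rates <- function(grid, solute_name) {
  dxm <- grid$dx_um * 1e-6
  D <- vapply(grid$material_names, function(m)
    lookup_diffusivity(m, solute_name, grid$layout$materials), numeric(1))
  Dmap <- matrix(D[grid$material_map], grid$ny, grid$nx)
  harm <- function(a, b) 2 * a * b / (a + b)
  cx <- NULL; cy <- NULL
  if (grid$nx > 1L) {
    Dl <- Dmap[, -grid$nx, drop = FALSE]
    Dr <- Dmap[, -1L, drop = FALSE]
    u <- harm(Dl, Dr) / dxm                       # conductance per area, m/s
    if (grid$barrier_mode == "interface" && !is.na(grid$membrane_face)) {
      j <- grid$membrane_face
      # membrane in series with the two half-cells
      u[, j] <- 1 / (dxm / (2 * Dl[, j]) + dxm / (2 * Dr[, j]) +
                       1 / grid$membrane_conductance)
    }
    cx <- u / dxm                                  # 1/s
  }
  if (grid$ny > 1L) {
    Du <- Dmap[-grid$ny, , drop = FALSE]
    Dd <- Dmap[-1L, , drop = FALSE]
    cy <- (harm(Du, Dd) / dxm) / dxm
  }
  list(cx = cx, cy = cy, Dmax = max(Dmap))
}

# dV/dt from diffusion (1/s rates applied to concentration differences).
.diffusion_rate <- function(v, rates) {
  ny <- nrow(v); nx <- ncol(v)
  dv <- matrix(0, ny, nx)
  if (!is.null(rates$cx)) {
    Fx <- rates$cx * (v[, -1L, drop = FALSE] - v[, -nx, drop = FALSE])
    dv[, -nx] <- dv[, -nx, drop = FALSE] + Fx
    dv[, -1L] <- dv[, -1L, drop = FALSE] - Fx
  }
  if (!is.null(rates$cy)) {
    Fy <- rates$cy * (v[-1L, , drop = FALSE] - v[-ny, , drop = FALSE])
    dv[-ny, ] <- dv[-ny, , drop = FALSE] + Fy
    dv[-1L, ] <- dv[-1L, , drop = FALSE] - Fy
  }
  dv
}

.stability_dt <- function(grid, rates) {
  # FTCS bound dt <= dx^2/(4 Dmax); membrane faces only lower conductances.
  dxm <- grid$dx_um * 1e-6
  dxm^2 / (4 * rates$Dmax)
}

#' Advance a concentration field by one explicit step
#'
#' One forward-time centred-space step with harmonic-mean interface fluxes,
#' zero-flux outer boundaries and a distributed source.
#'
#' @param field A `bbb_field`.
#' @param dt Time step in s; must satisfy the FTCS stability bound.
#' @param sources Optional ny x nx matrix of source rates (mol m^-3 s^-1)
#'   or a list of `list(region_role=, rate=)` specs.
#' @param solute_name Solute whose diffusivities are used (default
#'   `"abeta"`).
#' @param rates Precomputed face rates (internal use).
#' @return The advanced `bbb_field`.
#' @export
step_field <- function(field, dt, sources = NULL, solute_name = "abeta",
                       rates = NULL) {
  grid <- field$grid
  rates <- rates %||% .face_rates(grid, solute_name)
  if (dt > .stability_dt(grid, rates) * (1 + 1e-9))
    stop(structure(class = c("bbb_numerical_error", "error", "condition"),
                   list(message = sprintf(
                     "dt = %g s exceeds the FTCS stability bound %g s",
                     dt, .stability_dt(grid, rates)), call = NULL)))
  S <- .source_matrix(grid, sources)
  v <- field$values + dt * (.diffusion_rate(field$values, rates) + S)
  field$values <- .check_values(v, field$time + dt)
  field$time <- field$time + dt
  field
}

.source_matrix <- function(grid, sources) {
  if (is.null(sources)) return(0)
  if (is.matrix(sources)) return(sources)
  S <- matrix(0, grid$ny, grid$nx)
  for (s in sources) {
    if (s$rate < 0) stop("source rate must be >= 0", call. = FALSE)
    S[.region_cells(grid, s$region_role)] <- S[.region_cells(grid, s$region_role)] + s$rate
  }
  S
}

.check_values <- function(v, time) {
  if (any(!is.finite(v)))
    stop(structure(class = c("bbb_numerical_error", "error", "condition"),
                   list(message = sprintf(
                     "non-finite concentration at t = %g s (cell %d)",
                     time, which(!is.finite(v))[1]), call = NULL)))
  neg <- v < 0
  if (any(neg)) {
    tol <- -1e-12 * max(abs(v), 1e-300)
    if (any(v < tol))
      stop(structure(class = c("bbb_numerical_error", "error", "condition"),
                     list(message = sprintf(
                       "negative concentration %g at t = %g s (cell %d)",
                       min(v), time, which.min(v)), call = NULL)))
    v[neg] <- 0  # clip roundoff-level negatives
  }
  v
}

# Sparse diffusion operator A (N x N, 1/s) for the implicit scheme.
.diffusion_operator <- function(grid, rates) {
  ny <- grid$ny; nx <- grid$nx
  ii <- integer(0); jj <- integer(0); aa <- numeric(0)
  if (!is.null(rates$cx)) {
    i <- rep(seq_len(ny), nx - 1L)
    j <- rep(seq_len(nx - 1L), each = ny)
    k1 <- (j - 1L) * ny + i
    k2 <- j * ny + i
    a <- as.vector(rates$cx)
    ii <- c(ii, k1, k2, k1, k2); jj <- c(jj, k2, k1, k1, k2)
    aa <- c(aa, a, a, -a, -a)
  }
  if (!is.null(rates$cy)) {
    i <- rep(seq_len(ny - 1L), nx)
    j <- rep(seq_len(nx), each = ny - 1L)
    k1 <- (j - 1L) * ny + i
    k2 <- k1 + 1L
    a <- as.vector(rates$cy)
    ii <- c(ii, k1, k2, k1, k2); jj <- c(jj, k2, k1, k1, k2)
    aa <- c(aa, a, a, -a, -a)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = aa, dims = c(ny * nx, ny * nx))
}

#' Build a simulation configuration
#'
#' @param layout A `bbb_layout` (ignored if `grid` is given).
#' @param solute Solute name or [solute()] object.
#' @param t_end End time, s.
#' @param dx_um Grid spacing (used when `grid` is NULL), default 50.
#' @param dt Time step, s. `NULL` chooses `0.9 * dx^2/(4 Dmax)` for the
#'   explicit scheme and `min(snapshot_interval, 600)` for the implicit one.
#' @param initial_values Named region -> mol m^-3 (or matrix / scalar).
#' @param sources List of `list(region_role=, rate=)`, rate in
#'   mol m^-3 s^-1.
#' @param schedule List of `list(region_role=, period_s=, reset_value=)`.
#' @param pinned Named list/vector of region role -> concentration held
#'   fixed throughout the run (Dirichlet reservoirs), e.g. for fixed-end
#'   slab problems. Applied after every step.
#' @param snapshot_interval Interval between stored snapshots, s.
#' @param method `"explicit"` (FTCS) or `"implicit"` (backward Euler).
#' @param grid Optional prebuilt `bbb_grid`.
#' @param membrane_conductance Optional membrane conductance override, m/s.
#' @return An object of class `bbb_simconfig`.
#' @export
simulation_config <- function(layout = build_default_layout(),
                              solute = "abeta", t_end,
                              dx_um = 50, dt = NULL,
                              initial_values = list(), sources = list(),
                              schedule = list(), pinned = list(),
                              snapshot_interval = t_end,
                              method = c("explicit", "implicit"),
                              grid = NULL,
                              membrane_conductance = NULL) {
  method <- match.arg(method)
  solute_name <- if (inherits(solute, "bbb_solute")) solute$name else solute
  grid <- grid %||% discretize(layout, dx_um,
                               membrane_conductance = membrane_conductance)
  if (t_end <= 0) stop("t_end must be positive", call. = FALSE)
  if (!is.null(dt) && dt <= 0) stop("dt must be positive", call. = FALSE)
  if (snapshot_interval <= 0)
    stop("snapshot_interval must be positive", call. = FALSE)
  for (sc in schedule) {
    if (sc$period_s <= 0) stop("schedule period must be > 0", call. = FALSE)
    if (sc$reset_value < 0) stop("reset_value must be >= 0", call. = FALSE)
  }
  structure(list(grid = grid, solute_name = solute_name, t_end = t_end,
                 dt = dt, initial_values = initial_values, sources = sources,
                 schedule = schedule, pinned = pinned,
                 snapshot_interval = snapshot_interval,
                 method = method),
            class = "bbb_simconfig")
}

#' Replace the medium of one region
#'
#' Models an instantaneous medium-replacement event: every cell of the
#' region is set to `reset_value` (0 for fresh, tracer-free medium); other
#' cells and the field time are untouched.
#'
#' @param field A `bbb_field`.
#' @param region_role Region to replace.
#' @param reset_value New concentration, mol m^-3 (default 0).
#' @return The modified field, with attribute `"mass_removed_mol"` giving
#'   the net solute mass removed by the exchange.
#' @export
apply_replacement <- function(field, region_role, reset_value = 0) {
  idx <- .region_cells(field$grid, region_role)
  dxm <- field$grid$dx_um * 1e-6
  hm <- field$grid$layout$height_um * 1e-6
  removed <- sum(field$values[idx] - reset_value) * dxm^2 * hm
  field$values[idx] <- reset_value
  attr(field, "mass_removed_mol") <- removed
  field
}

#' Run a transport simulation
#'
#' Integrates the configuration from t = 0 to `t_end`, applying each
#' replacement schedule at every multiple of its period and storing
#' snapshots (post-event at event times) at the requested interval.
#' Deterministic: no randomness is involved.
#'
#' @param config A `bbb_simconfig`.
#' @return An object of class `bbb_history`: `times`, `snapshots` (list of
#'   ny x nx matrices, mol m^-3), `events` (data frame: time_s, region,
#'   reset_value, mass_removed_mol), `grid`, `config`.
#' @export
run_simulation <- function(config) {
  grid <- config$grid
  rates <- .face_rates(grid, config$solute_name)
  field <- concentration_field(grid, config$initial_values)
  S <- .source_matrix(grid, config$sources)
  pin_idx <- lapply(names(config$pinned), function(role)
    .region_cells(grid, role))
  apply_pins <- function(v) {
    for (k in seq_along(pin_idx))
      v[pin_idx[[k]]] <- as.numeric(config$pinned[[k]])
    v
  }
  field$values <- apply_pins(field$values)

  dt <- config$dt %||% (if (config$method == "explicit")
    0.9 * .stability_dt(grid, rates) else min(config$snapshot_interval, 600))
  if (config$method == "explicit" && dt > .stability_dt(grid, rates))
    stop(structure(class = c("bbb_numerical_error", "error", "condition"),
                   list(message = sprintf(
                     "dt = %g s exceeds the FTCS stability bound %g s",
                     dt, .stability_dt(grid, rates)), call = NULL)))

  ev_times <- sort(unique(unlist(lapply(config$schedule, function(sc) {
    if (sc$period_s > config$t_end) return(numeric(0))
    seq(sc$period_s, config$t_end, by = sc$period_s)
  }))))
  snap_times <- unique(sort(c(seq(0, config$t_end,
                                  by = config$snapshot_interval),
                              ev_times, config$t_end)))
  breaks <- unique(sort(c(0, ev_times, snap_times, config$t_end)))

  # Implicit backward Euler. Pinned (Dirichlet) cells are eliminated from
  # the linear system: solve (I - h A)_FF x_F = v_F + h (S_F + A_FP x_P).
  factor_cache <- new.env(parent = emptyenv())
  A_op <- NULL
  free_idx <- NULL
  implicit_solve <- function(v, h) {
    if (is.null(A_op)) {
      A_op <<- .diffusion_operator(grid, rates)
      pins <- unlist(pin_idx)
      free_idx <<- if (length(pins))
        setdiff(seq_len(grid$ny * grid$nx), pins) else
          seq_len(grid$ny * grid$nx)
    }
    key <- sprintf("%.12g", h)
    if (is.null(factor_cache[[key]])) {
      M <- Matrix::Diagonal(grid$ny * grid$nx) - h * A_op
      factor_cache[[key]] <- Matrix::Cholesky(Matrix::forceSymmetric(
        M[free_idx, free_idx, drop = FALSE]))
    }
    vv <- as.vector(v)
    Sv <- as.vector(S + matrix(0, grid$ny, grid$nx))
    b <- vv[free_idx] + h * Sv[free_idx]
    if (length(free_idx) < length(vv)) {
      coup <- as.vector(A_op[free_idx, -free_idx, drop = FALSE] %*%
                          vv[-free_idx])
      b <- b + h * coup
    }
    out <- vv
    out[free_idx] <- as.vector(Matrix::solve(factor_cache[[key]], b))
    matrix(out, grid$ny, grid$nx)
  }

  snapshots <- list(field$values)
  times <- 0
  events <- list()
  for (seg in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[seg]; t1 <- breaks[seg + 1L]
    nsteps <- max(1L, ceiling((t1 - t0) / dt - 1e-9))
    h <- (t1 - t0) / nsteps
    for (k in seq_len(nsteps)) {
      if (config$method == "explicit") {
        v <- field$values +
          h * (.diffusion_rate(field$values, rates) + S)
      } else {
        v <- implicit_solve(field$values, h)
      }
      field$values <- apply_pins(.check_values(v, t0 + k * h))
    }
    field$time <- t1
    if (t1 %in% ev_times) {
      for (sc in config$schedule) {
        if (abs(t1 / sc$period_s - round(t1 / sc$period_s)) < 1e-9) {
          field <- apply_replacement(field, sc$region_role, sc$reset_value)
          events[[length(events) + 1L]] <- data.frame(
            time_s = t1, region = sc$region_role,
            reset_value = sc$reset_value,
            mass_removed_mol = attr(field, "mass_removed_mol"))
        }
      }
    }
    if (t1 %in% snap_times) {
      snapshots[[length(snapshots) + 1L]] <- field$values
      times <- c(times, t1)
    }
  }
  structure(list(times = times, snapshots = snapshots,
                 events = if (length(events)) do.call(rbind, events) else
                   data.frame(time_s = numeric(0), region = character(0),
                              reset_value = numeric(0),
                              mass_removed_mol = numeric(0)),
                 grid = grid, config = config),
            class = "bbb_history")
}

#' @export
print.bbb_history <- function(x, ...) {
  cat(sprintf(
    "bbb_history: %d snapshots over %g s (%s scheme), %d events, grid %dx%d\n",
    length(x$times), max(x$times), x$config$method, nrow(x$events),
    x$grid$ny, x$grid$nx))
  invisible(x)
}

#' Snapshot of a history as a field
#'
#' @param history A `bbb_history`.
#' @param t Time in s; the nearest stored snapshot is returned. Must lie
#'   within the history span.
#' @return A `bbb_field`.
#' @export
snapshot_at <- function(history, t) {
  if (t < min(history$times) - 1e-9 || t > max(history$times) + 1e-9)
    stop(sprintf("t = %g s outside history span [%g, %g]", t,
                 min(history$times), max(history$times)), call. = FALSE)
  k <- which.min(abs(history$times - t))
  structure(list(grid = history$grid, values = history$snapshots[[k]],
                 time = history$times[k]), class = "bbb_field")
}

#' Column-averaged concentration profile across the channels
#'
#' Averages the concentration along the channel direction (y), returning
#' the profile along the axis perpendicular to the channels.
#'
#' @param history A `bbb_history`.
#' @param t Time in s (nearest snapshot; must lie within the span).
#' @return Data frame with `position_um` (cell centres) and
#'   `concentration_mol_m3`; region boundary positions are attached as
#'   attribute `"boundaries_um"`.
#' @export
profile_along_axis <- function(history, t) {
  f <- snapshot_at(history, t)
  grid <- f$grid
  pos <- grid$x0_um + (seq_len(grid$nx) - 0.5) * grid$dx_um
  out <- data.frame(position_um = pos,
                    concentration_mol_m3 = colMeans(f$values))
  attr(out, "boundaries_um") <- vapply(grid$layout$regions, function(r)
    r$x_range[2], numeric(1))
  attr(out, "time_s") <- f$time
  out
}

#' Total solute mass of a field
#'
#' `sum(C) * dx^2 * height`, in mol.
#'
#' @param field A `bbb_field`.
#' @return Mass in mol.
#' @export
total_mass <- function(field) {
  dxm <- field$grid$dx_um * 1e-6
  sum(field$values) * dxm^2 * (field$grid$layout$height_um * 1e-6)
}

#' Mean concentration of one region
#'
#' @param field A `bbb_field`.
#' @param region_role Region role.
#' @return Mean concentration, mol m^-3.
#' @export
region_mean <- function(field, region_role) {
  mean(field$values[.region_cells(field$grid, region_role)])
}

#' Time course of a region mean over a history
#'
#' @param history A `bbb_history`.
#' @param region_role Region role.
#' @return Data frame `time_s`, `mean_mol_m3`.
#' @export
region_mean_series <- function(history, region_role) {
  idx <- .region_cells(history$grid, region_role)
  data.frame(time_s = history$times,
             mean_mol_m3 = vapply(history$snapshots, function(v)
               mean(v[idx]), numeric(1)))
}

# ---- plain-text persistence ------------------------------------------------

#' Export a simulation history to plain-text files
#'
#' Writes `times.csv`, `events.csv`, `material_map.csv`, `config.json`
#' (grid geometry and run parameters) and one `snapshot_<k>.csv` matrix
#' per stored time into `dir`.
#'
#' @param history A `bbb_history`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_history <- function(history, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(index = seq_along(history$times) - 1L,
                              time_s = history$times),
                   file.path(dir, "times.csv"), row.names = FALSE)
  utils::write.csv(history$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  utils::write.table(history$grid$material_map,
                     file.path(dir, "material_map.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(dx_um = history$grid$dx_um, nx = history$grid$nx,
               ny = history$grid$ny, solute = history$config$solute_name,
               method = history$config$method,
               t_end = history$config$t_end,
               snapshot_interval = history$config$snapshot_interval,
               height_um = history$grid$layout$height_um,
               membrane_conductance = history$grid$membrane_conductance,
               layout = layout_to_config(history$grid$layout))
  jsonlite::write_json(meta, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  for (k in seq_along(history$snapshots))
    utils::write.table(history$snapshots[[k]],
                       file.path(dir, sprintf("snapshot_%04d.csv", k - 1L)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Write a concentration profile as CSV
#'
#' @param profile Output of [profile_along_axis()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(profile, path, row.names = FALSE)
  invisible(path)
}
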