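# Heterogeneous monodomain solver: Godunov operator splitting with
# explicit-Euler reaction substeps and an implicit-Euler finite-volume
# diffusion solve. The diffusion matrix is constant in time, so its sparse
# Cholesky factorization is computed once and reused every step.

#' Monodomain discretization parameters
#'
#' @param beta Surface-to-volume ratio of the myocytes, 1/um (default 0.14,
#'   the standard monodomain value; with `C_m` below it gives a ~30 pF
#'   whole-cell capacitance for the template's mean myocyte).
#' @param C_m Membrane capacitance per unit area. Default 1 uF/cm^2
#'   (= 1e-5 nF/um^2), the Bondarenko value.
#' @param dt_o Reaction (ODE) step, ms. If `NULL`, the ionic model's default
#'   is used (1e-4 ms for Bondarenko, 0.01 ms for the surrogate).
#' @param dt_p Diffusion (PDE) step, ms; must be an integer multiple of
#'   `dt_o`.
#' @return Object of class `monodomain_params`.
#' @examples
#' monodomain_params()
#' @export
monodomain_params <- function(beta = 0.14, C_m = 1e-5, dt_o = NULL,
                              dt_p = 0.01) {
  if (beta <= 0 || C_m <= 0) stop("beta and C_m must be positive",
                                  call. = FALSE)
  if (dt_p <= 0) stop("dt_p must be positive", call. = FALSE)
  if (!is.null(dt_o)) {
    N_o <- round(dt_p / dt_o)
    if (N_o < 1 || abs(N_o * dt_o - dt_p) > 1e-9 * dt_p)
      stop("dt_p must be an integer multiple of dt_o", call. = FALSE)
  }
  structure(list(beta = beta, C_m = C_m, dt_o = dt_o, dt_p = dt_p),
            class = "monodomain_params")
}

.resolve_dt <- function(params, model) {
  dt_o <- params$dt_o %||% model$dt_o_default
  N_o <- as.integer(round(params$dt_p / dt_o))
  if (N_o < 1L || abs(N_o * dt_o - params$dt_p) > 1e-9 * params$dt_p)
    stop("dt_p must be an integer multiple of dt_o", call. = FALSE)
  list(dt_o = params$dt_p / N_o, N_o = N_o)
}

## Diffusion system assembly ----------------------------------------------------

#' Assemble the implicit finite-volume diffusion system of a mesh
#'
#' Builds the symmetric positive-definite system
#' `(alpha I + L) V^{n+1} = alpha V*` of the implicit-Euler diffusion stage,
#' where `alpha = beta C_m h^2 / dt_p` and `L` is the finite-volume
#' Laplacian with one transmission coefficient per interior face
#' ([face_coefficient()]); boundary faces are omitted (no-flux). Every row
#' sums to `alpha`, so uniform fields are exact fixed points.
#'
#' @param mesh A `tissue_mesh`.
#' @param params [monodomain_params()].
#' @return Object of class `diffusion_system`: the sparse matrix `M`, its
#'   cached Cholesky factorization, and `alpha` (uS/um).
#' @export
assemble_diffusion_system <- function(mesh, params = monodomain_params()) {
  stopifnot(inherits(mesh, "tissue_mesh"))
  nx <- mesh$nx; ny <- mesh$ny
  n <- nx * ny
  # (1/um)(nF/um^2)(um^2)/ms = nF/(um ms) = uS/um, same units as the face
  # transmission coefficients
  alpha <- params$beta * params$C_m * mesh$h^2 / params$dt_p

  id <- function(ix, iy) ix + (iy - 1L) * nx
  # east faces
  fe <- mesh$face_e[seq_len(nx - 1L), , drop = FALSE]
  ie <- which(!is.na(fe) & fe != .FT[["MEMBRANE"]])
  ce <- face_coefficient(fe[ie], mesh$table, mesh$d)
  ex <- (ie - 1L) %% (nx - 1L) + 1L
  ey <- (ie - 1L) %/% (nx - 1L) + 1L
  # north faces
  fn <- mesh$face_n[, seq_len(ny - 1L), drop = FALSE]
  inn <- which(!is.na(fn) & fn != .FT[["MEMBRANE"]])
  cn <- face_coefficient(fn[inn], mesh$table, mesh$d)
  nxi <- (inn - 1L) %% nx + 1L
  nyi <- (inn - 1L) %/% nx + 1L

  ii <- c(id(ex, ey), id(nxi, nyi))
  jj <- c(id(ex + 1L, ey), id(nxi, nyi + 1L))
  cc <- c(ce, cn)
  if (any(cc < 0)) stop("negative face coefficient", call. = FALSE)

  .build_system(n, ii, jj, cc, rep(alpha, n),
                meta = list(kind = "microscopic", nx = nx, ny = ny,
                            h = mesh$h, alpha = alpha))
}

# assemble M = diag(alpha) + Laplacian(links), factorize, return system
.build_system <- function(n, ii, jj, w, alpha, meta) {
  L <- Matrix::sparseMatrix(i = c(ii, jj, seq_len(n)),
                            j = c(jj, ii, seq_len(n)),
                            x = c(-w, -w, alpha + .row_weight(n, ii, jj, w)),
                            dims = c(n, n))
  M <- methods::as(L, "symmetricMatrix")
  ch <- Matrix::Cholesky(M, LDL = FALSE, perm = TRUE)
  structure(list(M = M, chol = ch, alpha = alpha, n = n, meta = meta),
            class = "diffusion_system")
}

.row_weight <- function(n, ii, jj, w) {
  rw <- numeric(n)
  if (length(ii)) {
    t1 <- rowsum(c(w, w), c(ii, jj))
    rw[as.integer(rownames(t1))] <- t1[, 1L]
  }
  rw
}

#' One implicit-Euler diffusion step
#'
#' Solves `M V^{n+1} = alpha * V_star` with the cached factorization.
#'
#' @param system A `diffusion_system`.
#' @param V_star Field after the reaction stage.
#' @return `V^{n+1}`.
#' @export
diffusion_step <- function(system, V_star) {
  stopifnot(inherits(system, "diffusion_system"))
  if (length(V_star) != system$n)
    stop("V_star has length ", length(V_star), ", expected ", system$n,
         call. = FALSE)
  out <- as.numeric(Matrix::solve(system$chol, system$alpha * V_star,
                                  system = "A"))
  res <- max(abs(system$M %*% out - system$alpha * V_star))
  if (!is.finite(res) || res > 1e-6 * max(1, max(abs(V_star))))
    stop("diffusion solve did not converge: residual ", res, call. = FALSE)
  out
}

## Stimulus protocols -----------------------------------------------------------

#' Stimulus protocols
#'
#' A protocol is a list of pulses, each with a spatial `region` (resolved
#' against the mesh or network when the simulation starts), `start` and
#' `duration` (ms) and `amplitude` (pA/pF; `NULL` = the ionic model's frozen
#' default, twice diastolic threshold). Presets:
#' `"left_edge"` (LP: plane wave along the fibers), `"bottom_edge"` (TP:
#' transversal plane wave), `"center_point"` (point stimulus, elliptical
#' wave), `"s1s2_crossfield"` (S1 plane + S2 quadrant, spiral induction
#' demo).
#'
#' @param preset Preset name, or `"custom"` with an explicit `pulses` list.
#' @param start S1 onset, ms.
#' @param duration Pulse duration, ms (default 2).
#' @param amplitude Pulse amplitude, pA/pF, or `NULL` for the model default.
#' @param s2_delay S1-S2 coupling interval, ms (crossfield preset only).
#' @param pulses For `preset = "custom"`: list of pulses, each a list with
#'   fields `region` (see Details), `start`, `duration`, `amplitude`.
#' @details A `region` is either a preset keyword (`"left_edge"`,
#'   `"bottom_edge"`, `"center"`, `"lower_left"`) or a vector of volume/cell
#'   indices.
#' @return Object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(preset = c("left_edge", "bottom_edge",
                                         "center_point", "s1s2_crossfield",
                                         "custom"),
                              start = 0, duration = 2, amplitude = NULL,
                              s2_delay = 65, pulses = NULL) {
  preset <- match.arg(preset)
  mk <- function(region, start, duration, amplitude)
    list(region = region, start = start, duration = duration,
         amplitude = amplitude)
  pl <- switch(preset,
    left_edge = list(mk("left_edge", start, duration, amplitude)),
    bottom_edge = list(mk("bottom_edge", start, duration, amplitude)),
    center_point = list(mk("center", start, duration, amplitude)),
    s1s2_crossfield = list(
      mk("left_edge", start, duration, amplitude),
      mk("lower_left", start + s2_delay, duration, amplitude)),
    custom = pulses)
  if (!length(pl)) stop("protocol has no pulses", call. = FALSE)
  for (p in pl)
    if (p$duration <= 0) stop("pulse durations must be positive",
                              call. = FALSE)
  structure(list(preset = preset, pulses = pl), class = "stimulus_protocol")
}

# Resolve a pulse region to indices for a mesh (volumes) or network (cells).
.resolve_region <- function(region, x) {
  if (is.numeric(region)) return(as.integer(region))
  if (inherits(x, "tissue_mesh")) {
    nx <- x$nx; ny <- x$ny
    idx <- switch(region,
      left_edge = which(as.integer(row(x$cell_id)) <= 2L),
      bottom_edge = which(as.integer(col(x$cell_id)) <= 2L),
      center = {
        cxy <- c((nx + 1) / 2, (ny + 1) / 2)
        r2 <- (200 / x$h)^2
        which((as.integer(row(x$cell_id)) - cxy[1])^2 +
              (as.integer(col(x$cell_id)) - cxy[2])^2 <= r2)
      },
      lower_left = which(as.integer(row(x$cell_id)) <= nx / 2 &
                         as.integer(col(x$cell_id)) <= ny / 2),
      stop("unknown stimulus region '", region, "'", call. = FALSE))
  } else {
    nd <- x$nodes
    idx <- switch(region,
      left_edge = which(nd$touch_l),
      bottom_edge = which(nd$touch_b),
      center = {
        cx <- (max(nd$cx) + min(nd$cx)) / 2
        cy <- (max(nd$cy) + min(nd$cy)) / 2
        which((nd$cx - cx)^2 + (nd$cy - cy)^2 <= 200^2)
      },
      lower_left = which(nd$cx <= (max(nd$cx) + min(nd$cx)) / 2 &
                         nd$cy <= (max(nd$cy) + min(nd$cy)) / 2),
      stop("unknown stimulus region '", region, "'", call. = FALSE))
  }
  if (!length(idx)) stop("stimulus region is empty", call. = FALSE)
  idx
}

## Shared time-stepping core ----------------------------------------------------

# system: diffusion_system; geometry: list with coordinates (um) per node.
.simulate_core <- function(system, model, params, protocol, T_end,
                           probes = integer(0), snapshot_times = numeric(0),
                           V_act = -60, V_up = -30, V_rearm = -60,
                           stop_when_quiescent = FALSE, quiescent_V = -70,
                           quiescent_span = 10, meta = list(),
                           V0 = NULL, eta0 = NULL) {
  n <- system$n
  dts <- .resolve_dt(params, model)
  n_steps <- as.integer(round(T_end / params$dt_p))
  if (abs(n_steps * params$dt_p - T_end) > 1e-9 * max(1, T_end))
    stop("T_end must be a multiple of dt_p", call. = FALSE)

  # resolved pulses
  x_for_regions <- meta$region_host
  default_amp <- if (identical(meta$kind, "microscopic"))
    model$stim_default_micro else model$stim_default
  pulses <- lapply(protocol$pulses, function(p) {
    list(idx = .resolve_region(p$region, x_for_regions),
         start = p$start, stop = p$start + p$duration,
         amp = p$amplitude %||% default_amp)
  })

  V <- if (is.null(V0)) rep(model$V_rest + 0, n) else V0 + 0
  eta <- if (is.null(eta0))
    matrix(model$init_state, nrow = model$n_states, ncol = n)
  else matrix(as.numeric(eta0), nrow = model$n_states, ncol = n)
  if (length(V) != n || ncol(eta) != n)
    stop("V0/eta0 do not match the system size", call. = FALSE)
  stim <- numeric(n)

  armed <- rep(1L, n)
  ap_count <- integer(n)
  act_time <- rep(NA_real_, n)
  last_active <- rep(-Inf, n)

  probe_V <- if (length(probes))
    matrix(NA_real_, n_steps + 1L, length(probes)) else NULL
  if (!is.null(probe_V)) probe_V[1L, ] <- V[probes]
  snaps <- list()
  snap_steps <- as.integer(round(snapshot_times / params$dt_p))

  quiet_since <- NA_real_
  t <- 0
  last_step <- n_steps
  for (k in seq_len(n_steps)) {
    t0 <- t
    # reaction stage (stimulus applied in the ODE stage)
    stim[] <- 0
    for (p in pulses)
      if (t0 < p$stop && (t0 + params$dt_p) > p$start)
        stim[p$idx] <- stim[p$idx] + p$amp
    .ionic_step(model, V, eta, stim, dts$N_o, dts$dt_o)
    # diffusion stage
    V <- diffusion_step(system, V)
    t <- k * params$dt_p

    .update_trackers(V, armed, ap_count, act_time, last_active, t,
                     V_act, V_up, V_rearm)
    if (!is.null(probe_V)) probe_V[k + 1L, ] <- V[probes]
    if (k %in% snap_steps) snaps[[as.character(t)]] <- V + 0

    if (stop_when_quiescent) {
      if (max(V) < quiescent_V && t > max(vapply(pulses, `[[`, 0, "stop"))) {
        if (is.na(quiet_since)) quiet_since <- t
        if (t - quiet_since >= quiescent_span) { last_step <- k; break }
      } else quiet_since <- NA_real_
    }
  }

  structure(list(
    n = n, T_end = T_end, t_stop = last_step * params$dt_p,
    dt_p = params$dt_p,
    times = seq(0, by = params$dt_p, length.out =
                  if (!is.null(probe_V)) nrow(probe_V) else 0L),
    probes = probes, probe_V = probe_V,
    snapshots = snaps,
    V_final = V,
    activation = act_time, ap_count = ap_count,
    last_active = ifelse(is.finite(last_active), last_active, NA_real_),
    V_act = V_act,
    params = params, model_name = model$name, protocol = protocol,
    meta = meta), class = "sim_result")
}

#' Simulate the microscopic monodomain model
#'
#' Advances the heterogeneous monodomain equation on a volume mesh by
#' Godunov splitting: `N_o` explicit-Euler reaction substeps per volume,
#' then one implicit-Euler finite-volume diffusion solve, per `dt_p`.
#'
#' @param mesh A `tissue_mesh`.
#' @param ionic An [ionic_model][ionic_models].
#' @param params [monodomain_params()].
#' @param protocol A [stimulus_protocol()].
#' @param T_end Simulation end, ms (multiple of `dt_p`).
#' @param probes Volume indices whose V is recorded every `dt_p`.
#' @param snapshot_times Times (ms) at which full V fields are stored.
#' @param ... Further options passed to the core integrator: tracker
#'   thresholds (`V_act`, `V_up`, `V_rearm`), quiescence early-stop
#'   (`stop_when_quiescent`, `quiescent_V`, `quiescent_span`), and initial
#'   state (`V0`, `eta0`) to resume or start from a prepared excitation.
#' @return A `sim_result` with activation map, AP counts and traces; volume
#'   fields are indexed like `mesh$cell_id`.
#' @export
simulate_microscopic <- function(mesh, ionic, params = monodomain_params(),
                                 protocol = stimulus_protocol("left_edge"),
                                 T_end = 20, probes = integer(0),
                                 snapshot_times = numeric(0), ...) {
  stopifnot(inherits(mesh, "tissue_mesh"), inherits(ionic, "ionic_model"))
  system <- assemble_diffusion_system(mesh, params)
  meta <- list(kind = "microscopic", region_host = mesh,
               mesh_hash = mesh_hash(mesh),
               x_um = as.numeric(row(mesh$cell_id)) * mesh$h,
               y_um = as.numeric(col(mesh$cell_id)) * mesh$h)
  .simulate_core(system, ionic, params, protocol, T_end,
                 probes = probes, snapshot_times = snapshot_times,
                 meta = meta, ...)
}

#' Content hash of a mesh
#'
#' FNV-1a hash over the cell map and face types, used to key run metadata
#' and fibrosis realizations.
#'
#' @param mesh A `tissue_mesh`.
#' @return 16-character hex string.
#' @export
mesh_hash <- function(mesh) {
  f <- function(m) { m <- as.integer(m); m[is.na(m)] <- -1L; m }
  .fnv_hash(c(mesh$nx, mesh$ny, f(mesh$cell_id), f(mesh$face_e),
              f(mesh$face_n)))
}

#' @export
print.sim_result <- function(x, ...) {
  cat("sim_result (", x$meta$kind, ", ", x$model_name, "): ", x$n,
      if (identical(x$meta$kind, "discrete")) " cells, " else " volumes, ",
      "T_end = ", x$T_end, " ms",
      if (x$t_stop < x$T_end) paste0(" (quiescent, stopped at ", x$t_stop,
                                     " ms)"),
      "\n", sep = "")
  cat("  activated: ", sum(!is.na(x$activation)), "/", x$n,
      ", AP counts: ", paste(names(table(x$ap_count)),
                             table(x$ap_count), sep = "x",
                             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Plot simulation traces or fields
#'
#' With `type = "trace"`, plots the recorded probe voltages against time;
#' with `type = "field"`, images a stored snapshot (microscopic results).
#'
#' @param x A `sim_result`.
#' @param type `"trace"` or `"field"`.
#' @param snapshot Snapshot time (name) for `type = "field"`.
#' @param ... Passed to the base graphics call.
#' @export
plot.sim_result <- function(x, type = c("trace", "field"),
                            snapshot = NULL, ...) {
  type <- match.arg(type)
  if (type == "trace") {
    if (is.null(x$probe_V)) stop("no probes recorded", call. = FALSE)
    graphics::matplot(x$times, x$probe_V, type = "l", lty = 1,
                      xlab = "t (ms)", ylab = "V (mV)", ...)
  } else {
    if (!length(x$snapshots)) stop("no snapshots stored", call. = FALSE)
    nm <- snapshot %||% names(x$snapshots)[length(x$snapshots)]
    v <- x$snapshots[[as.character(nm)]]
    mesh <- x$meta$region_host
    graphics::image(seq_len(mesh$nx) * mesh$h, seq_len(mesh$ny) * mesh$h,
                    matrix(v, mesh$nx, mesh$ny), useRaster = TRUE, asp = 1,
                    xlab = "x (um)", ylab = "y (um)",
                    zlim = c(-90, 40), col = grDevices::hcl.colors(64),
                    ...)
  }
  invisible(x)
}
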