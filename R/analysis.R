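# Analysis operations: reentry detection, NA/A/S/NS activity classification,
# conduction velocity, side-to-side percolation and threshold fitting.

#' Reentry check time for a tissue extent
#'
#' Reentry is defined as remaining activity at `t_traverse + 60` ms, where
#' `t_traverse` is the time a fractionated plane wave near phi = 0.45 needs
#' to cross the tissue: about 60 ms (longitudinal) or 240 ms (transversal)
#' per cm. For the 1 cm study tissue this gives the canonical 120 ms (LP)
#' and 300 ms (TP) check times; for other extents it scales with the tissue
#' size along the propagation axis.
#'
#' @param extent_um Tissue extent along the propagation axis, um.
#' @param direction `"LP"` or `"TP"`.
#' @return Check time in ms.
#' @examples
#' reentry_check_time(1e4, "LP")  # 120
#' reentry_check_time(4e3, "LP")  # 84
#' @export
reentry_check_time <- function(extent_um, direction = c("LP", "TP")) {
  direction <- match.arg(direction)
  cv_eff <- if (direction == "LP") 1e4 / 60 else 1e4 / 240
  extent_um / cv_eff + 60
}

#' Detect reentry in a simulation result
#'
#' A run shows reentry when there is still activity (any cell/volume
#' depolarized above `V_act`) at the check time: 120 ms after the stimulus
#' for longitudinal (LP) propagation, 300 ms for transversal (TP) -- 60 ms
#' after a plane wave at phi = 0.45 would have been extinguished on the
#' 1 cm tissue. For other geometries pass `check_time = t_traverse + 60`.
#'
#' @param result A `sim_result` that ran at least to the check time (runs
#'   stopped early by the quiescence monitor count as quiescent).
#' @param direction `"LP"` or `"TP"` (sets the default check time).
#' @param check_time Override, ms.
#' @return `TRUE` if activity persists at the check time.
#' @export
detect_reentry <- function(result, direction = c("LP", "TP"),
                           check_time = NULL) {
  stopifnot(inherits(result, "sim_result"))
  direction <- match.arg(direction)
  check_time <- check_time %||% if (direction == "LP") 120 else 300
  # a quiescence-stopped run (t_stop < T_end) is quiet from t_stop onwards;
  # otherwise the simulation must actually span the check time
  if (result$t_stop < check_time && result$t_stop >= result$T_end)
    stop("simulation ended at ", result$t_stop,
         " ms, before the check time ", check_time, " ms", call. = FALSE)
  any(!is.na(result$last_active) &
        result$last_active >= check_time - result$dt_p / 2)
}

#' Classify per-cell electrical activity (NA / A / S / NS)
#'
#' Counts action potentials per cell as upward crossings of -30 mV with a
#' -60 mV re-arming hysteresis, and classifies each cell: `NA` no activity,
#' `A` a single AP, `S` sustained reentry (>= 2 APs and tissue still active
#' at the end), `NS` nonsustained reentry (>= 2 APs, activity stopped
#' early). For NS the tissue-wide stop time (last time any V > `V_act`) is
#' reported.
#'
#' @param result A `sim_result`.
#' @return Object of class `activity_classes`: per-cell factor `class`,
#'   percentage table `percent` (summing to 100), and `stop_time` (ms, NA
#'   unless activity stopped before the end).
#' @export
classify_activity <- function(result) {
  stopifnot(inherits(result, "sim_result"))
  stop_time <- if (all(is.na(result$last_active))) NA_real_
               else max(result$last_active, na.rm = TRUE)
  active_at_end <- !is.na(stop_time) &&
    stop_time >= min(result$t_stop, result$T_end) - result$dt_p / 2
  cls <- ifelse(result$ap_count == 0L, "NA",
         ifelse(result$ap_count == 1L, "A",
                if (active_at_end) "S" else "NS"))
  cls <- factor(cls, levels = c("NA", "A", "S", "NS"))
  pct <- 100 * as.numeric(table(cls)) / length(cls)
  names(pct) <- levels(cls)
  structure(list(class = cls, percent = pct,
                 stop_time = if (active_at_end) NA_real_ else stop_time,
                 n = length(cls)),
            class = "activity_classes")
}

#' @export
print.activity_classes <- function(x, ...) {
  cat("activity over", x$n, "cells:",
      paste(sprintf("%s %.1f%%", names(x$percent), x$percent),
            collapse = ", "), "\n")
  if (!is.na(x$stop_time))
    cat("  nonsustained activity stopped at", x$stop_time, "ms\n")
  invisible(x)
}

#' Conduction velocity between two probes
#'
#' Euclidean probe separation divided by the difference of first activation
#' times (first upward crossing of `V_act`).
#'
#' @param result A `sim_result`.
#' @param p1,p2 Probe indices (volumes or cells), at least 0.1 cm apart
#'   along the propagation axis and away from stimulus and boundary.
#' @return Velocity in um/ms.
#' @export
conduction_velocity <- function(result, p1, p2) {
  stopifnot(inherits(result, "sim_result"))
  t1 <- result$activation[p1]; t2 <- result$activation[p2]
  if (is.na(t1) || is.na(t2))
    stop("probe did not activate", call. = FALSE)
  if (t1 == t2) stop("probes activated simultaneously", call. = FALSE)
  dx <- result$meta$x_um[p2] - result$meta$x_um[p1]
  dy <- result$meta$y_um[p2] - result$meta$y_um[p1]
  sqrt(dx^2 + dy^2) / abs(t2 - t1)
}

#' Side-to-side connectivity of a (fibrotic) cell network
#'
#' `TRUE` when a path of retained links joins a non-removed cell touching
#' the source side to one touching the opposite side: left-right for LP,
#' bottom-top for TP. Union-find over the link list.
#'
#' @param network A `cell_network`, possibly after [apply_fibrosis()].
#' @param direction `"LP"` (left-right) or `"TP"` (bottom-top).
#' @param removed Optional removed-cell ids overriding `network$removed`.
#' @return Logical.
#' @export
side_connectivity <- function(network, direction = c("LP", "TP"),
                              removed = NULL) {
  stopifnot(inherits(network, "cell_network"))
  direction <- match.arg(direction)
  removed <- removed %||% network$removed
  rm_flag <- logical(network$n)
  rm_flag[removed] <- TRUE
  nd <- network$nodes
  if (direction == "LP") {
    a <- nd$id[nd$touch_l]; b <- nd$id[nd$touch_r]
  } else {
    a <- nd$id[nd$touch_b]; b <- nd$id[nd$touch_t]
  }
  lk <- network$links
  .percolates(network$n,
              cbind(lk$i, lk$j, deparse.level = 0),
              rm_flag, as.integer(a), as.integer(b))
}

#' Side-to-side connection probability curve C(phi)
#'
#' For each phi, draws seeded random removals of `round(phi N)` cells and
#' measures the fraction of realizations with a side-to-side connected path
#' ([side_connectivity()]). Topology only: no electrophysiology is run.
#'
#' @param network A `cell_network` (the full tissue, e.g. the tiled
#'   1 cm x 1 cm template).
#' @param phi Vector of fractions (default 0.40..0.60 by 0.01).
#' @param n_realizations Seeded removals per phi (default 100).
#' @param direction `"LP"` or `"TP"`.
#' @param base_seed Per-realization seeds are
#'   `base_seed + 1000 * phi_index + realization_index`.
#' @return Object of class `percolation_curve`: data.frame `phi`, `n`,
#'   `n_connected`, `C`.
#' @export
percolation_curve <- function(network, phi = seq(0.40, 0.60, by = 0.01),
                              n_realizations = 100,
                              direction = c("LP", "TP"),
                              base_seed = 20150713) {
  stopifnot(inherits(network, "cell_network"))
  direction <- match.arg(direction)
  nd <- network$nodes
  if (direction == "LP") {
    a <- as.integer(nd$id[nd$touch_l]); b <- as.integer(nd$id[nd$touch_r])
  } else {
    a <- as.integer(nd$id[nd$touch_b]); b <- as.integer(nd$id[nd$touch_t])
  }
  links <- cbind(network$links$i, network$links$j, deparse.level = 0)
  N <- network$n
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  out <- data.frame(phi = phi, n = n_realizations, n_connected = 0L)
  for (ip in seq_along(phi)) {
    n_rm <- .round_half_up(phi[ip] * N)
    conn <- 0L
    for (r in seq_len(n_realizations)) {
      set.seed(base_seed + 1000L * ip + r)
      rm_flag <- logical(N)
      if (n_rm > 0) rm_flag[sample.int(N, n_rm)] <- TRUE
      if (.percolates(N, links, rm_flag, a, b)) conn <- conn + 1L
    }
    out$n_connected[ip] <- conn
  }
  out$C <- out$n_connected / out$n
  structure(list(curve = out, direction = direction,
                 base_seed = base_seed, n_cells = N),
            class = "percolation_curve")
}

#' Percolation threshold from a connection-probability curve
#'
#' Fits a straight line through the points of the transition region
#' (`C` in `[0.1, 0.9]` by default) and solves for the 50% crossing
#' `C(phi_c) = 0.5`. A logistic fit is available behind `method`.
#'
#' @param curve A `percolation_curve`, or a data.frame with columns `phi`
#'   and `C`.
#' @param window Transition band of C used for the fit.
#' @param method `"linear"` (default) or `"logistic"`.
#' @return `phi_c`.
#' @examples
#' percolation_threshold(data.frame(phi = seq(0, 1, 0.05),
#'                                  C = 1 - seq(0, 1, 0.05))) # 0.5
#' @export
percolation_threshold <- function(curve, window = c(0.1, 0.9),
                                  method = c("linear", "logistic")) {
  method <- match.arg(method)
  d <- if (inherits(curve, "percolation_curve")) curve$curve else curve
  if (min(d$C) >= 0.5 || max(d$C) <= 0.5)
    stop("curve does not span the transition: C = 0.5 is not crossed",
         call. = FALSE)
  if (method == "linear") {
    sel <- d$C >= window[1] & d$C <= window[2]
    if (sum(sel) < 2)
      stop("fewer than 2 points inside the transition window", call. = FALSE)
    fit <- lm(C ~ phi, data = d[sel, , drop = FALSE])
    phi_c <- (0.5 - coef(fit)[[1]]) / coef(fit)[[2]]
  } else {
    fit <- stats::glm(C ~ phi, family = stats::quasibinomial(),
                      data = d, weights = d$n)
    phi_c <- -coef(fit)[[1]] / coef(fit)[[2]]
  }
  unname(phi_c)
}

#' @export
print.percolation_curve <- function(x, ...) {
  cat("percolation_curve (", x$direction, "): ", nrow(x$curve),
      " phi values, ", x$curve$n[1], " realizations each, ",
      x$n_cells, " cells\n", sep = "")
  print(x$curve, digits = 3)
  invisible(x)
}

#' Plot a percolation curve with its threshold fit
#'
#' @param x A `percolation_curve`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.percolation_curve <- function(x, ...) {
  d <- x$curve
  graphics::plot(d$phi, d$C, pch = 16, ylim = c(0, 1),
                 xlab = expression(phi), ylab = expression(C(phi)), ...)
  ok <- tryCatch(percolation_threshold(x), error = function(e) NULL)
  if (!is.null(ok)) {
    graphics::abline(h = 0.5, lty = 3)
    graphics::abline(v = ok, lty = 2)
    graphics::mtext(sprintf("phi_c = %.3f", ok), side = 3, line = 0.2)
  }
  invisible(x)
}

#' Conduction velocity versus fibrosis fraction
#'
#' Per-phi mean and SD of the conduction velocity over the realizations in
#' which the wave traversed the tissue; non-traversing runs are excluded
#' and counted.
#'
#' @param ensemble An `ensemble_result` from [run_ensemble()].
#' @return data.frame `phi`, `cv_mean`, `cv_sd`, `n_traversed`,
#'   `n_excluded`.
#' @export
cv_vs_phi <- function(ensemble) {
  stopifnot(inherits(ensemble, "ensemble_result"))
  s <- ensemble$summary
  data.frame(phi = s$phi, cv_mean = s$cv_mean, cv_sd = s$cv_sd,
             n_traversed = s$n_traversed,
             n_excluded = s$n - s$n_traversed)
}
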