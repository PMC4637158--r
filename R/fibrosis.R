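# Seeded random microfibrosis: isolate a fraction phi of the myocytes by
# removing all their gap junctions, and Monte-Carlo ensembles over phi.

#' Apply a random fibrosis realization
#'
#' Samples `round(phi * N)` cells uniformly without replacement with the
#' seeded generator (rounding half away from zero) and isolates them: on a
#' mesh their gap-junction faces become membrane; on a network their links
#' are deleted (nodes kept). The selection depends only on `(phi, seed, N)`,
#' so a mesh and its reduced network receive identical realizations.
#'
#' @param x A `tissue_mesh` or `cell_network`.
#' @param phi Fraction of isolated cells, in `[0, 1]`.
#' @param seed Integer seed of the realization.
#' @return `x` modified, with a `realization` attribute of class
#'   `fibrosis_realization` (`phi`, `seed`, `removed` ids).
#' @examples
#' nw <- apply_fibrosis(reduce_to_network(build_template()), 0.5, seed = 1)
#' length(attr(nw, "realization")$removed) # 16
#' @export
apply_fibrosis <- function(x, phi, seed) {
  if (phi < 0 || phi > 1) stop("phi must lie in [0, 1]", call. = FALSE)
  N <- if (inherits(x, "tissue_mesh")) x$n_cells
       else if (inherits(x, "cell_network")) x$n
       else stop("x must be a tissue_mesh or cell_network", call. = FALSE)
  n_rm <- .round_half_up(phi * N)
  removed <- integer(0)
  if (n_rm > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    removed <- sort(sample.int(N, n_rm))
  }
  real <- structure(list(phi = phi, seed = as.integer(seed),
                         removed = removed, n_cells = N),
                    class = "fibrosis_realization")
  if (inherits(x, "tissue_mesh")) {
    if (length(removed)) {
      gj <- .FT[c("PLICATE", "INTERPLICATE", "COMBINED_PLICATE")]
      rm_flag <- logical(max(x$cell_id))
      rm_flag[removed] <- TRUE
      nx <- x$nx; ny <- x$ny
      east_nb <- x$cell_id[c(2:nx, 1L), , drop = FALSE]
      north_nb <- x$cell_id[, c(2:ny, 1L), drop = FALSE]
      kill_e <- x$face_e %in% gj &
        (rm_flag[x$cell_id] | rm_flag[east_nb])
      kill_n <- x$face_n %in% gj &
        (rm_flag[x$cell_id] | rm_flag[north_nb])
      x$face_e[matrix(kill_e, nx, ny)] <- .FT[["MEMBRANE"]]
      x$face_n[matrix(kill_n, nx, ny)] <- .FT[["MEMBRANE"]]
    }
    x$removed <- removed
  } else {
    if (length(removed)) {
      rm_flag <- logical(x$n)
      rm_flag[removed] <- TRUE
      keep <- !(rm_flag[x$links$i] | rm_flag[x$links$j])
      x$links <- x$links[keep, , drop = FALSE]
      rownames(x$links) <- NULL
    }
    x$removed <- removed
  }
  attr(x, "realization") <- real
  x
}

# round-half-away-from-zero (base round() rounds half to even)
.round_half_up <- function(x) trunc(x + sign(x) * 0.5)

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.fibrosis_realization <- function(x, ...) {
  cat("fibrosis_realization: phi = ", x$phi, ", seed = ", x$seed, ", ",
      length(x$removed), "/", x$n_cells, " cells isolated\n", sep = "")
  invisible(x)
}

#' Ensemble specification
#'
#' Defines a Monte-Carlo fibrosis ensemble: the phi grid, the number of
#' seeded realizations per phi, the stimulated direction and the model.
#' The study defaults are 100 realizations per phi over 0.40..0.55 in steps
#' of 0.01.
#'
#' @param phi Vector of fibrosis fractions.
#' @param n_realizations Realizations per phi.
#' @param base_seed Base of the per-realization seed,
#'   `seed = base_seed + 1000 * phi_index + realization_index`.
#' @param direction `"LP"` (left-edge stimulus, along fibers) or `"TP"`
#'   (bottom-edge stimulus, across fibers).
#' @param model `"discrete"` or `"microscopic"`.
#' @param ionic `"surrogate"` or `"bondarenko"`.
#' @param T_check Reentry check time, ms; `NULL` = the 1 cm canonical
#'   values 120 (LP) / 300 (TP). For other tissue extents use
#'   [reentry_check_time()].
#' @param dt_p Diffusion step for the ensemble runs, ms.
#' @return Object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(phi = seq(0.40, 0.55, by = 0.01),
                          n_realizations = 100, base_seed = 20150713,
                          direction = c("LP", "TP"),
                          model = c("discrete", "microscopic"),
                          ionic = c("surrogate", "bondarenko"),
                          T_check = NULL, dt_p = 0.05) {
  direction <- match.arg(direction)
  if (any(phi < 0 | phi > 1)) stop("phi values must lie in [0, 1]",
                                   call. = FALSE)
  if (n_realizations < 1) stop("n_realizations must be >= 1", call. = FALSE)
  structure(list(phi = phi, n_realizations = as.integer(n_realizations),
                 base_seed = as.integer(base_seed), direction = direction,
                 model = match.arg(model), ionic = match.arg(ionic),
                 T_check = T_check %||%
                   if (direction == "LP") 120 else 300,
                 dt_p = dt_p),
            class = "ensemble_spec")
}

#' Run a Monte-Carlo fibrosis ensemble
#'
#' For every `(phi, realization)`: apply the seeded fibrosis, stimulate a
#' plane wave (left edge for LP, bottom edge for TP), simulate to the
#' reentry check time and record the outcome ([detect_reentry()]), the
#' NA/A/S/NS activity-class percentages, the activity stop time and (when
#' the wave traversed) the conduction velocity. Individual run failures are
#' recorded and the ensemble continues.
#'
#' @param spec An [ensemble_spec()].
#' @param base A `cell_network` (for `model = "discrete"`) or `tissue_mesh`.
#' @param progress Print one line per phi.
#' @return Object of class `ensemble_result`: `runs` (one row per
#'   realization) and `summary` (per phi: `n`, `n_reentry`, `P`, Wilson 95%
#'   `CI_low`/`CI_high`, mean/SD conduction velocity over traversing runs).
#' @export
run_ensemble <- function(spec, base, progress = interactive()) {
  stopifnot(inherits(spec, "ensemble_spec"))
  ionic <- switch(spec$ionic, surrogate = surrogate_model(),
                  bondarenko = bondarenko_model())
  params <- monodomain_params(dt_p = spec$dt_p)
  protocol <- stimulus_protocol(
    if (spec$direction == "LP") "left_edge" else "bottom_edge")
  runs <- vector("list", length(spec$phi) * spec$n_realizations)
  k <- 0L
  for (ip in seq_along(spec$phi)) {
    ph <- spec$phi[ip]
    for (r in seq_len(spec$n_realizations)) {
      k <- k + 1L
      seed <- spec$base_seed + 1000L * ip + r
      runs[[k]] <- tryCatch(
        .ensemble_run(spec, base, ph, seed, ionic, params, protocol),
        error = function(e)
          data.frame(phi = ph, seed = seed, ok = FALSE, reentry = NA,
                     cv = NA_real_, traversed = NA, stop_time = NA_real_,
                     pct_NA = NA_real_, pct_A = NA_real_, pct_S = NA_real_,
                     pct_NS = NA_real_, error = conditionMessage(e)))
    }
    if (progress)
      message(sprintf("phi = %.2f done (%d runs)", ph,
                      spec$n_realizations))
  }
  runs <- do.call(rbind, runs)
  structure(list(runs = runs, summary = .summarize_ensemble(runs),
                 spec = spec), class = "ensemble_result")
}

.ensemble_run <- function(spec, base, phi, seed, ionic, params, protocol) {
  xb <- apply_fibrosis(base, phi, seed)
  T_end <- ceiling(spec$T_check / params$dt_p) * params$dt_p
  sim <- if (spec$model == "discrete")
    simulate_discrete(xb, ionic, params, protocol, T_end = T_end,
                      stop_when_quiescent = TRUE)
  else
    simulate_microscopic(xb, ionic, params, protocol, T_end = T_end,
                         stop_when_quiescent = TRUE)
  reentry <- detect_reentry(sim, spec$direction, check_time = spec$T_check)
  cls <- classify_activity(sim)
  cv <- .ensemble_cv(sim, xb, spec$direction)
  stop_time <- if (all(is.na(sim$last_active))) NA_real_
               else max(sim$last_active, na.rm = TRUE)
  data.frame(phi = phi, seed = seed, ok = TRUE, reentry = reentry,
             cv = cv$cv, traversed = cv$traversed,
             stop_time = stop_time,
             pct_NA = cls$percent[["NA"]], pct_A = cls$percent[["A"]],
             pct_S = cls$percent[["S"]], pct_NS = cls$percent[["NS"]],
             error = NA_character_)
}

# conduction velocity between two probe bands at 1/4 and 3/4 of the tissue
# extent along the propagation axis (first activation within each band)
.ensemble_cv <- function(sim, x, direction) {
  xs <- sim$meta$x_um; ys <- sim$meta$y_um
  pos <- if (direction == "LP") xs else ys
  lo <- min(pos) + 0.25 * diff(range(pos))
  hi <- min(pos) + 0.75 * diff(range(pos))
  t1 <- suppressWarnings(min(sim$activation[abs(pos - lo) < 50],
                             na.rm = TRUE))
  t2 <- suppressWarnings(min(sim$activation[abs(pos - hi) < 50],
                             na.rm = TRUE))
  traversed <- is.finite(t1) && is.finite(t2) && t2 > t1
  cv <- if (traversed) (hi - lo) / (t2 - t1) else NA_real_
  list(cv = cv, traversed = traversed)
}

.summarize_ensemble <- function(runs) {
  out <- lapply(split(runs, runs$phi), function(d) {
    ok <- d[d$ok %in% TRUE, , drop = FALSE]
    n <- nrow(ok)
    x <- sum(ok$reentry %in% TRUE)
    ci <- .wilson_ci(x, n)
    data.frame(phi = d$phi[1], n = n, n_reentry = x,
               P = if (n) x / n else NA_real_,
               CI_low = ci[1], CI_high = ci[2],
               cv_mean = mean(ok$cv[ok$traversed %in% TRUE]),
               cv_sd = sd(ok$cv[ok$traversed %in% TRUE]),
               n_traversed = sum(ok$traversed %in% TRUE),
               n_failed = nrow(d) - n)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Wilson 95% binomial interval
.wilson_ci <- function(x, n, z = 1.959964) {
  if (!n) return(c(NA_real_, NA_real_))
  p <- x / n
  den <- 1 + z^2 / n
  c0 <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, c0 - hw), min(1, c0 + hw))
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat("ensemble_result: ", x$spec$model, " model, ", x$spec$direction,
      " stimulus, ", x$spec$n_realizations, " realizations per phi\n",
      sep = "")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Plot the reentry probability curve of an ensemble
#'
#' @param x An `ensemble_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ensemble_result <- function(x, ...) {
  s <- x$summary
  graphics::plot(s$phi, s$P, type = "b", pch = 16, ylim = c(0, 1),
                 xlab = expression(phi), ylab = "P(reentry)", ...)
  graphics::arrows(s$phi, s$CI_low, s$phi, s$CI_high, angle = 90,
                   code = 3, length = 0.03)
  invisible(x)
}
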