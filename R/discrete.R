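# The equivalent discrete model: one isopotential node per myocyte, with
# pairwise conductances obtained by reducing the cytoplasm + gap-junction
# resistor network of the microstructure (series path resistance per
# junction, parallel combination over the junctions of a cell pair).

#' Gap-junction links of a mesh
#'
#' One link per gap-junction face, with the cells on both sides, the
#' junction volume coordinates `gp` (the two face-adjacent volumes), the
#' junction type and its conductance `G_k` (uS).
#'
#' @param mesh A `tissue_mesh`.
#' @return data.frame with columns `cell_i`, `cell_j`, `gi_x`, `gi_y`,
#'   `gj_x`, `gj_y`, `type`, `G`.
#' @export
identify_cell_adjacency <- function(mesh) {
  stopifnot(inherits(mesh, "tissue_mesh"))
  .junction_faces(mesh, periodic = FALSE)
}

#' Manhattan path distance of a junction (volume count)
#'
#' `dist = |pr_i - gp_i|_1 + |pr_j - gp_j|_1`: the number of
#' cytoplasm-connected volumes the current crosses from the reference volume
#' of cell i through gap junction k to the reference volume of cell j,
#' evaluated as pure index arithmetic.
#'
#' @param pr_i,gp_i,pr_j,gp_j Volume index pairs `c(ix, iy)`.
#' @return Integer distance (dimensionless volume count).
#' @examples
#' path_distance(c(10, 3), c(12, 3), c(15, 3), c(13, 3)) # 4
#' @export
path_distance <- function(pr_i, gp_i, pr_j, gp_j) {
  sum(abs(pr_i - gp_i)) + sum(abs(pr_j - gp_j))
}

#' Series resistance of one junction path
#'
#' `R = dist / (sigma_c h) + 1 / G_k`: cytoplasmic path resistance in series
#' with the junction resistance.
#'
#' @param dist Volume count from [path_distance()].
#' @param G_k Junction conductance, uS.
#' @param sigma_c Cytoplasm conductivity, uS/um.
#' @param h Volume edge, um.
#' @return Resistance in 1/uS.
#' @examples
#' junction_resistance(4, 0.5) # 3.25
#' @export
junction_resistance <- function(dist, G_k, sigma_c = 0.4, h = 8) {
  if (any(G_k <= 0))
    stop("G_k must be positive (isolated junctions are removed upstream)",
         call. = FALSE)
  if (any(dist < 0) || sigma_c <= 0 || h <= 0)
    stop("dist must be >= 0 and sigma_c, h positive", call. = FALSE)
  dist / (sigma_c * h) + 1 / G_k
}

#' Equivalent conductance of a cell pair
#'
#' Parallel combination `G_ij = 1 / R_ij`, `1/R_ij = sum_k 1/R_ijk` over the
#' junctions connecting one cell pair.
#'
#' @param R_ijk Per-junction series resistances (1/uS), length >= 1.
#' @return Equivalent conductance, uS.
#' @examples
#' equivalent_conductance(c(2, 2)) # 1
#' @export
equivalent_conductance <- function(R_ijk) {
  if (!length(R_ijk))
    stop("cell pair has no junctions: not adjacent", call. = FALSE)
  sum(1 / R_ijk)
}

#' Reduce a mesh to the equivalent discrete cell network
#'
#' Builds the one-node-per-myocyte network: node areas `A_i` (um^2, volume
#' count times h^2), reference volumes `pr_i` (the cell volume closest to
#' the cell centroid, ties to the lowest `(x, y)` index), and one aggregated
#' equivalent conductance `G_ij` per adjacent cell pair from the
#' series/parallel reduction.
#'
#' @param mesh A `tissue_mesh`.
#' @param audit If `TRUE`, attach the per-junction table (`links_audit`).
#' @return Object of class `cell_network`: `nodes` (id, area, pr, centroid,
#'   boundary-touch flags), `links` (i, j, `G` in uS, `ng` junction count),
#'   `h`, `d`, and the source mesh hash.
#' @examples
#' nw <- reduce_to_network(build_template())
#' nrow(nw$nodes) # 32
#' @export
reduce_to_network <- function(mesh, audit = FALSE) {
  stopifnot(inherits(mesh, "tissue_mesh"))
  bb <- .cell_bbox(mesh$cell_id)
  nc <- mesh$n_cells

  # reference volume per cell: nearest to centroid, ties to lowest (x, y)
  ix <- as.integer(row(mesh$cell_id)); iy <- as.integer(col(mesh$cell_id))
  f <- as.integer(mesh$cell_id)
  cx <- as.numeric(tapply(ix, factor(f, levels = 1:nc), mean))
  cy <- as.numeric(tapply(iy, factor(f, levels = 1:nc), mean))
  d2 <- (ix - cx[f])^2 + (iy - cy[f])^2
  ord <- order(f, d2, ix, iy)
  first <- ord[!duplicated(f[ord])]
  pr_x <- integer(nc); pr_y <- integer(nc)
  pr_x[f[first]] <- ix[first]
  pr_y[f[first]] <- iy[first]

  nodes <- data.frame(
    id = seq_len(nc),
    area = bb$nvol * mesh$h^2,
    nvol = bb$nvol,
    pr_x = pr_x, pr_y = pr_y,
    cx = cx * mesh$h, cy = cy * mesh$h,
    touch_l = bb$xmin == 1L, touch_r = bb$xmax == mesh$nx,
    touch_b = bb$ymin == 1L, touch_t = bb$ymax == mesh$ny)

  lk <- identify_cell_adjacency(mesh)
  if (nrow(lk)) {
    i <- pmin(lk$cell_i, lk$cell_j); j <- pmax(lk$cell_i, lk$cell_j)
    # orient gp coordinates with the (i, j) ordering
    swap <- lk$cell_i > lk$cell_j
    gi_x <- ifelse(swap, lk$gj_x, lk$gi_x)
    gi_y <- ifelse(swap, lk$gj_y, lk$gi_y)
    gj_x <- ifelse(swap, lk$gi_x, lk$gj_x)
    gj_y <- ifelse(swap, lk$gi_y, lk$gj_y)
    dist <- abs(pr_x[i] - gi_x) + abs(pr_y[i] - gi_y) +
      abs(pr_x[j] - gj_x) + abs(pr_y[j] - gj_y)
    R <- junction_resistance(dist, lk$G, mesh$table$sigma_c, mesh$h)
    key <- paste(i, j)
    Ginv <- rowsum(1 / R, key)          # sum_k 1/R_ijk
    ng <- rowsum(rep(1L, length(R)), key)
    pr <- do.call(rbind, strsplit(rownames(Ginv), " "))
    links <- data.frame(i = as.integer(pr[, 1L]), j = as.integer(pr[, 2L]),
                        G = as.numeric(Ginv), ng = as.integer(ng))
    links <- links[order(links$i, links$j), ]
    rownames(links) <- NULL
  } else {
    links <- data.frame(i = integer(), j = integer(), G = numeric(),
                        ng = integer())
  }

  nw <- structure(list(nodes = nodes, links = links,
                       n = nc, h = mesh$h, d = mesh$d,
                       nx = mesh$nx, ny = mesh$ny,
                       sigma_c = mesh$table$sigma_c,
                       removed = integer(0),
                       mesh_hash = mesh_hash(mesh)),
                  class = "cell_network")
  if (audit && nrow(lk)) {
    nw$links_audit <- data.frame(i = i, j = j, dist = dist, G_k = lk$G,
                                 type = lk$type, R = R)
  }
  nw
}

#' Assemble the diffusion system of a cell network
#'
#' The implicit-Euler network diffusion stage
#' `(diag(alpha_i) + L_G) V^{n+1} = alpha * V*` with
#' `alpha_i = beta C_m A_i d / dt_p` (uS) and the weighted graph Laplacian
#' of the equivalent conductances.
#'
#' @param network A `cell_network`.
#' @param params [monodomain_params()].
#' @return A `diffusion_system`.
#' @export
assemble_network_system <- function(network, params = monodomain_params()) {
  stopifnot(inherits(network, "cell_network"))
  # beta C_m A_i d / dt_p: (1/um)(nF/um^2)(um^2)(um)/ms = nF/ms = uS
  alpha <- params$beta * params$C_m * network$nodes$area * network$d /
    params$dt_p
  lk <- network$links
  .build_system(network$n, lk$i, lk$j, lk$G, alpha,
                meta = list(kind = "discrete", alpha = alpha))
}

#' Simulate the discrete cell-network model
#'
#' Same Godunov splitting as [simulate_microscopic()], with one state per
#' myocyte and the network diffusion solve of [assemble_network_system()].
#'
#' @param network A `cell_network` (see [reduce_to_network()],
#'   [apply_fibrosis()]).
#' @inheritParams simulate_microscopic
#' @param probes Cell ids whose V is recorded every `dt_p`.
#' @return A `sim_result` indexed by cell id.
#' @export
simulate_discrete <- function(network, ionic, params = monodomain_params(),
                              protocol = stimulus_protocol("left_edge"),
                              T_end = 20, probes = integer(0),
                              snapshot_times = numeric(0), ...) {
  stopifnot(inherits(network, "cell_network"), inherits(ionic, "ionic_model"))
  system <- assemble_network_system(network, params)
  meta <- list(kind = "discrete", region_host = network,
               mesh_hash = network$mesh_hash,
               x_um = network$nodes$cx, y_um = network$nodes$cy)
  .simulate_core(system, ionic, params, protocol, T_end,
                 probes = probes, snapshot_times = snapshot_times,
                 meta = meta, ...)
}

#' @export
print.cell_network <- function(x, ...) {
  cat("cell_network: ", x$n, " cells, ", nrow(x$links),
      " links (equivalent conductances)\n", sep = "")
  if (length(x$removed))
    cat("  fibrosis: ", length(x$removed), " cells isolated (phi = ",
        signif(length(x$removed) / x$n, 3), ")\n", sep = "")
  if (nrow(x$links))
    cat("  G_ij (uS): min ", signif(min(x$links$G), 3), ", median ",
        signif(stats::median(x$links$G), 3), ", max ",
        signif(max(x$links$G), 3), "\n", sep = "")
  invisible(x)
}

#' @export
summary.cell_network <- function(object, ...) {
  print(object)
  deg <- tabulate(c(object$links$i, object$links$j), nbins = object$n)
  cat("  degree: mean ", signif(mean(deg), 4), ", range [",
      min(deg), ", ", max(deg), "]\n", sep = "")
  invisible(object)
}

#' Plot a cell network
#'
#' Draws nodes at cell centroids and links shaded by conductance.
#'
#' @param x A `cell_network`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cell_network <- function(x, ...) {
  nd <- x$nodes; lk <- x$links
  graphics::plot(nd$cx, nd$cy, pch = 16, cex = 0.5, asp = 1,
                 xlab = "x (um)", ylab = "y (um)", ...)
  if (nrow(lk)) {
    w <- lk$G / max(lk$G)
    graphics::segments(nd$cx[lk$i], nd$cy[lk$i], nd$cx[lk$j], nd$cy[lk$j],
                       col = grDevices::gray(1 - 0.8 * w))
  }
  if (length(x$removed))
    graphics::points(nd$cx[x$removed], nd$cy[x$removed], pch = 4,
                     col = "red")
  invisible(x)
}
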