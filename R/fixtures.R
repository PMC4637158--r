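# Hand-checkable toy fixtures used by the oracle tests and the CLI
# `make-fixtures` subcommand. Everything is built in code.

#' Build the toy fixtures
#'
#' Returns (and optionally writes to `dir`) the small hand-checkable
#' objects used by the oracle tests:
#' * `mesh_2cell`: two 4 x 2-volume cells abutting end-to-end with a known
#'   plicate junction layout;
#' * `mesh_pair_membrane`: the same two cells separated by membrane only;
#' * `lattice_3x3`: a 3 x 3 toy cell network with unit conductances;
#' * `ring`: an n-cell ring network with one weak (slow) link;
#' * `rest_field`: a uniform resting field for conservation tests.
#'
#' @param dir Optional directory to serialize the fixtures into.
#' @param ring_n Ring size.
#' @param ring_G,ring_G_slow Normal and slow link conductances, uS.
#' @return Named list of fixtures.
#' @export
make_fixtures <- function(dir = NULL, ring_n = 12, ring_G = 0.25,
                          ring_G_slow = 0.02) {
  fx <- list(
    mesh_2cell = fixture_two_cell_mesh(junction = "PLICATE"),
    mesh_pair_membrane = fixture_two_cell_mesh(junction = "MEMBRANE"),
    lattice_3x3 = fixture_lattice_network(3, 3),
    ring = fixture_ring_network(ring_n, ring_G, ring_G_slow),
    rest_field = rep(-82, 25))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_mesh(fx$mesh_2cell, file.path(dir, "mesh_2cell.txt"))
    write_mesh(fx$mesh_pair_membrane,
               file.path(dir, "mesh_pair_membrane.txt"))
    write_network(fx$lattice_3x3, file.path(dir, "lattice_3x3"))
    write_network(fx$ring, file.path(dir, "ring"))
  }
  fx
}

#' Two-cell toy mesh
#'
#' Two 4 x 2-volume cells side by side along the fiber axis. With
#' `junction = "PLICATE"` the two faces of the abutment both carry plicate
#' junctions; `"MEMBRANE"` isolates the cells; `"SINGLE"` keeps one
#' junction on the lower lane only.
#'
#' @param junction Abutment type.
#' @return A `tissue_mesh` of 2 cells on an 8 x 2 grid.
#' @export
fixture_two_cell_mesh <- function(junction = c("PLICATE", "MEMBRANE",
                                               "SINGLE")) {
  junction <- match.arg(junction)
  cid <- matrix(0L, 8L, 2L)
  cid[1:4, ] <- 1L
  cid[5:8, ] <- 2L
  fe <- matrix(NA_integer_, 8L, 2L)
  fn <- matrix(NA_integer_, 8L, 2L)
  fe[c(1:3, 5:7), ] <- .FT[["CYTOPLASM"]]
  fn[, 1L] <- .FT[["CYTOPLASM"]]
  fe[4L, ] <- switch(junction,
                     PLICATE = .FT[["PLICATE"]],
                     MEMBRANE = .FT[["MEMBRANE"]],
                     SINGLE = c(.FT[["PLICATE"]], .FT[["MEMBRANE"]]))
  .new_mesh(cid, fe, fn, h = 8, d = 10)
}

#' Toy lattice cell network
#'
#' `nx x ny` cells on a square lattice with unit-conductance links, unit
#' areas scaled to one 8 um volume, for connectivity oracles.
#'
#' @param nx,ny Lattice dimensions.
#' @param G Link conductance, uS.
#' @return A `cell_network`.
#' @export
fixture_lattice_network <- function(nx, ny, G = 1) {
  n <- nx * ny
  id <- matrix(seq_len(n), nx, ny)
  links <- rbind(
    data.frame(i = as.integer(id[-nx, , drop = FALSE]),
               j = as.integer(id[-1L, , drop = FALSE])),
    data.frame(i = as.integer(id[, -ny, drop = FALSE]),
               j = as.integer(id[, -1L, drop = FALSE])))
  links$G <- G
  links$ng <- 1L
  nodes <- data.frame(
    id = seq_len(n),
    area = 64, nvol = 1L,
    pr_x = as.integer(row(id)), pr_y = as.integer(col(id)),
    cx = as.numeric(row(id)) * 8, cy = as.numeric(col(id)) * 8,
    touch_l = as.integer(row(id)) == 1L,
    touch_r = as.integer(row(id)) == nx,
    touch_b = as.integer(col(id)) == 1L,
    touch_t = as.integer(col(id)) == ny)
  structure(list(nodes = nodes, links = links, n = n, h = 8, d = 10,
                 nx = nx, ny = ny, sigma_c = 0.4, removed = integer(0),
                 mesh_hash = "fixture"),
            class = "cell_network")
}

#' Ring cell network with one slow link
#'
#' An `n`-cell ring whose links all have conductance `G` except one weak
#' (slow) link `G_slow`; used to build a circulating excitation
#' (unidirectional block) oracle for reentry detection.
#'
#' @param n Ring size.
#' @param G,G_slow Conductances, uS.
#' @param area Node area, um^2 (default one mean myocyte, ~30 volumes).
#' @return A `cell_network`.
#' @export
fixture_ring_network <- function(n = 12, G = 0.25, G_slow = 0.02,
                                 area = 30 * 64) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  r <- 200
  nodes <- data.frame(
    id = seq_len(n), area = area, nvol = as.integer(area / 64),
    pr_x = 1L, pr_y = 1L,
    cx = r * cos(th), cy = r * sin(th),
    touch_l = FALSE, touch_r = FALSE, touch_b = FALSE, touch_t = FALSE)
  links <- data.frame(i = seq_len(n),
                      j = c(seq_len(n)[-1L], 1L),
                      G = c(rep(G, n - 1L), G_slow),
                      ng = 1L)
  structure(list(nodes = nodes, links = links, n = n, h = 8, d = 10,
                 nx = NA_integer_, ny = NA_integer_, sigma_c = 0.4,
                 removed = integer(0), mesh_hash = "fixture"),
            class = "cell_network")
}
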