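# Myocyte-resolved microstructure: the frozen 32-cell template unit on the
# 8 um grid, tiling, face typing and geometry statistics.
#
# Volume indexing is 1-based, [ix, iy], with ix along the fiber (x) axis.
# Faces are identified by the lower-index volume: face_e[ix, iy] sits between
# volumes (ix, iy) and (ix + 1, iy); face_n[ix, iy] between (ix, iy) and
# (ix, iy + 1). For a tileable mesh the columns ix = nx / iy = ny hold the
# wrap-around (seam) face types used when units are abutted; they are ignored
# by the solvers, for which boundary faces are no-flux.

## Face type codes ------------------------------------------------------------

#' Face connection types
#'
#' Every interior face of a tissue mesh carries exactly one of five connection
#' types: `MEMBRANE` (no flux), `CYTOPLASM` (within one cell), and three gap
#' junction classes: `PLICATE` (aligned end-to-end abutments between cells),
#' `INTERPLICATE` (stepped or offset longitudinal contacts) and
#' `COMBINED_PLICATE` (lateral side-to-side contacts).
#'
#' @return Named integer vector mapping type names to the codes stored in
#'   `face_e` / `face_n` matrices of a [tissue_mesh].
#' @examples
#' face_types()
#' @export
face_types <- function() {
  c(MEMBRANE = 0L, CYTOPLASM = 1L, PLICATE = 2L,
    INTERPLICATE = 3L, COMBINED_PLICATE = 4L)
}

.FT <- face_types()

#' Conductance table for the five connection types
#'
#' Conductivities and gap-junction conductances of the microstructure:
#' membrane `sigma_m = 0`, cytoplasm `sigma_c = 0.4` uS/um, plicate
#' `G_p = 0.5` uS, interplicate `G_i = 0.33` uS and combined plicate
#' `G_c = 0.062` uS.
#'
#' @param sigma_m,sigma_c Conductivities in uS/um.
#' @param G_p,G_i,G_c Gap-junction conductances in uS.
#' @return Object of class `conductance_table`.
#' @examples
#' conductance_table()
#' @export
conductance_table <- function(sigma_m = 0.0, sigma_c = 0.4,
                              G_p = 0.5, G_i = 0.33, G_c = 0.062) {
  if (sigma_m != 0)
    stop("sigma_m must be 0: the membrane is non-conducting", call. = FALSE)
  if (any(c(sigma_c, G_p, G_i, G_c) <= 0))
    stop("sigma_c, G_p, G_i, G_c must all be positive", call. = FALSE)
  structure(list(sigma_m = sigma_m, sigma_c = sigma_c,
                 G_p = G_p, G_i = G_i, G_c = G_c),
            class = "conductance_table")
}

#' Face transmission coefficient
#'
#' Maps a face type to the coefficient entering the finite-volume diffusion
#' stencil, in uS/um: 0 for membrane, `sigma_c` for cytoplasm, and `G / d`
#' for the three gap-junction conductances (the lumped junction conductance
#' spread over the tissue depth `d`).
#'
#' @param ftype Face type: a code from [face_types()] or its name.
#' @param table A [conductance_table()].
#' @param d Tissue depth in um (default 10).
#' @return Numeric vector of coefficients in uS/um.
#' @examples
#' face_coefficient("PLICATE", d = 10) # 0.05
#' @export
face_coefficient <- function(ftype, table = conductance_table(), d = 10) {
  if (d <= 0) stop("depth d must be positive", call. = FALSE)
  if (is.character(ftype)) {
    bad <- setdiff(ftype, names(.FT))
    if (length(bad)) stop("unknown face type: ", bad[1], call. = FALSE)
    ftype <- .FT[ftype]
  }
  if (!all(ftype %in% .FT)) stop("unknown face type code", call. = FALSE)
  per <- c(table$sigma_m, table$sigma_c,
           table$G_p / d, table$G_i / d, table$G_c / d)
  unname(per[as.integer(ftype) + 1L])
}

## Template specification ------------------------------------------------------

#' Specification of the basic 32-myocyte template unit
#'
#' Target geometry statistics for the basic template unit: 32 cells on an
#' 8 um grid with depth 10 um, mean cell length 120.9 um (SD 27.8), mean
#' width 18.3 um (SD 3.5) and on average 6 neighboring myocytes per cell.
#' The realized template is a frozen deterministic layout (see
#' [build_template()]); [build_template()] validates that the frozen layout
#' meets the requested targets and errors otherwise.
#'
#' @param h Spatial step in um (fixed at 8).
#' @param d Tissue depth in um (fixed at 10).
#' @param n_cells Number of myocytes in the unit (fixed at 32).
#' @param target_mean_length,target_sd_length Cell length targets, um.
#' @param target_mean_width,target_sd_width Cell width targets, um.
#' @param target_mean_neighbors Mean number of connected neighboring cells.
#' @param junction_coverage Gap-junction placement densities, named:
#'   `plicate`, `interplicate`, `combined_plicate` are the fractions of
#'   faces of each contact class that carry a junction (the rest are
#'   membrane); `lateral_interplicate` is the fraction of each side-to-side
#'   contact, taken at the two ends of the contact run (the intercalated
#'   disc region), promoted to interplicate junctions. The defaults are the
#'   frozen calibration for which homogeneous conduction velocities reach
#'   410 um/ms (longitudinal) and 130 um/ms (transversal) with the
#'   Bondarenko kinetics; at least one junction face per contact is always
#'   kept, so connectivity is independent of coverage.
#' @param rng_seed Integer recorded in the mesh metadata. The layout itself
#'   is a versioned constant and does not depend on it.
#' @return Object of class `template_spec`.
#' @export
template_spec <- function(h = 8, d = 10, n_cells = 32,
                          target_mean_length = 120.9, target_sd_length = 27.8,
                          target_mean_width = 18.3, target_sd_width = 3.5,
                          target_mean_neighbors = 6,
                          junction_coverage = c(plicate = 1.0,
                                                interplicate = 0.6,
                                                combined_plicate = 0.7,
                                                lateral_interplicate = 0.55),
                          rng_seed = 1L) {
  if (h <= 0 || d <= 0) stop("h and d must be positive", call. = FALSE)
  cov <- junction_coverage
  if (is.null(names(cov)) ||
      !all(c("plicate", "interplicate", "combined_plicate") %in% names(cov)))
    stop("junction_coverage needs named entries plicate, interplicate, ",
         "combined_plicate", call. = FALSE)
  if (!"lateral_interplicate" %in% names(cov))
    cov[["lateral_interplicate"]] <- 0
  core <- cov[c("plicate", "interplicate", "combined_plicate")]
  if (any(core <= 0 | core > 1))
    stop("junction_coverage fractions must lie in (0, 1]", call. = FALSE)
  if (cov[["lateral_interplicate"]] < 0 || cov[["lateral_interplicate"]] > 1)
    stop("lateral_interplicate must lie in [0, 1]", call. = FALSE)
  structure(list(h = h, d = d, n_cells = as.integer(n_cells),
                 target_mean_length = target_mean_length,
                 target_sd_length = target_sd_length,
                 target_mean_width = target_mean_width,
                 target_sd_width = target_sd_width,
                 target_mean_neighbors = target_mean_neighbors,
                 junction_coverage = cov,
                 rng_seed = as.integer(rng_seed)),
            class = "template_spec")
}

## Frozen template layout ------------------------------------------------------
#
# The unit is 60 x 18 volumes (480 um x 144 um). It consists of two
# side-by-side half-units of 30 columns whose row banding is vertically
# offset (left half boundaries {2,4,6,9,11,13,15}, right half
# {3,5,7,10,12,14,16}); every longitudinal contact between half-units (and
# across the tile seam) is therefore stepped. Each row of a half-unit holds
# two cells split at a per-row breakpoint; in two rows the split is itself
# stepped by one lane, producing interdigitated cell ends. 2 rows per
# half-unit are 3 volumes high, the rest 2, so cell widths are 16 or 24 um.
# The layout is frozen; only its summary statistics are spec-level contracts.

.template_layout <- function() {
  heights_A <- c(2L, 2L, 2L, 3L, 2L, 2L, 2L, 3L)
  heights_B <- c(3L, 2L, 2L, 3L, 2L, 2L, 2L, 2L)
  bp_A <- c(9L, 19L, 12L, 17L, 11L, 18L, 13L, 16L)   # split columns, left half
  bp_B <- c(20L, 10L, 18L, 12L, 19L, 11L, 17L, 13L)  # split columns, right half
  list(nx = 60L, ny = 18L, half = 30L,
       heights_A = heights_A, heights_B = heights_B,
       bp_A = bp_A, bp_B = bp_B,
       # rows whose split is stepped: the left cell annexes two extra volumes
       # of its top lane past the breakpoint
       step_A = 1L, step_B = 2L)
}

.template_cell_id <- function() {
  lay <- .template_layout()
  cid <- matrix(0L, lay$nx, lay$ny)
  y0 <- 0L
  for (r in seq_along(lay$heights_A)) {   # left half, cells 1..16
    hgt <- lay$heights_A[r]
    rows <- (y0 + 1L):(y0 + hgt)
    cid[1:lay$bp_A[r], rows] <- 2L * r - 1L
    cid[(lay$bp_A[r] + 1L):lay$half, rows] <- 2L * r
    y0 <- y0 + hgt
  }
  y0 <- 0L
  for (r in seq_along(lay$heights_B)) {   # right half, cells 17..32
    hgt <- lay$heights_B[r]
    rows <- (y0 + 1L):(y0 + hgt)
    cid[(lay$half + 1L):(lay$half + lay$bp_B[r]), rows] <- 15L + 2L * r
    cid[(lay$half + lay$bp_B[r] + 1L):lay$nx, rows] <- 16L + 2L * r
    y0 <- y0 + hgt
  }
  # stepped (interdigitated) splits: left cell keeps 2 extra top-lane volumes
  r <- lay$step_A
  top <- sum(lay$heights_A[seq_len(r)])
  cid[(lay$bp_A[r] + 1L):(lay$bp_A[r] + 2L), top] <- 2L * r - 1L
  r <- lay$step_B
  top <- sum(lay$heights_B[seq_len(r)])
  cid[(lay$half + lay$bp_B[r] + 1L):(lay$half + lay$bp_B[r] + 2L), top] <-
    15L + 2L * r
  cid
}

## Face classification ---------------------------------------------------------

# Classify every face (including wrap-around seams when torus = TRUE) of a
# cell_id matrix, with full junction coverage. Returns nx x ny integer
# matrices face_e, face_n; non-torus outer faces are NA.
.classify_faces <- function(cid, torus = TRUE) {
  nx <- nrow(cid); ny <- ncol(cid)
  east_nb <- cid[c(2:nx, 1L), , drop = FALSE]
  north_nb <- cid[, c(2:ny, 1L), drop = FALSE]

  # bounding boxes and x-planes of vertical contacts, computed on the torus
  # representation used for typing
  ys <- .cell_bbox(cid)

  face_e <- matrix(NA_integer_, nx, ny)
  face_n <- matrix(NA_integer_, nx, ny)

  same_e <- cid == east_nb
  same_n <- cid == north_nb
  face_e[same_e] <- .FT[["CYTOPLASM"]]
  face_n[same_n] <- .FT[["CYTOPLASM"]]

  # vertical (east) faces between distinct cells: PLICATE when the contact is
  # a flat aligned end-to-end abutment (equal y-spans, single x-plane),
  # INTERPLICATE otherwise
  idx_e <- which(!same_e)
  if (length(idx_e)) {
    ix <- (idx_e - 1L) %% nx + 1L
    a <- cid[idx_e]; b <- east_nb[idx_e]
    key <- paste(pmin(a, b), pmax(a, b))
    spans_eq <- ys$ymin[a] == ys$ymin[b] & ys$ymax[a] == ys$ymax[b]
    one_plane <- ave(ix, key, FUN = function(v) length(unique(v))) == 1L
    face_e[idx_e] <- ifelse(spans_eq & one_plane,
                            .FT[["PLICATE"]], .FT[["INTERPLICATE"]])
  }
  idx_n <- which(!same_n)
  face_n[idx_n] <- .FT[["COMBINED_PLICATE"]]

  if (!torus) {
    face_e[nx, ] <- NA_integer_
    face_n[, ny] <- NA_integer_
  }
  list(face_e = face_e, face_n = face_n)
}

.cell_bbox <- function(cid) {
  ix <- as.integer(row(cid)); iy <- as.integer(col(cid))
  f <- factor(as.integer(cid), levels = seq_len(max(cid)))
  list(xmin = as.integer(tapply(ix, f, min)),
       xmax = as.integer(tapply(ix, f, max)),
       ymin = as.integer(tapply(iy, f, min)),
       ymax = as.integer(tapply(iy, f, max)),
       nvol = as.integer(table(f)))
}

# Junction placement along each intercellular contact. Two deterministic
# operations per (cell pair, face class) group:
#  * lateral contacts first have `lateral_interplicate` of their faces, at
#    the two ends of the contact run, promoted to INTERPLICATE: the lateral
#    borders nearest the cell ends belong to the intercalated disc and carry
#    the larger junctions;
#  * every class is then thinned to its coverage fraction, kept faces evenly
#    spaced along the contact, at least one per contact (so cell adjacency
#    is independent of coverage), the rest becoming MEMBRANE.
.apply_coverage <- function(faces, cid, coverage, torus = TRUE) {
  nx <- nrow(cid); ny <- ncol(cid)
  east_nb <- cid[c(2:nx, 1L), , drop = FALSE]
  north_nb <- cid[, c(2:ny, 1L), drop = FALSE]

  frac_li <- if ("lateral_interplicate" %in% names(coverage))
    coverage[["lateral_interplicate"]] else 0
  frac_of <- c(rep(NA_real_, 2),
               coverage[["plicate"]], coverage[["interplicate"]],
               coverage[["combined_plicate"]])
  thin <- function(face, nb) {
    idx <- which(face %in% .FT[c("PLICATE", "INTERPLICATE", "COMBINED_PLICATE")])
    if (!length(idx)) return(face)
    a <- cid[idx]; b <- nb[idx]
    key <- paste(pmin(a, b), pmax(a, b), face[idx])
    for (grp in split(idx, key)) {
      ftype <- face[grp[1]]
      frac <- frac_of[ftype + 1L]
      n <- length(grp)
      k <- max(1L, as.integer(round(frac * n)))
      if (k >= n) next
      keep <- unique(as.integer(round((seq_len(k) - 0.5) / k * n + 0.5)))
      drop <- setdiff(seq_len(n), keep)
      face[grp[order(grp)][drop]] <- .FT[["MEMBRANE"]]
    }
    face
  }
  faces$face_e <- thin(faces$face_e, east_nb)
  faces$face_n <- thin(faces$face_n, north_nb)

  # intercalated-disc promotion, applied after thinning so it is independent
  # of the interplicate coverage of the longitudinal interfaces
  if (frac_li > 0) {
    face <- faces$face_n
    lateral <- cid != north_nb & !is.na(face)
    if (!torus) lateral[, ny] <- FALSE
    idx <- which(lateral)
    if (length(idx)) {
      a <- cid[idx]; b <- north_nb[idx]
      key <- paste(pmin(a, b), pmax(a, b))
      for (grp in split(idx, key)) {
        n <- length(grp)
        k <- .round_half_up(frac_li * n)
        if (k < 1L) next
        grp <- grp[order(grp)]
        ends <- unique(c(head(seq_len(n), ceiling(k / 2)),
                         tail(seq_len(n), floor(k / 2))))
        face[grp[ends]] <- .FT[["INTERPLICATE"]]
      }
      faces$face_n <- face
    }
  }
  faces
}

## Mesh constructor and template builder ---------------------------------------

.new_mesh <- function(cell_id, face_e, face_n, h, d, spec = NULL,
                      tileable = FALSE, unit_dim = NULL) {
  structure(list(nx = nrow(cell_id), ny = ncol(cell_id),
                 h = h, d = d,
                 cell_id = cell_id, face_e = face_e, face_n = face_n,
                 n_cells = max(cell_id),
                 tileable = tileable,
                 unit_dim = unit_dim %||% c(nrow(cell_id), ncol(cell_id)),
                 table = conductance_table(),
                 spec = spec),
            class = "tissue_mesh")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the basic 32-myocyte template unit
#'
#' Constructs the frozen basic unit of the cardiac microstructure: 32
#' myocytes on a 60 x 18 grid of 8 um volumes (480 um x 144 um, depth
#' 10 um). Cell shapes are staggered bricks with interdigitated ends whose
#' geometry statistics meet the `spec` targets; gap-junction face types are
#' placed deterministically with `PLICATE` at aligned end-to-end abutments,
#' `INTERPLICATE` at stepped/offset longitudinal contacts and
#' `COMBINED_PLICATE` at lateral contacts, thinned to the requested
#' `junction_coverage`. The unit is tileable: wrap-around face types are
#' stored in the last face column/row and reused at seams by
#' [tile_template()].
#'
#' @param spec A [template_spec()].
#' @return A `tissue_mesh`.
#' @examples
#' unit <- build_template()
#' cell_geometry_stats(unit)
#' @export
build_template <- function(spec = template_spec()) {
  stopifnot(inherits(spec, "template_spec"))
  if (spec$n_cells != 32L)
    stop("infeasible spec: the frozen template has n_cells = 32, got ",
         spec$n_cells, call. = FALSE)
  if (spec$h != 8)
    stop("infeasible spec: the template is defined on the h = 8 um grid",
         call. = FALSE)
  cid <- .template_cell_id()
  faces <- .classify_faces(cid, torus = TRUE)
  faces <- .apply_coverage(faces, cid, spec$junction_coverage, torus = TRUE)
  mesh <- .new_mesh(cid, faces$face_e, faces$face_n, spec$h, spec$d,
                    spec = spec, tileable = TRUE)
  st <- cell_geometry_stats(mesh)
  chk <- function(got, want, what) {
    if (abs(got - want) > 0.05 * want)
      stop("infeasible spec: frozen template ", what, " = ",
           signif(got, 4), " misses target ", want, " by more than 5%",
           call. = FALSE)
  }
  chk(st$mean_length, spec$target_mean_length, "mean_length")
  chk(st$mean_width, spec$target_mean_width, "mean_width")
  if (abs(st$mean_neighbors - spec$target_mean_neighbors) > 0.5)
    stop("infeasible spec: frozen template mean_neighbors = ",
         signif(st$mean_neighbors, 4), " misses target ",
         spec$target_mean_neighbors, " by more than 0.5", call. = FALSE)
  mesh
}

#' Tile a template unit into a larger tissue
#'
#' Lays `ux` by `uy` translated copies of a tileable unit. Cell ids are
#' relabeled globally unique; faces at the seams between copies carry the
#' unit's wrap-around face types.
#'
#' @param unit A tileable `tissue_mesh` (see [build_template()]).
#' @param ux,uy Number of copies along x (fiber) and y.
#' @return A `tissue_mesh` of `ux * uy * unit$n_cells` cells.
#' @examples
#' tis <- tile_template(build_template(), 2, 1)
#' tis$n_cells # 64
#' @export
tile_template <- function(unit, ux, uy) {
  stopifnot(inherits(unit, "tissue_mesh"))
  if (!isTRUE(unit$tileable))
    stop("mesh is not tileable: no wrap-around face types present",
         call. = FALSE)
  ux <- as.integer(ux); uy <- as.integer(uy)
  if (ux < 1L || uy < 1L) stop("ux and uy must be >= 1", call. = FALSE)
  if (ux == 1L && uy == 1L) return(unit)
  nx <- unit$nx; ny <- unit$ny; nc <- unit$n_cells
  NX <- nx * ux; NY <- ny * uy
  cid <- matrix(0L, NX, NY)
  fe <- matrix(NA_integer_, NX, NY)
  fn <- matrix(NA_integer_, NX, NY)
  for (ty in seq_len(uy)) for (tx in seq_len(ux)) {
    off <- ((ty - 1L) * ux + (tx - 1L)) * nc
    rows <- (tx - 1L) * nx + seq_len(nx)
    cols <- (ty - 1L) * ny + seq_len(ny)
    cid[rows, cols] <- unit$cell_id + off
    fe[rows, cols] <- unit$face_e
    fn[rows, cols] <- unit$face_n
  }
  .new_mesh(cid, fe, fn, unit$h, unit$d, spec = unit$spec,
            tileable = TRUE, unit_dim = c(nx, ny))
}

#' Tile a template to cover a physical tissue size
#'
#' Smallest tiling whose extent reaches at least `cm_x` by `cm_y`
#' centimetres (e.g. the 1 cm x 1 cm study tissue).
#'
#' @param unit A tileable `tissue_mesh`.
#' @param cm_x,cm_y Minimum tissue extent in cm.
#' @return A `tissue_mesh`.
#' @export
tile_to_size <- function(unit, cm_x = 1, cm_y = 1) {
  um_x <- cm_x * 1e4; um_y <- cm_y * 1e4
  ux <- ceiling(um_x / (unit$nx * unit$h))
  uy <- ceiling(um_y / (unit$ny * unit$h))
  tile_template(unit, ux, uy)
}

## Geometry statistics ----------------------------------------------------------

#' Cell geometry statistics of a mesh
#'
#' Length and width are axis-aligned bounding-box extents (um) along the
#' fiber (x) and transverse (y) axes; neighbors are distinct cells sharing at
#' least one gap-junction face.
#'
#' @param mesh A `tissue_mesh`.
#' @param neighbors How to count neighbors: `"periodic"` uses wrap-around
#'   faces of a tileable unit (a cell's neighborhood in an extended tissue),
#'   `"interior"` averages only over cells not touching the mesh boundary,
#'   `"all"` uses interior faces for every cell. Default: `"periodic"` for a
#'   tileable mesh, `"all"` otherwise.
#' @return Object of class `cell_stats`: mean/sd length and width (um) and
#'   mean neighbor count.
#' @examples
#' cell_geometry_stats(build_template())
#' @export
cell_geometry_stats <- function(mesh,
                                neighbors = c("auto", "periodic",
                                              "interior", "all")) {
  stopifnot(inherits(mesh, "tissue_mesh"))
  neighbors <- match.arg(neighbors)
  if (neighbors == "auto")
    neighbors <- if (isTRUE(mesh$tileable)) "periodic" else "all"
  bb <- .cell_bbox(mesh$cell_id)
  len <- (bb$xmax - bb$xmin + 1L) * mesh$h
  wid <- (bb$ymax - bb$ymin + 1L) * mesh$h

  deg <- .neighbor_degrees(mesh, periodic = neighbors == "periodic")
  if (neighbors == "interior") {
    inner <- bb$xmin > 1L & bb$ymin > 1L &
      bb$xmax < mesh$nx & bb$ymax < mesh$ny
    if (!any(inner))
      stop("no interior cells: mesh too small for interior neighbor counts",
           call. = FALSE)
    mean_nb <- mean(deg[inner])
  } else {
    mean_nb <- mean(deg)
  }
  structure(list(mean_length = mean(len), sd_length = sd(len),
                 mean_width = mean(wid), sd_width = sd(wid),
                 mean_neighbors = mean_nb, n_cells = mesh$n_cells),
            class = "cell_stats")
}

# Per-cell count of distinct cells sharing >= 1 gap-junction face.
.neighbor_degrees <- function(mesh, periodic = FALSE) {
  prs <- .junction_pairs(mesh, periodic = periodic)
  deg <- integer(mesh$n_cells)
  if (nrow(prs)) {
    tab <- table(factor(c(prs$i, prs$j), levels = seq_len(mesh$n_cells)))
    deg <- as.integer(tab)
  }
  deg
}

# Unique unordered cell pairs connected by >= 1 gap-junction face.
.junction_pairs <- function(mesh, periodic = FALSE) {
  lk <- .junction_faces(mesh, periodic = periodic)
  if (!nrow(lk)) return(data.frame(i = integer(), j = integer()))
  key <- paste(pmin(lk$cell_i, lk$cell_j), pmax(lk$cell_i, lk$cell_j))
  lk <- lk[!duplicated(key), c("cell_i", "cell_j")]
  data.frame(i = pmin(lk$cell_i, lk$cell_j), j = pmax(lk$cell_i, lk$cell_j))
}

# All gap-junction faces as a link table (one row per face): cell ids, the
# junction volume coordinates on both sides, type code and conductance G_k.
.junction_faces <- function(mesh, periodic = FALSE) {
  nx <- mesh$nx; ny <- mesh$ny
  gj <- .FT[c("PLICATE", "INTERPLICATE", "COMBINED_PLICATE")]
  Gval <- c(NA, NA, mesh$table$G_p, mesh$table$G_i, mesh$table$G_c)

  res <- list()
  lim_e <- if (periodic) nx else nx - 1L
  fe <- mesh$face_e[seq_len(lim_e), , drop = FALSE]
  idx <- which(fe %in% gj)
  if (length(idx)) {
    ix <- (idx - 1L) %% lim_e + 1L
    iy <- (idx - 1L) %/% lim_e + 1L
    jx <- ifelse(ix == nx, 1L, ix + 1L)
    res$e <- data.frame(
      cell_i = mesh$cell_id[cbind(ix, iy)],
      cell_j = mesh$cell_id[cbind(jx, iy)],
      gi_x = ix, gi_y = iy, gj_x = jx, gj_y = iy,
      type = fe[idx], G = Gval[fe[idx] + 1L])
  }
  lim_n <- if (periodic) ny else ny - 1L
  fnm <- mesh$face_n[, seq_len(lim_n), drop = FALSE]
  idx <- which(fnm %in% gj)
  if (length(idx)) {
    ix <- (idx - 1L) %% nx + 1L
    iy <- (idx - 1L) %/% nx + 1L
    jy <- ifelse(iy == ny, 1L, iy + 1L)
    res$n <- data.frame(
      cell_i = mesh$cell_id[cbind(ix, iy)],
      cell_j = mesh$cell_id[cbind(ix, jy)],
      gi_x = ix, gi_y = iy, gj_x = ix, gj_y = jy,
      type = fnm[idx], G = Gval[fnm[idx] + 1L])
  }
  if (!length(res))
    return(data.frame(cell_i = integer(), cell_j = integer(),
                      gi_x = integer(), gi_y = integer(),
                      gj_x = integer(), gj_y = integer(),
                      type = integer(), G = numeric()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

## Methods ----------------------------------------------------------------------

#' @export
print.tissue_mesh <- function(x, ...) {
  cat("tissue_mesh: ", x$nx, " x ", x$ny, " volumes (",
      x$nx * x$h, " x ", x$ny * x$h, " um), h = ", x$h,
      " um, d = ", x$d, " um\n", sep = "")
  cat("  cells: ", x$n_cells,
      if (isTRUE(x$tileable)) "  (tileable unit grid)" else "", "\n", sep = "")
  ft <- table(factor(c(x$face_e[seq_len(x$nx - 1L), ],
                       x$face_n[, seq_len(x$ny - 1L)]),
                     levels = .FT, labels = names(.FT)))
  cat("  interior faces: ",
      paste(names(ft), as.integer(ft), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.cell_stats <- function(x, ...) {
  cat(sprintf("cell geometry over %d cells:\n", x$n_cells))
  cat(sprintf("  length %.1f +/- %.1f um, width %.1f +/- %.1f um\n",
              x$mean_length, x$sd_length, x$mean_width, x$sd_width))
  cat(sprintf("  mean gap-junction neighbors %.3f\n", x$mean_neighbors))
  invisible(x)
}

#' @export
summary.tissue_mesh <- function(object, ...) {
  print(object)
  print(cell_geometry_stats(object))
  invisible(object)
}

#' Plot a tissue mesh
#'
#' Displays the cell map (`what = "cells"`) or the face-type map
#' (`what = "faces"`) with base graphics.
#'
#' @param x A `tissue_mesh`.
#' @param what `"cells"` or `"faces"`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.tissue_mesh <- function(x, what = c("cells", "faces"), ...) {
  what <- match.arg(what)
  if (what == "cells") {
    cols <- grDevices::hcl.colors(x$n_cells, "Spectral")
    set.seed(7L); cols <- sample(cols)
    graphics::image(seq_len(x$nx) * x$h, seq_len(x$ny) * x$h, x$cell_id,
                    col = cols, useRaster = TRUE, asp = 1,
                    xlab = "x (um)", ylab = "y (um)", ...)
  } else {
    fe <- x$face_e; fe[is.na(fe)] <- 1L
    graphics::image(seq_len(x$nx) * x$h, seq_len(x$ny) * x$h, fe,
                    col = c("white", "grey85", "red", "orange", "blue"),
                    useRaster = TRUE, asp = 1,
                    xlab = "x (um)", ylab = "y (um)", ...)
  }
  invisible(x)
}
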