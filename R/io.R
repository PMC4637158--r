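# Plain-text serialization: meshes, networks, traces, VTK export, flat
# key=value run configs.

#' Write / read a tissue mesh as plain text
#'
#' Documented container: a header of `key value` lines (`nx`, `ny`, `h`,
#' `d`, `tileable`, `unit_nx`, `unit_ny`), then the `cell_id` matrix and
#' the east/north face-type matrices, each as `ny` whitespace-separated
#' rows (seam/boundary entries as `NA`).
#'
#' @param mesh A `tissue_mesh`.
#' @param path File path.
#' @return `write_mesh`: the path, invisibly. `read_mesh`: the mesh.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "tissue_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("cardiomaze-mesh 1",
               paste("nx", mesh$nx), paste("ny", mesh$ny),
               paste("h", mesh$h), paste("d", mesh$d),
               paste("tileable", as.integer(isTRUE(mesh$tileable))),
               paste("unit_nx", mesh$unit_dim[1]),
               paste("unit_ny", mesh$unit_dim[2])), con)
  dump_mat <- function(m, tag) {
    writeLines(paste("matrix", tag), con)
    write.table(t(m), con, row.names = FALSE, col.names = FALSE)
  }
  dump_mat(mesh$cell_id, "cell_id")
  dump_mat(mesh$face_e, "face_e")
  dump_mat(mesh$face_n, "face_n")
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "cardiomaze-mesh"))
    stop("not a cardiomaze mesh file", call. = FALSE)
  hdr <- strsplit(lines[2:8], " ")
  kv <- stats::setNames(vapply(hdr, `[`, "", 2), vapply(hdr, `[`, "", 1))
  nx <- as.integer(kv[["nx"]]); ny <- as.integer(kv[["ny"]])
  at <- 9L
  grab <- function() {
    stopifnot(startsWith(lines[at], "matrix"))
    rows <- lines[(at + 1L):(at + ny)]
    at <<- at + ny + 1L
    m <- t(vapply(strsplit(rows, " +"), function(r)
      suppressWarnings(as.integer(r)), integer(nx)))
    t(m) # stored row-per-iy; back to [ix, iy]
  }
  cid <- grab(); fe <- grab(); fn <- grab()
  .new_mesh(cid, fe, fn, as.numeric(kv[["h"]]), as.numeric(kv[["d"]]),
            tileable = kv[["tileable"]] == "1",
            unit_dim = c(as.integer(kv[["unit_nx"]]),
                         as.integer(kv[["unit_ny"]])))
}

#' Write / read a cell network as CSV files
#'
#' Writes `<prefix>_nodes.csv` (cell id, area, reference volume, centroid,
#' boundary-touch flags) and `<prefix>_edges.csv` (cell pair and equivalent
#' conductance `G_ij` in uS), loadable independently of the mesh.
#'
#' @param network A `cell_network`.
#' @param prefix Path prefix.
#' @return `write_network`: prefix, invisibly; `read_network`: the network.
#' @export
write_network <- function(network, prefix) {
  stopifnot(inherits(network, "cell_network"))
  write.csv(network$nodes, paste0(prefix, "_nodes.csv"), row.names = FALSE)
  write.csv(network$links, paste0(prefix, "_edges.csv"), row.names = FALSE)
  meta <- data.frame(key = c("n", "h", "d", "nx", "ny", "sigma_c",
                             "mesh_hash", "removed"),
                     value = c(network$n, network$h, network$d, network$nx,
                               network$ny, network$sigma_c,
                               network$mesh_hash,
                               paste(network$removed, collapse = ";")))
  write.csv(meta, paste0(prefix, "_meta.csv"), row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_network
#' @export
read_network <- function(prefix) {
  nodes <- read.csv(paste0(prefix, "_nodes.csv"))
  links <- read.csv(paste0(prefix, "_edges.csv"))
  meta <- read.csv(paste0(prefix, "_meta.csv"),
                   colClasses = c("character", "character"))
  kv <- stats::setNames(meta$value, meta$key)
  rmv <- kv[["removed"]]
  structure(list(nodes = nodes, links = links,
                 n = as.integer(kv[["n"]]), h = as.numeric(kv[["h"]]),
                 d = as.numeric(kv[["d"]]), nx = as.integer(kv[["nx"]]),
                 ny = as.integer(kv[["ny"]]),
                 sigma_c = as.numeric(kv[["sigma_c"]]),
                 removed = if (nzchar(rmv))
                   as.integer(strsplit(rmv, ";")[[1]]) else integer(0),
                 mesh_hash = kv[["mesh_hash"]]),
            class = "cell_network")
}

#' Export a mesh field as a legacy-VTK structured grid
#'
#' ASCII `STRUCTURED_POINTS` export of the cell map (or any per-volume
#' field) for visualization.
#'
#' @param mesh A `tissue_mesh`.
#' @param path Output file (`.vtk`).
#' @param field Per-volume values; default the cell ids.
#' @param name Field name in the VTK file.
#' @return The path, invisibly.
#' @export
write_vtk <- function(mesh, path, field = NULL, name = "cell_id") {
  stopifnot(inherits(mesh, "tissue_mesh"))
  field <- field %||% as.numeric(mesh$cell_id)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "cardiomaze structured grid", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", mesh$nx, mesh$ny),
               "ORIGIN 0 0 0",
               sprintf("SPACING %g %g 1", mesh$h, mesh$h),
               sprintf("POINT_DATA %d", mesh$nx * mesh$ny),
               sprintf("SCALARS %s float 1", name),
               "LOOKUP_TABLE default"), con)
  writeLines(format(field, trim = TRUE), con)
  invisible(path)
}

#' Write probe traces as CSV
#'
#' Columns `t_ms` and one `V_mV` column per probe.
#'
#' @param result A `sim_result` with recorded probes.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_traces <- function(result, path) {
  stopifnot(inherits(result, "sim_result"))
  if (is.null(result$probe_V)) stop("no probes recorded", call. = FALSE)
  d <- data.frame(t_ms = result$times, result$probe_V)
  names(d) <- c("t_ms", paste0("V_mV_p", result$probes))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Flat key=value run configuration files
#'
#' `read_config` parses `key = value` lines (numbers become numeric,
#' `#` comments and blank lines are skipped); `write_config` is the
#' inverse. All physical constants default to the study values and can be
#' overridden by a config.
#'
#' @param path File path.
#' @param config Named list.
#' @return `read_config`: named list; `write_config`: path, invisibly.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop("malformed config line: '", ln, "'", call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  writeLines(paste(names(config), unlist(config), sep = " = "), path)
  invisible(path)
}
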