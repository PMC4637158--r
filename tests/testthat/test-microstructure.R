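test_that("face coefficients map types to transmission coefficients", {
  tab <- conductance_table()
  expect_equal(face_coefficient("MEMBRANE", tab, 10), 0)
  expect_equal(face_coefficient("CYTOPLASM", tab, 10), 0.4)
  expect_equal(face_coefficient("PLICATE", tab, 10), 0.05)
  expect_equal(face_coefficient("INTERPLICATE", tab, 10), 0.033)
  expect_equal(face_coefficient("COMBINED_PLICATE", tab, 10), 0.0062)
  # symmetric: a face has one coefficient regardless of the side it is
  # approached from, and codes round-trip through the integer encoding
  expect_equal(face_coefficient(face_types(), tab, 10),
               face_coefficient(names(face_types()), tab, 10))
  expect_error(face_coefficient("PLICATE", tab, d = 0), "positive")
  expect_error(face_coefficient("NONSENSE", tab), "unknown")
})

test_that("conductance table enforces its invariants", {
  expect_error(conductance_table(sigma_m = 0.1), "sigma_m")
  expect_error(conductance_table(G_c = 0), "positive")
})

test_that("frozen template meets the target geometry statistics", {
  u <- fix_template()
  expect_s3_class(u, "tissue_mesh")
  expect_identical(u$n_cells, 32L)
  expect_identical(sort(unique(as.integer(u$cell_id))), 1:32)
  st <- cell_geometry_stats(u)
  expect_close(st$mean_length, 120.9, 0.05)
  expect_close(st$mean_width, 18.3, 0.05)
  expect_lt(abs(st$mean_neighbors - 6), 0.5)
  # SDs are on the scale of the targets too
  expect_close(st$sd_length, 27.8, 0.15)
  expect_close(st$sd_width, 3.5, 0.15)
})

test_that("template cells are 4-connected and faces are classified", {
  u <- fix_template()
  # every cell is one 4-connected component
  for (cc in seq_len(u$n_cells)) {
    mask <- u$cell_id == cc
    idx <- which(mask, arr.ind = TRUE)
    expect_lt(nrow(idx), u$nx * u$ny) # no cell spans the unit
    seen <- matrix(FALSE, u$nx, u$ny)
    queue <- idx[1, , drop = FALSE]
    seen[queue] <- TRUE
    while (nrow(queue)) {
      p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (dxy in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        q <- p + dxy
        if (q[1] >= 1 && q[1] <= u$nx && q[2] >= 1 && q[2] <= u$ny &&
            mask[q[1], q[2]] && !seen[q[1], q[2]]) {
          seen[q[1], q[2]] <- TRUE
          queue <- rbind(queue, q)
        }
      }
    }
    expect_true(all(seen[mask]))
  }
})

test_that("same-cell faces are cytoplasm, intercell faces never cytoplasm", {
  u <- fix_template()
  ft <- face_types()
  east_nb <- u$cell_id[c(2:u$nx, 1L), ]
  north_nb <- u$cell_id[, c(2:u$ny, 1L)]
  same_e <- u$cell_id == east_nb
  expect_true(all(u$face_e[same_e] == ft[["CYTOPLASM"]]))
  expect_true(all(u$face_e[!same_e] != ft[["CYTOPLASM"]]))
  same_n <- u$cell_id == north_nb
  expect_true(all(u$face_n[same_n] == ft[["CYTOPLASM"]]))
  expect_true(all(u$face_n[!same_n] != ft[["CYTOPLASM"]]))
})

test_that("infeasible template specs raise constructive errors", {
  expect_error(build_template(template_spec(n_cells = 16)), "n_cells")
  expect_error(build_template(template_spec(h = 10)), "8 um grid")
  expect_error(build_template(template_spec(target_mean_length = 300)),
               "mean_length")
})

test_that("tiling translates the unit and preserves statistics", {
  u <- fix_template()
  expect_identical(tile_template(u, 1, 1), u)
  t21 <- tile_template(u, 2, 1)
  expect_identical(t21$n_cells, 64L)
  expect_identical(t21$nx, 2L * u$nx)
  # every cell is a translate: bbox-derived stats identical to the unit
  su <- cell_geometry_stats(u)
  st <- cell_geometry_stats(t21)
  expect_equal(st$mean_length, su$mean_length)
  expect_equal(st$mean_width, su$mean_width)
  # population SDs identical (sample SDs differ only through n)
  pop_sd <- function(s, n) s * sqrt((n - 1) / n)
  expect_equal(pop_sd(st$sd_length, 64), pop_sd(su$sd_length, 32),
               tolerance = 1e-12)
  # seam faces of the left copy equal the unit wrap-around faces
  expect_identical(t21$face_e[u$nx, ], u$face_e[u$nx, ])
  # tiling to >= 1 cm x 1 cm
  t1 <- tile_to_size(u, 1, 1)
  expect_gte(t1$nx * t1$h, 1e4)
  expect_gte(t1$ny * t1$h, 1e4)
  expect_lt((t1$nx - u$nx) * t1$h, 1e4) # smallest such tiling
  expect_error(tile_template(fixture_two_cell_mesh(), 2, 1), "tileable")
})

test_that("geometry stats on hand-built meshes match arithmetic", {
  # single rectangular 15 x 2 cell: length 120 um, width 16 um
  cid <- matrix(1L, 15, 2)
  fe <- matrix(c(rep(1L, 14), NA), 15, 2)
  fn <- matrix(c(rep(1L, 15), rep(NA, 15)), 15, 2)
  mesh <- cardiomaze:::.new_mesh(cid, fe, fn, h = 8, d = 10)
  st <- cell_geometry_stats(mesh)
  expect_equal(st$mean_length, 120)
  expect_equal(st$mean_width, 16)
  expect_equal(st$mean_neighbors, 0) # lone cell
  # two cells separated by membrane only: zero neighbors
  mm <- fixture_two_cell_mesh("MEMBRANE")
  expect_equal(cell_geometry_stats(mm)$mean_neighbors, 0)
  # plicate abutment: one neighbor each
  mp <- fixture_two_cell_mesh("PLICATE")
  expect_equal(cell_geometry_stats(mp)$mean_neighbors, 1)
})

test_that("mesh round-trips through the text container", {
  u <- fix_template()
  path <- withr::local_tempfile(fileext = ".txt")
  write_mesh(u, path)
  v <- read_mesh(path)
  expect_identical(v$cell_id, u$cell_id)
  expect_identical(v$face_e, u$face_e)
  expect_identical(v$face_n, u$face_n)
  expect_equal(v$h, u$h)
  expect_identical(mesh_hash(v), mesh_hash(u))
})

test_that("VTK export writes a well-formed structured grid", {
  path <- withr::local_tempfile(fileext = ".vtk")
  write_vtk(fixture_two_cell_mesh(), path)
  lines <- readLines(path)
  expect_match(lines[4], "STRUCTURED_POINTS")
  expect_match(lines[5], "DIMENSIONS 8 2 1")
  expect_length(lines, 10 + 16)
})
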