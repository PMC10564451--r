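test_that("binary STL round-trips a single triangle with fixed byte layout", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  mesh <- surface_mesh(v, rbind(c(1L, 2L, 3L)), source_label = "tri")
  path <- withr::local_tempfile(fileext = ".stl")
  write_stl(mesh, path, dialect = "binary")
  expect_identical(file.info(path)$size, 84 + 50 * 1)
  back <- read_stl(path)
  expect_identical(nrow(back$faces), 1L)
  expect_identical(nrow(back$vertices), 3L)
  expect_equal(back$vertices, mesh$vertices, ignore_attr = TRUE,
               tolerance = 1e-7)
})

test_that("binary writer length is 84 + 50 * n_faces and round trip preserves
           faces exactly, coordinates to float32", {
  for (mesh in list(tetrahedron_mesh(2), generate_arch(arch_spec())$mesh)) {
    path <- withr::local_tempfile(fileext = ".stl")
    write_stl(mesh, path, dialect = "binary")
    expect_identical(file.info(path)$size, 84 + 50 * nrow(mesh$faces))
    back <- read_stl(path)
    expect_identical(nrow(back$faces), nrow(mesh$faces))
    # float32 has ~7 decimal digits; coordinates here are O(10) mm
    expect_equal(max(abs(sort(back$vertices[, 1]) - sort(mesh$vertices[, 1]))),
                 0, tolerance = 1e-5)
  }
})

test_that("ASCII and binary dialects of the same mesh read back equal", {
  mesh <- tetrahedron_mesh(3.7)
  pa <- withr::local_tempfile(fileext = ".stl")
  pb <- withr::local_tempfile(fileext = ".stl")
  write_stl(mesh, pa, dialect = "ascii")
  write_stl(mesh, pb, dialect = "binary")
  ma <- read_stl(pa); mb <- read_stl(pb)
  expect_identical(ma$faces, mb$faces)
  expect_equal(ma$vertices, mb$vertices, tolerance = 1e-12)
})

test_that("ASCII tetrahedron has 4 faces, closed surface, analytic area", {
  a <- 2.5
  mesh <- tetrahedron_mesh(a)
  path <- withr::local_tempfile(fileext = ".stl")
  write_stl(mesh, path, dialect = "ascii")
  back <- read_stl(path)
  expect_identical(nrow(back$faces), 4L)
  expect_identical(nrow(back$vertices), 4L)  # soup merged to shared vertices
  # closed surface: every edge appears exactly twice
  edges <- rbind(back$faces[, c(1, 2)], back$faces[, c(2, 3)],
                 back$faces[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  expect_true(all(table(key) == 2))
  expect_equal(mesh_area(back), 4 * (sqrt(3) / 4) * a^2, tolerance = 1e-5)
})

test_that("malformed binary STL bodies raise format errors naming the offset", {
  mesh <- tetrahedron_mesh()
  path <- withr::local_tempfile(fileext = ".stl")
  write_stl(mesh, path, dialect = "binary")
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  trunc_path <- withr::local_tempfile(fileext = ".stl")
  writeBin(bytes[1:(length(bytes) - 30)], trunc_path)
  expect_error(read_stl(trunc_path), "truncated.*byte offset")
  extra_path <- withr::local_tempfile(fileext = ".stl")
  writeBin(c(bytes, as.raw(0:9)), extra_path)
  expect_error(read_stl(extra_path), "face-count mismatch.*byte offset")
  expect_error(read_stl(file.path(tempdir(), "no_such_file.stl")),
               "does not exist")
})

test_that("a binary file starting with 'solid' is still read as binary", {
  mesh <- tetrahedron_mesh()
  path <- withr::local_tempfile(fileext = ".stl")
  write_stl(mesh, path, dialect = "binary")
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  bytes[1:5] <- charToRaw("solid")
  writeBin(bytes, path)
  back <- read_stl(path)
  expect_identical(nrow(back$faces), 4L)
})

test_that("writer refuses empty meshes; validator reports issues without
           mutating", {
  empty <- structure(list(vertices = matrix(0, 1, 3),
                          faces = matrix(integer(), 0, 3),
                          source_label = ""), class = "surface_mesh")
  expect_error(write_stl(empty, tempfile()), "empty")
  expect_identical(validate_mesh(empty)$issue, "empty_mesh")

  clean <- tetrahedron_mesh()
  expect_identical(nrow(validate_mesh(clean)), 0L)

  bad_idx <- structure(list(vertices = clean$vertices,
                            faces = rbind(clean$faces, c(1L, 2L, 99L)),
                            source_label = ""), class = "surface_mesh")
  expect_true("face_index_out_of_range" %in% validate_mesh(bad_idx)$issue)

  degen <- structure(list(vertices = clean$vertices,
                          faces = rbind(clean$faces, c(1L, 1L, 2L)),
                          source_label = ""), class = "surface_mesh")
  expect_true("zero_area_face" %in% validate_mesh(degen)$issue)

  nonfin <- structure(list(vertices = rbind(clean$vertices, c(NaN, 0, 0)),
                           faces = clean$faces,
                           source_label = ""), class = "surface_mesh")
  expect_true("non_finite_coordinate" %in% validate_mesh(nonfin)$issue)
})

test_that("tooth points round-trip through JSON and CSV losslessly", {
  pts <- as_tooth_points(tibble::tibble(
    tooth_id = c("UR3", "UR4", "LL1", "LL1", "LR6"),
    role = c("buccal_cusp", "mesiobuccal_cusp", "incisal_edge_mesial",
             "incisal_edge_distal", "mesiobuccal_cusp"),
    timepoint = c("T0", "T0", "T1", "T1", "T0"),
    x = c(-12.345678901234, 0.1, 3, 4, 5),
    y = c(1, 2, 3, 4, 5) + 1 / 3,
    z = c(0, 0, 8, 8, 8)))
  for (ext in c(".json", ".csv")) {
    path <- withr::local_tempfile(fileext = ext)
    write_tooth_points(pts, path)
    back <- read_tooth_points(path)
    expect_equal(back, pts, tolerance = 1e-12)
  }
})

test_that("point sidecar validation rejects bad roles, duplicates, and comma
           decimals", {
  base <- tibble::tibble(tooth_id = "UR3", role = "buccal_cusp",
                         timepoint = "T0", x = 1, y = 2, z = 3)
  expect_error(as_tooth_points(dplyr::mutate(base, role = "lingual_groove")),
               "unknown tooth-point role")
  expect_error(as_tooth_points(dplyr::bind_rows(base, base)),
               "duplicate")
  expect_error(as_tooth_points(dplyr::mutate(base, timepoint = "T2")),
               "timepoint")
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("tooth_id,role,timepoint,x,y,z",
               "UR3,buccal_cusp,T0,\"1,5\",2,3"), csv)
  expect_error(read_tooth_points(csv), "row 1")
})
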