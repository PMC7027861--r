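# Importers: generic column-mapped tables, Oufti-style MAT cell lists,
# iSBatch-style spot tables, and the writer/importer round-trip property
# for every dialect with a fixture writer.

test_that("generic mesh CSV round-trips the fixture writer's polygons", {
  meshes <- random_cell_field(10, seed = 201)
  dir <- withr::local_tempdir()
  paths <- write_fixture(meshes, dialect = "generic-csv", dir = dir)
  got <- import_generic(paths["meshes"], column_mapping("generic"), kind = "mesh")
  expect_equal(nrow(got), 10)
  ord <- match(meshes$cell_id, got$cell_id)
  for (i in seq_len(10)) {
    expect_equal(got$mesh[[ord[i]]], meshes$mesh[[i]], tolerance = 1e-12)
  }
})

test_that("missing mapped columns raise SchemaError naming the column", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "spots.csv")
  readr::write_csv(tibble::tibble(spot_id = "a", frame_id = 0, x = 1), p)
  err <- expect_error(import_generic(p, column_mapping("generic"), kind = "spot"),
                      class = "cellmapr_schema_error")
  expect_match(conditionMessage(err), "\"y\"")
})

test_that("non-numeric coordinates raise ParseError with the row number", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "spots.csv")
  writeLines(c("spot_id,frame_id,x,y", "a,0,1.5,2.5", "b,0,oops,3"), p)
  err <- expect_error(import_generic(p, column_mapping("generic"), kind = "spot"),
                      class = "cellmapr_parse_error")
  expect_match(conditionMessage(err), "row 2")
})

test_that("1-based sources are shifted to the 0-based convention", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "spots.csv")
  readr::write_csv(tibble::tibble(spot_id = "a", frame_id = 0, x = 10, y = 20), p)
  m1 <- column_mapping("generic", base = 1)
  got <- import_generic(p, m1, kind = "spot")
  expect_equal(got$x, 9)
  expect_equal(got$y, 19)
  got0 <- import_generic(p, column_mapping("generic"), kind = "spot")
  expect_equal(got0$x, 10)
})

test_that("unmapped source columns are preserved", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "spots.csv")
  readr::write_csv(tibble::tibble(spot_id = "a", frame_id = 0, x = 1, y = 2,
                                  extra_score = 0.7), p)
  got <- import_generic(p, column_mapping("generic"), kind = "spot")
  expect_equal(got$extra_score, 0.7)
  expect_s3_class(attr(got, "raw"), "tbl_df")
})

test_that("unknown presets are rejected", {
  expect_error(column_mapping("no-such-program"), class = "cellmapr_schema_error")
})

test_that("oufti meshes reconstruct 2N-2 vertex polygons", {
  # one rod cell written with N = 10 mesh rows
  v <- make_mesh("rod", 20, 8, center = c(30, 30), angle = 15, n_vertices = 18)
  expect_equal(nrow(v), 18)  # N = 10 rows -> 2N - 2 = 18 vertices
  dir <- withr::local_tempdir()
  meshes <- tibble::tibble(cell_id = "7", frame_id = 2L, mesh = list(v))
  paths <- write_fixture(meshes, dialect = "oufti-mat", dir = dir)
  got <- import_oufti_mat(paths["mat"])
  expect_equal(nrow(got), 1)
  expect_equal(nrow(got$mesh[[1]]), 18)
  expect_gt(polygon_area(got$mesh[[1]]), 0)
  expect_equal(got$mesh[[1]], v, tolerance = 1e-6)
  expect_equal(got$frame_id, 2L)
})

test_that("empty oufti cell lists import as empty meshframes", {
  tf <- withr::local_tempfile(fileext = ".mat")
  write_mat(list(cellList = structure(list(), class = "mat_struct")), tf)
  got <- import_oufti_mat(tf)
  expect_equal(nrow(got), 0)
  expect_equal(attr(got, "n_skipped"), 0)
})

test_that("absent cell-list variables and degenerate meshes are handled", {
  tf <- withr::local_tempfile(fileext = ".mat")
  write_mat(list(other = 1), tf)
  expect_error(import_oufti_mat(tf), class = "cellmapr_schema_error")

  tf2 <- withr::local_tempfile(fileext = ".mat")
  cl <- structure(list(list(cellId = 1, frame = 0, mesh = matrix(1, 1, 4))),
                  class = "mat_struct")
  write_mat(list(cellList = cl), tf2)
  got <- import_oufti_mat(tf2)
  expect_equal(nrow(got), 0)
  expect_equal(attr(got, "n_skipped"), 1)
})

test_that("oufti round-trip recovers simulated cell lengths within 2%", {
  meshes <- random_cell_field(20, seed = 211)
  truth_len <- vapply(meshes$mesh, function(v) min_bounding_box(v)$length, numeric(1))
  dir <- withr::local_tempdir()
  paths <- write_fixture(meshes, dialect = "oufti-mat", dir = dir)
  got <- import_oufti_mat(paths["mat"])
  expect_equal(nrow(got), 20)
  got_len <- vapply(got$mesh, function(v) min_bounding_box(v)$length, numeric(1))
  ord <- match(as.character(readr::parse_number(meshes$cell_id)), got$cell_id)
  expect_true(all(abs(got_len[ord] - truth_len) / truth_len < 0.02))
})

test_that("isbatch spot tables round-trip with trajectory ids preserved", {
  set.seed(221)
  spots <- tibble::tibble(spot_id = sprintf("s%03d", 1:100),
                          frame_id = rep(0:4, each = 20),
                          x = stats::runif(100, 0, 100),
                          y = stats::runif(100, 0, 100),
                          intensity = stats::rpois(100, 50),
                          track_id = sprintf("t%02d", rep(1:20, 5)))
  dir <- withr::local_tempdir()
  paths <- write_fixture(spots = spots, dialect = "isbatch-csv", dir = dir)
  got <- import_isbatch_spots(paths["spots"])
  expect_equal(nrow(got), 100)
  expect_equal(got$spot_id, spots$spot_id)
  expect_equal(got$x, spots$x, tolerance = 1e-12)
  expect_equal(got$y, spots$y, tolerance = 1e-12)
  expect_equal(got$track_id, spots$track_id)
  expect_equal(attr(got, "n_duplicated"), 0)
})

test_that("header-only and duplicated-id spot tables are tolerated", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "empty.csv")
  writeLines("id,frame,x,y", p)
  got <- import_isbatch_spots(p)
  expect_equal(nrow(got), 0)

  p2 <- file.path(dir, "dup.csv")
  readr::write_csv(tibble::tibble(id = c("a", "a"), frame = c(0, 0),
                                  x = c(1, 2), y = c(3, 4)), p2)
  got2 <- import_isbatch_spots(p2)
  expect_equal(nrow(got2), 2)
  expect_equal(attr(got2, "n_duplicated"), 1)
})

test_that("microbej mesh export round-trips through its preset", {
  meshes <- random_cell_field(8, seed = 231)
  dir <- withr::local_tempdir()
  paths <- write_fixture(meshes, dialect = "microbej-csv", dir = dir)
  got <- import_generic(paths["meshes"], column_mapping("microbej"), kind = "mesh")
  expect_equal(nrow(got), 8)
  ord <- match(meshes$cell_id, got$cell_id)
  for (i in seq_len(8)) {
    expect_equal(got$mesh[[ord[i]]], meshes$mesh[[i]], tolerance = 1e-9)
  }
})

test_that("importing never changes coordinates beyond the base shift", {
  set.seed(241)
  spots <- tibble::tibble(spot_id = sprintf("s%d", 1:50), frame_id = 0L,
                          x = stats::runif(50, 0, 512), y = stats::runif(50, 0, 512))
  dir <- withr::local_tempdir()
  paths <- write_fixture(spots = spots, dialect = "generic-csv", dir = dir)
  got <- import_generic(paths["spots"], column_mapping("generic"), kind = "spot")
  expect_equal(got$x, spots$x, tolerance = 1e-15)
  expect_equal(got$y, spots$y, tolerance = 1e-15)
})
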