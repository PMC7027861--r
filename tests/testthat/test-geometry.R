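# Geometry module: bounding boxes, orientation, point-in-polygon,
# relativization, pixel extraction.

test_that("min_bounding_box recovers axis-aligned and rotated rectangles", {
  f <- min_bounding_box(cbind(c(0, 4, 4, 0), c(0, 0, 2, 2)))
  expect_equal(f$length, 4)
  expect_equal(f$width, 2)
  expect_equal(f$angle, 0)
  expect_equal(f$center, c(2, 1))

  v <- rotate_points(cbind(c(0, 4, 4, 0), c(0, 0, 2, 2)), 30, center = c(2, 1))
  f2 <- min_bounding_box(v)
  expect_equal(f2$length, 4, tolerance = 1e-9)
  expect_equal(f2$width, 2, tolerance = 1e-9)
  expect_equal(f2$angle, 30, tolerance = 1e-6)
  # independent angle-scan oracle agrees on the area
  ora <- oracle_min_box_area(v)
  expect_equal(f2$length * f2$width, ora$area, tolerance = 1e-9)
})

test_that("square boxes break angle ties toward zero", {
  f <- min_bounding_box(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  expect_equal(f$length, f$width)
  expect_equal(f$angle, 0)
})

test_that("collinear vertices raise DegenerateGeometry", {
  expect_error(min_bounding_box(cbind(c(0, 1, 2), c(0, 1, 2))),
               class = "cellmapr_degenerate_geometry")
})

test_that("box length and width are invariant under rotation of the polygon", {
  set.seed(11)
  for (rep in 1:25) {
    v <- random_convex_polygon()
    f0 <- min_bounding_box(v)
    th <- stats::runif(1, 0, 360)
    f1 <- min_bounding_box(rotate_points(v, th))
    expect_equal(f1$length, f0$length, tolerance = 1e-6)
    expect_equal(f1$width, f0$width, tolerance = 1e-6)
  }
})

test_that("orient_mesh places the box at the origin and preserves area", {
  v <- cbind(c(0, 4, 4, 0), c(0, 0, 2, 2))
  f <- min_bounding_box(v)
  o <- orient_mesh(v, f)
  expect_equal(o[order(o[, 1], o[, 2]), ],
               cbind(c(-2, -2, 2, 2), c(-1, 1, -1, 1)), tolerance = 1e-12)

  vr <- rotate_points(v, 30, center = c(2, 1))
  fr <- min_bounding_box(vr)
  or <- orient_mesh(vr, fr)
  expect_equal(sort(or[, 1]), sort(o[, 1]), tolerance = 1e-6)

  set.seed(7)
  for (rep in 1:20) {
    p <- random_convex_polygon()
    fp <- min_bounding_box(p)
    op <- orient_mesh(p, fp)
    expect_equal(polygon_area(op), polygon_area(p),
                 tolerance = 1e-9 * polygon_area(p))
    # extents match the fit, center at origin
    expect_equal(diff(range(op[, 1])), fp$length, tolerance = 1e-6)
    expect_equal(diff(range(op[, 2])), fp$width, tolerance = 1e-6)
    expect_equal(mean(range(op[, 1])), 0, tolerance = 1e-9)
    expect_equal(mean(range(op[, 2])), 0, tolerance = 1e-9)
  }
})

test_that("already-oriented meshes are unchanged by orient_mesh", {
  v <- cbind(c(-2, 2, 2, -2), c(-1, -1, 1, 1))
  f <- min_bounding_box(v)
  expect_equal(orient_mesh(v, f), unname(v), tolerance = 1e-12)
})

test_that("point_in_polygon matches the crossing-number oracle", {
  set.seed(23)
  for (rep in 1:20) {
    v <- random_convex_polygon()
    px <- stats::runif(200, -2, 12)
    py <- stats::runif(200, -2, 12)
    expect_identical(point_in_polygon(px, py, v),
                     oracle_point_in_polygon(px, py, v))
  }
})

test_that("boundary points count as inside", {
  v <- cbind(c(0, 4, 4, 0), c(0, 0, 2, 2))
  expect_true(all(point_in_polygon(c(0, 2, 4), c(0, 0, 2), v)))
})

test_that("spot_relative computes length-axis coordinates and inverts exactly", {
  fit <- min_bounding_box(cbind(c(0, 4, 4, 0), c(0, 0, 2, 2)))
  r <- spot_relative(3, 1.5, fit)
  expect_equal(unlist(r), c(l = 1, d = 0.5, l_rel = 0.25, d_rel = 0.25))
  expect_equal(unlist(spot_relative(2, 1, fit)),
               c(l = 0, d = 0, l_rel = 0, d_rel = 0))

  set.seed(5)
  for (rep in 1:10) {
    v <- random_convex_polygon()
    fit <- min_bounding_box(v)
    x <- stats::runif(100, 0, 10); y <- stats::runif(100, 0, 10)
    rel <- spot_relative(x, y, fit)
    inv <- spot_absolute(rel$l, rel$d, fit)
    expect_lt(max(abs(inv$x - x), abs(inv$y - y)), 1e-9)
  }
})

test_that("spot_relative rejects degenerate fits", {
  bad <- structure(list(length = 0, width = 0, angle = 0, center = c(0, 0)),
                   class = "box_fit")
  expect_error(spot_relative(1, 1, bad), class = "cellmapr_degenerate_geometry")
})

test_that("assign_spots handles contained, far and ambiguous spots", {
  mf <- mesh_frame(random_cell_field(4, seed = 31))
  ctr <- mf$fit[[2]]$center
  spots <- tibble::tibble(spot_id = c("a", "b"), frame_id = 0L,
                          x = c(ctr[1], 1e3), y = c(ctr[2], 1e3))
  asg <- assign_spots(spots, mf)
  expect_equal(asg$cell_id, c(mf$cell_id[2], NA))
  expect_false(any(asg$ambiguous))

  # two overlapping squares: the midpoint belongs to both, tie goes to
  # the nearer center and is flagged
  sq <- function(x0) cbind(c(x0, x0 + 4, x0 + 4, x0), c(0, 0, 4, 4))
  mf2 <- mesh_frame(tibble::tibble(cell_id = c("L", "R"), frame_id = 0L,
                                   source = "t", mesh = list(sq(0), sq(3))))
  asg2 <- assign_spots(tibble::tibble(spot_id = "m", frame_id = 0L,
                                      x = 3.4, y = 2), mf2)
  expect_equal(asg2$cell_id, "L")
  expect_true(asg2$ambiguous)
})

test_that("assign_spots agrees with the oracle on random fields", {
  mf <- mesh_frame(random_cell_field(20, seed = 47))
  set.seed(48)
  spots <- tibble::tibble(spot_id = sprintf("s%03d", 1:200), frame_id = 0L,
                          x = stats::runif(200, 0, 200),
                          y = stats::runif(200, 0, 200))
  asg <- assign_spots(spots, mf)
  for (s in seq_len(nrow(spots))) {
    inside <- vapply(seq_len(nrow(mf)), function(j)
      oracle_point_in_polygon(spots$x[s], spots$y[s], mf$mesh[[j]]), logical(1))
    if (!any(inside)) {
      expect_true(is.na(asg$cell_id[s]))
    } else {
      expect_true(asg$cell_id[s] %in% mf$cell_id[inside])
    }
  }
})

test_that("pixels_in_mesh extracts exactly the covered pixel centers", {
  img <- matrix(7, 10, 10)
  px <- pixels_in_mesh(cbind(c(1.5, 4.5, 4.5, 1.5), c(1.5, 1.5, 4.5, 4.5)), img)
  expect_equal(nrow(px), 9)            # centers 2,3,4 in both axes
  expect_true(all(px$intensity == 7))

  expect_error(pixels_in_mesh(cbind(c(100, 104, 104, 100), c(100, 100, 102, 102)),
                              img),
               class = "cellmapr_empty_cell")
})

test_that("pixels_in_mesh agrees with a full-image oracle scan", {
  set.seed(91)
  for (rep in 1:5) {
    v <- random_convex_polygon(scale = 20)
    img <- matrix(stats::runif(900), 30, 30)
    got <- pixels_in_mesh(v, img)
    grid <- expand.grid(col = 0:29, row = 0:29)
    keep <- oracle_point_in_polygon(grid$col, grid$row, v)
    expect_setequal(paste(got$row, got$col), paste(grid$row[keep], grid$col[keep]))
    expect_equal(got$intensity, img[cbind(got$row + 1, got$col + 1)])
  }
})

test_that("relativize_objects matches vertex-wise spot_relative", {
  mf <- mesh_frame(random_cell_field(5, seed = 13))
  # small triangles around each cell center
  objs <- dplyr::bind_rows(lapply(1:5, function(i) {
    ctr <- mf$fit[[i]]$center
    tibble::tibble(object_id = sprintf("o%d", i), frame_id = 0L,
                   vertices = list(cbind(ctr[1] + c(-1, 1, 0),
                                         ctr[2] + c(-1, -1, 1))))
  }))
  rel <- relativize_objects(objs, mf)
  expect_equal(rel$cell_id, mf$cell_id)
  for (i in 1:5) {
    v <- objs$vertices[[i]]
    expected <- spot_relative(v[, 1], v[, 2], mf$fit[[i]])
    expect_equal(rel$vertices_rel[[i]], cbind(expected$l, expected$d),
                 tolerance = 1e-12)
  }
  # concentric object: relative centroid at the origin
  ctr <- mf$fit[[1]]$center
  sq <- cbind(ctr[1] + c(-1, 1, 1, -1), ctr[2] + c(-1, -1, 1, 1))
  rel2 <- relativize_objects(tibble::tibble(object_id = "c", frame_id = 0L,
                                            vertices = list(sq)), mf)
  expect_equal(polygon_centroid(rel2$vertices_rel[[1]]), c(0, 0), tolerance = 1e-9)

  # centroid outside all cells: unassigned, outline untouched
  far <- tibble::tibble(object_id = "far", frame_id = 0L,
                        vertices = list(cbind(c(900, 902, 901), c(900, 900, 902))))
  rel3 <- relativize_objects(far, mf)
  expect_true(is.na(rel3$cell_id))
  expect_null(rel3$vertices_rel[[1]])
})
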