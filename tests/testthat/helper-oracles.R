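# Independent oracles used to verify the geometry and aggregation code.
# These are deliberately written with different algorithms from the
# implementation (scalar crossing-number loops, angle-scan minimization,
# brute-force group-bys) and stay independent of the paths they check.

# Crossing-number point-in-polygon (scalar, half-open edges + explicit
# boundary pass). Boundary counts as inside, matching the package's
# closed-polygon convention.
oracle_point_in_polygon <- function(px, py, v, eps = 1e-9) {
  n <- nrow(v)
  out <- logical(length(px))
  for (q in seq_along(px)) {
    x <- px[q]; y <- py[q]
    cn <- 0L
    on_edge <- FALSE
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      x1 <- v[i, 1]; y1 <- v[i, 2]; x2 <- v[j, 1]; y2 <- v[j, 2]
      # boundary
      dx <- x2 - x1; dy <- y2 - y1
      L2 <- dx * dx + dy * dy
      t <- if (L2 > 0) max(0, min(1, ((x - x1) * dx + (y - y1) * dy) / L2)) else 0
      if ((x - (x1 + t * dx))^2 + (y - (y1 + t * dy))^2 <= eps^2) {
        on_edge <- TRUE
        break
      }
      # upward/downward crossing of the horizontal ray
      if ((y1 <= y && y2 > y) || (y2 <= y && y1 > y)) {
        vt <- (y - y1) / (y2 - y1)
        if (x < x1 + vt * (x2 - x1)) cn <- cn + 1L
      }
    }
    out[q] <- on_edge || (cn %% 2L == 1L)
  }
  out
}

# Enclosing-box area at a fixed axis angle (degrees).
box_area_at_angle <- function(v, ang_deg) {
  th <- ang_deg * pi / 180
  xr <- cos(th) * v[, 1] + sin(th) * v[, 2]
  yr <- -sin(th) * v[, 1] + cos(th) * v[, 2]
  (max(xr) - min(xr)) * (max(yr) - min(yr))
}

# Angle-scan minimum enclosing-box oracle: exhaustive 0.01-degree grid
# over [0, 180), then two local grid refinements (1e-5 and 1e-8 degrees)
# around the running best. Returns the minimum area found.
oracle_min_box_area <- function(v, coarse_step = 0.01) {
  h <- grDevices::chull(v[, 1], v[, 2])
  v <- v[h, , drop = FALSE]
  scan <- function(angles) {
    best_a <- Inf; best_t <- angles[1]
    co <- cos(angles * pi / 180); si <- sin(angles * pi / 180)
    xmin <- rep(Inf, length(angles)); xmax <- rep(-Inf, length(angles))
    ymin <- xmin; ymax <- xmax
    for (i in seq_len(nrow(v))) {
      xr <- co * v[i, 1] + si * v[i, 2]
      yr <- -si * v[i, 1] + co * v[i, 2]
      xmin <- pmin(xmin, xr); xmax <- pmax(xmax, xr)
      ymin <- pmin(ymin, yr); ymax <- pmax(ymax, yr)
    }
    a <- (xmax - xmin) * (ymax - ymin)
    k <- which.min(a)
    list(area = a[k], angle = angles[k])
  }
  s1 <- scan(seq(0, 180 - coarse_step, by = coarse_step))
  s2 <- scan(seq(s1$angle - coarse_step, s1$angle + coarse_step, by = 1e-5))
  s3 <- scan(seq(s2$angle - 1e-5, s2$angle + 1e-5, by = 1e-8))
  list(area = min(s1$area, s2$area, s3$area), coarse_area = s1$area)
}

# Random simple polygons: convex hulls of random point clouds (always
# simple), at random scale/offset.
random_convex_polygon <- function(n_pts = 12L, scale = 10) {
  repeat {
    p <- cbind(stats::runif(n_pts, 0, scale), stats::runif(n_pts, 0, scale))
    h <- grDevices::chull(p[, 1], p[, 2])
    if (length(h) >= 3L) return(p[h, , drop = FALSE])
  }
}

# Shoelace area by the trapezoid formula (different arithmetic from the
# implementation's cross-product form).
oracle_polygon_area <- function(v) {
  n <- nrow(v)
  j <- c(n, seq_len(n - 1L))
  abs(sum((v[j, 1] + v[, 1]) * (v[j, 2] - v[, 2]))) / 2
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# Non-overlapping random rod cells on a grid, for assignment tests.
random_cell_field <- function(n_cells, seed, frame_id = 0L) {
  set.seed(seed)
  per_row <- ceiling(sqrt(n_cells))
  rows <- lapply(seq_len(n_cells), function(i) {
    len <- stats::runif(1, 12, 28)
    wid <- stats::runif(1, 5, 9)
    ang <- stats::runif(1, -90, 90)
    cx <- 20 + 40 * ((i - 1L) %% per_row)
    cy <- 20 + 40 * ((i - 1L) %/% per_row)
    tibble::tibble(cell_id = sprintf("cell_%03d", i), frame_id = frame_id,
                   source = "synthetic",
                   mesh = list(make_mesh("rod", len, wid, center = c(cx, cy),
                                         angle = ang)))
  })
  dplyr::bind_rows(rows)
}
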