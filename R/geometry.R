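# Coordinate mathematics: minimum-area bounding boxes, orientation of cells
# onto their length axis, spot/object relativization and pixel extraction.
#
# Conventions (also stated in dataset manifests): pixel coordinates are
# 0-based with pixel centers at integer coordinates; y increases downward;
# all angles are reported in degrees, with the length-axis angle in
# [-90, 90) relative to the image x-axis.

## ---- polygon primitives -----------------------------------------------

as_vertex_matrix <- function(vertices) {
  if (is.data.frame(vertices)) vertices <- cbind(vertices$x, vertices$y)
  v <- unname(as.matrix(vertices))
  if (ncol(v) != 2L) cm_stop("degenerate_geometry", "vertices must be two-column (x, y)")
  storage.mode(v) <- "double"
  v
}

#' Signed polygon area (shoelace)
#'
#' Positive for counterclockwise vertex order in a y-down image coordinate
#' system is *negative*; this function reports the conventional shoelace
#' sign (positive = counterclockwise in mathematical axes). Use
#' [polygon_area()] for the absolute area.
#'
#' @param vertices two-column matrix or data frame with `x`, `y`.
#' @return signed area in square pixels.
#' @export
polygon_signed_area <- function(vertices) {
  v <- as_vertex_matrix(vertices)
  n <- nrow(v)
  x <- v[, 1L]; y <- v[, 2L]
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Absolute polygon area
#' @inheritParams polygon_signed_area
#' @return area in square pixels (>= 0).
#' @export
polygon_area <- function(vertices) abs(polygon_signed_area(vertices))

#' Polygon centroid
#' @inheritParams polygon_signed_area
#' @return numeric length-2 vector (x, y).
#' @export
polygon_centroid <- function(vertices) {
  v <- as_vertex_matrix(vertices)
  n <- nrow(v)
  x <- v[, 1L]; y <- v[, 2L]
  j <- c(2:n, 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-300) return(c(mean(x), mean(y)))
  c(sum((x + x[j]) * cr) / (6 * a), sum((y + y[j]) * cr) / (6 * a))
}

# counterclockwise normalization (shoelace sign > 0)
ensure_ccw <- function(vertices) {
  v <- as_vertex_matrix(vertices)
  if (polygon_signed_area(v) < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  v
}

# Simple-polygon check: no two non-adjacent edges intersect. O(n^2); cell
# outlines have tens of vertices so this is never the bottleneck.
is_simple_polygon <- function(vertices, eps = 1e-12) {
  v <- as_vertex_matrix(vertices)
  n <- nrow(v)
  if (n < 3L) return(FALSE)
  if (anyDuplicated(v) > 0L) return(FALSE)
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- cross2(p3, p4, p1); d2 <- cross2(p3, p4, p2)
    d3 <- cross2(p1, p2, p3); d4 <- cross2(p1, p2, p4)
    if (((d1 > eps && d2 < -eps) || (d1 < -eps && d2 > eps)) &&
        ((d3 > eps && d4 < -eps) || (d3 < -eps && d4 > eps))) return(TRUE)
    on_seg <- function(p, q, r) {
      abs(cross2(p, q, r)) <= eps &&
        min(p[1], q[1]) - eps <= r[1] && r[1] <= max(p[1], q[1]) + eps &&
        min(p[2], q[2]) - eps <= r[2] && r[2] <= max(p[2], q[2]) + eps
    }
    on_seg(p3, p4, p1) || on_seg(p3, p4, p2) || on_seg(p1, p2, p3) || on_seg(p1, p2, p4)
  }
  idx <- seq_len(n)
  nxt <- c(2:n, 1L)
  for (i in idx) {
    for (j in idx[idx > i]) {
      # skip adjacent edges (sharing a vertex), including the wrap pair
      if (j == i || j == (i %% n) + 1L || i == (j %% n) + 1L) next
      if (seg_int(v[i, ], v[nxt[i], ], v[j, ], v[nxt[j], ])) return(FALSE)
    }
  }
  TRUE
}

cross2 <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])

## ---- rotation helpers --------------------------------------------------

#' Rotate points by an angle in degrees
#'
#' @param xy two-column matrix of points.
#' @param angle_deg rotation angle, degrees, counterclockwise in
#'   mathematical axes.
#' @param center optional pivot (default origin).
#' @return rotated two-column matrix.
#' @export
rotate_points <- function(xy, angle_deg, center = c(0, 0)) {
  xy <- as_vertex_matrix(xy)
  th <- angle_deg * pi / 180
  co <- cos(th); si <- sin(th)
  dx <- xy[, 1L] - center[1]; dy <- xy[, 2L] - center[2]
  cbind(co * dx - si * dy + center[1], si * dx + co * dy + center[2])
}

## ---- minimum-area bounding box ----------------------------------------

#' Minimum-area bounding box of a polygon
#'
#' Computes the minimum-area enclosing rectangle by rotating calipers over
#' the convex hull, the standard definition of a cell's "minimal bounding
#' box". The box's longer side defines the cell's length axis; its
#' orientation (degrees, in `[-90, 90)`) is the angle needed to turn the
#' cell onto the image x-axis with [orient_mesh()]. Area ties between
#' candidate hull edges are broken toward the axis angle of smallest
#' absolute value, so axis-aligned squares report angle 0.
#'
#' @param vertices polygon vertices (matrix or data frame with x, y).
#' @return a `box_fit`: list with `length`, `width` (pixels,
#'   `length >= width`), `angle` (degrees in `[-90, 90)`) and `center`
#'   (numeric x, y).
#' @examples
#' min_bounding_box(cbind(c(0, 4, 4, 0), c(0, 0, 2, 2)))
#' @export
min_bounding_box <- function(vertices) {
  v <- as_vertex_matrix(vertices)
  if (nrow(v) < 3L) cm_stop("degenerate_geometry", "need at least 3 vertices")
  h <- grDevices::chull(v[, 1L], v[, 2L])
  if (length(h) < 3L)
    cm_stop("degenerate_geometry", "vertices are collinear or degenerate")
  hv <- v[h, , drop = FALSE]
  n <- nrow(hv)
  edges <- hv[c(2:n, 1L), , drop = FALSE] - hv
  th <- atan2(edges[, 2L], edges[, 1L])  # radians
  best <- NULL
  for (k in seq_len(n)) {
    co <- cos(-th[k]); si <- sin(-th[k])
    rx <- co * hv[, 1L] - si * hv[, 2L]
    ry <- si * hv[, 1L] + co * hv[, 2L]
    ex <- range(rx); ey <- range(ry)
    area <- diff(ex) * diff(ey)
    # axis of the longer side, normalized to [-90, 90)
    ang <- th[k] * 180 / pi
    if (diff(ex) >= diff(ey)) {
      len <- diff(ex); wid <- diff(ey); axis_ang <- ang
    } else {
      len <- diff(ey); wid <- diff(ex); axis_ang <- ang + 90
    }
    axis_ang <- ((axis_ang + 90) %% 180) - 90
    # square boxes: either axis qualifies; prefer the smaller |angle|
    if (abs(len - wid) <= 1e-9 * max(len, wid)) {
      alt <- ((axis_ang + 180) %% 180) - 90
      if (abs(alt) < abs(axis_ang)) axis_ang <- alt
    }
    cx <- mean(ex); cy <- mean(ey)
    ctr <- c(cos(th[k]) * cx - sin(th[k]) * cy, sin(th[k]) * cx + cos(th[k]) * cy)
    cand <- list(length = len, width = wid, angle = axis_ang, center = ctr, area = area)
    # area ties (distinct boxes can tie exactly) are broken by the longer
    # box length — a rotation-invariant quantity — and only then by the
    # smaller |angle|, so (length, width) is stable under input rotation
    if (is.null(best) ||
        area < best$area * (1 - 1e-9) ||
        (area <= best$area * (1 + 1e-9) &&
         (len > best$length * (1 + 1e-9) ||
          (len >= best$length * (1 - 1e-9) &&
           abs(axis_ang) < abs(best$angle) - 1e-12)))) {
      best <- cand
    }
  }
  structure(best[c("length", "width", "angle", "center")], class = "box_fit")
}

#' @export
print.box_fit <- function(x, ...) {
  cat(sprintf("<box_fit> length %.4g px, width %.4g px, angle %.4g deg, center (%.4g, %.4g)\n",
              x$length, x$width, x$angle, x$center[1], x$center[2]))
  invisible(x)
}

#' Turn a cell outline onto its length axis
#'
#' Rotates the outline by minus the box angle about the box center and
#' translates the center to the origin, so the cell lies along the x-axis
#' with its midpoint at (0, 0). The x-extent of the result equals the box
#' length and the y-extent its width; polygon area is preserved.
#'
#' @param vertices polygon vertices.
#' @param fit the [min_bounding_box()] fit of the same polygon.
#' @return two-column matrix of rotated vertices.
#' @export
orient_mesh <- function(vertices, fit) {
  v <- as_vertex_matrix(vertices)
  r <- rotate_points(v, -fit$angle, center = fit$center)
  cbind(r[, 1L] - fit$center[1], r[, 2L] - fit$center[2])
}

## ---- point in polygon --------------------------------------------------

#' Even-odd point-in-polygon test
#'
#' Vectorized over query points. Points on the polygon boundary count as
#' inside (closed polygon), so membrane-localized spots are assigned
#' deterministically.
#'
#' @param px,py query point coordinates.
#' @param vertices polygon vertices.
#' @param eps tolerance for the boundary test, pixels.
#' @return logical vector, one element per query point.
#' @export
point_in_polygon <- function(px, py, vertices, eps = 1e-9) {
  v <- as_vertex_matrix(vertices)
  n <- nrow(v)
  m <- length(px)
  inside <- logical(m)
  boundary <- logical(m)
  xi <- v[, 1L]; yi <- v[, 2L]
  xj <- xi[c(n, 1:(n - 1L))]; yj <- yi[c(n, 1:(n - 1L))]
  for (k in seq_len(n)) {
    x1 <- xj[k]; y1 <- yj[k]; x2 <- xi[k]; y2 <- yi[k]
    # even-odd ray crossing (ray toward +x)
    crosses <- ((y2 > py) != (y1 > py))
    if (any(crosses)) {
      xint <- x2 + (py - y2) * (x1 - x2) / (y1 - y2)
      inside <- xor(inside, crosses & (px < xint))
    }
    # boundary: point within eps of segment
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    if (len2 == 0) {
      boundary <- boundary | (abs(px - x1) <= eps & abs(py - y1) <= eps)
    } else {
      t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
      d2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
      boundary <- boundary | (d2 <= eps * eps)
    }
  }
  inside | boundary
}

## ---- spot relativization ----------------------------------------------

#' Transform spots into cell-relative coordinates
#'
#' Rotates spot coordinates into the cell's length-axis frame: `l` runs
#' along the length axis (0 at mid-cell), `d` across the width axis (0 on
#' the central axis, positive toward the rotated +y direction; no
#' biological polarity is implied). `l_rel` and `d_rel` divide by cell
#' length and width, so spots inside the bounding box satisfy
#' `|l_rel| <= 0.5`, `|d_rel| <= 0.5`.
#'
#' @param x,y spot coordinates in pixels (vectorized).
#' @param fit the host cell's [min_bounding_box()] fit.
#' @return tibble with `l`, `d`, `l_rel`, `d_rel`.
#' @export
spot_relative <- function(x, y, fit) {
  if (fit$length <= 0 || fit$width <= 0)
    cm_stop("degenerate_geometry", "cell has zero length or width")
  r <- rotate_points(cbind(x, y), -fit$angle, center = fit$center)
  l <- r[, 1L] - fit$center[1]
  d <- r[, 2L] - fit$center[2]
  tibble::tibble(l = l, d = d, l_rel = l / fit$length, d_rel = d / fit$width)
}

#' Inverse of [spot_relative()]
#'
#' @param l,d cell-relative coordinates in pixels.
#' @param fit the cell's box fit.
#' @return tibble with image coordinates `x`, `y`.
#' @export
spot_absolute <- function(l, d, fit) {
  p <- rotate_points(cbind(l + fit$center[1], d + fit$center[2]), fit$angle,
                     center = fit$center)
  tibble::tibble(x = p[, 1L], y = p[, 2L])
}

## ---- spot-to-cell assignment ------------------------------------------

#' Assign spots to the cells that contain them
#'
#' A spot belongs to the cell whose outline contains it (even-odd rule,
#' boundary inclusive). When several outlines contain a spot — touching
#' cells in chains — it is assigned to the cell with the nearest bounding
#' box center and flagged ambiguous rather than discarded. Spots contained
#' by no outline are left unassigned (`cell_id` NA); unassignability is a
#' value, not an error, so spot counts are always conserved.
#'
#' @param spots tibble with at least `spot_id`, `frame_id`, `x`, `y`.
#' @param meshframe a meshframe tibble as built by [mesh_frame()].
#' @return `spots` plus columns `cell_id` (NA when unassigned) and
#'   `ambiguous` (logical).
#' @export
assign_spots <- function(spots, meshframe) {
  spots <- tibble::as_tibble(spots)
  if (nrow(spots) == 0L) {
    return(dplyr::mutate(spots, cell_id = character(0), ambiguous = logical(0)))
  }
  cell_id <- rep(NA_character_, nrow(spots))
  ambiguous <- rep(FALSE, nrow(spots))
  for (fr in unique(spots$frame_id)) {
    sp_i <- which(spots$frame_id == fr)
    mf <- meshframe[meshframe$frame_id == fr, , drop = FALSE]
    if (nrow(mf) == 0L) next
    px <- spots$x[sp_i]; py <- spots$y[sp_i]
    hits <- vapply(seq_len(nrow(mf)), function(j) {
      point_in_polygon(px, py, mf$mesh[[j]])
    }, logical(length(sp_i)))
    hits <- matrix(hits, nrow = length(sp_i))
    nhit <- rowSums(hits)
    for (s in which(nhit > 0L)) {
      js <- which(hits[s, ])
      if (length(js) > 1L) {
        ctrs <- vapply(js, function(j) {
          f <- mf$fit[[j]]
          (px[s] - f$center[1])^2 + (py[s] - f$center[2])^2
        }, numeric(1))
        js <- js[which.min(ctrs)]
        ambiguous[sp_i[s]] <- TRUE
      }
      cell_id[sp_i[s]] <- mf$cell_id[js]
    }
  }
  dplyr::mutate(spots, cell_id = cell_id, ambiguous = ambiguous)
}

## ---- pixel extraction --------------------------------------------------

#' Extract the image pixels covered by a cell outline
#'
#' Returns every pixel whose center (integer 0-based coordinates) lies
#' inside the polygon, with its intensity and length-axis coordinates.
#' Pixels outside the image bounds are clipped.
#'
#' @param vertices cell outline in pixel coordinates.
#' @param image numeric matrix; `image[r + 1, c + 1]` is the intensity of
#'   the pixel with center (x = c, y = r), 0-based.
#' @param fit optional precomputed [min_bounding_box()] fit.
#' @return tibble with `row`, `col` (0-based), `x`, `y`, `intensity`,
#'   `l`, `d`, `l_rel`, `d_rel`.
#' @export
pixels_in_mesh <- function(vertices, image, fit = NULL) {
  v <- as_vertex_matrix(vertices)
  if (is.null(fit)) fit <- min_bounding_box(v)
  nr <- nrow(image); nc <- ncol(image)
  cmin <- max(0L, floor(min(v[, 1L]))); cmax <- min(nc - 1L, ceiling(max(v[, 1L])))
  rmin <- max(0L, floor(min(v[, 2L]))); rmax <- min(nr - 1L, ceiling(max(v[, 2L])))
  if (cmin > cmax || rmin > rmax)
    cm_stop("empty_cell", "no pixel center inside the outline after clipping")
  g <- expand.grid(col = cmin:cmax, row = rmin:rmax)
  keep <- point_in_polygon(g$col, g$row, v)
  if (!any(keep))
    cm_stop("empty_cell", "no pixel center inside the outline after clipping")
  g <- g[keep, , drop = FALSE]
  rel <- spot_relative(g$col, g$row, fit)
  tibble::tibble(
    row = as.integer(g$row), col = as.integer(g$col),
    x = as.numeric(g$col), y = as.numeric(g$row),
    intensity = image[cbind(g$row + 1L, g$col + 1L)],
    l = rel$l, d = rel$d, l_rel = rel$l_rel, d_rel = rel$d_rel
  )
}

## ---- object relativization --------------------------------------------

#' Transform fluorescent-object outlines into cell-relative coordinates
#'
#' Each object is attached to the cell whose outline contains the object's
#' centroid (same nearest-center tie rule as [assign_spots()]); its
#' vertices are then transformed with the host cell's length-axis
#' transform, i.e. vertex-wise [spot_relative()]. Objects whose centroid
#' falls in no cell are left unassigned with their outline unchanged.
#'
#' @param objects tibble with `object_id`, `frame_id` and a `vertices`
#'   list-column of outline matrices.
#' @param meshframe a meshframe tibble.
#' @return `objects` with columns `cell_id`, `ambiguous` and a
#'   `vertices_rel` list-column (NULL where unassigned).
#' @export
relativize_objects <- function(objects, meshframe) {
  objects <- tibble::as_tibble(objects)
  if (nrow(objects) == 0L) {
    return(dplyr::mutate(objects, cell_id = character(0), ambiguous = logical(0),
                         vertices_rel = list()))
  }
  cents <- t(vapply(objects$vertices, polygon_centroid, numeric(2)))
  probe <- tibble::tibble(
    spot_id = objects$object_id, frame_id = objects$frame_id,
    x = cents[, 1L], y = cents[, 2L]
  )
  asg <- assign_spots(probe, meshframe)
  vertices_rel <- vector("list", nrow(objects))
  for (i in seq_len(nrow(objects))) {
    if (is.na(asg$cell_id[i])) next
    j <- which(meshframe$cell_id == asg$cell_id[i] &
                 meshframe$frame_id == objects$frame_id[i])[1]
    fit <- meshframe$fit[[j]]
    v <- as_vertex_matrix(objects$vertices[[i]])
    rel <- spot_relative(v[, 1L], v[, 2L], fit)
    vertices_rel[[i]] <- cbind(rel$l, rel$d)
  }
  dplyr::mutate(objects, cell_id = asg$cell_id, ambiguous = asg$ambiguous,
                vertices_rel = vertices_rel)
}
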