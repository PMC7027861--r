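# Intensity analytics on the cell length axis: per-cell profiles,
# kymographs, demographs, fluorescence-versus-division profile matrices
# and their hierarchical clustering.

#' Mean-intensity profile along the length axis
#'
#' Splits the normalized length axis `l_rel` in \[-0.5, 0.5\] into
#' `n_bins` equal bins and averages the intensity of the pixels whose
#' center falls in each bin. Empty interior bins are filled by linear
#' interpolation from their populated neighbors and flagged.
#'
#' @param pixels a [pixels_in_mesh()] result (needs `l_rel`,
#'   `intensity`).
#' @param n_bins number of bins (default 25).
#' @return tibble with `bin`, `l_rel` (bin center), `value`,
#'   `interpolated`.
#' @export
axis_profile <- function(pixels, n_bins = 25L) {
  if (nrow(pixels) == 0L) cm_stop("empty_cell", "no pixels to profile")
  edges <- seq(-0.5, 0.5, length.out = n_bins + 1L)
  idx <- pmin(pmax(findInterval(pixels$l_rel, edges, rightmost.closed = TRUE), 1L), n_bins)
  val <- rep(NA_real_, n_bins)
  agg <- tapply(pixels$intensity, factor(idx, levels = seq_len(n_bins)), mean)
  val[!is.na(agg)] <- agg[!is.na(agg)]
  filled <- is.na(val)
  if (all(filled)) cm_stop("empty_cell", "all profile bins empty")
  if (any(filled)) {
    known <- which(!filled)
    val <- if (length(known) == 1L) rep(val[known], n_bins) else
      stats::approx(known, val[known], xout = seq_len(n_bins), rule = 2)$y
  }
  tibble::tibble(bin = seq_len(n_bins),
                 l_rel = (edges[-1] + edges[-length(edges)]) / 2,
                 value = val, interpolated = filled)
}

#' Kymograph of one cell track
#'
#' Stacks the length-axis profile of one cell over time: row t is the
#' [axis_profile()] of the cell's outline applied to image frame t.
#' Because the bounding-box length axis has no intrinsic pole identity,
#' the orientation sign is held consistent across frames by choosing, for
#' each frame, the orientation (as-is or flipped) whose profile has the
#' smaller L2 distance to the previous frame's profile.
#'
#' @param track_meshes tibble with `frame_id` and `mesh` list-column
#'   (one row per movie frame, ascending), plus optional `time`.
#' @param stack an image stack (list of matrices or `image_stack`); frame
#'   `i` of the track uses `frames[[frame_id + 1]]`.
#' @param n_bins profile bins (default 25).
#' @param track_id label stored on the result (default `"track"`).
#' @return a `kymograph`: list with `matrix` (frames x bins), `time`,
#'   `track_id`.
#' @export
kymograph <- function(track_meshes, stack, n_bins = 25L, track_id = NULL) {
  frames <- if (inherits(stack, "image_stack")) stack$frames else stack
  tm <- track_meshes[order(track_meshes$frame_id), , drop = FALSE]
  mat <- matrix(NA_real_, nrow(tm), n_bins)
  prev <- NULL
  for (i in seq_len(nrow(tm))) {
    fid <- tm$frame_id[i]
    if (fid + 1L > length(frames) || fid < 0L)
      cm_stop("missing_frame", sprintf("image frame %d absent from stack", fid))
    img <- frames[[fid + 1L]]
    px <- pixels_in_mesh(tm$mesh[[i]], img)
    prof <- axis_profile(px, n_bins)$value
    if (!is.null(prev)) {
      if (sum((rev(prof) - prev)^2) < sum((prof - prev)^2)) prof <- rev(prof)
    }
    mat[i, ] <- prof
    prev <- prof
  }
  structure(list(matrix = mat,
                 time = if ("time" %in% names(tm)) tm$time else tm$frame_id,
                 track_id = track_id %||% "track"),
            class = "kymograph")
}

#' Demograph: population profile matrix ordered by cell length
#'
#' One row per cell, rows sorted by ascending cell length (ties broken by
#' `cell_id`), so the matrix reads as a population-wide picture of
#' localization versus cell size. Optional per-cell normalization divides
#' each row by its maximum.
#'
#' @param profiles tibble with `cell_id` and a `profile` list-column of
#'   equal-length numeric vectors (e.g. `axis_profile()$value`).
#' @param cell_lengths tibble with `cell_id`, `length`.
#' @param normalize divide each row by its max (default FALSE).
#' @return matrix (cells x bins) with rownames = cell ids, ordered by
#'   length; lengths in `attr(, "length")`.
#' @export
demograph <- function(profiles, cell_lengths, normalize = FALSE) {
  cl <- cell_lengths[order(cell_lengths$length, cell_lengths$cell_id), ]
  rows <- match(cl$cell_id, profiles$cell_id)
  mat <- do.call(rbind, profiles$profile[rows])
  if (normalize) {
    mx <- apply(mat, 1L, max)
    mx[mx == 0] <- 1
    mat <- mat / mx
  }
  rownames(mat) <- cl$cell_id
  attr(mat, "length") <- cl$length
  mat
}

#' Fluorescence-versus-division profile matrix
#'
#' For each cell (track) with a complete cycle, linearly interpolates its
#' mean cellular fluorescence against percentage-of-division onto a
#' common grid (default 0-100 in steps of 1, 101 points). Grid points
#' outside a cell's observed percentage range are filled by nearest-value
#' extrapolation and flagged. Tracks with fewer than two annotated frames
#' are excluded and counted.
#'
#' @param tracks annotated, filtered tracks (`percent`, `fluor`).
#' @param grid percentage grid (default `0:100`).
#' @param z_normalize center/scale each row to mean 0, sd 1 (for
#'   clustering).
#' @return matrix (cells x grid) with attributes `grid`, `extrapolated`
#'   (logical matrix), `excluded` (track ids).
#' @export
profile_matrix <- function(tracks, grid = 0:100, z_normalize = FALSE) {
  parts <- split(tracks[!is.na(tracks$percent), ], tracks$track_id[!is.na(tracks$percent)])
  ok <- vapply(parts, function(tr) nrow(tr) >= 2L, logical(1))
  excluded <- names(parts)[!ok]
  if (length(excluded)) cm_log("%d tracks with < 2 annotated frames excluded", length(excluded))
  parts <- parts[ok]
  if (!length(parts)) cm_stop("cluster_error", "no tracks with annotated cycles")
  mat <- t(vapply(parts, function(tr) {
    agg <- dplyr::summarise(dplyr::group_by(tr, percent),
                            fluor = mean(fluor), .groups = "drop")
    stats::approx(agg$percent, agg$fluor, xout = grid, rule = 2)$y
  }, numeric(length(grid))))
  extrap <- t(vapply(parts, function(tr) {
    grid < min(tr$percent) | grid > max(tr$percent)
  }, logical(length(grid))))
  if (z_normalize) {
    mu <- rowMeans(mat)
    sdv <- apply(mat, 1L, stats::sd)
    sdv[sdv == 0] <- 1
    mat <- (mat - mu) / sdv
  }
  rownames(mat) <- names(parts)
  attr(mat, "grid") <- grid
  attr(mat, "extrapolated") <- extrap
  attr(mat, "excluded") <- excluded
  mat
}

#' Dissimilarity matrix between fluorescence profiles
#'
#' @param pm profile matrix (cells x grid), >= 2 rows.
#' @param method `"euclidean"` (L2 distance of rows, default) or
#'   `"correlation"` (1 - Pearson r, so perfectly anticorrelated rows are
#'   at distance 2).
#' @return symmetric matrix with zero diagonal.
#' @export
dissimilarity_matrix <- function(pm, method = c("euclidean", "correlation")) {
  method <- match.arg(method)
  if (nrow(pm) < 2L) cm_stop("dissimilarity_error", "need at least 2 profiles")
  if (method == "euclidean") {
    d <- as.matrix(stats::dist(pm, method = "euclidean"))
  } else {
    sdv <- apply(pm, 1L, stats::sd)
    if (any(sdv == 0))
      cm_stop("dissimilarity_error",
              sprintf("zero-variance profile for cell %s",
                      rownames(pm)[which(sdv == 0)[1]] %||% which(sdv == 0)[1]))
    d <- 1 - stats::cor(t(pm))
    diag(d) <- 0
  }
  d
}

#' Hierarchical clustering of fluorescence profiles
#'
#' Agglomerative clustering on a precomputed dissimilarity matrix, cut at
#' `k` clusters. Labels are relabeled in decreasing cluster size (cluster
#' 1 is the largest), and per-cluster summaries (size, fraction of cells,
#' mean and sd profile) are attached.
#'
#' @param d dissimilarity matrix from [dissimilarity_matrix()].
#' @param k number of clusters.
#' @param linkage `"average"` (default), `"complete"` or `"ward"`
#'   (Ward.D2).
#' @param pm optional profile matrix for the per-cluster mean/sd profile
#'   summaries.
#' @return a `cluster_result`: list with `labels` (named integer vector),
#'   `sizes`, `fractions`, `summary` (tibble of cluster x grid mean/sd),
#'   `hclust`.
#' @export
cluster_profiles <- function(d, k, linkage = c("average", "complete", "ward"),
                             pm = NULL) {
  linkage <- match.arg(linkage)
  n <- nrow(d)
  if (k < 1L || k > n) cm_stop("cluster_error", sprintf("k = %d outside 1..%d", k, n))
  hc <- stats::hclust(stats::as.dist(d),
                      method = if (linkage == "ward") "ward.D2" else linkage)
  raw <- stats::cutree(hc, k = k)
  sizes <- sort(table(raw), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  labels <- stats::setNames(as.integer(relabel[as.character(raw)]), names(raw))
  sizes <- as.integer(table(factor(labels, levels = seq_len(k))))
  fractions <- sizes / n
  summary <- NULL
  if (!is.null(pm)) {
    grid <- attr(pm, "grid") %||% seq_len(ncol(pm))
    summary <- dplyr::bind_rows(lapply(seq_len(k), function(cl) {
      rows <- pm[labels == cl, , drop = FALSE]
      tibble::tibble(cluster = cl, grid = grid,
                     mean = colMeans(rows),
                     sd = apply(rows, 2L, stats::sd))
    }))
  }
  structure(list(labels = labels, sizes = sizes, fractions = fractions,
                 summary = summary, hclust = hc, k = k),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k = %d\n", x$k))
  for (i in seq_len(x$k)) {
    cat(sprintf("  cluster %d: n = %d (%.1f%%)\n", i, x$sizes[i], 100 * x$fractions[i]))
  }
  invisible(x)
}
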