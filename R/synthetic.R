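# Synthetic fixture and ground-truth generator. Everything here is
# deterministic per seed (R's default Mersenne-Twister, fixed by
# set.seed), so tests and acceptance runs regenerate bit-identical data.
#
# The generator defines the study conditions the analytics are verified
# under: rod/coccus/ovococcus outlines, Gaussian-spot images with
# optional Poisson noise, and exponentially growing tracks that halve
# their length at a division threshold.

#' Generate a synthetic cell outline
#'
#' Three idealized Gram-positive morphologies: `rod` (rectangle with
#' semicircular caps, a bacillus), `coccus` (circle; width is forced
#' equal to length) and `ovococcus` (ellipse). The polygon is simple,
#' counterclockwise, and its true minimum bounding box is
#' (length, width, angle) up to discretization of the caps.
#'
#' @param shape `"rod"`, `"coccus"` or `"ovococcus"`.
#' @param length,width cell dimensions in pixels (`length >= width`).
#' @param center numeric (x, y) center in pixels.
#' @param angle orientation of the length axis, degrees.
#' @param n_vertices approximate vertex count (>= 8; rounded to an even
#'   total).
#' @return two-column vertex matrix.
#' @export
make_mesh <- function(shape = c("rod", "coccus", "ovococcus"),
                      length = 20, width = 8, center = c(0, 0), angle = 0,
                      n_vertices = 32L) {
  shape <- match.arg(shape)
  if (shape == "coccus") width <- length
  if (width > length)
    cm_stop("geometry_error", "width must not exceed length")
  if (width <= 0) cm_stop("geometry_error", "width must be positive")
  if (n_vertices < 8L) cm_stop("geometry_error", "need at least 8 vertices")
  if (shape == "rod") {
    # odd points per cap so each arc contains its apex -> exact length extent
    m <- max(5L, n_vertices %/% 2L)
    if (m %% 2L == 0L) m <- m + 1L
    r <- width / 2
    cx <- length / 2 - r
    right <- cbind(cx + r * cos(seq(-pi / 2, pi / 2, length.out = m)),
                   r * sin(seq(-pi / 2, pi / 2, length.out = m)))
    left <- cbind(-cx + r * cos(seq(pi / 2, 3 * pi / 2, length.out = m)),
                  r * sin(seq(pi / 2, 3 * pi / 2, length.out = m)))
    v <- rbind(right, left)
  } else {
    n <- n_vertices + n_vertices %% 2L
    th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
    v <- cbind(length / 2 * cos(th), width / 2 * sin(th))
  }
  v <- rotate_points(v, angle)
  v <- cbind(v[, 1L] + center[1], v[, 2L] + center[2])
  ensure_ccw(v)
}

# Archetype fluorescence-vs-division profiles (piecewise linear in
# percent). Waypoints chosen so pairwise curve separation is ~0.5-0.6
# in arbitrary units around the late cycle.
archetype_profiles <- list(
  dip_then_recover = function(p) stats::approx(c(0, 60, 80, 100), c(1, 1, 0.4, 0.7),
                                               xout = p, rule = 2)$y,
  gradual = function(p) stats::approx(c(0, 100), c(1, 0.9), xout = p, rule = 2)$y,
  late_drop = function(p) stats::approx(c(0, 80, 100), c(1, 1, 0.3), xout = p, rule = 2)$y
)

#' Simulate exponentially growing, dividing cell tracks
#'
#' Each lineage grows as `L(t) = L_birth * exp(g t)` and divides into two
#' equal daughters once its true length reaches `division_length`; the
#' track follows one daughter, so divisions appear as length halvings
#' within the track. Observed lengths carry multiplicative noise
#' `exp(rnorm(0, length_noise_sd))`. A fraction of tracks are planted
#' non-growers (constant true length, same observation noise). Mean
#' cellular fluorescence follows one of three archetype profiles of the
#' cycle (dip-then-recover, gradual, late-drop) plus Gaussian noise.
#'
#' @param n_cells number of tracks.
#' @param growth_rate exponential growth rate, per minute (default 0.01).
#' @param division_length true length at which a cell divides, pixels.
#' @param length_noise_sd sd of multiplicative observation noise
#'   (default 0.03).
#' @param frame_interval seconds between frames (default 120, the 2-min
#'   movie cadence).
#' @param n_frames frames per track.
#' @param non_grower_fraction fraction of planted non-growing tracks
#'   (default 0.1).
#' @param fluor_noise_sd sd of additive fluorescence noise (default
#'   0.05, ~10% of the archetype curve separation).
#' @param archetype_fractions length-3 fractions of the archetypes
#'   (dip_then_recover, gradual, late_drop).
#' @param width_ratio cell width as a fraction of birth length.
#' @param seed RNG seed (required: truth must be reproducible).
#' @return list with `tracks` (tibble: track_id, frame_id, time, length,
#'   width, fluor) and `truth` (list: per-track division indices,
#'   non-grower flags, archetype labels, parameters, seed).
#' @export
simulate_timelapse <- function(n_cells = 100L, growth_rate = 0.01,
                               division_length = 4, length_noise_sd = 0.03,
                               frame_interval = 120, n_frames = 80L,
                               non_grower_fraction = 0.1,
                               fluor_noise_sd = 0.05,
                               archetype_fractions = c(0.4, 0.4, 0.2),
                               width_ratio = 0.45, seed) {
  stopifnot(n_cells >= 1L, growth_rate > 0, division_length > 0,
            frame_interval > 0, n_frames >= 2L)
  set.seed(seed)
  g_sec <- growth_rate / 60
  n_ng <- round(n_cells * non_grower_fraction)
  non_grower <- rep(FALSE, n_cells)
  if (n_ng > 0L) non_grower[sample.int(n_cells, n_ng)] <- TRUE
  arch_names <- names(archetype_profiles)
  archetype <- sample(arch_names, n_cells, replace = TRUE,
                      prob = archetype_fractions)
  times <- (seq_len(n_frames) - 1L) * frame_interval
  rows <- vector("list", n_cells)
  truth_div <- vector("list", n_cells)
  ids <- sprintf("track_%04d", seq_len(n_cells))
  for (i in seq_len(n_cells)) {
    lb <- division_length / 2 * stats::runif(1, 0.9, 1.1)
    true_len <- numeric(n_frames)
    percent <- rep(NA_real_, n_frames)
    divs <- integer(0)
    cur <- lb
    t_birth <- 0
    for (f in seq_len(n_frames)) {
      t <- times[f]
      if (non_grower[i]) {
        true_len[f] <- lb
        next
      }
      val <- cur * exp(g_sec * (t - t_birth))
      if (val >= division_length) {
        # divided between f-1 and f: observe the daughter
        divs <- c(divs, f - 2L)           # 0-based index of frame before drop
        cur <- val / 2
        t_birth <- t
        val <- cur
      }
      true_len[f] <- val
      # progress proxy for the fluorescence model
      percent[f] <- 100 * log(val / cur) / log(division_length / cur)
    }
    divs <- divs[divs >= 0L]
    obs_len <- true_len * exp(stats::rnorm(n_frames, 0, length_noise_sd))
    pfun <- archetype_profiles[[archetype[i]]]
    p_for_fluor <- ifelse(is.na(percent), 50, percent)
    fluor <- pfun(p_for_fluor) + stats::rnorm(n_frames, 0, fluor_noise_sd)
    rows[[i]] <- tibble::tibble(
      track_id = ids[i], frame_id = seq_len(n_frames) - 1L, time = times,
      length = obs_len, width = width_ratio * lb, fluor = fluor)
    truth_div[[i]] <- divs
  }
  tracks <- dplyr::bind_rows(rows)
  truth <- list(divisions = stats::setNames(truth_div, ids),
                non_grower = stats::setNames(non_grower, ids),
                archetype = stats::setNames(archetype, ids),
                params = list(growth_rate = growth_rate,
                              division_length = division_length,
                              length_noise_sd = length_noise_sd,
                              frame_interval = frame_interval,
                              n_frames = n_frames,
                              non_grower_fraction = non_grower_fraction,
                              fluor_noise_sd = fluor_noise_sd),
                seed = seed)
  list(tracks = tracks, truth = truth)
}

#' Render a synthetic fluorescence image
#'
#' Image = background + one isotropic Gaussian per spot (amplitude,
#' sigma), optionally Poisson-sampled. Pixel (x = c, y = r), 0-based,
#' maps to `image[r + 1, c + 1]`.
#'
#' @param dim image size, (rows, cols).
#' @param spots tibble with `x`, `y` and optional `amplitude`.
#' @param psf_sigma Gaussian sigma of the rendered point-spread, pixels.
#' @param background constant background level.
#' @param poisson apply Poisson shot noise?
#' @param amplitude default spot amplitude.
#' @param seed RNG seed (only used when `poisson = TRUE`).
#' @return numeric matrix.
#' @export
render_image <- function(dim = c(64L, 64L), spots = NULL, psf_sigma = 2,
                         background = 0, poisson = FALSE, amplitude = 100,
                         seed = NULL) {
  img <- matrix(background, dim[1], dim[2])
  if (!is.null(spots) && nrow(spots) > 0L) {
    xs <- seq_len(dim[2]) - 1L
    ys <- seq_len(dim[1]) - 1L
    amp <- spots[["amplitude"]] %||% rep(amplitude, nrow(spots))
    for (k in seq_len(nrow(spots))) {
      gx <- exp(-((xs - spots$x[k])^2) / (2 * psf_sigma^2))
      gy <- exp(-((ys - spots$y[k])^2) / (2 * psf_sigma^2))
      img <- img + amp[k] * outer(gy, gx)
    }
  }
  if (poisson) {
    if (!is.null(seed)) set.seed(seed)
    img <- matrix(stats::rpois(length(img), lambda = img), dim[1], dim[2])
  }
  img
}

#' Planted spot positions inside a cell
#'
#' Standard localization patterns used to emulate divisome/replisome
#' behavior: `midcell` (one spot at l_rel = 0), `quarter` (spots at
#' l_rel = -0.25 and +0.25), and `sweep` (one position moving linearly
#' from mid-cell at s = 0 to the quarter position at s = 1).
#'
#' @param fit the cell's [min_bounding_box()] fit.
#' @param pattern `"midcell"`, `"quarter"` or `"sweep"`.
#' @param s sweep progress in \[0, 1\] (only for `"sweep"`).
#' @return tibble of image-coordinate spot positions `x`, `y` plus the
#'   planted `l_rel`.
#' @export
plant_spots <- function(fit, pattern = c("midcell", "quarter", "sweep"), s = 0) {
  pattern <- match.arg(pattern)
  l_rel <- switch(pattern,
    midcell = 0,
    quarter = c(-0.25, 0.25),
    sweep = 0.25 * s)
  abs <- spot_absolute(l_rel * fit$length, 0, fit)
  tibble::tibble(x = abs$x, y = abs$y, l_rel = l_rel)
}

## ---- fixture writers ---------------------------------------------------

#' Write import fixtures in a supported dialect
#'
#' Writes meshes and/or spots as files structurally valid for the
#' matching importer, closing the import(write(X)) = X round-trip
#' property for every dialect the package can read.
#'
#' @param meshes tibble with `cell_id`, `frame_id`, `mesh` list-column
#'   (0-based coordinates).
#' @param spots optional spot tibble (`spot_id`, `frame_id`, `x`, `y`,
#'   optional `intensity`, `track_id`).
#' @param dialect `"generic-csv"`, `"oufti-mat"`, `"isbatch-csv"` or
#'   `"microbej-csv"`.
#' @param dir output directory.
#' @return named character vector of written paths.
#' @export
write_fixture <- function(meshes = NULL, spots = NULL,
                          dialect = c("generic-csv", "oufti-mat",
                                      "isbatch-csv", "microbej-csv"),
                          dir = tempfile("fixture")) {
  if (is.character(dialect) && length(dialect) == 1L &&
      !dialect %in% c("generic-csv", "oufti-mat", "isbatch-csv", "microbej-csv"))
    cm_stop("dialect_error", sprintf("unsupported dialect: %s", dialect))
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- character()
  if (dialect == "generic-csv") {
    if (!is.null(meshes)) {
      long <- vertices_to_long(meshes$cell_id, meshes$frame_id, meshes$mesh)
      names(long)[1] <- "cell_id"
      long$vertex <- long$vertex
      p <- file.path(dir, "meshes.csv")
      readr::write_csv(long[c("cell_id", "frame_id", "vertex", "x", "y")], p,
                       progress = FALSE)
      out["meshes"] <- p
    }
    if (!is.null(spots)) {
      p <- file.path(dir, "spots.csv")
      readr::write_csv(spots, p, progress = FALSE)
      out["spots"] <- p
    }
  } else if (dialect == "oufti-mat") {
    if (is.null(meshes)) meshes <- tibble::tibble(cell_id = character(),
                                                  frame_id = integer(), mesh = list())
    cl <- lapply(seq_len(nrow(meshes)), function(i) {
      v <- as_vertex_matrix(meshes$mesh[[i]])
      m <- nrow(v)
      if (m %% 2L != 0L)
        cm_stop("dialect_error", "oufti-mat meshes need an even vertex count")
      n <- m / 2L + 1L
      left <- v[1:n, , drop = FALSE]
      right <- v[c(1L, if (m >= n + 1L) m:(n + 1L) else integer(0), n), , drop = FALSE]
      list(cellId = as.numeric(gsub("\\D", "", meshes$cell_id[i])),
           frame = as.numeric(meshes$frame_id[i]),
           mesh = cbind(left, right) + 1)   # 1-based on disk
    })
    p <- file.path(dir, "cells.mat")
    write_mat(list(cellList = structure(cl, class = "mat_struct")), p)
    out["mat"] <- p
  } else if (dialect == "isbatch-csv") {
    if (is.null(spots)) cm_stop("dialect_error", "isbatch-csv needs spots")
    df <- tibble::tibble(id = spots$spot_id, frame = spots$frame_id,
                         x = spots$x + 1, y = spots$y + 1)
    if (!is.null(spots$intensity)) df$intensity <- spots$intensity
    if (!is.null(spots$track_id)) df$trajectory <- spots$track_id
    p <- file.path(dir, "spots_isbatch.csv")
    readr::write_csv(df, p, progress = FALSE)
    out["spots"] <- p
  } else if (dialect == "microbej-csv") {
    if (is.null(meshes)) cm_stop("dialect_error", "microbej-csv needs meshes")
    long <- vertices_to_long(meshes$cell_id, meshes$frame_id, meshes$mesh)
    df <- tibble::tibble(NAME = long$id, POSITION = long$frame_id,
                         INDEX = long$vertex,
                         `LOCATION.x` = long$x + 1, `LOCATION.y` = long$y + 1)
    p <- file.path(dir, "meshes_microbej.csv")
    readr::write_csv(df, p, progress = FALSE)
    out["meshes"] <- p
  }
  out
}
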