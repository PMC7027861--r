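# Rendering of the analytics to figure files. Every renderer is a pure
# function of (data, style): it writes the figure and returns the exact
# data table it drew, so tests assert on the table and never on pixels.
# Default palettes are the colorblind-safe viridis maps shipped with
# ggplot2.

utils::globalVariables(c(
  "x", "y", "id", "vertex", "value", "group", "l", "d", "rank",
  "envelope_lo", "envelope_hi", "time", "bin", "percent", "length",
  "cluster", "fluor", "track_id", "lo", "hi", "frame_id", "l_rel",
  "mean_", "sd_", "label", "xend", "yend", "intensity", "panel", "grid"
))

save_figure <- function(plot, path, width = 6, height = 4) {
  if (is.null(path)) return(invisible(NULL))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  ok <- tryCatch({
    ggplot2::ggsave(path, plot, width = width, height = height, dpi = 150)
    TRUE
  }, error = function(e) {
    cm_stop("io_error", sprintf("cannot write figure %s: %s", path, conditionMessage(e)))
  })
  invisible(path)
}

#' Overlay of raw image, cell outlines and spots
#'
#' Draws the microscopy frame (if given) with cell outlines and detected
#' spots on top, in image coordinates (y down). Returns the drawn
#' coordinates so geometry can be asserted without image diffing.
#'
#' @param image optional numeric matrix (one frame).
#' @param meshframe optional meshframe tibble (uses `cell_id`, `mesh`).
#' @param spots optional spot tibble (`x`, `y`).
#' @param path optional output figure file (.pdf or .png).
#' @return list with `plot` (ggplot), `data` (list of tibbles:
#'   `outlines`, `spots`, `image_dim`) and `path`.
#' @export
render_overlay <- function(image = NULL, meshframe = NULL, spots = NULL,
                           path = NULL) {
  p <- ggplot2::ggplot()
  data <- list()
  if (!is.null(image)) {
    img_df <- tibble::tibble(
      x = rep(seq_len(ncol(image)) - 1L, each = nrow(image)),
      y = rep(seq_len(nrow(image)) - 1L, times = ncol(image)),
      intensity = as.vector(image))
    p <- p + ggplot2::geom_raster(data = img_df, ggplot2::aes(x, y, fill = intensity)) +
      ggplot2::scale_fill_viridis_c()
    data$image_dim <- tibble::tibble(rows = nrow(image), cols = ncol(image))
  }
  if (!is.null(meshframe) && nrow(meshframe) > 0L) {
    outl <- vertices_to_long(meshframe$cell_id, meshframe$frame_id, meshframe$mesh)
    p <- p + ggplot2::geom_path(
      data = dplyr::bind_rows(lapply(split(outl, outl$id), function(d) {
        dplyr::bind_rows(d, d[1, ])   # close the ring
      })),
      ggplot2::aes(x, y, group = id), color = "white", linewidth = 0.3)
    data$outlines <- outl
  }
  if (!is.null(spots) && nrow(spots) > 0L) {
    sp <- tibble::as_tibble(spots)[c("x", "y")]
    p <- p + ggplot2::geom_point(data = sp, ggplot2::aes(x, y),
                                 color = "orange", size = 0.8)
    data$spots <- sp
  }
  p <- p + ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::theme_void()
  save_figure(p, path)
  list(plot = p, data = data, path = path)
}

#' Render an analytics plot from a specification
#'
#' One entry point for all figure kinds. Each renderer writes the figure
#' (when `path` is given) and returns the plotted table; renderers are
#' deterministic in their inputs.
#'
#' Kinds and their `data` argument:
#' * `overlay`: list(image, meshframe, spots) — delegates to
#'   [render_overlay()].
#' * `tower`: a [density_projection()] result.
#' * `demograph`: a [demograph()] matrix.
#' * `kymograph`: a [kymograph()] object.
#' * `tracks`: annotated tracks (length and fluorescence vs percent).
#' * `trajectory_xy`: spot tibble with `x`, `y`, `track_id`.
#' * `tree`: a [build_lineage()] result.
#' * `histogram`: numeric vector in `data$values`.
#' * `movie_strip`: list(track_meshes, stack) — one panel per frame.
#' * `cluster_summary`: a [cluster_profiles()] result (needs summaries).
#'
#' @param kind plot kind (see above).
#' @param data the kind-specific data.
#' @param path optional output file.
#' @param options list of style options (currently `palette`).
#' @return list with `plot`, `data` (tibble actually drawn) and `path`.
#' @export
render_plot <- function(kind, data, path = NULL, options = list()) {
  kinds <- c("overlay", "tower", "demograph", "kymograph", "tracks",
             "trajectory_xy", "tree", "histogram", "movie_strip",
             "cluster_summary")
  if (!kind %in% kinds)
    cm_stop("spec_error", sprintf("unknown plot kind: %s", kind))
  switch(kind,
    overlay = render_overlay(data$image, data$meshframe, data$spots, path),
    tower = {
      df <- tibble::as_tibble(data)
      p <- ggplot2::ggplot(df, ggplot2::aes(x, y, fill = value)) +
        ggplot2::geom_raster() + ggplot2::scale_fill_viridis_c() +
        ggplot2::facet_wrap(~group) + ggplot2::coord_fixed() +
        ggplot2::labs(x = "relative length axis", y = "relative width axis")
      save_figure(p, path)
      list(plot = p, data = df, path = path)
    },
    demograph = {
      m <- data
      df <- tibble::tibble(
        cell = rep(seq_len(nrow(m)), times = ncol(m)),
        bin = rep(seq_len(ncol(m)), each = nrow(m)),
        value = as.vector(m))
      p <- ggplot2::ggplot(df, ggplot2::aes(bin, cell, fill = value)) +
        ggplot2::geom_raster() + ggplot2::scale_fill_viridis_c() +
        ggplot2::labs(x = "length-axis bin", y = "cells (by length)")
      save_figure(p, path)
      list(plot = p, data = df, path = path)
    },
    kymograph = {
      m <- data$matrix
      df <- tibble::tibble(
        time = rep(data$time, times = ncol(m)),
        bin = rep(seq_len(ncol(m)), each = nrow(m)),
        value = as.vector(m))
      p <- ggplot2::ggplot(df, ggplot2::aes(bin, time, fill = value)) +
        ggplot2::geom_raster() + ggplot2::scale_fill_viridis_c() +
        ggplot2::scale_y_reverse() +
        ggplot2::labs(x = "length-axis bin", y = "time (s)")
      save_figure(p, path)
      list(plot = p, data = df, path = path)
    },
    tracks = {
      df <- tibble::as_tibble(data)[c("track_id", "time", "length", "fluor", "percent")]
      p <- ggplot2::ggplot(df, ggplot2::aes(time, length, group = track_id)) +
        ggplot2::geom_line(alpha = 0.4) +
        ggplot2::labs(x = "time (s)", y = "cell length (px)")
      save_figure(p, path)
      list(plot = p, data = df, path = path)
    },
    trajectory_xy = {
      df <- tibble::as_tibble(data)[c("track_id", "x", "y")]
      p <- ggplot2::ggplot(df, ggplot2::aes(x, y, color = track_id)) +
        ggplot2::geom_path() + ggplot2::scale_y_reverse() +
        ggplot2::coord_fixed() + ggplot2::theme_minimal()
      save_figure(p, path)
      list(plot = p, data = df, path = path)
    },
    tree = {
      df <- lineage_layout(data)
      segs <- df$segments
      p <- ggplot2::ggplot() +
        ggplot2::geom_segment(data = segs,
                              ggplot2::aes(x = x, y = y, xend = xend, yend = yend)) +
        ggplot2::geom_text(data = df$nodes, ggplot2::aes(x, y, label = label),
                           hjust = -0.2, size = 3) +
        ggplot2::labs(x = "time (s)", y = NULL) + ggplot2::theme_minimal()
      save_figure(p, path)
      list(plot = p, data = df$nodes, path = path)
    },
    histogram = {
      df <- tibble::tibble(value = data$values)
      p <- ggplot2::ggplot(df, ggplot2::aes(value)) +
        ggplot2::geom_histogram(bins = data$bins %||% 30L)
      save_figure(p, path)
      list(plot = p, data = df, path = path)
    },
    movie_strip = {
      tm <- data$track_meshes
      frames <- if (inherits(data$stack, "image_stack")) data$stack$frames else data$stack
      panels <- lapply(seq_len(nrow(tm)), function(i) {
        img <- frames[[tm$frame_id[i] + 1L]]
        tibble::tibble(panel = i, frame_id = tm$frame_id[i],
                       x = rep(seq_len(ncol(img)) - 1L, each = nrow(img)),
                       y = rep(seq_len(nrow(img)) - 1L, times = ncol(img)),
                       intensity = as.vector(img))
      })
      df <- dplyr::bind_rows(panels)
      p <- ggplot2::ggplot(df, ggplot2::aes(x, y, fill = intensity)) +
        ggplot2::geom_raster() + ggplot2::scale_fill_viridis_c() +
        ggplot2::facet_wrap(~panel, nrow = 1) + ggplot2::scale_y_reverse() +
        ggplot2::coord_fixed() + ggplot2::theme_void()
      save_figure(p, path, width = 2 * nrow(tm), height = 2.5)
      list(plot = p, data = df, path = path,
           panel_manifest = tibble::tibble(panel = seq_len(nrow(tm)),
                                           frame_id = tm$frame_id))
    },
    cluster_summary = {
      df <- data$summary
      if (is.null(df)) cm_stop("spec_error", "cluster result lacks profile summaries")
      p <- ggplot2::ggplot(df, ggplot2::aes(grid, mean)) +
        ggplot2::geom_ribbon(ggplot2::aes(ymin = mean - sd, ymax = mean + sd),
                             fill = "pink", alpha = 0.6) +
        ggplot2::geom_line(color = "deeppink3") +
        ggplot2::facet_wrap(~cluster, ncol = 1) +
        ggplot2::labs(x = "% of division", y = "mean fluorescence (a.u.)")
      save_figure(p, path)
      list(plot = p, data = df, path = path)
    }
  )
}

# Simple rectangular lineage layout: x = cumulative time, y = leaf order.
lineage_layout <- function(lineage) {
  children <- split(lineage$track_id,
                    factor(lineage$parent_id, levels = lineage$track_id))
  dur <- stats::setNames(lineage$duration, lineage$track_id)
  nodes <- list(); segs <- list()
  leaf_y <- 0
  place <- function(id, x0) {
    ch <- children[[id]]
    x1 <- x0 + dur[[id]]
    if (is.null(ch) || !length(ch)) {
      leaf_y <<- leaf_y + 1
      y <- leaf_y
    } else {
      ys <- vapply(sort(ch), place, numeric(1), x0 = x1)
      y <- mean(ys)
      for (cy in ys) segs[[length(segs) + 1L]] <<-
        tibble::tibble(x = x1, y = y, xend = x1, yend = cy)
    }
    nodes[[length(nodes) + 1L]] <<- tibble::tibble(label = id, x = x1, y = y)
    segs[[length(segs) + 1L]] <<- tibble::tibble(x = x0, y = y, xend = x1, yend = y)
    y
  }
  for (r in attr(lineage, "roots")) place(r, 0)
  list(nodes = dplyr::bind_rows(nodes), segments = dplyr::bind_rows(segs))
}
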