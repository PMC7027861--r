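# The standard data model every importer feeds and every analysis consumes.
#
# A dataset is a plain list (class "cellmap_dataset") of tibbles:
#   meshframe      one row per cell per frame: outline, box fit, rotated outline
#   spotframe      detected fluorescent foci in image coordinates
#   spots_relative foci in cell-relative coordinates, joined to their host cell
#   objectframe    fluorescent-object outlines, optionally cell-relative
#   tracks         per-cell time series (time, length, width, fluorescence, parent)
#   images         manifest of image stacks (paths + metadata), never pixels
#   cell_list      untouched copies of the original inputs, keyed by source
#
# Pixel convention everywhere: 0-based indices, pixel centers at integer
# coordinates, y down. Importers convert 1-based sources by subtracting 1.

#' Build a meshframe from raw cell outlines
#'
#' Validates each outline (at least three vertices, simple polygon,
#' strictly positive area), normalizes vertex order to counterclockwise,
#' then computes the minimum-area bounding box and the outline rotated
#' onto its length axis with midpoint at (0, 0).
#'
#' @param meshes tibble with columns `cell_id`, `frame_id`, `source` and a
#'   `mesh` list-column of two-column vertex matrices (or data frames).
#' @return the input with list-columns `fit` (box_fit) and `rotated`, and
#'   scalar columns `length`, `width`, `angle`, `center_x`, `center_y`.
#' @export
mesh_frame <- function(meshes) {
  meshes <- tibble::as_tibble(meshes)
  if (!"source" %in% names(meshes)) meshes$source <- "unknown"
  if (anyDuplicated(meshes[c("cell_id", "frame_id")]) > 0L) {
    d <- meshes[duplicated(meshes[c("cell_id", "frame_id")]), ]
    cm_stop("duplicate_cell",
            sprintf("duplicate (cell_id, frame_id): %s @ %s",
                    d$cell_id[1], d$frame_id[1]))
  }
  n <- nrow(meshes)
  fit <- vector("list", n); rotated <- vector("list", n)
  mesh <- vector("list", n)
  for (i in seq_len(n)) {
    v <- as_vertex_matrix(meshes$mesh[[i]])
    if (nrow(v) < 3L)
      cm_stop("degenerate_geometry",
              sprintf("cell %s: fewer than 3 vertices", meshes$cell_id[i]))
    if (polygon_area(v) <= 0 || !is_simple_polygon(v))
      cm_stop("degenerate_geometry",
              sprintf("cell %s: outline is not a simple positive-area polygon",
                      meshes$cell_id[i]))
    v <- ensure_ccw(v)
    f <- min_bounding_box(v)
    mesh[[i]] <- v
    fit[[i]] <- f
    rotated[[i]] <- orient_mesh(v, f)
  }
  meshes$mesh <- mesh
  meshes$fit <- fit
  meshes$rotated <- rotated
  meshes$length <- vapply(fit, `[[`, numeric(1), "length")
  meshes$width <- vapply(fit, `[[`, numeric(1), "width")
  meshes$angle <- vapply(fit, `[[`, numeric(1), "angle")
  meshes$center_x <- vapply(fit, function(f) f$center[1], numeric(1))
  meshes$center_y <- vapply(fit, function(f) f$center[2], numeric(1))
  meshes
}

empty_spotframe <- function() {
  tibble::tibble(spot_id = character(), frame_id = integer(),
                 channel = character(), x = double(), y = double(),
                 intensity = double(), time = double())
}

empty_spots_relative <- function() {
  tibble::tibble(spot_id = character(), cell_id = character(),
                 frame_id = integer(), channel = character(),
                 l = double(), d = double(),
                 l_rel = double(), d_rel = double(), ambiguous = logical())
}

empty_tracks <- function() {
  tibble::tibble(track_id = character(), frame_id = integer(), time = double(),
                 length = double(), width = double(), fluor = double(),
                 parent_id = character())
}

#' Assemble a standard dataset from imported frames
#'
#' Computes the meshframe, assigns spots to cells, relativizes spots and
#' objects, and stores the original input records untouched in
#' `cell_list`. Spot counts are conserved: every input spot appears either
#' in `spots_relative` or in the unassigned remainder
#' (`attr(ds$spots_relative, "n_unassigned")`).
#'
#' @param meshes raw mesh tibble (see [mesh_frame()]).
#' @param spots optional spot tibble (`spot_id`, `frame_id`, `x`, `y`,
#'   optional `channel`, `intensity`, `time`).
#' @param objects optional object tibble (`object_id`, `frame_id`,
#'   `vertices` list-column).
#' @param tracks optional track tibble.
#' @param images optional image manifest tibble (`path`, `channel`,
#'   `pixel_size`, `time_interval`).
#' @param cell_list optional named list of original input tibbles keyed by
#'   source; defaults to the inputs as given.
#' @return a `cellmap_dataset`.
#' @export
build_dataset <- function(meshes, spots = NULL, objects = NULL, tracks = NULL,
                          images = NULL, cell_list = NULL) {
  mf <- mesh_frame(meshes)
  if (is.null(cell_list)) {
    cell_list <- list()
    cell_list[[unique(c(mf$source, "mesh"))[1]]] <-
      tibble::as_tibble(meshes)[intersect(names(meshes), c("cell_id", "frame_id", "source", "mesh"))]
    if (!is.null(spots)) cell_list[["spots"]] <- tibble::as_tibble(spots)
    if (!is.null(objects)) cell_list[["objects"]] <- tibble::as_tibble(objects)
    if (!is.null(tracks)) cell_list[["tracks"]] <- tibble::as_tibble(tracks)
  }
  if (is.null(spots) || nrow(spots) == 0L) {
    spotframe <- empty_spotframe()
    spots_relative <- empty_spots_relative()
    attr(spots_relative, "n_unassigned") <- 0L
  } else {
    spotframe <- tibble::as_tibble(spots)
    if (!"spot_id" %in% names(spotframe))
      spotframe$spot_id <- sprintf("spot_%06d", seq_len(nrow(spotframe)))
    if (!"channel" %in% names(spotframe)) spotframe$channel <- "default"
    stopifnot(all(is.finite(spotframe$x)), all(is.finite(spotframe$y)),
              all(spotframe$frame_id >= 0L))
    asg <- assign_spots(spotframe, mf)
    keep <- !is.na(asg$cell_id)
    rel_rows <- vector("list", sum(keep))
    ki <- which(keep)
    if (length(ki)) {
      key <- paste(mf$cell_id, mf$frame_id, sep = "\r")
      lookup <- match(paste(asg$cell_id[ki], asg$frame_id[ki], sep = "\r"), key)
      rel <- do.call(rbind, lapply(seq_along(ki), function(s) {
        fit <- mf$fit[[lookup[s]]]
        as.data.frame(spot_relative(asg$x[ki[s]], asg$y[ki[s]], fit))
      }))
      spots_relative <- tibble::tibble(
        spot_id = asg$spot_id[ki], cell_id = asg$cell_id[ki],
        frame_id = asg$frame_id[ki], channel = asg$channel[ki],
        l = rel$l, d = rel$d, l_rel = rel$l_rel, d_rel = rel$d_rel,
        ambiguous = asg$ambiguous[ki]
      )
    } else {
      spots_relative <- empty_spots_relative()
    }
    attr(spots_relative, "n_unassigned") <- sum(!keep)
  }
  if (is.null(objects) || nrow(objects) == 0L) {
    objectframe <- tibble::tibble(object_id = character(), frame_id = integer(),
                                  vertices = list(), cell_id = character(),
                                  ambiguous = logical(), vertices_rel = list())
  } else {
    objectframe <- relativize_objects(tibble::as_tibble(objects), mf)
  }
  if (is.null(tracks)) tracks <- empty_tracks()
  if (is.null(images)) {
    images <- tibble::tibble(path = character(), channel = character(),
                             pixel_size = double(), time_interval = double())
  }
  ds <- structure(list(
    meshframe = mf,
    spotframe = spotframe,
    spots_relative = spots_relative,
    objectframe = objectframe,
    tracks = tibble::as_tibble(tracks),
    images = tibble::as_tibble(images),
    cell_list = cell_list,
    convention = "pixels-0-based-center-integer-y-down"
  ), class = "cellmap_dataset")
  validate_dataset(ds)
  ds
}

validate_dataset <- function(ds) {
  known <- unique(c(ds$meshframe$cell_id, ds$tracks$track_id))
  ref <- unique(stats::na.omit(ds$spots_relative$cell_id))
  bad <- setdiff(ref, known)
  if (length(bad))
    cm_stop("corrupt_dataset", sprintf("unknown cell_id referenced: %s", bad[1]))
  invisible(ds)
}

#' @export
print.cellmap_dataset <- function(x, ...) {
  cat("<cellmap_dataset>\n")
  cat(sprintf("  meshframe:       %d cells\n", nrow(x$meshframe)))
  cat(sprintf("  spotframe:       %d spots (%d unassigned)\n", nrow(x$spotframe),
              attr(x$spots_relative, "n_unassigned") %||% 0L))
  cat(sprintf("  spots_relative:  %d rows\n", nrow(x$spots_relative)))
  cat(sprintf("  objectframe:     %d objects\n", nrow(x$objectframe)))
  cat(sprintf("  tracks:          %d rows, %d tracks\n", nrow(x$tracks),
              length(unique(x$tracks$track_id))))
  cat(sprintf("  cell_list:       %s\n", paste(names(x$cell_list), collapse = ", ")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- persistence -------------------------------------------------------

# Long-format serialization of a list-column of vertex matrices.
vertices_to_long <- function(ids, frame_ids, vlist, extra = NULL) {
  if (length(vlist) == 0L) {
    return(tibble::tibble(id = character(), frame_id = integer(),
                          vertex = integer(), x = double(), y = double()))
  }
  n <- vapply(vlist, nrow, integer(1))
  out <- tibble::tibble(
    id = rep(ids, n),
    frame_id = rep(frame_ids, n),
    vertex = unlist(lapply(n, seq_len)),
    x = unlist(lapply(vlist, function(v) v[, 1L])),
    y = unlist(lapply(vlist, function(v) v[, 2L]))
  )
  out
}

long_to_vertices <- function(df) {
  sp <- split(df[c("x", "y")], paste(df$id, df$frame_id, sep = "\r"))
  keys <- unique(paste(df$id, df$frame_id, sep = "\r"))
  lapply(keys, function(k) as_vertex_matrix(sp[[k]]))
}

#' Save / load a dataset as delimited tables with a checksummed manifest
#'
#' Every table is written as an RFC-4180 CSV (UTF-8, header row); the
#' manifest is plain `key: value` text listing each file with its MD5
#' checksum plus the pixel-coordinate convention. Doubles are written with
#' shortest round-trip precision, so `load_dataset(save_dataset(ds))`
#' reproduces all numeric fields exactly.
#'
#' @param ds a `cellmap_dataset`.
#' @param directory output directory (created if absent).
#' @return `save_dataset`: the manifest path, invisibly.
#'   `load_dataset`: the reconstructed dataset.
#' @export
save_dataset <- function(ds, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  wr <- function(df, name) {
    p <- file.path(directory, name)
    readr::write_csv(df, p, progress = FALSE)
    files[[name]] <<- name
    p
  }
  cells <- ds$meshframe[setdiff(names(ds$meshframe), c("mesh", "fit", "rotated"))]
  wr(cells, "cells.csv")
  wr(vertices_to_long(ds$meshframe$cell_id, ds$meshframe$frame_id, ds$meshframe$mesh),
     "mesh_vertices.csv")
  wr(vertices_to_long(ds$meshframe$cell_id, ds$meshframe$frame_id, ds$meshframe$rotated),
     "mesh_vertices_rotated.csv")
  wr(ds$spotframe, "spots.csv")
  sr <- ds$spots_relative
  wr(sr, "spots_relative.csv")
  obj <- ds$objectframe
  wr(obj[setdiff(names(obj), c("vertices", "vertices_rel"))], "objects.csv")
  if (nrow(obj)) {
    wr(vertices_to_long(obj$object_id, obj$frame_id, obj$vertices), "object_vertices.csv")
  } else {
    wr(tibble::tibble(id = character(), frame_id = integer(), vertex = integer(),
                      x = double(), y = double()), "object_vertices.csv")
  }
  wr(ds$tracks, "tracks.csv")
  wr(ds$images, "images.csv")
  for (src in names(ds$cell_list)) {
    cl <- ds$cell_list[[src]]
    if (!is.data.frame(cl)) next
    flat <- cl[!vapply(cl, is.list, logical(1))]
    wr(tibble::as_tibble(flat), sprintf("cell_list_%s.csv", src))
  }
  manifest <- file.path(directory, "manifest.txt")
  lines <- c(
    "format: cellmapr-dataset-v1",
    paste0("convention: ", ds$convention),
    paste0("n_unassigned_spots: ", attr(ds$spots_relative, "n_unassigned") %||% 0L),
    vapply(names(files), function(f) {
      sprintf("file: %s md5:%s", f, unname(tools::md5sum(file.path(directory, f))))
    }, character(1))
  )
  writeLines(lines, manifest)
  invisible(manifest)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(directory) {
  manifest <- file.path(directory, "manifest.txt")
  if (!file.exists(manifest)) cm_stop("corrupt_dataset", "manifest.txt missing")
  lines <- readLines(manifest)
  conv <- sub("^convention: ", "", grep("^convention: ", lines, value = TRUE))
  fl <- grep("^file: ", lines, value = TRUE)
  fnames <- sub("^file: (\\S+) md5:.*$", "\\1", fl)
  sums <- sub("^file: \\S+ md5:(\\S+)$", "\\1", fl)
  for (i in seq_along(fnames)) {
    p <- file.path(directory, fnames[i])
    if (!file.exists(p))
      cm_stop("corrupt_dataset", sprintf("missing table file: %s", fnames[i]))
    if (!identical(unname(tools::md5sum(p)), sums[i]))
      cm_stop("corrupt_dataset", sprintf("checksum mismatch: %s", fnames[i]))
  }
  rd <- function(name, types = NULL) {
    readr::read_csv(file.path(directory, name), show_col_types = FALSE,
                    progress = FALSE, col_types = types)
  }
  cells <- rd("cells.csv", readr::cols(cell_id = readr::col_character(),
                                       frame_id = readr::col_integer()))
  mv <- rd("mesh_vertices.csv", readr::cols(id = readr::col_character()))
  if (nrow(cells)) {
    key <- paste(cells$cell_id, cells$frame_id, sep = "\r")
    sp <- split(mv[c("x", "y")], factor(paste(mv$id, mv$frame_id, sep = "\r"), levels = key))
    meshes <- tibble::tibble(cell_id = cells$cell_id, frame_id = cells$frame_id,
                             source = cells$source, mesh = lapply(sp, as_vertex_matrix))
  } else {
    meshes <- tibble::tibble(cell_id = character(), frame_id = integer(),
                             source = character(), mesh = list())
  }
  spots <- rd("spots.csv", readr::cols(spot_id = readr::col_character(),
                                       frame_id = readr::col_integer(),
                                       channel = readr::col_character()))
  tracks <- rd("tracks.csv", readr::cols(track_id = readr::col_character(),
                                         frame_id = readr::col_integer(),
                                         parent_id = readr::col_character()))
  images <- rd("images.csv", readr::cols(path = readr::col_character(),
                                         channel = readr::col_character()))
  objs <- rd("objects.csv", readr::cols(object_id = readr::col_character(),
                                        frame_id = readr::col_integer()))
  ov <- rd("object_vertices.csv", readr::cols(id = readr::col_character()))
  objects <- NULL
  if (nrow(objs)) {
    key <- paste(objs$object_id, objs$frame_id, sep = "\r")
    sp <- split(ov[c("x", "y")], factor(paste(ov$id, ov$frame_id, sep = "\r"), levels = key))
    objects <- tibble::tibble(object_id = objs$object_id, frame_id = objs$frame_id,
                              vertices = lapply(sp, as_vertex_matrix))
  }
  cl_files <- fnames[startsWith(fnames, "cell_list_")]
  cell_list <- lapply(cl_files, function(f) rd(f))
  names(cell_list) <- sub("^cell_list_(.*)\\.csv$", "\\1", cl_files)
  ds <- build_dataset(
    meshes,
    spots = if (nrow(spots)) spots else NULL,
    objects = objects,
    tracks = if (nrow(tracks)) tracks else NULL,
    images = if (nrow(images)) images else NULL,
    cell_list = cell_list
  )
  ds$convention <- conv
  ds
}

## ---- image stacks ------------------------------------------------------

#' Read and write image stacks as TIFF
#'
#' An image stack is a list of identically sized numeric matrices (one per
#' frame) with channel and optional pixel-size / time-interval metadata.
#' TIFF storage uses 32-bit float samples, so intensities round-trip
#' within single precision.
#'
#' @param path TIFF file (single- or multi-page).
#' @param channel channel label stored alongside the pixels.
#' @param pixel_size micrometers per pixel (optional metadata).
#' @param time_interval seconds between frames (optional metadata).
#' @return `read_image_stack`: a list with `frames`, `channel`,
#'   `pixel_size`, `time_interval`.
#' @export
read_image_stack <- function(path, channel = "default", pixel_size = NA_real_,
                             time_interval = NA_real_) {
  if (!file.exists(path)) cm_stop("io_error", sprintf("no such image: %s", path))
  frames <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 3L) f <- f[, , 1L]
    f
  })
  dims <- vapply(frames, function(f) paste(dim(f), collapse = "x"), character(1))
  if (length(unique(dims)) != 1L)
    cm_stop("corrupt_dataset", "image stack frames differ in size")
  structure(list(frames = frames, channel = channel, pixel_size = pixel_size,
                 time_interval = time_interval), class = "image_stack")
}

#' @rdname read_image_stack
#' @param stack an `image_stack` (or bare list of matrices).
#' @export
write_image_stack <- function(stack, path) {
  frames <- if (inherits(stack, "image_stack")) stack$frames else stack
  scale <- max(1, max(vapply(frames, max, numeric(1))))
  tiff::writeTIFF(lapply(frames, function(f) f / scale), path,
                  bits.per.sample = 32L)
  # store the scale so readers can recover raw intensities
  writeLines(readr::format_csv(tibble::tibble(scale = scale)),
             paste0(path, ".scale"))
  invisible(path)
}

#' @rdname read_image_stack
#' @export
read_image_stack_scaled <- function(path, ...) {
  st <- read_image_stack(path, ...)
  sc_path <- paste0(path, ".scale")
  if (file.exists(sc_path)) {
    sc <- readr::read_csv(sc_path, show_col_types = FALSE, progress = FALSE)$scale[1]
    st$frames <- lapply(st$frames, function(f) f * sc)
  }
  st
}
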