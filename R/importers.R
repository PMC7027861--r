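# Importers: one generic delimited-table path driven by column mappings,
# plus bespoke parsers for the two structured dialects (Oufti-style MAT
# cell lists, iSBatch-style spot tables). MicrobeJ, SuperSegger,
# Morphometrics and ObjectJ exports are supported through shipped
# column-mapping presets applied to their delimited tables; their native
# binary session formats are out of scope.

#' Column mappings for generic table import
#'
#' A column mapping names, for each standard field, the column that holds
#' it in a source table, plus the source's coordinate base (0 or 1;
#' 1-based sources are shifted by -1 on import). Presets ship as
#' plain-text `key = value` files under
#' `system.file("presets", package = "cellmapr")`.
#'
#' @param preset one of `"generic"`, `"microbej"`, `"supersegger"`,
#'   `"morphometrics"`, `"objectj"`, or NULL to build a custom mapping.
#' @param ... named overrides `standard_field = "source column"`.
#' @param base coordinate base of the source (0 or 1); overrides the
#'   preset's.
#' @return a `column_mapping`: list with `name`, `base` and `map`.
#' @export
column_mapping <- function(preset = "generic", ..., base = NULL) {
  if (!is.null(preset)) {
    path <- system.file("presets", paste0(preset, ".conf"), package = "cellmapr")
    if (!nzchar(path))
      cm_stop("schema_error", sprintf("unknown column-mapping preset: %s", preset))
    kv <- read_kv(path)
    map <- kv[setdiff(names(kv), c("preset", "base"))]
    out <- list(name = kv[["preset"]], base = as.integer(kv[["base"]]), map = map)
  } else {
    out <- list(name = "custom", base = 0L, map = list())
  }
  dots <- list(...)
  for (nm in names(dots)) out$map[[nm]] <- dots[[nm]]
  if (!is.null(base)) out$base <- as.integer(base)
  structure(out, class = "column_mapping")
}

read_kv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  stats::setNames(lapply(kv, function(p) trimws(p[2])), trimws(vapply(kv, `[`, "", 1)))
}

required_fields <- list(
  spot = c("frame_id", "x", "y"),
  mesh = c("cell_id", "frame_id", "x", "y"),
  object = c("object_id", "frame_id", "x", "y"),
  track = c("track_id", "frame_id", "length")
)

#' Generic delimited-table import
#'
#' Reads any delimited export whose columns can be described by a
#' [column_mapping()], returning standardized records. Coordinates from
#' 1-based sources are converted to the 0-based pixel convention; no
#' other coordinate is altered. Source columns that are not mapped are
#' preserved untouched (they end up in the dataset's `cell_list`).
#'
#' @param path delimited file (comma-separated, header row).
#' @param mapping a [column_mapping()].
#' @param kind `"mesh"`, `"spot"`, `"object"` or `"track"`.
#' @return for `"spot"`/`"track"`: a tibble of standardized rows plus the
#'   unmapped columns; for `"mesh"`/`"object"`: a tibble with a vertex
#'   list-column (`mesh` / `vertices`). The raw table is attached as
#'   `attr(, "raw")`.
#' @export
import_generic <- function(path, mapping = column_mapping("generic"),
                           kind = c("spot", "mesh", "object", "track")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) cm_stop("io_error", sprintf("no such file: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_guess()))
  req <- required_fields[[kind]]
  for (f in req) {
    col <- mapping$map[[f]]
    if (is.null(col))
      cm_stop("schema_error", sprintf("mapping does not cover required field \"%s\"", f))
    if (!col %in% names(raw))
      cm_stop("schema_error", sprintf("missing mapped column \"%s\" (field %s)", col, f))
  }
  get <- function(f) if (!is.null(mapping$map[[f]]) && mapping$map[[f]] %in% names(raw))
    raw[[mapping$map[[f]]]] else NULL
  num <- function(f, v) {
    if (is.null(v)) return(NULL)
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) & !is.na(v))
    if (length(bad))
      cm_stop("parse_error",
              sprintf("non-numeric value for field %s at row %d: \"%s\"", f, bad[1], v[bad[1]]))
    out
  }
  shift <- as.numeric(mapping$base)
  std <- switch(kind,
    spot = tibble::tibble(
      spot_id = as.character(get("spot_id") %||% sprintf("spot_%06d", seq_len(nrow(raw)))),
      frame_id = as.integer(num("frame_id", get("frame_id"))),
      x = num("x", get("x")) - shift,
      y = num("y", get("y")) - shift
    ),
    mesh = tibble::tibble(
      cell_id = as.character(get("cell_id")),
      frame_id = as.integer(num("frame_id", get("frame_id"))),
      vertex = if (!is.null(get("vertex"))) as.integer(num("vertex", get("vertex"))) else NA_integer_,
      x = num("x", get("x")) - shift,
      y = num("y", get("y")) - shift
    ),
    object = tibble::tibble(
      object_id = as.character(get("object_id")),
      frame_id = as.integer(num("frame_id", get("frame_id"))),
      x = num("x", get("x")) - shift,
      y = num("y", get("y")) - shift
    ),
    track = tibble::tibble(
      track_id = as.character(get("track_id")),
      frame_id = as.integer(num("frame_id", get("frame_id"))),
      time = num("time", get("time")) %||% rep(NA_real_, nrow(raw)),
      length = num("length", get("length")),
      width = num("width", get("width")) %||% rep(NA_real_, nrow(raw)),
      fluor = num("fluor", get("fluor")) %||% rep(NA_real_, nrow(raw)),
      parent_id = as.character(get("parent_id") %||% rep(NA_character_, nrow(raw)))
    )
  )
  for (f in c("channel", "intensity", "time", "track_id")) {
    if (kind == "spot" && !is.null(get(f)) && !f %in% names(std)) std[[f]] <- get(f)
  }
  mapped_cols <- unlist(mapping$map[names(mapping$map) %in% names(raw)], use.names = FALSE)
  extra <- raw[setdiff(names(raw), unlist(mapping$map, use.names = FALSE))]
  for (nm in names(extra)) if (!nm %in% names(std)) std[[nm]] <- extra[[nm]]
  if (kind %in% c("mesh", "object")) {
    idcol <- if (kind == "mesh") "cell_id" else "object_id"
    std <- std[order(std$frame_id, std[[idcol]],
                     if (all(is.na(std$vertex %||% NA))) seq_len(nrow(std)) else std$vertex), ]
    key <- paste(std[[idcol]], std$frame_id, sep = "\r")
    keys <- unique(key)
    sp <- split(std[c("x", "y")], factor(key, levels = keys))
    ids <- std[[idcol]][match(keys, key)]
    frames <- std$frame_id[match(keys, key)]
    out <- tibble::tibble(frame_id = frames)
    out[[idcol]] <- ids
    vcol <- if (kind == "mesh") "mesh" else "vertices"
    out[[vcol]] <- lapply(sp, as_vertex_matrix)
    out$source <- mapping$name
    out <- out[c(idcol, "frame_id", vcol, "source")]
  } else {
    std$source <- mapping$name
    out <- std
  }
  attr(out, "raw") <- raw
  out
}

#' Import an Oufti-style MAT cell list
#'
#' Reads a MAT v5 file whose `cellList` variable is a struct array with,
#' per cell, a `mesh` of paired left/right contour points (N rows of
#' `x_left, y_left, x_right, y_right`). Each mesh is converted to a
#' single simple polygon by concatenating the left contour with the
#' reversed right contour and dropping the duplicated shared end points,
#' giving `2N - 2` vertices. Oufti files are 1-based; coordinates are
#' shifted to the 0-based convention. Genealogy fields (`ancestor`,
#' `birthframe`), when present, are forwarded as a tracks fragment.
#' Cells whose mesh has fewer than 2 rows or whose polygon is degenerate
#' are skipped and counted (`attr(, "n_skipped")`), never repaired.
#'
#' @param path MAT v5 file.
#' @param var name of the cell-list variable (layouts vary between
#'   program versions; default `"cellList"`).
#' @return tibble of meshes (`cell_id`, `frame_id`, `mesh`, `source`)
#'   with attributes `tracks` (tibble or NULL), `n_skipped` and `raw`.
#' @export
import_oufti_mat <- function(path, var = "cellList") {
  vars <- read_mat(path)
  if (!var %in% names(vars))
    cm_stop("schema_error", sprintf("variable \"%s\" absent from MAT file", var))
  cl <- vars[[var]]
  if (!inherits(cl, "mat_struct"))
    cm_stop("schema_error", sprintf("\"%s\" is not a struct array", var))
  rows <- list(); skipped <- 0L; tr <- list()
  for (cell in cl) {
    mesh <- cell$mesh
    if (is.null(mesh) || !is.matrix(mesh) || nrow(mesh) < 2L || ncol(mesh) < 4L) {
      skipped <- skipped + 1L
      cm_log("skipping cell with degenerate mesh")
      next
    }
    nr <- nrow(mesh)
    left <- mesh[, 1:2, drop = FALSE]
    right <- mesh[, 3:4, drop = FALSE]
    poly <- rbind(left, right[rev(seq_len(nr - 2L)) + 1L, , drop = FALSE]) - 1  # to 0-based
    if (polygon_area(poly) <= 0 || !is_simple_polygon(poly)) {
      skipped <- skipped + 1L
      cm_log("skipping cell with non-simple polygon")
      next
    }
    cid <- as.character(cell$cellId %||% (length(rows) + 1L))
    fid <- as.integer(cell$frame %||% 0)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      cell_id = cid, frame_id = fid, mesh = list(poly), source = "oufti")
    if (!is.null(cell$ancestor) || !is.null(cell$birthframe)) {
      tr[[length(tr) + 1L]] <- tibble::tibble(
        track_id = cid,
        parent_id = if (is.null(cell$ancestor) || !length(cell$ancestor) ||
                        as.numeric(cell$ancestor[1]) == 0) NA_character_
                    else as.character(as.numeric(cell$ancestor[1])),
        birth_frame = as.integer(cell$birthframe %||% NA))
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(cell_id = character(), frame_id = integer(),
                   mesh = list(), source = character())
  attr(out, "tracks") <- if (length(tr)) dplyr::bind_rows(tr) else NULL
  attr(out, "n_skipped") <- skipped
  attr(out, "raw") <- cl
  out
}

#' Import an iSBatch-style spot table
#'
#' Delimited table with one detected focus per row; columns `id`, `frame`,
#' `x`, `y` and optionally `intensity` and `trajectory` (the spot-track
#' id, preserved for trajectory plots). Coordinates are 1-based in the
#' source and shifted to 0-based. Duplicated spot ids within a frame are
#' accepted and counted (`attr(, "n_duplicated")`).
#'
#' @param path delimited file.
#' @return spot tibble with `spot_id`, `frame_id`, `x`, `y` and any of
#'   `intensity`, `track_id`, `channel` present in the source.
#' @export
import_isbatch_spots <- function(path) {
  mapping <- column_mapping("isbatch")
  out <- import_generic(path, mapping, kind = "spot")
  if ("trajectory" %in% names(out)) {
    out$track_id <- as.character(out$trajectory)
    out$trajectory <- NULL
  }
  dup <- sum(duplicated(out[c("spot_id", "frame_id")]))
  if (dup > 0L) cm_log("%d duplicated spot ids within a frame", dup)
  attr(out, "n_duplicated") <- dup
  out
}
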