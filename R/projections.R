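# Population-level localization summaries: equal-count length groups,
# 2-D density "cell towers", and length-axis projections ordered by cell
# length.

#' Split cells into equal-count length groups
#'
#' Cells are sorted by (length, cell_id) and split into `n_groups`
#' contiguous blocks whose sizes differ by at most one; when the cell
#' count is not divisible, the remainder is distributed one extra cell to
#' the shortest-length groups. Ties in length are broken by `cell_id`, so
#' the grouping is deterministic across runs.
#'
#' @param lengths numeric cell lengths (pixels).
#' @param n_groups number of groups (default 5).
#' @param cell_id optional ids used for tie-breaking and reporting.
#' @param widths optional widths for the per-group mean width summary.
#' @return tibble with `cell_id`, `length`, `group` plus a `summary`
#'   attribute (per-group size, mean length, mean width).
#' @export
length_groups <- function(lengths, n_groups = 5L, cell_id = NULL, widths = NULL) {
  n <- length(lengths)
  if (n_groups < 1L || n_groups > n)
    cm_stop("grouping_error",
            sprintf("n_groups (%d) must be between 1 and the cell count (%d)", n_groups, n))
  if (is.null(cell_id)) cell_id <- sprintf("cell_%06d", seq_len(n))
  ord <- order(lengths, cell_id)
  base <- n %/% n_groups
  r <- n %% n_groups
  sizes <- rep(base, n_groups) + c(rep(1L, r), rep(0L, n_groups - r))
  group_sorted <- rep(seq_len(n_groups), sizes)
  group <- integer(n)
  group[ord] <- group_sorted
  out <- tibble::tibble(cell_id = cell_id, length = lengths, group = group)
  if (is.null(widths)) widths <- rep(NA_real_, n)
  smry <- dplyr::summarise(
    dplyr::group_by(dplyr::mutate(out, width = widths), group),
    n = dplyr::n(), mean_length = mean(length), mean_width = mean(width),
    .groups = "drop")
  attr(out, "summary") <- smry
  out
}

#' 2-D localization density per length group
#'
#' Pools the cell-relative spot coordinates of each length group onto one
#' grid per group — the "cell tower" heatmap. Histogram mode counts spots
#' per bin and conserves the total; kernel mode evaluates a product
#' Gaussian kernel density (bandwidth from the grid spec) at bin centers,
#' scaled so the midpoint-rule integral over the grid is ~1.
#'
#' @param spots_relative tibble with `cell_id` and the coordinate columns
#'   named by `coords`.
#' @param grouping a [length_groups()] result (matched on `cell_id`);
#'   NULL pools everything into one group.
#' @param grid list with `nx`, `ny`, `xlim`, `ylim`, `bandwidth`.
#'   Defaults to 25 x 25 bins over \[-0.6, 0.6\]^2 of relative
#'   coordinates, which admits spots marginally outside the box.
#' @param mode `"histogram"` (default) or `"kernel"`.
#' @param coords names of the coordinate columns (default `l_rel`,
#'   `d_rel`; use `l`, `d` for absolute pixels with a wider `grid`).
#' @return tibble with one row per (group, bin): `group`, `xbin`, `ybin`,
#'   bin centers `x`, `y`, and `value`. Bin edges are attached as
#'   attributes `xedges`, `yedges`.
#' @export
density_projection <- function(spots_relative, grouping = NULL,
                               grid = list(nx = 25L, ny = 25L,
                                           xlim = c(-0.6, 0.6), ylim = c(-0.6, 0.6),
                                           bandwidth = 0.05),
                               mode = c("histogram", "kernel"),
                               coords = c("l_rel", "d_rel")) {
  mode <- match.arg(mode)
  sp <- tibble::as_tibble(spots_relative)
  if (is.null(grouping)) {
    sp$group <- 1L
  } else {
    sp$group <- grouping$group[match(sp$cell_id, grouping$cell_id)]
  }
  xe <- seq(grid$xlim[1], grid$xlim[2], length.out = grid$nx + 1L)
  ye <- seq(grid$ylim[1], grid$ylim[2], length.out = grid$ny + 1L)
  xc <- (xe[-1] + xe[-length(xe)]) / 2
  yc <- (ye[-1] + ye[-length(ye)]) / 2
  groups <- sort(unique(stats::na.omit(sp$group)))
  out <- list()
  for (g in groups) {
    gx <- sp[[coords[1]]][sp$group == g & !is.na(sp$group)]
    gy <- sp[[coords[2]]][sp$group == g & !is.na(sp$group)]
    if (length(gx) == 0L) {
      cm_log("length group %s has no spots; empty grid", g)
      val <- matrix(0, grid$nx, grid$ny)
    } else if (mode == "histogram") {
      ix <- findInterval(gx, xe, rightmost.closed = TRUE)
      iy <- findInterval(gy, ye, rightmost.closed = TRUE)
      ok <- ix >= 1L & ix <= grid$nx & iy >= 1L & iy <= grid$ny
      val <- matrix(0, grid$nx, grid$ny)
      if (any(ok)) {
        tab <- table(factor(ix[ok], levels = seq_len(grid$nx)),
                     factor(iy[ok], levels = seq_len(grid$ny)))
        val <- val + unclass(tab)
      }
    } else {
      h <- grid$bandwidth
      val <- matrix(0, grid$nx, grid$ny)
      for (k in seq_along(gx)) {
        val <- val + outer(stats::dnorm(xc, gx[k], h), stats::dnorm(yc, gy[k], h))
      }
      val <- val / length(gx)
    }
    out[[length(out) + 1L]] <- tibble::tibble(
      group = g,
      xbin = rep(seq_len(grid$nx), times = grid$ny),
      ybin = rep(seq_len(grid$ny), each = grid$nx),
      x = rep(xc, times = grid$ny),
      y = rep(yc, each = grid$nx),
      value = as.vector(val)
    )
  }
  res <- dplyr::bind_rows(out)
  attr(res, "xedges") <- xe
  attr(res, "yedges") <- ye
  attr(res, "mode") <- mode
  res
}

#' Length-axis projection ordered by cell length
#'
#' Every cell is ranked by ascending length (ties by `cell_id`), and each
#' spot is emitted as (cell rank, position on the length axis), together
#' with the cell's half-length envelope for drawing the cell outline
#' band. The output is invariant to the input row order.
#'
#' @param spots_relative tibble with `cell_id` and the column named by
#'   `coord`.
#' @param cell_lengths tibble with `cell_id`, `length`.
#' @param coord spot coordinate to project (default `"l"`, pixels; use
#'   `"l_rel"` for normalized positions).
#' @return tibble with `cell_id`, `rank`, `length`, `envelope_lo`,
#'   `envelope_hi` and the projected spot coordinate (NA for spotless
#'   cells, which still occupy a rank).
#' @export
length_axis_projection <- function(spots_relative, cell_lengths, coord = "l") {
  cl <- tibble::as_tibble(cell_lengths)
  cl <- cl[order(cl$length, cl$cell_id), ]
  cl$rank <- seq_len(nrow(cl))
  sp <- tibble::as_tibble(spots_relative)
  sp <- sp[order(sp$cell_id, sp$spot_id %||% seq_len(nrow(sp)), sp[[coord]]), ]
  joined <- dplyr::left_join(
    cl[c("cell_id", "rank", "length")],
    sp[c("cell_id", coord)],
    by = "cell_id")
  joined$envelope_lo <- -joined$length / 2
  joined$envelope_hi <- joined$length / 2
  joined[order(joined$rank, joined[[coord]]), ]
}
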