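# Time-lapse analytics: division detection from length trajectories,
# percentage-of-division alignment, track quality filtering, binning by
# percent of division, and lineage trees with Newick export.
#
# A track is the time series of one cell line: columns `track_id`,
# `frame_id`, `time` (seconds), `length`, `width`, `fluor` (mean cellular
# fluorescence) and optional `parent_id`. Times must be strictly
# increasing within a track and lengths positive.

check_track <- function(track) {
  stopifnot(all(diff(track$time) > 0), all(track$length > 0))
  invisible(track)
}

#' Detect divisions from a length trajectory
#'
#' Cell length is used as a proxy for division when the upstream
#' segmentation software has not provided genealogy: a division is called
#' between consecutive observations t and t+1 when
#' `length(t+1) <= (1 - drop_fraction) * length(t)`. A true division
#' halves the length, so the default drop of 25% tolerates observation
#' noise while excluding ordinary growth fluctuation. Explicit genealogy
#' supplied by an importer takes precedence over length-based calls.
#'
#' @param track one track tibble (>= 2 frames), ordered by time.
#' @param drop_fraction relative length drop that calls a division
#'   (default 0.25).
#' @param genealogy optional integer vector of division frame indices
#'   supplied by the segmentation software; returned as-is when present.
#' @return 0-based indices `i` such that the division happened between
#'   frames `i` and `i + 1`.
#' @export
detect_divisions <- function(track, drop_fraction = 0.25, genealogy = NULL) {
  if (!is.null(genealogy)) return(as.integer(genealogy))
  check_track(track)
  len <- track$length
  which(len[-1] <= (1 - drop_fraction) * len[-length(len)]) - 1L
}

#' Percentage-of-division per frame
#'
#' Assigns each observation its progress through the cell cycle:
#' 0% at the birth frame, 100% at the division frame, interpolated
#' linearly in wall-clock time (not frame index) in between, which honors
#' uneven sampling intervals. Cycle boundaries are the detected division
#' frames; the track's first frame counts as a birth only when
#' `birth_at_start` is TRUE (the synthetic generator starts tracks at
#' birth; real movies usually start mid-cycle). Frames outside complete
#' cycles are marked incomplete and get NA.
#'
#' @param track one track tibble ordered by time.
#' @param divisions division indices from [detect_divisions()] (0-based,
#'   division between `i` and `i + 1`).
#' @param birth_at_start does the track start at a birth?
#' @return `track` with columns `percent` (0-100 or NA), `cycle` (integer
#'   id within track, NA outside complete cycles) and `complete`.
#' @export
percent_division <- function(track, divisions, birth_at_start = FALSE) {
  check_track(track)
  n <- nrow(track)
  div <- sort(as.integer(divisions))
  # birth frames: frame after each division; optionally frame 0
  births <- div + 1L
  if (birth_at_start) births <- c(0L, births)
  percent <- rep(NA_real_, n)
  cycle <- rep(NA_integer_, n)
  cyc <- 0L
  for (b in births) {
    d <- div[div >= b]               # next division at or after this birth
    if (!length(d)) next             # cycle never completes
    d <- d[1]
    cyc <- cyc + 1L
    idx <- (b:d) + 1L                # rows of this cycle (birth..division)
    t0 <- track$time[b + 1L]; t1 <- track$time[d + 1L]
    percent[idx] <- if (t1 > t0) 100 * (track$time[idx] - t0) / (t1 - t0) else 0
    cycle[idx] <- cyc
  }
  dplyr::mutate(track, percent = percent, cycle = cycle,
                complete = !is.na(cycle))
}

#' Annotate every track of a cohort
#'
#' Runs [detect_divisions()] and [percent_division()] per track.
#'
#' @param tracks tibble of all tracks.
#' @inheritParams detect_divisions
#' @inheritParams percent_division
#' @return annotated tracks; division indices per track in
#'   `attr(, "divisions")`.
#' @export
annotate_tracks <- function(tracks, drop_fraction = 0.25, birth_at_start = FALSE) {
  parts <- split(tracks, tracks$track_id)
  divs <- lapply(parts, detect_divisions, drop_fraction = drop_fraction)
  out <- dplyr::bind_rows(lapply(names(parts), function(id) {
    percent_division(parts[[id]], divs[[id]], birth_at_start = birth_at_start)
  }))
  attr(out, "divisions") <- divs
  out
}

#' Filter tracks by growth, fluorescence and cycle completeness
#'
#' Discards tracks that (in order of evaluation) show no growth
#' (max length / birth length within the observed cycle below
#' `min_growth_ratio`), have mean fluorescence below `min_fluor`, or
#' never complete a cell cycle. Each discarded track gets a reason;
#' reasons are counted in `attr(, "discarded")`.
#'
#' @param tracks annotated tracks ([annotate_tracks()]).
#' @param min_growth_ratio minimum max/birth length ratio (default 1.2).
#' @param min_fluor minimum mean fluorescence (default -Inf: keep all).
#' @param require_complete discard tracks without a complete cycle.
#' @return kept tracks; `attr(, "discarded")` is a tibble of
#'   (track_id, reason), `attr(, "discard_fraction")` the discarded share.
#' @export
filter_tracks <- function(tracks, min_growth_ratio = 1.2, min_fluor = -Inf,
                          require_complete = TRUE) {
  parts <- split(tracks, tracks$track_id)
  reason <- vapply(parts, function(tr) {
    ratio <- if (any(tr$complete)) {
      cyc1 <- tr[!is.na(tr$cycle) & tr$cycle == min(tr$cycle, na.rm = TRUE), ]
      max(cyc1$length) / cyc1$length[1]
    } else {
      max(tr$length) / tr$length[1]
    }
    if (ratio < min_growth_ratio) return("no growth")
    if (mean(tr$fluor, na.rm = TRUE) < min_fluor) return("low fluorescence")
    if (require_complete && !any(tr$complete)) return("incomplete cycle")
    ""
  }, character(1))
  kept_ids <- names(reason)[reason == ""]
  out <- tracks[tracks$track_id %in% kept_ids, , drop = FALSE]
  disc <- tibble::tibble(track_id = names(reason)[reason != ""],
                         reason = unname(reason[reason != ""]))
  attr(out, "discarded") <- disc
  attr(out, "discard_fraction") <- nrow(disc) / length(parts)
  out
}

#' Bin observations by percentage of division
#'
#' Aggregates a per-frame quantity over all kept tracks into ten (by
#' default) bins of cell-cycle progress: \[0,10), \[10,20), ...,
#' \[90,100\]. Empty bins are reported with NA aggregates and counted.
#'
#' @param tracks annotated (and typically filtered) tracks.
#' @param quantity name of the column to aggregate (default `"fluor"`).
#' @param n_bins number of bins (default 10).
#' @return tibble with `bin`, `lo`, `hi`, `n`, `mean`, `sd`.
#' @export
bin_by_percent <- function(tracks, quantity = "fluor", n_bins = 10L) {
  p <- tracks$percent
  q <- tracks[[quantity]]
  ok <- !is.na(p)
  edges <- seq(0, 100, length.out = n_bins + 1L)
  bin <- pmin(findInterval(p[ok], edges, rightmost.closed = TRUE), n_bins)
  out <- tibble::tibble(bin = seq_len(n_bins),
                        lo = edges[-length(edges)], hi = edges[-1])
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin = bin, q = q[ok]), bin),
    n = dplyr::n(), mean = mean(q), sd = stats::sd(q), .groups = "drop")
  out <- dplyr::left_join(out, agg, by = "bin")
  out$n[is.na(out$n)] <- 0L
  empty <- sum(out$n == 0L)
  if (empty) cm_log("%d empty percent-of-division bins", empty)
  attr(out, "n_empty") <- empty
  out
}

## ---- lineage trees -----------------------------------------------------

#' Build a lineage forest from parent references
#'
#' Nodes are track ids, edges run parent to daughter (at most two per
#' node), and branch lengths are cycle durations in seconds (last minus
#' first observed time of the track). Cyclic parent references raise a
#' `lineage_error`.
#'
#' @param tracks track tibble with `track_id`, `time`, optional
#'   `parent_id`.
#' @return a `lineage_tree`: tibble of nodes (`track_id`, `parent_id`,
#'   `duration`) with the roots in `attr(, "roots")`.
#' @export
build_lineage <- function(tracks) {
  per <- dplyr::summarise(
    dplyr::group_by(tracks, track_id),
    parent_id = if ("parent_id" %in% names(tracks)) {
      v <- stats::na.omit(parent_id)
      if (length(v)) as.character(v[1]) else NA_character_
    } else NA_character_,
    duration = max(time) - min(time), .groups = "drop")
  per$parent_id[per$parent_id %in% c("", "0", "NA")] <- NA_character_
  unknown <- !is.na(per$parent_id) & !per$parent_id %in% per$track_id
  per$parent_id[unknown] <- NA_character_
  # cycle check by walking up from every node
  idx <- stats::setNames(per$parent_id, per$track_id)
  for (id in per$track_id) {
    seen <- character(); cur <- id
    while (!is.na(idx[[cur]])) {
      if (cur %in% seen) cm_stop("lineage_error", "cyclic parent references")
      seen <- c(seen, cur)
      cur <- idx[[cur]]
    }
  }
  kids <- table(stats::na.omit(per$parent_id))
  if (any(kids > 2L))
    cm_stop("lineage_error", "a cell cannot have more than two daughters")
  structure(per, class = c("lineage_tree", class(per)),
            roots = per$track_id[is.na(per$parent_id)])
}

#' Newick export of a lineage forest
#'
#' One Newick string per root, branch lengths in seconds, node names =
#' track ids (internal nodes labeled too, as divisions are observed
#' cells).
#'
#' @param lineage a [build_lineage()] result.
#' @return character vector of Newick strings, one per root.
#' @export
lineage_newick <- function(lineage) {
  children <- split(lineage$track_id, factor(lineage$parent_id, levels = lineage$track_id))
  dur <- stats::setNames(lineage$duration, lineage$track_id)
  rec <- function(id) {
    ch <- children[[id]]
    lab <- sprintf("%s:%g", id, dur[[id]])
    if (is.null(ch) || !length(ch)) return(lab)
    sprintf("(%s)%s", paste(vapply(sort(ch), rec, character(1)), collapse = ","), lab)
  }
  vapply(attr(lineage, "roots"), function(r) paste0(rec(r), ";"), character(1))
}
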