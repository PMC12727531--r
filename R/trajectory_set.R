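#' Trajectory set container
#'
#' A `TrajectorySet` holds the time-ordered 2D localizations of many tracked
#' particles in physical units (micrometres, seconds), together with the
#' acquisition metadata needed to convert between spot tables and pixel masks.
#'
#' @param spots data.frame with columns `track_id`, `frame` (0-based integer),
#'   `t_s`, `x_um`, `y_um` and optionally `intensity` (background-subtracted,
#'   arbitrary units; `NA` when absent).
#' @param frame_interval frame interval in seconds (> 0).
#' @param pixel_size pixel size in micrometres per pixel (> 0).
#' @param condition free-text condition label (e.g. "control", "puromycin").
#' @param cell_id cell identifier applied to every track (single value or one
#'   per track).
#'
#' @details Tracks with fewer than 2 localizations are dropped with a message
#' (a single spot carries no displacement information). Within each track,
#' spots are sorted by frame and times must be strictly increasing. Tracks are
#' ordered by ascending `track_id` so downstream output is deterministic.
#'
#' Coordinates use the image convention: origin at the image (0,0) corner,
#' the centre of 0-based pixel `(i, j)` at `((j + 0.5) * pixel_size,
#' (i + 0.5) * pixel_size)`.
#'
#' @return An object of class `TrajectorySet`: a list with elements `spots`
#'   (the localization table), `tracks` (per-track table with `track_id`,
#'   `cell_id`, `compartment`, `n_points`), `frame_interval`, `pixel_size`,
#'   `condition`.
#' @export
trajectory_set <- function(spots, frame_interval, pixel_size,
                           condition = "unspecified", cell_id = "cell_1") {
  stopifnot(is.data.frame(spots))
  required <- c("track_id", "frame", "t_s", "x_um", "y_um")
  missing_cols <- setdiff(required, names(spots))
  if (length(missing_cols) > 0) {
    stop("spots table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!is.numeric(frame_interval) || length(frame_interval) != 1 ||
      !is.finite(frame_interval) || frame_interval <= 0) {
    stop("frame_interval must be a single positive number (seconds)")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 ||
      !is.finite(pixel_size) || pixel_size <= 0) {
    stop("pixel_size must be a single positive number (um/pixel)")
  }
  if (!all(is.finite(spots$x_um)) || !all(is.finite(spots$y_um)) ||
      !all(is.finite(spots$t_s))) {
    stop("all localization coordinates and times must be finite")
  }
  if (is.null(spots$intensity)) spots$intensity <- NA_real_

  spots <- spots[order(spots$track_id, spots$frame), , drop = FALSE]
  rownames(spots) <- NULL

  counts <- table(spots$track_id)
  short <- names(counts)[counts < 2]
  if (length(short) > 0) {
    message(length(short), " track(s) with <2 localizations dropped")
    spots <- spots[!(spots$track_id %in% short), , drop = FALSE]
  }
  if (nrow(spots) == 0) stop("no usable tracks (all had <2 localizations)")

  ids <- sort(unique(spots$track_id))
  for (id in ids) {
    tt <- spots$t_s[spots$track_id == id]
    if (any(diff(tt) <= 0)) {
      stop("track ", id, ": times are not strictly increasing")
    }
  }

  if (length(cell_id) == 1) cell_id <- rep(cell_id, length(ids))
  if (length(cell_id) != length(ids)) {
    stop("cell_id must have length 1 or one entry per track")
  }

  tracks <- data.frame(
    track_id = ids,
    cell_id = cell_id,
    compartment = factor(rep("unassigned", length(ids)),
                         levels = c("cytoplasmic", "nuclear", "unassigned")),
    n_points = as.integer(counts[as.character(ids)]),
    stringsAsFactors = FALSE
  )
  rownames(tracks) <- NULL

  structure(
    list(spots = spots, tracks = tracks,
         frame_interval = frame_interval, pixel_size = pixel_size,
         condition = condition),
    class = "TrajectorySet"
  )
}

#' @export
print.TrajectorySet <- function(x, ...) {
  cat("TrajectorySet:", nrow(x$tracks), "tracks,", nrow(x$spots),
      "localizations\n")
  cat("  frame interval:", x$frame_interval, "s; pixel size:",
      x$pixel_size, "um; condition:", x$condition, "\n")
  cat("  compartments:",
      paste(names(table(x$tracks$compartment)),
            table(x$tracks$compartment), collapse = ", "), "\n")
  invisible(x)
}

#' Number of tracks in a TrajectorySet
#' @param ts a `TrajectorySet`.
#' @return integer track count.
#' @export
n_tracks <- function(ts) nrow(ts$tracks)

#' Extract one trajectory's localization table
#' @param ts a `TrajectorySet`.
#' @param track_id the track to extract.
#' @return data.frame of that track's spots, ordered by frame.
#' @export
get_track <- function(ts, track_id) {
  out <- ts$spots[ts$spots$track_id == track_id, , drop = FALSE]
  if (nrow(out) == 0) stop("no track with id ", track_id)
  rownames(out) <- NULL
  out
}

#' Subset a TrajectorySet by track id
#' @param ts a `TrajectorySet`.
#' @param track_ids ids to keep.
#' @return a `TrajectorySet` containing only the requested tracks.
#' @export
subset_tracks <- function(ts, track_ids) {
  keep <- ts$tracks$track_id %in% track_ids
  if (!any(keep)) stop("no matching tracks")
  ts$tracks <- ts$tracks[keep, , drop = FALSE]
  ts$spots <- ts$spots[ts$spots$track_id %in% track_ids, , drop = FALSE]
  rownames(ts$tracks) <- rownames(ts$spots) <- NULL
  ts
}

#' Combine trajectory sets
#'
#' Concatenates the tracks of several `TrajectorySet` objects acquired with
#' identical frame interval and pixel size, re-numbering track ids to keep
#' them unique. Used to assemble mixtures from separately simulated
#' populations.
#'
#' @param ... `TrajectorySet` objects.
#' @param condition condition label of the combined set.
#' @return a `TrajectorySet`; the new `track_id`s are sequential integers and
#'   attribute `source_set` on the tracks table records provenance.
#' @export
combine_trajectory_sets <- function(..., condition = "combined") {
  sets <- list(...)
  stopifnot(length(sets) >= 1)
  fi <- unique(vapply(sets, function(s) s$frame_interval, numeric(1)))
  px <- unique(vapply(sets, function(s) s$pixel_size, numeric(1)))
  if (length(fi) != 1 || length(px) != 1) {
    stop("all sets must share frame_interval and pixel_size")
  }
  spots_list <- list()
  source_set <- integer(0)
  next_id <- 1L
  for (k in seq_along(sets)) {
    s <- sets[[k]]
    ids <- s$tracks$track_id
    remap <- stats::setNames(seq.int(next_id, next_id + length(ids) - 1L), ids)
    sp <- s$spots
    sp$track_id <- as.integer(remap[as.character(sp$track_id)])
    spots_list[[k]] <- sp
    source_set <- c(source_set, rep(k, length(ids)))
    next_id <- next_id + length(ids)
  }
  out <- trajectory_set(do.call(rbind, spots_list), fi, px,
                        condition = condition)
  attr(out$tracks, "source_set") <- source_set
  out
}

#' Image stack container
#'
#' Wraps a 2D image or a (y, x, t) stack with its physical calibration.
#'
#' @param pixels numeric matrix `[y, x]` or 3D array `[y, x, t]`.
#' @param pixel_size pixel size, um/pixel (> 0).
#' @param frame_interval frame interval, seconds (single frames may use the
#'   default 1).
#' @return object of class `ImageStack`.
#' @export
image_stack <- function(pixels, pixel_size, frame_interval = 1) {
  if (is.matrix(pixels)) pixels <- array(pixels, dim = c(dim(pixels), 1))
  if (!is.array(pixels) || length(dim(pixels)) != 3 || any(dim(pixels) == 0)) {
    stop("pixels must be a non-empty matrix or [y, x, t] array")
  }
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    stop("pixel_size must be > 0")
  }
  if (!is.numeric(frame_interval) || frame_interval <= 0) {
    stop("frame_interval must be > 0")
  }
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$pixels)
  cat("ImageStack:", d[1], "x", d[2], "pixels,", d[3], "frame(s);",
      x$pixel_size, "um/px\n")
  invisible(x)
}

#' Number of frames in an ImageStack
#' @param img an `ImageStack`.
#' @return integer frame count.
#' @export
n_frames <- function(img) dim(img$pixels)[3]

#' Extract one frame as a matrix
#' @param img an `ImageStack`.
#' @param frame 1-based frame index.
#' @return numeric matrix `[y, x]`.
#' @export
get_frame <- function(img, frame = 1) {
  if (frame < 1 || frame > n_frames(img)) stop("frame out of range")
  img$pixels[, , frame]
}

# um coordinate -> 1-based pixel index (row from y, col from x); pixel i
# (0-based) spans [i*px, (i+1)*px) so centre sits at (i+0.5)*px
um_to_pixel <- function(coord_um, pixel_size) {
  as.integer(floor(coord_um / pixel_size)) + 1L
}

pixel_to_um <- function(idx, pixel_size) {
  (idx - 0.5) * pixel_size
}
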