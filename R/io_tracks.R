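#' Read particle trajectories
#'
#' Reads tracking output into a [trajectory_set()]. Two dialects are
#' supported: the plain-CSV schema written by [write_tracks()] (columns
#' `track_id, frame, t_s, x_um, y_um, intensity`, with calibration carried in
#' `#`-prefixed header lines) and the TrackMate "export tracks" XML dialect
#' (`<Tracks>` / `<particle>` / `<detection t= x= y=>` with coordinates
#' already in micrometres).
#'
#' @param path input file.
#' @param format `"csv"` or `"xml_trackmate"`.
#' @param pixel_size,frame_interval explicit calibration overrides
#'   (um/pixel, seconds). Required when the file carries none.
#' @param condition condition label; defaults to a label stored in the file,
#'   else "unspecified".
#' @return a `TrajectorySet`. Tracks with fewer than 2 spots are dropped with
#'   a message; tracks are ordered by ascending id.
#' @export
read_tracks <- function(path, format = c("csv", "xml_trackmate"),
                        pixel_size = NULL, frame_interval = NULL,
                        condition = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
    csv = read_tracks_csv(path, pixel_size, frame_interval, condition),
    xml_trackmate = read_tracks_xml(path, pixel_size, frame_interval,
                                    condition)
  )
}

read_tracks_csv <- function(path, pixel_size, frame_interval, condition) {
  header <- character(0)
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || !startsWith(line, "#")) break
    header <- c(header, line)
  }
  meta <- parse_csv_meta(header)
  if (is.null(pixel_size)) pixel_size <- meta$pixel_size_um
  if (is.null(frame_interval)) frame_interval <- meta$frame_interval_s
  if (is.null(condition)) condition <- meta$condition
  if (is.null(condition)) condition <- "unspecified"
  if (is.null(pixel_size) || is.null(frame_interval)) {
    stop("calibration metadata missing from ", path,
         ": pass pixel_size and frame_interval explicitly")
  }
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop("failed to parse CSV ", path, ": ",
                             conditionMessage(e))
  )
  required <- c("track_id", "frame", "t_s", "x_um", "y_um")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop("malformed track CSV ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  }
  bad <- which(!is.finite(df$x_um) | !is.finite(df$y_um) |
                 !is.finite(df$t_s))
  if (length(bad) > 0) {
    stop("malformed track CSV ", path, ": non-finite coordinates at data row ",
         bad[1])
  }
  trajectory_set(df, frame_interval, pixel_size, condition = condition)
}

parse_csv_meta <- function(lines) {
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^#\\s*([a-z_]+)\\s*:\\s*(.+)$", ln))[[1]]
    if (length(m) == 3) {
      key <- m[2]
      val <- trimws(m[3])
      if (key %in% c("pixel_size_um", "frame_interval_s")) {
        out[[key]] <- as.numeric(val)
      } else {
        out[[key]] <- val
      }
    }
  }
  out
}

read_tracks_xml <- function(path, pixel_size, frame_interval, condition) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("failed to parse XML ", path, ": ",
                                           conditionMessage(e)))
  root <- xml2::xml_find_first(doc, "//Tracks")
  if (inherits(root, "xml_missing")) {
    stop("malformed TrackMate XML ", path, ": no <Tracks> element")
  }
  if (is.null(frame_interval)) {
    fi <- xml2::xml_attr(root, "frameInterval")
    if (!is.na(fi)) frame_interval <- as.numeric(fi)
  }
  if (is.null(pixel_size)) {
    px <- xml2::xml_attr(root, "pixelSize")
    if (!is.na(px)) pixel_size <- as.numeric(px)
  }
  if (is.null(frame_interval) || is.null(pixel_size)) {
    stop("calibration metadata missing from ", path,
         ": pass pixel_size and frame_interval explicitly")
  }
  if (is.null(condition)) {
    cond <- xml2::xml_attr(root, "condition")
    condition <- if (is.na(cond)) "unspecified" else cond
  }
  particles <- xml2::xml_find_all(root, ".//particle")
  if (length(particles) == 0) stop("no <particle> records in ", path)
  spots_list <- vector("list", length(particles))
  for (k in seq_along(particles)) {
    dets <- xml2::xml_find_all(particles[[k]], ".//detection")
    if (length(dets) == 0) {
      stop("malformed TrackMate XML ", path, ": particle ", k,
           " has no detections")
    }
    t_frame <- as.numeric(xml2::xml_attr(dets, "t"))
    x <- as.numeric(xml2::xml_attr(dets, "x"))
    y <- as.numeric(xml2::xml_attr(dets, "y"))
    if (anyNA(t_frame) || anyNA(x) || anyNA(y)) {
      stop("malformed TrackMate XML ", path, ": particle ", k,
           " has a detection with missing t/x/y")
    }
    inten <- suppressWarnings(as.numeric(xml2::xml_attr(dets, "intensity")))
    spots_list[[k]] <- data.frame(
      track_id = k, frame = as.integer(round(t_frame)),
      t_s = t_frame * frame_interval, x_um = x, y_um = y,
      intensity = inten
    )
  }
  trajectory_set(do.call(rbind, spots_list), frame_interval, pixel_size,
                 condition = condition)
}

#' Write particle trajectories
#'
#' Serializes a `TrajectorySet` in either the package CSV schema (calibration
#' as `#`-prefixed header lines) or the TrackMate tracks XML dialect. Both
#' forms round-trip through [read_tracks()] to within float-print tolerance.
#'
#' @param ts a `TrajectorySet`.
#' @param path output file.
#' @param format `"csv"` or `"xml_trackmate"`.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(ts, path, format = c("csv", "xml_trackmate")) {
  format <- match.arg(format)
  stopifnot(inherits(ts, "TrajectorySet"))
  if (format == "csv") {
    header <- c(
      sprintf("# pixel_size_um: %.17g", ts$pixel_size),
      sprintf("# frame_interval_s: %.17g", ts$frame_interval),
      sprintf("# condition: %s", ts$condition)
    )
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    utils::write.csv(ts$spots, con, row.names = FALSE)
  } else {
    root <- xml2::xml_new_root(
      "Tracks",
      nTracks = as.character(n_tracks(ts)),
      frameInterval = sprintf("%.17g", ts$frame_interval),
      pixelSize = sprintf("%.17g", ts$pixel_size),
      spaceUnits = "micron", timeUnits = "s",
      condition = ts$condition
    )
    for (id in ts$tracks$track_id) {
      tr <- ts$spots[ts$spots$track_id == id, , drop = FALSE]
      p <- xml2::xml_add_child(root, "particle",
                               nSpots = as.character(nrow(tr)))
      for (i in seq_len(nrow(tr))) {
        xml2::xml_add_child(p, "detection",
                            t = sprintf("%d", tr$frame[i]),
                            x = sprintf("%.17g", tr$x_um[i]),
                            y = sprintf("%.17g", tr$y_um[i]),
                            intensity = if (is.na(tr$intensity[i])) "NA"
                                        else sprintf("%.17g", tr$intensity[i]))
      }
    }
    xml2::write_xml(root, path)
  }
  invisible(path)
}

#' Read and write TIFF images as ImageStacks
#'
#' Thin wrappers over the tiff package; multi-page TIFFs map to the time
#' axis. Calibration is not stored in the TIFF and must be supplied.
#'
#' @param path TIFF file.
#' @param pixel_size um/pixel.
#' @param frame_interval seconds per frame.
#' @return [read_image_stack()]: an `ImageStack`; [write_image_stack()]:
#'   `path`, invisibly.
#' @export
read_image_stack <- function(path, pixel_size, frame_interval = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  image_stack(arr, pixel_size, frame_interval)
}

#' @rdname read_image_stack
#' @param img an `ImageStack`; intensities are rescaled to `[0, 1]` on write
#'   if they exceed that range.
#' @export
write_image_stack <- function(img, path) {
  stopifnot(inherits(img, "ImageStack"))
  mx <- max(img$pixels)
  scale <- if (mx > 1) mx else 1
  pages <- lapply(seq_len(n_frames(img)),
                  function(k) img$pixels[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Assign trajectories to cellular compartments
#'
#' Labels each trajectory by where its localizations fall relative to a cell
#' mask and (optionally) a nuclear mask, so that only cytosolic trajectories
#' enter the translation-state analysis. A trajectory is `nuclear` if any of
#' its points falls inside the nuclear mask (strict removal), `cytoplasmic`
#' if at least `min_fraction` of its points lie inside the cell mask and
#' outside the nuclear mask, and `unassigned` otherwise.
#'
#' @param ts a `TrajectorySet`.
#' @param cell_mask binary `ImageStack` (single frame used) covering the cell.
#' @param nuclear_mask optional binary `ImageStack` for the nucleus.
#' @param min_fraction fraction of a track's points that must be cytosolic
#'   for the `cytoplasmic` label (default 1 = all points).
#' @return the `TrajectorySet` with updated `compartment` labels; coordinates
#'   are never modified.
#' @export
apply_compartment_mask <- function(ts, cell_mask, nuclear_mask = NULL,
                                   min_fraction = 1) {
  stopifnot(inherits(ts, "TrajectorySet"), inherits(cell_mask, "ImageStack"))
  if (abs(cell_mask$pixel_size - ts$pixel_size) > 1e-9) {
    stop("cell_mask pixel_size differs from TrajectorySet pixel_size")
  }
  cm <- get_frame(cell_mask, 1) > 0
  nm <- NULL
  if (!is.null(nuclear_mask)) {
    stopifnot(inherits(nuclear_mask, "ImageStack"))
    nm <- get_frame(nuclear_mask, 1) > 0
    if (!all(dim(nm) == dim(cm))) stop("cell and nuclear masks differ in size")
  }
  col <- um_to_pixel(ts$spots$x_um, ts$pixel_size)
  row <- um_to_pixel(ts$spots$y_um, ts$pixel_size)
  if (any(col < 1 | col > ncol(cm) | row < 1 | row > nrow(cm))) {
    stop("track coordinates fall outside the mask extent: ",
         "mask/track coordinate range mismatch")
  }
  in_cell <- cm[cbind(row, col)]
  in_nuc <- if (is.null(nm)) rep(FALSE, length(row)) else nm[cbind(row, col)]
  for (i in seq_len(nrow(ts$tracks))) {
    sel <- ts$spots$track_id == ts$tracks$track_id[i]
    if (any(in_nuc[sel])) {
      ts$tracks$compartment[i] <- "nuclear"
    } else if (mean(in_cell[sel] & !in_nuc[sel]) >= min_fraction) {
      ts$tracks$compartment[i] <- "cytoplasmic"
    } else {
      ts$tracks$compartment[i] <- "unassigned"
    }
  }
  ts
}

#' Keep only cytoplasmic trajectories
#'
#' @param ts a `TrajectorySet` previously labelled by
#'   [apply_compartment_mask()].
#' @return a `TrajectorySet` restricted to `compartment == "cytoplasmic"`.
#' @export
cytoplasmic_tracks <- function(ts) {
  keep <- ts$tracks$track_id[ts$tracks$compartment == "cytoplasmic"]
  if (length(keep) == 0) stop("no cytoplasmic tracks")
  subset_tracks(ts, keep)
}
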