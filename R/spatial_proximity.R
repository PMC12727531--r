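#' Detect ER tubule junctions
#'
#' Identifies three-way (and higher) junctions of the ER tubule network from
#' a single-channel ER-marker image: the image is binarized (Otsu threshold
#' by default), thinned to a one-pixel skeleton (Zhang-Suen), skeleton
#' pixels with three or more skeleton neighbours (8-connectivity) are marked
#' as branch points, and branch points closer than `merge_radius` are merged
#' to their centroid — a thick junction yields a small clump of branch
#' pixels, not several junctions.
#'
#' @param er_image single-channel `ImageStack` (first frame used).
#' @param threshold `"otsu"` or a numeric cut-off on intensity.
#' @param merge_radius branch points within this distance (um) are merged
#'   (default 0.25 um).
#' @return data.frame of class `JunctionSet` with columns `x_um`, `y_um`;
#'   attributes `merge_radius`, `n_branch_pixels`. Empty (with a warning)
#'   when the skeleton is empty.
#' @export
detect_junctions <- function(er_image, threshold = "otsu",
                             merge_radius = 0.25) {
  stopifnot(inherits(er_image, "ImageStack"))
  px <- er_image$pixel_size
  img <- get_frame(er_image, 1)
  if (identical(threshold, "otsu")) {
    rng <- range(img)
    scaled <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
    thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
    bw <- scaled > thr
  } else {
    bw <- img > threshold
  }
  skel <- skeletonize(bw)
  if (!any(skel)) {
    warning("empty skeleton: no ER structure above threshold")
    out <- data.frame(x_um = numeric(0), y_um = numeric(0))
    class(out) <- c("JunctionSet", "data.frame")
    attr(out, "merge_radius") <- merge_radius
    attr(out, "n_branch_pixels") <- 0L
    return(out)
  }
  cn <- crossing_number(skel)
  branch <- which(skel & cn >= 3, arr.ind = TRUE)
  if (nrow(branch) == 0) {
    out <- data.frame(x_um = numeric(0), y_um = numeric(0))
    class(out) <- c("JunctionSet", "data.frame")
    attr(out, "merge_radius") <- merge_radius
    attr(out, "n_branch_pixels") <- 0L
    return(out)
  }
  pts <- cbind(x = pixel_to_um(branch[, "col"], px),
               y = pixel_to_um(branch[, "row"], px))
  merged <- merge_close_points(pts, merge_radius)
  out <- data.frame(x_um = merged[, 1], y_um = merged[, 2])
  class(out) <- c("JunctionSet", "data.frame")
  attr(out, "merge_radius") <- merge_radius
  attr(out, "n_branch_pixels") <- nrow(branch)
  out
}

# Zhang-Suen binary thinning to a 1-pixel-wide skeleton
skeletonize <- function(bw) {
  img <- bw * 1L
  pad <- function(m) {
    out <- matrix(0L, nrow(m) + 2, ncol(m) + 2)
    out[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
    out
  }
  p <- pad(img)
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      nr <- nrow(p); nc <- ncol(p)
      i <- 2:(nr - 1); j <- 2:(nc - 1)
      P2 <- p[i - 1, j];     P3 <- p[i - 1, j + 1]
      P4 <- p[i, j + 1];     P5 <- p[i + 1, j + 1]
      P6 <- p[i + 1, j];     P7 <- p[i + 1, j - 1]
      P8 <- p[i, j - 1];     P9 <- p[i - 1, j - 1]
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 == 0 & P3 == 1) + (P3 == 0 & P4 == 1) +
        (P4 == 0 & P5 == 1) + (P5 == 0 & P6 == 1) +
        (P6 == 0 & P7 == 1) + (P7 == 0 & P8 == 1) +
        (P8 == 0 & P9 == 1) + (P9 == 0 & P2 == 1)
      if (phase == 1) {
        cond <- p[i, j] == 1 & B >= 2 & B <= 6 & A == 1 &
          (P2 * P4 * P6 == 0) & (P4 * P6 * P8 == 0)
      } else {
        cond <- p[i, j] == 1 & B >= 2 & B <= 6 & A == 1 &
          (P2 * P4 * P8 == 0) & (P2 * P6 * P8 == 0)
      }
      if (any(cond)) {
        sub <- p[i, j]
        sub[cond] <- 0L
        p[i, j] <- sub
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  p[2:(nrow(p) - 1), 2:(ncol(p) - 1)] == 1L
}

# crossing number: 0->1 transitions around the 8-neighbour cycle of each
# pixel; 1 marks line ends, 2 line interiors, >=3 branch points. Unlike a
# raw neighbour count this is robust to the two-pixel staircases thinning
# leaves on diagonal lines.
crossing_number <- function(bw) {
  m <- bw * 1L
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  shift <- function(di, dj) p[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)]
  # clockwise neighbour cycle starting north
  cyc <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
              c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  acc <- matrix(0L, nr, nc)
  for (k in seq_along(cyc)) {
    a <- shift(cyc[[k]][1], cyc[[k]][2])
    nxt <- cyc[[if (k == length(cyc)) 1 else k + 1]]
    b <- shift(nxt[1], nxt[2])
    acc <- acc + (a == 0L & b == 1L)
  }
  acc
}

# single-linkage merge of points within `radius`; returns cluster centroids
merge_close_points <- function(pts, radius) {
  n <- nrow(pts)
  if (n == 1) return(pts)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  d <- as.matrix(stats::dist(pts))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (d[i, j] <= radius) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  centroids <- t(vapply(unique(roots), function(r) {
    colMeans(pts[roots == r, , drop = FALSE])
  }, numeric(2)))
  centroids[order(centroids[, 1], centroids[, 2]), , drop = FALSE]
}

#' Nearest-reference distances
#'
#' Euclidean distance from each query point to its nearest reference point
#' (e.g. mRNA puncta to ER junctions, or mRNA to lysosome centres).
#'
#' @param points matrix/data.frame of query `x`, `y` in um.
#' @param refs matrix/data.frame of reference `x`, `y` in um (non-empty).
#' @return numeric vector of minimum distances, um, one per query point.
#' @export
nearest_distance <- function(points, refs) {
  points <- as.matrix(points)
  refs <- as.matrix(refs)
  if (nrow(refs) == 0) stop("refs must be non-empty")
  if (nrow(points) == 0) return(numeric(0))
  out <- numeric(nrow(points))
  # chunked pairwise distances: exact, memory-bounded
  chunk <- max(1L, as.integer(1e6 / nrow(refs)))
  for (start in seq(1, nrow(points), by = chunk)) {
    idx <- start:min(start + chunk - 1, nrow(points))
    dx <- outer(points[idx, 1], refs[, 1], "-")
    dy <- outer(points[idx, 2], refs[, 2], "-")
    out[idx] <- sqrt(apply(dx^2 + dy^2, 1, min))
  }
  out
}

#' Fraction of points within a radius of any reference
#'
#' The colocalization statistic used for e.g. "fraction of translating mRNAs
#' within 300 nm of LNPK signal": the fraction of query points whose
#' nearest-reference distance is at most `radius`.
#'
#' @param points,refs as in [nearest_distance()]; `points` must be
#'   non-empty.
#' @param radius distance cut-off, um (default 0.3).
#' @return fraction in `[0, 1]`.
#' @export
fraction_within_radius <- function(points, refs, radius = 0.3) {
  points <- as.matrix(points)
  if (nrow(points) == 0) stop("points must be non-empty")
  mean(nearest_distance(points, refs) <= radius)
}

#' Match puncta to trajectories per frame
#'
#' Associates detected puncta (e.g. SunTag foci) with mRNA trajectories:
#' within each frame, candidate punctum-trajectory pairs closer than
#' `max_pixels * pixel_size` are assigned greedily in order of increasing
#' distance (ties broken by punctum then track id), each punctum to at most
#' one trajectory and vice versa. A trajectory is called SunTag-positive
#' when matched in at least `min_frames_matched` frames.
#'
#' @param puncta data.frame with `x_um`, `y_um`, `frame` and optionally
#'   `intensity` and `punctum_id` (default row number).
#' @param ts a `TrajectorySet` sharing the puncta's pixel size and frame
#'   base.
#' @param max_pixels match radius in pixels (default 2).
#' @param min_frames_matched frames a track must be matched in to be called
#'   positive (default 1).
#' @return list of class `MatchTable`: `matches` (data.frame `punctum_id`,
#'   `track_id`, `frame`, `dist_um`), `unmatched_puncta`,
#'   `positive_tracks`, `max_match_distance_um`.
#' @export
match_puncta_to_tracks <- function(puncta, ts, max_pixels = 2,
                                   min_frames_matched = 1) {
  stopifnot(inherits(ts, "TrajectorySet"), is.data.frame(puncta))
  if (is.null(puncta$punctum_id)) puncta$punctum_id <- seq_len(nrow(puncta))
  radius <- max_pixels * ts$pixel_size
  matches <- list()
  unmatched <- integer(0)
  for (fr in sort(unique(puncta$frame))) {
    pu <- puncta[puncta$frame == fr, , drop = FALSE]
    sp <- ts$spots[ts$spots$frame == fr, , drop = FALSE]
    if (nrow(sp) == 0) { unmatched <- c(unmatched, pu$punctum_id); next }
    dx <- outer(pu$x_um, sp$x_um, "-")
    dy <- outer(pu$y_um, sp$y_um, "-")
    dmat <- sqrt(dx^2 + dy^2)
    cand <- which(dmat <= radius, arr.ind = TRUE)
    if (nrow(cand) == 0) { unmatched <- c(unmatched, pu$punctum_id); next }
    cand_df <- data.frame(p = cand[, 1], s = cand[, 2],
                          d = dmat[cand],
                          pid = pu$punctum_id[cand[, 1]],
                          tid = sp$track_id[cand[, 2]])
    cand_df <- cand_df[order(cand_df$d, cand_df$pid, cand_df$tid), ]
    used_p <- used_t <- character(0)
    for (rr in seq_len(nrow(cand_df))) {
      pid <- as.character(cand_df$pid[rr]); tid <- as.character(cand_df$tid[rr])
      if (pid %in% used_p || tid %in% used_t) next
      matches[[length(matches) + 1]] <- data.frame(
        punctum_id = cand_df$pid[rr], track_id = cand_df$tid[rr],
        frame = fr, dist_um = cand_df$d[rr])
      used_p <- c(used_p, pid); used_t <- c(used_t, tid)
    }
    unmatched <- c(unmatched,
                   setdiff(pu$punctum_id, as.numeric(used_p)))
  }
  matches <- if (length(matches) > 0) do.call(rbind, matches) else
    data.frame(punctum_id = numeric(0), track_id = numeric(0),
               frame = numeric(0), dist_um = numeric(0))
  tab <- table(matches$track_id)
  positive <- as.numeric(names(tab)[tab >= min_frames_matched])
  structure(list(matches = matches, unmatched_puncta = unmatched,
                 positive_tracks = sort(positive),
                 max_match_distance_um = radius),
            class = "MatchTable")
}

#' Distance-binned, end-normalized intensity profile
#'
#' Bins puncta by their minimum organelle distance into eight 500-nm bins
#' centred 0.75-4.25 um (half-open `[centre - 0.25, centre + 0.25)`),
#' averages intensity per bin, and normalizes by the mean of the farthest
#' (4.25 um) bin, whose normalized value is therefore exactly 1. Distances
#' outside the bin support are excluded; empty interior bins are reported as
#' `NA` with their zero counts, never interpolated.
#'
#' @param min_distances per-punctum minimum distance to the organelle, um.
#' @param intensities per-punctum intensity, a.u. (same length).
#' @return data.frame of class `ProximityProfile`: `bin_center_um`,
#'   `mean_intensity`, `normalized`, `n`.
#' @export
proximity_profile <- function(min_distances, intensities) {
  if (length(min_distances) != length(intensities)) {
    stop("min_distances and intensities must have equal length")
  }
  centers <- seq(0.75, 4.25, by = 0.5)
  mean_i <- rep(NA_real_, length(centers))
  n <- integer(length(centers))
  for (b in seq_along(centers)) {
    lo <- centers[b] - 0.25; hi <- centers[b] + 0.25
    sel <- min_distances >= lo & min_distances < hi
    n[b] <- sum(sel)
    if (n[b] > 0) mean_i[b] <- mean(intensities[sel])
  }
  ref <- mean_i[length(centers)]
  if (is.na(ref) || n[length(centers)] == 0) {
    stop("no puncta in the 4.25 um reference bin: cannot normalize; ",
         "provide data extending to at least 4.0-4.5 um")
  }
  out <- data.frame(bin_center_um = centers, mean_intensity = mean_i,
                    normalized = mean_i / ref, n = n)
  class(out) <- c("ProximityProfile", "data.frame")
  out
}

#' Render classified trajectories as pseudocoloured movies
#'
#' Maps classified trajectory positions onto two blank (y, x, t) stacks —
#' one for translating, one for non-translating tracks — placing each
#' localization's intensity (1 when absent) at its pixel, then Gaussian
#' blurring each frame with `blur_sigma` (default 0.05 um, mimicking the
#' localization accuracy). Deterministic; positions outside the field are
#' clipped with a warning.
#'
#' @param ts a `TrajectorySet`.
#' @param labels per-track labels aligned with `ts$tracks` (or a
#'   `TrajectoryMsd` table).
#' @param field_size_um side of the output field, um; defaults to covering
#'   the data.
#' @param blur_sigma Gaussian sigma, um; 0 leaves single-pixel spots.
#' @return list with `translating` and `non_translating` `ImageStack`s.
#' @export
render_classified_movie <- function(ts, labels, field_size_um = NULL,
                                    blur_sigma = 0.05) {
  stopifnot(inherits(ts, "TrajectorySet"))
  if (is.data.frame(labels)) {
    lab <- labels$label[match(ts$tracks$track_id, labels$track_id)]
  } else lab <- labels
  stopifnot(length(lab) == nrow(ts$tracks))
  px <- ts$pixel_size
  if (is.null(field_size_um)) {
    field_size_um <- max(ts$spots$x_um, ts$spots$y_um) + 2 * px
  }
  n_px <- ceiling(field_size_um / px)
  frames <- sort(unique(ts$spots$frame))
  nt <- length(frames)
  mk <- function() array(0, dim = c(n_px, n_px, nt))
  stacks <- list(translating = mk(), non_translating = mk())
  lab_by_id <- stats::setNames(lab, ts$tracks$track_id)
  sp <- ts$spots
  col <- um_to_pixel(sp$x_um, px)
  row <- um_to_pixel(sp$y_um, px)
  outside <- col < 1 | col > n_px | row < 1 | row > n_px
  if (any(outside)) {
    warning(sum(outside), " localization(s) outside the rendered field were",
            " clipped")
  }
  fr_idx <- match(sp$frame, frames)
  inten <- ifelse(is.na(sp$intensity), 1, sp$intensity)
  for (i in which(!outside)) {
    L <- lab_by_id[as.character(sp$track_id[i])]
    if (L == "translating") {
      stacks$translating[row[i], col[i], fr_idx[i]] <-
        stacks$translating[row[i], col[i], fr_idx[i]] + inten[i]
    } else if (L == "non_translating") {
      stacks$non_translating[row[i], col[i], fr_idx[i]] <-
        stacks$non_translating[row[i], col[i], fr_idx[i]] + inten[i]
    }
  }
  if (blur_sigma > 0) {
    sig_px <- blur_sigma / px
    for (nm in names(stacks)) for (k in seq_len(nt)) {
      stacks[[nm]][, , k] <-
        as.matrix(EBImage::gblur(EBImage::Image(stacks[[nm]][, , k]),
                                 sigma = sig_px))
    }
  }
  list(translating = image_stack(stacks$translating, px, ts$frame_interval),
       non_translating = image_stack(stacks$non_translating, px,
                                     ts$frame_interval))
}

#' Junction detection precision and recall against ground truth
#'
#' Scores a detected `JunctionSet` against known junction coordinates: a
#' detection is a true positive when it falls within `tol_um` of an as-yet
#' unmatched true junction (greedy nearest-first matching).
#'
#' @param detected data.frame `x_um`, `y_um` of detections.
#' @param truth data.frame `x_um`, `y_um` of ground-truth junctions.
#' @param tol_um matching tolerance, um.
#' @return list with `precision`, `recall`, `n_matched`.
#' @export
junction_detection_score <- function(detected, truth, tol_um = 0.25) {
  nd <- nrow(detected); nt <- nrow(truth)
  if (nd == 0 || nt == 0) {
    return(list(precision = if (nd == 0) NA_real_ else 0,
                recall = if (nt == 0) NA_real_ else 0, n_matched = 0L))
  }
  dx <- outer(detected$x_um, truth$x_um, "-")
  dy <- outer(detected$y_um, truth$y_um, "-")
  dmat <- sqrt(dx^2 + dy^2)
  cand <- which(dmat <= tol_um, arr.ind = TRUE)
  n_matched <- 0L
  if (nrow(cand) > 0) {
    ord <- order(dmat[cand])
    used_d <- used_t <- integer(0)
    for (r in ord) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (i %in% used_d || j %in% used_t) next
      used_d <- c(used_d, i); used_t <- c(used_t, j)
      n_matched <- n_matched + 1L
    }
  }
  list(precision = n_matched / nd, recall = n_matched / nt,
       n_matched = n_matched)
}
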