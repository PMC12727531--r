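# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# a single track walking a fixed step along x each frame
make_lattice_track <- function(n_frames = 12, step = 0.1, start = c(1, 1),
                               track_id = 1, dt = 1) {
  data.frame(
    track_id = track_id,
    frame = 0:(n_frames - 1),
    t_s = (0:(n_frames - 1)) * dt,
    x_um = start[1] + step * (0:(n_frames - 1)),
    y_um = start[2],
    intensity = NA_real_
  )
}

make_stationary_set <- function(n_frames = 12, pos = c(2, 3)) {
  trajectory_set(make_lattice_track(n_frames, step = 0, start = pos),
                 frame_interval = 1, pixel_size = 0.1)
}

# small random trajectory set with reproducible coordinates
make_random_set <- function(n_tracks = 20, n_frames = 15, field = 10,
                            seed = 1, pixel_size = 0.1) {
  set.seed(seed)
  spots <- do.call(rbind, lapply(seq_len(n_tracks), function(id) {
    start <- runif(2, 1, field - 1)
    data.frame(
      track_id = id, frame = 0:(n_frames - 1), t_s = 0:(n_frames - 1),
      x_um = start[1] + cumsum(c(0, rnorm(n_frames - 1, sd = 0.05))),
      y_um = start[2] + cumsum(c(0, rnorm(n_frames - 1, sd = 0.05))),
      intensity = runif(n_frames, 50, 150)
    )
  }))
  trajectory_set(spots, frame_interval = 1, pixel_size = pixel_size)
}

# brute-force oracles ------------------------------------------------------

brute_nearest_distance <- function(points, refs) {
  points <- as.matrix(points); refs <- as.matrix(refs)
  out <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    best <- Inf
    for (j in seq_len(nrow(refs))) {
      d <- sqrt(sum((points[i, ] - refs[j, ])^2))
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}

# maximum bipartite matching size under a distance cap, by exhaustive
# recursion (instances kept to <= 8 puncta)
brute_max_matching <- function(dmat, radius) {
  np <- nrow(dmat)
  best <- 0L
  recurse <- function(p, used_t, count) {
    if (p > np) { best <<- max(best, count); return(invisible()) }
    recurse(p + 1L, used_t, count)  # leave punctum p unmatched
    for (t in seq_len(ncol(dmat))) {
      if (!used_t[t] && dmat[p, t] <= radius) {
        used_t[t] <- TRUE
        recurse(p + 1L, used_t, count + 1L)
        used_t[t] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, ncol(dmat)), 0L)
  best
}

brute_ensemble_msd <- function(ts, max_lag) {
  dt <- ts$frame_interval
  ks <- seq_len(floor(max_lag / dt))
  out <- data.frame(lag_s = ks * dt, msd_um2 = NA_real_, n_pairs = 0L)
  for (ki in seq_along(ks)) {
    sds <- numeric(0)
    for (id in ts$tracks$track_id) {
      tr <- ts$spots[ts$spots$track_id == id, ]
      for (i in seq_len(nrow(tr))) for (j in seq_len(nrow(tr))) {
        if (tr$frame[j] - tr$frame[i] == ks[ki]) {
          sds <- c(sds, (tr$x_um[j] - tr$x_um[i])^2 +
                     (tr$y_um[j] - tr$y_um[i])^2)
        }
      }
    }
    out$msd_um2[ki] <- mean(sds)
    out$n_pairs[ki] <- length(sds)
  }
  out[out$n_pairs > 0, ]
}

# binary disc mask stack
make_disc_mask <- function(n_px, centre_px, radius_px, pixel_size = 0.1,
                           n_frames = 1) {
  m <- matrix(0, n_px, n_px)
  for (r in seq_len(n_px)) for (cc in seq_len(n_px)) {
    if ((r - centre_px[1])^2 + (cc - centre_px[2])^2 <= radius_px^2) {
      m[r, cc] <- 1
    }
  }
  image_stack(array(rep(m, n_frames), dim = c(n_px, n_px, n_frames)),
              pixel_size)
}
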