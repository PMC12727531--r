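#' Simulation configuration
#'
#' Parameters of the Monte Carlo trajectory generators. A configuration may
#' describe several diffusive populations (mixtures) via parallel vectors of
#' diffusion coefficients and population fractions.
#'
#' @param diffusion_coefficients per-population diffusion coefficients D,
#'   um^2/s (all >= 0).
#' @param fractions population weights, non-negative, summing to 1.
#' @param dimensionality 2 or 3. In 3D mode displacements are drawn along all
#'   three Cartesian axes and the output trajectories are the (x, y)
#'   projection, mirroring quasi-2D imaging of the ER sheet near the
#'   coverslip; 2D mode is exact for analytic checks.
#' @param step_interval time step, seconds.
#' @param n_steps displacements per trajectory (localizations = n_steps + 1).
#' @param n_particles number of trajectories.
#' @param localization_sigma static localization error, um; added as
#'   independent zero-mean Gaussian noise per frame per axis (not cumulative),
#'   which produces the 4*sigma^2 intercept of the ensemble MSD line.
#' @param confinement_radius radius of the reflecting circular boundary, um;
#'   scalar, or one value per population with `NA` meaning unconfined. `NULL`
#'   for free diffusion.
#' @param field_size_um side of the square field in which trajectories start
#'   (uniformly at random); keeps fixtures compatible with image masks.
#' @param seed integer RNG seed; every generator is bit-reproducible given
#'   the configuration and seed.
#' @return object of class `SimulationConfig`.
#' @export
sim_config <- function(diffusion_coefficients, fractions = NULL,
                       dimensionality = 2, step_interval = 1,
                       n_steps = 20, n_particles = 100,
                       localization_sigma = 0, confinement_radius = NULL,
                       field_size_um = 20, seed = 1) {
  D <- as.numeric(diffusion_coefficients)
  if (length(D) == 0 || any(!is.finite(D)) || any(D < 0)) {
    stop("diffusion_coefficients must be finite and >= 0")
  }
  if (is.null(fractions)) fractions <- rep(1 / length(D), length(D))
  fractions <- as.numeric(fractions)
  if (length(fractions) != length(D) || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be non-negative, one per population, and sum to 1")
  }
  if (!dimensionality %in% c(2, 3)) stop("dimensionality must be 2 or 3")
  if (step_interval <= 0) stop("step_interval must be > 0")
  if (n_steps < 1) stop("n_steps must be >= 1")
  if (n_particles < 1) stop("n_particles must be >= 1")
  if (localization_sigma < 0) stop("localization_sigma must be >= 0")
  if (!is.null(confinement_radius)) {
    cr <- as.numeric(confinement_radius)
    if (!length(cr) %in% c(1, length(D))) {
      stop("confinement_radius must be scalar or one value per population")
    }
    if (any(!is.na(cr) & cr <= 0)) stop("confinement_radius must be > 0")
    confinement_radius <- cr
  }
  structure(list(
    diffusion_coefficients = D, fractions = fractions,
    dimensionality = dimensionality, step_interval = step_interval,
    n_steps = as.integer(n_steps), n_particles = as.integer(n_particles),
    localization_sigma = localization_sigma,
    confinement_radius = confinement_radius,
    field_size_um = field_size_um, seed = as.integer(seed)
  ), class = "SimulationConfig")
}

with_sim_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate free Brownian trajectories
#'
#' Monte Carlo random walk: at each time step every particle draws an
#' independent zero-mean Gaussian displacement of standard deviation
#' `sqrt(2 * D * dt)` along each Cartesian axis (2 or 3 axes per
#' `config$dimensionality`; 3D runs are projected to the x-y plane).
#' Localization error is added afterwards as independent per-frame Gaussian
#' noise of standard deviation `localization_sigma` per axis.
#'
#' @param config a [sim_config()]. Any `confinement_radius` is ignored here.
#' @return list with `tracks` (a `TrajectorySet`) and `truth` (list with
#'   per-trajectory `population` index, `fractions`, `diffusion_coefficients`,
#'   and the seed).
#' @export
simulate_brownian <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  cfg <- config
  cfg$confinement_radius <- NULL
  simulate_walk(cfg, confined = rep(FALSE, length(cfg$diffusion_coefficients)))
}

#' Simulate confined trajectories
#'
#' Identical step statistics to [simulate_brownian()], but each particle's
#' displacement is reflected at a circular boundary of radius
#' `confinement_radius` centred on the particle's starting position, so the
#' long-time per-trajectory MSD plateaus at a level set by the radius
#' (uniform occupancy of a disc of radius R gives a plateau near R^2).
#' Populations whose `confinement_radius` entry is `NA` diffuse freely,
#' allowing confined/free mixtures with ground-truth labels.
#'
#' @param config a [sim_config()] with `confinement_radius` set.
#' @return same structure as [simulate_brownian()]; `truth$confined` flags
#'   which populations are confined and `truth$confinement_radius` records
#'   the radii.
#' @export
simulate_confined <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (is.null(config$confinement_radius)) {
    stop("confinement_radius must be set for simulate_confined")
  }
  cr <- config$confinement_radius
  if (length(cr) == 1) cr <- rep(cr, length(config$diffusion_coefficients))
  if (any(!is.na(cr) & cr <= config$localization_sigma)) {
    warning("confinement_radius <= localization_sigma: ",
            "confinement is unresolvable at this localization error")
  }
  config$confinement_radius <- cr
  simulate_walk(config, confined = !is.na(cr))
}

simulate_walk <- function(config, confined) {
  c_ <- config
  with_sim_seed(c_$seed, {
    n_pop <- length(c_$diffusion_coefficients)
    pop <- sample.int(n_pop, c_$n_particles, replace = TRUE,
                      prob = c_$fractions)
    dt <- c_$step_interval
    n_pts <- c_$n_steps + 1L
    ndim <- c_$dimensionality
    spots_list <- vector("list", c_$n_particles)
    for (i in seq_len(c_$n_particles)) {
      D <- c_$diffusion_coefficients[pop[i]]
      start <- stats::runif(ndim, 0, c_$field_size_um)
      steps <- matrix(stats::rnorm(c_$n_steps * ndim, sd = sqrt(2 * D * dt)),
                      ncol = ndim)
      cum <- apply(steps, 2, cumsum)
      if (c_$n_steps == 1L) cum <- matrix(cum, nrow = 1)
      pos <- rbind(start, sweep(cum, 2, start, "+"))
      if (confined[pop[i]]) {
        R <- c_$confinement_radius[pop[i]]
        pos <- reflect_in_ball(pos, start, R)
      }
      xy <- pos[, 1:2, drop = FALSE]
      if (c_$localization_sigma > 0) {
        xy <- xy + matrix(stats::rnorm(length(xy),
                                       sd = c_$localization_sigma),
                          ncol = 2)
      }
      spots_list[[i]] <- data.frame(
        track_id = i, frame = 0:(n_pts - 1L), t_s = (0:(n_pts - 1L)) * dt,
        x_um = xy[, 1], y_um = xy[, 2], intensity = NA_real_
      )
    }
    ts <- trajectory_set(do.call(rbind, spots_list), dt,
                         pixel_size = 0.1, condition = "simulated")
    list(tracks = ts,
         truth = list(population = pop, fractions = c_$fractions,
                      diffusion_coefficients = c_$diffusion_coefficients,
                      confined = confined,
                      confinement_radius = c_$confinement_radius,
                      seed = c_$seed))
  })
}

# Reflect successive positions at a sphere/circle of radius R about `centre`.
# Radial folding handles steps larger than the boundary: the distance from
# the centre folds as a triangle wave on [0, R], preserving direction.
reflect_in_ball <- function(pos, centre, R) {
  for (k in seq_len(nrow(pos))) {
    v <- pos[k, ] - centre
    r <- sqrt(sum(v^2))
    if (r > R) {
      f <- r %% (2 * R)
      if (f > R) f <- 2 * R - f
      pos_k <- centre + v * (f / r)
      # displace all later raw positions rigidly so increments are preserved
      shift <- pos_k - pos[k, ]
      pos[k:nrow(pos), ] <- sweep(pos[k:nrow(pos), , drop = FALSE], 2, shift,
                                  "+")
    }
  }
  pos
}

#' Simulate a confined/free trajectory mixture
#'
#' Convenience wrapper assembling the standard two-population fixture used
#' throughout the tests: a confined ("translating-like") population of known
#' fraction and a freely diffusing population, with per-trajectory
#' ground-truth labels.
#'
#' @param n_particles total trajectories.
#' @param fraction_confined ground-truth confined fraction in `[0, 1]`.
#' @param d_free free-population diffusion coefficient, um^2/s.
#' @param d_confined confined-population diffusion coefficient, um^2/s.
#' @param confinement_radius boundary radius, um.
#' @param n_steps,step_interval,localization_sigma,field_size_um,seed as in
#'   [sim_config()].
#' @return list with `tracks` and `truth` (`truth$confined_track` is the
#'   per-trajectory logical label).
#' @export
simulate_translation_mixture <- function(n_particles, fraction_confined,
                                         d_free = 0.1, d_confined = 0.5,
                                         confinement_radius = 0.1,
                                         n_steps = 20, step_interval = 1,
                                         localization_sigma = 0.02,
                                         field_size_um = 20, seed = 1) {
  cfg <- sim_config(
    diffusion_coefficients = c(d_confined, d_free),
    fractions = c(fraction_confined, 1 - fraction_confined),
    dimensionality = 2, step_interval = step_interval, n_steps = n_steps,
    n_particles = n_particles, localization_sigma = localization_sigma,
    confinement_radius = c(confinement_radius, NA),
    field_size_um = field_size_um, seed = seed
  )
  out <- simulate_confined(cfg)
  out$truth$fraction_confined <- fraction_confined
  out$truth$confined_track <- out$truth$population == 1L
  out
}

#' Synthesize an ER tubule network image with known junctions
#'
#' Builds a connected planar tubule graph and rasterizes it: branch nodes
#' are placed on a jittered grid and connected by the grid's 4-neighbour
#' lattice (polygonal tubule networks with near-orthogonal three- and
#' four-way intersections, the geometry of the peripheral ER); nodes of
#' degree below three receive short terminal stubs until every recorded
#' junction is a genuine three-way (or higher) tubule intersection. The
#' recorded ground truth is the set of node coordinates.
#'
#' @param n_junctions number of branch nodes (0 gives a single straight
#'   tubule and an empty junction list).
#' @param field_size_um side of the square field, um.
#' @param tubule_width_um rendered tubule width, um.
#' @param pixel_size um/pixel of the rendered image.
#' @param seed RNG seed.
#' @return list with `image` (binary `ImageStack`) and `truth` (list with
#'   `junctions`: data.frame `x_um`, `y_um`; and `segments`).
#' @export
synth_er_network <- function(n_junctions, field_size_um = 20,
                             tubule_width_um = 0.2, pixel_size = 0.05,
                             seed = 1) {
  stopifnot(n_junctions >= 0)
  with_sim_seed(seed, {
    if (n_junctions == 0) {
      y0 <- field_size_um / 2
      segs <- matrix(c(field_size_um * 0.1, y0, field_size_um * 0.9, y0),
                     ncol = 4)
      img <- rasterize_segments(segs, field_size_um, tubule_width_um,
                                pixel_size)
      return(list(image = img,
                  truth = list(junctions = data.frame(x_um = numeric(0),
                                                      y_um = numeric(0)),
                               segments = segs)))
    }
    layout <- grid_graph_nodes(n_junctions, field_size_um)
    nodes <- layout$nodes
    segs <- layout$segments
    deg <- node_degrees(nodes, segs)
    stub_len <- min(1.0, field_size_um / 8)
    for (i in seq_len(nrow(nodes))) {
      while (deg[i] < 3) {
        dir <- stub_direction(nodes, segs, i, stub_len, field_size_um,
                              tubule_width_um)
        end <- nodes[i, ] + stub_len * dir
        segs <- rbind(segs, c(nodes[i, 1], nodes[i, 2], end[1], end[2]))
        deg[i] <- deg[i] + 1
      }
    }
    img <- rasterize_segments(segs, field_size_um, tubule_width_um,
                              pixel_size)
    list(image = img,
         truth = list(junctions = data.frame(x_um = nodes[, 1],
                                             y_um = nodes[, 2]),
                      segments = segs))
  })
}

# Branch nodes on a jittered grid, connected by the grid's 4-neighbour
# lattice (first n cells in row-major order, which is always connected).
# Near-orthogonal tubule incidences keep every junction resolvable: at
# shallow intersection angles the skeleton branch point migrates along the
# tubule by ~width/tan(angle/2) and the junction becomes undetectable at
# imaging resolution, so the fixture avoids them by construction.
grid_graph_nodes <- function(n, field) {
  g <- ceiling(sqrt(n))
  cell <- field / (g + 1)
  idx <- seq_len(n) - 1L
  gx <- idx %% g + 1L
  gy <- idx %/% g + 1L
  jit <- matrix(stats::runif(2 * n, -0.15 * cell, 0.15 * cell), ncol = 2)
  nodes <- cbind(gx, gy) * cell + jit
  segs <- matrix(numeric(0), ncol = 4)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (abs(gx[i] - gx[j]) + abs(gy[i] - gy[j]) == 1L) {
        segs <- rbind(segs, c(nodes[i, ], nodes[j, ]))
      }
    }
  }
  list(nodes = nodes, segments = segs)
}

node_degrees <- function(nodes, segs, tol = 1e-9) {
  deg <- integer(nrow(nodes))
  if (nrow(segs) == 0) return(deg)
  for (i in seq_len(nrow(nodes))) {
    a <- abs(segs[, 1] - nodes[i, 1]) < tol & abs(segs[, 2] - nodes[i, 2]) < tol
    b <- abs(segs[, 3] - nodes[i, 1]) < tol & abs(segs[, 4] - nodes[i, 2]) < tol
    deg[i] <- sum(a) + sum(b)
  }
  deg
}

# pick a stub direction with maximal angular clearance from the edges already
# incident at node i, rejecting candidates whose stub would pass near any
# existing segment or leave the field
stub_direction <- function(nodes, segs, i, stub_len, field, width) {
  p <- nodes[i, ]
  inc <- numeric(0)
  if (nrow(segs) > 0) {
    for (k in seq_len(nrow(segs))) {
      if (all(abs(segs[k, 1:2] - p) < 1e-9)) {
        inc <- c(inc, atan2(segs[k, 4] - p[2], segs[k, 3] - p[1]))
      } else if (all(abs(segs[k, 3:4] - p) < 1e-9)) {
        inc <- c(inc, atan2(segs[k, 2] - p[2], segs[k, 1] - p[1]))
      }
    }
  }
  # axis-aligned candidates first: thinning erodes the tips of diagonal
  # strokes much faster than axis-aligned ones, so axis stubs survive
  # skeletonization intact; diagonals remain as fallback
  cand <- c(0, pi / 2, pi, 3 * pi / 2,
            seq(pi / 4, 2 * pi, by = pi / 4),
            seq(0, 2 * pi, length.out = 25)[-25])
  clearance <- vapply(cand, function(a) {
    if (length(inc) == 0) return(pi)
    min(abs(((a - inc + pi) %% (2 * pi)) - pi))
  }, numeric(1))
  # keep the listed priority (axes first) among directions with at least
  # 45 degrees of clearance from the incident tubules
  ord <- c(which(clearance >= pi / 4), setdiff(order(-clearance),
                                               which(clearance >= pi / 4)))
  for (a in cand[ord]) {
    dir <- c(cos(a), sin(a))
    end <- p + stub_len * dir
    if (any(end < 0.5) || any(end > field - 0.5)) next
    ok <- TRUE
    if (nrow(segs) > 0) {
      mid <- p + 0.6 * stub_len * dir
      for (k in seq_len(nrow(segs))) {
        shares_node <- all(abs(segs[k, 1:2] - p) < 1e-9) ||
          all(abs(segs[k, 3:4] - p) < 1e-9)
        if (shares_node) next
        dmin <- min(point_segment_distance(end[1], end[2], segs[k, ]),
                    point_segment_distance(mid[1], mid[2], segs[k, ]))
        if (dmin < 3 * width) { ok <- FALSE; break }
      }
    }
    if (ok) return(dir)
  }
  # fall back to the best-clearance direction even if crowded
  a <- cand[which.max(clearance)]
  c(cos(a), sin(a))
}

point_segment_distance <- function(px, py, seg) {
  vx <- seg[3] - seg[1]; vy <- seg[4] - seg[2]
  wx <- px - seg[1]; wy <- py - seg[2]
  L2 <- vx^2 + vy^2
  tt <- if (L2 == 0) 0 else pmin(1, pmax(0, (wx * vx + wy * vy) / L2))
  sqrt((wx - tt * vx)^2 + (wy - tt * vy)^2)
}

rasterize_segments <- function(segs, field, width, pixel_size) {
  n_px <- round(field / pixel_size)
  img <- matrix(0, nrow = n_px, ncol = n_px)
  half <- width / 2
  xs <- pixel_to_um(seq_len(n_px), pixel_size)
  for (k in seq_len(nrow(segs))) {
    s <- segs[k, ]
    cmin <- max(1L, um_to_pixel(min(s[1], s[3]) - half, pixel_size))
    cmax <- min(n_px, um_to_pixel(max(s[1], s[3]) + half, pixel_size))
    rmin <- max(1L, um_to_pixel(min(s[2], s[4]) - half, pixel_size))
    rmax <- min(n_px, um_to_pixel(max(s[2], s[4]) + half, pixel_size))
    if (cmin > cmax || rmin > rmax) next
    grid <- expand.grid(r = rmin:rmax, c = cmin:cmax)
    d <- point_segment_distance_vec(xs[grid$c], xs[grid$r], s)
    hit <- d <= half
    img[cbind(grid$r[hit], grid$c[hit])] <- 1
  }
  image_stack(img, pixel_size)
}

point_segment_distance_vec <- function(px, py, seg) {
  vx <- seg[3] - seg[1]; vy <- seg[4] - seg[2]
  wx <- px - seg[1]; wy <- py - seg[2]
  L2 <- vx^2 + vy^2
  tt <- if (L2 == 0) rep(0, length(px)) else
    pmin(1, pmax(0, (wx * vx + wy * vy) / L2))
  sqrt((wx - tt * vx)^2 + (wy - tt * vy)^2)
}

#' Synthesize FRAP and recruitment time series
#'
#' Generates noiseless or Gaussian-noised kinetic fixtures with known
#' half-time `log(2) / rate`.
#'
#' `frap`: `n_prebleach` frames at the pre-bleach level `plateau`, an
#' instantaneous bleach to `bleach_depth * plateau`, then saturating
#' exponential recovery towards `recovery_level` with rate constant `rate`.
#' `recruitment`: `n_pre` frames at `baseline`, then
#' `I(t) = baseline + plateau * (1 - exp(-rate * t))` from the activation
#' frame.
#'
#' @param kind `"frap"` or `"recruitment"`.
#' @param plateau pre-bleach level (frap) or saturation amplitude above
#'   baseline (recruitment), arbitrary units.
#' @param rate recovery/recruitment rate constant, 1/s (half-time
#'   `log(2)/rate`); 0 gives no recovery.
#' @param noise_sd Gaussian noise standard deviation, a.u.
#' @param seed RNG seed (used only when `noise_sd > 0`).
#' @param frame_interval seconds per frame.
#' @param n_frames post-event frames.
#' @param n_pre pre-event frames (the FRAP protocol's 10 pre-bleach frames).
#' @param baseline recruitment pre-activation level, a.u. (default 1, the
#'   level of a pre-activation-normalized signal).
#' @param bleach_depth post-bleach intensity as a fraction of `plateau`.
#' @param recovery_level FRAP recovery asymptote (defaults to full recovery
#'   at the pre-bleach level).
#' @return list with `trace` (a [kinetic_trace()]) and `truth` (list with
#'   `t_half`, `rate`, `plateau`).
#' @export
synth_kinetic_trace <- function(kind = c("frap", "recruitment"),
                                plateau = 1, rate = log(2) / 7.9,
                                noise_sd = 0, seed = 1,
                                frame_interval = 1, n_frames = 120,
                                n_pre = 10, baseline = 1,
                                bleach_depth = 0.2,
                                recovery_level = plateau) {
  kind <- match.arg(kind)
  stopifnot(rate >= 0, noise_sd >= 0, n_pre >= 1, n_frames >= 2)
  t_post <- (0:(n_frames - 1)) * frame_interval
  t_pre <- -(n_pre:1) * frame_interval
  if (kind == "frap") {
    bleach <- bleach_depth * plateau
    post <- if (rate == 0) rep(bleach, n_frames) else
      bleach + (recovery_level - bleach) * (1 - exp(-rate * t_post))
    intens <- c(rep(plateau, n_pre), post)
  } else {
    post <- if (rate == 0) rep(baseline, n_frames) else
      baseline + plateau * (1 - exp(-rate * t_post))
    intens <- c(rep(baseline, n_pre), post)
  }
  if (noise_sd > 0) {
    intens <- with_sim_seed(seed,
                            intens + stats::rnorm(length(intens),
                                                  sd = noise_sd))
  }
  trace <- kinetic_trace(c(t_pre, t_post), intens, event_index = n_pre + 1L)
  list(trace = trace,
       truth = list(t_half = if (rate > 0) log(2) / rate else Inf,
                    rate = rate, plateau = plateau, kind = kind))
}

#' Synthesize puncta whose intensity depends on organelle distance
#'
#' Places puncta uniformly in a field containing reference points (e.g.
#' lysosome centres) and assigns each punctum an intensity from a supplied
#' distance-response function plus Gaussian noise — the fixture for
#' distance-binned intensity profiles.
#'
#' @param n_puncta number of puncta.
#' @param refs data.frame/matrix of reference `x_um`, `y_um`.
#' @param field_size_um field side, um.
#' @param intensity_fun function of distance (um) returning mean intensity.
#' @param noise_sd intensity noise sd.
#' @param seed RNG seed.
#' @return data.frame `x_um`, `y_um`, `min_dist_um`, `intensity`.
#' @export
synth_distance_puncta <- function(n_puncta, refs, field_size_um = 20,
                                  intensity_fun = function(d) 1,
                                  noise_sd = 0, seed = 1) {
  refs <- as.matrix(refs)
  with_sim_seed(seed, {
    xy <- matrix(stats::runif(2 * n_puncta, 0, field_size_um), ncol = 2)
    d <- nearest_distance(xy, refs)
    inten <- vapply(d, intensity_fun, numeric(1)) +
      stats::rnorm(n_puncta, sd = noise_sd)
    data.frame(x_um = xy[, 1], y_um = xy[, 2], min_dist_um = d,
               intensity = inten)
  })
}
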