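test_that("a + cross yields one junction at its centre", {
  px <- 0.05
  img <- matrix(0, 100, 100)
  img[48:52, 10:90] <- 1
  img[10:90, 48:52] <- 1
  j <- detect_junctions(image_stack(img, px))
  expect_equal(nrow(j), 1)
  centre <- (50 - 0.5) * px
  expect_lt(abs(j$x_um - centre), px)
  expect_lt(abs(j$y_um - centre), px)
})

test_that("a straight tubule has no junctions", {
  px <- 0.05
  img <- matrix(0, 100, 100)
  img[48:52, 10:90] <- 1
  j <- detect_junctions(image_stack(img, px))
  expect_equal(nrow(j), 0)
  expect_warning(j0 <- detect_junctions(image_stack(img * 0 + 0.0, px),
                                        threshold = 0.5),
                 "empty skeleton")
  expect_equal(nrow(j0), 0)
})

test_that("synthetic networks are detected with high precision and recall", {
  for (sd in c(1, 33)) {
    net <- synth_er_network(25, tubule_width_um = 0.2, seed = sd)
    j <- detect_junctions(net$image, merge_radius = 0.25)
    score <- junction_detection_score(j, net$truth$junctions, tol_um = 0.25)
    expect_gte(score$precision, 0.95)
    expect_gte(score$recall, 0.95)
  }
})

test_that("nearest distances match a double-loop oracle", {
  expect_equal(nearest_distance(cbind(1, 2), cbind(1, 2)), 0)
  expect_equal(nearest_distance(cbind(0, 0), cbind(1, 0)), 1.0)
  set.seed(31)
  pts <- matrix(runif(2000, 0, 10), ncol = 2)
  refs <- matrix(runif(60, 0, 10), ncol = 2)
  expect_equal(nearest_distance(pts, refs),
               brute_nearest_distance(pts, refs), tolerance = 1e-12)
  expect_error(nearest_distance(pts, refs[0, , drop = FALSE]), "non-empty")
})

test_that("proximity statistics are invariant under rigid transforms", {
  set.seed(32)
  pts <- matrix(runif(100, 0, 10), ncol = 2)
  refs <- matrix(runif(20, 0, 10), ncol = 2)
  d0 <- nearest_distance(pts, refs)
  f0 <- fraction_within_radius(pts, refs, 0.5)
  theta <- 1.1
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  shift <- c(3, -7)
  ptsT <- sweep(pts %*% R, 2, shift, "+")
  refsT <- sweep(refs %*% R, 2, shift, "+")
  expect_equal(nearest_distance(ptsT, refsT), d0, tolerance = 1e-9)
  expect_equal(fraction_within_radius(ptsT, refsT, 0.5), f0)
})

test_that("fraction within radius counts exactly like brute force", {
  expect_equal(fraction_within_radius(cbind(c(1, 2), c(1, 2)),
                                      cbind(c(1, 2), c(1, 2))), 1.0)
  far <- cbind(c(5, 6), c(5, 6))
  refs <- cbind(0, 0)
  expect_equal(fraction_within_radius(far, refs, 0.3), 0.0)
  set.seed(33)
  pts <- matrix(runif(400, 0, 5), ncol = 2)
  rf <- matrix(runif(30, 0, 5), ncol = 2)
  expect_equal(fraction_within_radius(pts, rf, 0.3),
               mean(brute_nearest_distance(pts, rf) <= 0.3))
  expect_error(fraction_within_radius(pts[0, , drop = FALSE], rf),
               "non-empty")
})

test_that("puncta match within 2 pixels and not beyond", {
  ts <- trajectory_set(make_lattice_track(5, step = 0, start = c(2, 2)),
                       1, 0.1)
  exact <- data.frame(x_um = 2, y_um = 2, frame = 0)
  m <- match_puncta_to_tracks(exact, ts)
  expect_equal(nrow(m$matches), 1)
  expect_equal(m$positive_tracks, 1)
  # 3 pixels away -> unmatched
  off <- data.frame(x_um = 2 + 3 * 0.1, y_um = 2, frame = 0)
  m2 <- match_puncta_to_tracks(off, ts)
  expect_equal(nrow(m2$matches), 0)
  expect_equal(m2$unmatched_puncta, 1)
})

test_that("greedy matching equals optimal on non-conflicting layouts", {
  set.seed(34)
  for (rep in 1:10) {
    # well-separated track positions, puncta jittered near a subset
    n_tracks <- sample(3:6, 1)
    centres <- cbind(seq_len(n_tracks) * 3, seq_len(n_tracks) * 2)
    spots <- do.call(rbind, lapply(seq_len(n_tracks), function(id) {
      data.frame(track_id = id, frame = 0:1, t_s = 0:1,
                 x_um = centres[id, 1], y_um = centres[id, 2],
                 intensity = NA_real_)
    }))
    ts <- trajectory_set(spots, 1, 0.1)
    n_puncta <- sample(2:8, 1)
    near <- sample(n_tracks, min(n_puncta, n_tracks))
    pun <- data.frame(
      x_um = c(centres[near, 1] + runif(length(near), -0.1, 0.1),
               runif(n_puncta - length(near), 20, 30)),
      y_um = c(centres[near, 2] + runif(length(near), -0.1, 0.1),
               runif(n_puncta - length(near), 20, 30)),
      frame = 0)
    m <- match_puncta_to_tracks(pun, ts, max_pixels = 2)
    sp0 <- ts$spots[ts$spots$frame == 0, ]
    dmat <- sqrt(outer(pun$x_um, sp0$x_um, "-")^2 +
                   outer(pun$y_um, sp0$y_um, "-")^2)
    expect_equal(nrow(m$matches),
                 brute_max_matching(dmat, 2 * ts$pixel_size))
  }
})

test_that("each punctum matches at most one trajectory per frame", {
  # two tracks both within radius of one punctum
  spots <- rbind(make_lattice_track(3, step = 0, start = c(2, 2),
                                    track_id = 1),
                 make_lattice_track(3, step = 0, start = c(2.1, 2),
                                    track_id = 2))
  ts <- trajectory_set(spots, 1, 0.1)
  pun <- data.frame(x_um = 2.04, y_um = 2, frame = c(0, 1, 2))
  m <- match_puncta_to_tracks(pun, ts)
  expect_equal(as.vector(table(m$matches$frame)), rep(1L, 3))
  # nearest-first: track 1 at distance 0.04 wins over track 2 at 0.06
  expect_true(all(m$matches$track_id == 1))
})

test_that("distance-independent intensity gives a flat unit profile", {
  set.seed(35)
  d <- runif(500, 0.5, 4.5)
  prof <- proximity_profile(d, rep(7, 500))
  expect_equal(nrow(prof), 8)
  expect_equal(prof$bin_center_um, seq(0.75, 4.25, 0.5))
  expect_equal(prof$normalized, rep(1, 8))
  expect_equal(prof$normalized[8], 1)  # reference bin exactly 1
})

test_that("step intensity shows up as a near/far bin ratio", {
  set.seed(36)
  d <- runif(4000, 0.5, 4.5)
  inten <- ifelse(d < 2, 2, 1)
  prof <- proximity_profile(d, inten)
  near <- prof$normalized[prof$bin_center_um <= 1.75]
  far <- prof$normalized[prof$bin_center_um >= 2.75]
  expect_equal(mean(near) / mean(far), 2, tolerance = 0.02)
})

test_that("profile bins are half-open with support [0.5, 4.5)", {
  # distances outside the support never enter a bin
  d <- c(0.2, 0.49, 4.5, 5.0, 0.5, 4.49)
  prof <- proximity_profile(d, rep(1, 6))
  expect_equal(sum(prof$n), 2L)  # only 0.5 and 4.49 fall in bins
  expect_equal(prof$n[1], 1L)
  expect_equal(prof$n[8], 1L)
  # edge at 1.0 belongs to the 1.25 bin (half-open)
  p2 <- proximity_profile(c(1.0, 4.3), c(5, 1))
  expect_equal(p2$n[1], 0L)
  expect_equal(p2$n[2], 1L)
})

test_that("an empty reference bin blocks normalization", {
  d <- runif(100, 0.5, 3.0)
  expect_error(proximity_profile(d, rep(1, 100)), "4.25")
  expect_error(proximity_profile(1:3, 1:2), "equal length")
})

test_that("rendered movies separate labels and conserve intensity", {
  spots <- rbind(make_lattice_track(3, step = 0, start = c(1, 1),
                                    track_id = 1),
                 make_lattice_track(3, step = 0.4, start = c(3, 3),
                                    track_id = 2))
  ts <- trajectory_set(spots, 1, 0.1)
  labels <- c("translating", "non_translating")
  out <- render_classified_movie(ts, labels, field_size_um = 6,
                                 blur_sigma = 0.05)
  # translating stack contains only track 1's signal
  expect_equal(sum(out$translating$pixels > 1e-6 * max(out$translating$pixels)) > 0, TRUE)
  for (k in 1:3) {
    expect_equal(sum(out$translating$pixels[, , k]), 1, tolerance = 0.02)
    expect_equal(sum(out$non_translating$pixels[, , k]), 1, tolerance = 0.02)
  }
  # blur_sigma = 0 leaves single-pixel spots
  raw <- render_classified_movie(ts, labels, field_size_um = 6,
                                 blur_sigma = 0)
  expect_equal(sum(raw$translating$pixels[, , 1] > 0), 1)
  expect_warning(
    render_classified_movie(ts, labels, field_size_um = 2),
    "clipped")
})
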