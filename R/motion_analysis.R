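#' Classification configuration
#'
#' Thresholds and minima used by the translation-state classifier. Defaults
#' are the study values: a per-trajectory MSD cut-off of 0.055 um^2 at lag
#' 1 s for mRNA (strictly below = translating), an effective cut-off of
#' 0.04 um^2 for ribosomes, and a minimum of 10 localizations per trajectory
#' for classification.
#'
#' @param msd_threshold mRNA translation cut-off on lag-`lag` MSD, um^2.
#' @param ribosome_threshold slow-ribosome cut-off, um^2.
#' @param min_localizations minimum localizations for a trajectory to be
#'   classified (>= 2).
#' @param lag MSD lag time, seconds.
#' @return object of class `ClassificationConfig`.
#' @export
classification_config <- function(msd_threshold = 0.055,
                                  ribosome_threshold = 0.04,
                                  min_localizations = 10, lag = 1) {
  stopifnot(msd_threshold > 0, ribosome_threshold > 0,
            min_localizations >= 2, lag > 0)
  structure(list(msd_threshold = msd_threshold,
                 ribosome_threshold = ribosome_threshold,
                 min_localizations = as.integer(min_localizations),
                 lag = lag),
            class = "ClassificationConfig")
}

#' Per-trajectory MSD and translation-state classification
#'
#' For each trajectory, averages the squared displacement between
#' consecutive frames at the configured lag:
#' `MSD_tau = sum_i ((x_{i+1} - x_i)^2 + (y_{i+1} - y_i)^2) / n`
#' over all available lag pairs, then labels the trajectory `translating`
#' when `MSD_tau` falls strictly below the threshold, `non_translating`
#' otherwise, and `unclassified` when it has fewer than `min_localizations`
#' points. Frame gaps (missed detections) are skipped, counted and warned
#' about rather than treated as longer lags.
#'
#' @param ts a `TrajectorySet` whose frame interval matches `cfg$lag` (the
#'   lag must be an integer number of frames).
#' @param cfg a [classification_config()].
#' @param threshold which cut-off to apply: `"mrna"` (0.055 um^2 default) or
#'   `"ribosome"` (0.04 um^2 default).
#' @return data.frame of class `TrajectoryMsd` with columns `track_id`,
#'   `msd_lag1_um2`, `n_disp`, `label`; attribute `threshold_um2` records
#'   the cut-off used, `lag_s` the lag.
#' @export
trajectory_msd <- function(ts, cfg = classification_config(),
                           threshold = c("mrna", "ribosome")) {
  stopifnot(inherits(ts, "TrajectorySet"),
            inherits(cfg, "ClassificationConfig"))
  threshold <- match.arg(threshold)
  lag_frames <- cfg$lag / ts$frame_interval
  if (abs(lag_frames - round(lag_frames)) > 1e-6) {
    stop("cfg$lag must be an integer multiple of the frame interval")
  }
  lag_frames <- as.integer(round(lag_frames))
  ids <- ts$tracks$track_id
  msd <- n_disp <- numeric(length(ids))
  n_gap <- 0L
  for (k in seq_along(ids)) {
    tr <- ts$spots[ts$spots$track_id == ids[k], , drop = FALSE]
    if (nrow(tr) <= lag_frames) {
      msd[k] <- NA_real_; n_disp[k] <- 0
      next
    }
    # displacement pairs exactly lag_frames apart; others are gaps
    i1 <- seq_len(nrow(tr) - lag_frames)
    ok <- (tr$frame[i1 + lag_frames] - tr$frame[i1]) == lag_frames
    n_gap <- n_gap + sum(!ok)
    if (!any(ok)) { msd[k] <- NA_real_; n_disp[k] <- 0; next }
    dx <- tr$x_um[i1 + lag_frames][ok] - tr$x_um[i1][ok]
    dy <- tr$y_um[i1 + lag_frames][ok] - tr$y_um[i1][ok]
    msd[k] <- mean(dx^2 + dy^2)
    n_disp[k] <- sum(ok)
  }
  if (n_gap > 0) {
    warning(n_gap, " displacement pair(s) skipped due to frame gaps")
  }
  out <- data.frame(track_id = ids, msd_lag1_um2 = msd,
                    n_disp = as.integer(n_disp),
                    label = "unclassified", stringsAsFactors = FALSE)
  out <- classify_translation(out, cfg,
                              n_points = ts$tracks$n_points,
                              threshold = threshold)
  class(out) <- c("TrajectoryMsd", "data.frame")
  attr(out, "lag_s") <- cfg$lag
  out
}

#' Apply the translation-state cut-off
#'
#' Labels trajectories `translating` when their per-trajectory MSD is
#' strictly below the cut-off and `non_translating` otherwise; ties at the
#' threshold are non-translating. Trajectories with fewer than
#' `min_localizations` points remain `unclassified`.
#'
#' @param msd data.frame with `msd_lag1_um2` and `n_disp` columns (e.g. from
#'   [trajectory_msd()]).
#' @param cfg a [classification_config()].
#' @param n_points optional per-trajectory localization counts; defaults to
#'   `n_disp + 1` (no-gap assumption).
#' @param threshold `"mrna"` or `"ribosome"` cut-off.
#' @return the input with its `label` column set; attribute `threshold_um2`
#'   records the cut-off applied.
#' @export
classify_translation <- function(msd, cfg = classification_config(),
                                 n_points = NULL,
                                 threshold = c("mrna", "ribosome")) {
  threshold <- match.arg(threshold)
  thr <- if (threshold == "mrna") cfg$msd_threshold else
    cfg$ribosome_threshold
  if (is.null(n_points)) n_points <- msd$n_disp + 1L
  classified <- n_points >= cfg$min_localizations & !is.na(msd$msd_lag1_um2)
  msd$label <- ifelse(!classified, "unclassified",
                      ifelse(msd$msd_lag1_um2 < thr, "translating",
                             "non_translating"))
  attr(msd, "threshold_um2") <- thr
  msd
}

#' Translating fraction
#'
#' Fraction of classified trajectories labelled `translating`; unclassified
#' trajectories are excluded from both numerator and denominator.
#'
#' @param msd a `TrajectoryMsd` table (or any data.frame with a `label`
#'   column).
#' @return fraction in `[0, 1]`.
#' @export
translating_fraction <- function(msd) {
  lab <- msd$label
  classified <- lab %in% c("translating", "non_translating")
  if (!any(classified)) {
    stop("no classified trajectories: cannot compute a translating fraction")
  }
  sum(lab == "translating") / sum(classified)
}

#' Ensemble (population) MSD
#'
#' Averages the squared displacement over all trajectory pairs at each
#' multiple of the frame interval up to `max_lag` seconds. Lags at which no
#' trajectory contributes a pair are omitted. Frame gaps contribute no
#' pairs.
#'
#' @param ts a `TrajectorySet`.
#' @param max_lag largest lag time, seconds.
#' @return data.frame of class `EnsembleMsd` with `lag_s`, `msd_um2`,
#'   `n_pairs`.
#' @export
ensemble_msd <- function(ts, max_lag) {
  stopifnot(inherits(ts, "TrajectorySet"), max_lag > 0)
  dt <- ts$frame_interval
  max_k <- floor(max_lag / dt + 1e-9)
  if (max_k < 1) stop("max_lag shorter than one frame interval")
  sums <- counts <- numeric(max_k)
  for (id in ts$tracks$track_id) {
    tr <- ts$spots[ts$spots$track_id == id, , drop = FALSE]
    n <- nrow(tr)
    for (k in seq_len(min(max_k, n - 1))) {
      i1 <- seq_len(n - k)
      ok <- (tr$frame[i1 + k] - tr$frame[i1]) == k
      if (!any(ok)) next
      dx <- tr$x_um[i1 + k][ok] - tr$x_um[i1][ok]
      dy <- tr$y_um[i1 + k][ok] - tr$y_um[i1][ok]
      sums[k] <- sums[k] + sum(dx^2 + dy^2)
      counts[k] <- counts[k] + sum(ok)
    }
  }
  keep <- counts > 0
  out <- data.frame(lag_s = (seq_len(max_k) * dt)[keep],
                    msd_um2 = (sums / pmax(counts, 1))[keep],
                    n_pairs = as.integer(counts[keep]))
  class(out) <- c("EnsembleMsd", "data.frame")
  out
}

#' Apparent diffusion coefficient from the ensemble MSD
#'
#' Ordinary least-squares line through the first `n_fit_points` ensemble MSD
#' points, interpreted with the 2D diffusion-with-static-error model
#' `MSD(tau) = 4 * D_app * tau + 4 * sigma^2`: `D_app` is the slope over 4
#' and `sigma` the square root of the intercept over 4. Only the first few
#' lags are used because confined trajectories bend the curve at longer
#' lags. Negative slope or intercept are clamped to zero and flagged.
#'
#' @param ens an [ensemble_msd()] table.
#' @param n_fit_points number of leading lags to fit (default 4).
#' @return list of class `EnsembleMsdFit` with `d_app` (um^2/s), `sigma`
#'   (um), `n_dimensions = 2`, `n_fit_points`, `clamped` flags and the `lm`
#'   fit.
#' @export
fit_dapp <- function(ens, n_fit_points = 4) {
  stopifnot(is.data.frame(ens), n_fit_points >= 2)
  if (nrow(ens) < n_fit_points) {
    stop("need at least ", n_fit_points, " ensemble MSD points")
  }
  d <- ens[seq_len(n_fit_points), ]
  fit <- stats::lm(msd_um2 ~ lag_s, data = d)
  slope <- unname(stats::coef(fit)[2])
  icpt <- unname(stats::coef(fit)[1])
  n_dim <- 2
  clamped <- c(d_app = FALSE, sigma = FALSE)
  d_app <- slope / (2 * n_dim)
  if (d_app < 0) { d_app <- 0; clamped["d_app"] <- TRUE }
  sigma <- if (icpt >= 0) sqrt(icpt) / 2 else { clamped["sigma"] <- TRUE; 0 }
  structure(list(d_app = d_app, sigma = sigma, n_dimensions = n_dim,
                 n_fit_points = n_fit_points, clamped = clamped, fit = fit),
            class = "EnsembleMsdFit")
}

#' @export
print.EnsembleMsdFit <- function(x, ...) {
  cat(sprintf("Ensemble MSD fit (first %d lags): D_app = %.4g um^2/s, sigma = %.4g um\n",
              x$n_fit_points, x$d_app, x$sigma))
  if (any(x$clamped)) cat("  note: clamped at zero:",
                          paste(names(x$clamped)[x$clamped], collapse = ", "),
                          "\n")
  invisible(x)
}

#' Pooled single-lag displacements
#'
#' Extracts the pooled set of displacement magnitudes `r` at a fixed lag
#' time from every trajectory — the sample that the displacement-CDF mixture
#' model is fitted to.
#'
#' @param ts a `TrajectorySet`.
#' @param lag_t lag time, seconds (integer multiple of the frame interval).
#' @return numeric vector of displacements, um (class `DisplacementSample`,
#'   attribute `lag_t`).
#' @export
displacements <- function(ts, lag_t = ts$frame_interval) {
  stopifnot(inherits(ts, "TrajectorySet"))
  k <- lag_t / ts$frame_interval
  if (abs(k - round(k)) > 1e-6 || k < 1) {
    stop("lag_t must be a positive integer multiple of the frame interval")
  }
  k <- as.integer(round(k))
  out <- numeric(0)
  for (id in ts$tracks$track_id) {
    tr <- ts$spots[ts$spots$track_id == id, , drop = FALSE]
    if (nrow(tr) <= k) next
    i1 <- seq_len(nrow(tr) - k)
    ok <- (tr$frame[i1 + k] - tr$frame[i1]) == k
    dx <- tr$x_um[i1 + k][ok] - tr$x_um[i1][ok]
    dy <- tr$y_um[i1 + k][ok] - tr$y_um[i1][ok]
    out <- c(out, sqrt(dx^2 + dy^2))
  }
  structure(out, lag_t = lag_t, class = c("DisplacementSample", "numeric"))
}

#' Theoretical displacement CDF of a diffusion mixture
#'
#' `CDF(r) = 1 - sum_j A_j * exp(-r^2 / (4 * D_j * t))` — the cumulative
#' distribution of 2D displacement magnitudes for a mixture of Brownian
#' species with fractions `A_j` and diffusion coefficients `D_j` at lag `t`.
#'
#' @param r displacement magnitudes, um.
#' @param fractions mixture weights (summing to 1).
#' @param D diffusion coefficients, um^2/s.
#' @param lag_t lag time, s.
#' @return CDF values in `[0, 1]`.
#' @export
cdf_mixture_model <- function(r, fractions, D, lag_t) {
  stopifnot(length(fractions) == length(D))
  acc <- 0
  for (j in seq_along(D)) {
    acc <- acc + fractions[j] * exp(-r^2 / (4 * D[j] * lag_t))
  }
  1 - acc
}

#' Sample displacements from a diffusion mixture
#'
#' Draws displacement magnitudes directly from the mixture displacement
#' distribution (Rayleigh per component with scale `sqrt(2 * D * t)`),
#' providing the generator-side oracle for CDF mixture fitting.
#'
#' @param n sample size.
#' @param fractions,D,lag_t mixture parameters as in [cdf_mixture_model()].
#' @param seed RNG seed.
#' @return numeric vector of `n` displacements (um) with attribute
#'   `component` giving each draw's ground-truth component.
#' @export
sample_cdf_mixture <- function(n, fractions, D, lag_t = 1, seed = 1) {
  stopifnot(length(fractions) == length(D), abs(sum(fractions) - 1) < 1e-8)
  with_sim_seed(seed, {
    comp <- sample.int(length(D), n, replace = TRUE, prob = fractions)
    # |N(0,2Dt)|^2 summed over 2 axes => r ~ Rayleigh(scale sqrt(2Dt))
    r <- sqrt(stats::rnorm(n, sd = sqrt(2 * D[comp] * lag_t))^2 +
                stats::rnorm(n, sd = sqrt(2 * D[comp] * lag_t))^2)
    structure(r, component = comp)
  })
}

#' Fit a multi-component displacement-CDF mixture
#'
#' Nonlinear least squares of the mixture model
#' `CDF(r) = 1 - sum_j A_j exp(-r^2 / (4 D_j t))` against the empirical CDF
#' of the pooled displacements (no binning: the ECDF is evaluated at the
#' sorted sample). Constraints `A_j >= 0`, `sum A_j = 1`, `D_j >= 0` are
#' enforced by parameterizing log-weights (normalized inside the model) and
#' log-diffusivities. Levenberg-Marquardt is run from several quantile-based
#' starts and the best residual sum of squares wins. When `n_components` is
#' `NULL`, models with 1-3 components are fitted and selected by BIC.
#' Components are reported in descending `D`; adjacent components whose `D`
#' differ by less than two-fold are merged in the report (weight-summed,
#' weight-averaged `D`) and flagged, since the model is not identifiable for
#' close diffusivities.
#'
#' @param r displacement sample (um), e.g. from [displacements()].
#' @param lag_t lag time of the sample, s.
#' @param n_components 1, 2 or 3, or `NULL` for BIC selection.
#' @param n_starts multi-start count per model size.
#' @param max_points ECDF points used in the fit (the sorted sample is
#'   thinned evenly above this size; keeps large samples fast without
#'   binning).
#' @return list of class `CdfMixtureFit`: `fractions`, `D` (descending),
#'   `lag_t`, `rss`, `n_components_used`, `merged` and `pruned` flags
#'   (components below 2% weight are dropped from the report as fitting
#'   noise), `bic`.
#' @export
fit_cdf_mixture <- function(r, lag_t = 1, n_components = NULL,
                            n_starts = 8, max_points = 2000) {
  r <- as.numeric(r)
  r <- r[is.finite(r) & r >= 0]
  if (length(r) < 10) stop("too few displacements to fit")
  if (length(r) < 100) {
    warning("fewer than 100 displacements: CDF fit will be unstable")
  }
  rs <- sort(r)
  n <- length(rs)
  ecdf_y <- seq_len(n) / n
  if (n > max_points) {
    idx <- unique(round(seq(1, n, length.out = max_points)))
    rs <- rs[idx]; ecdf_y <- ecdf_y[idx]
  }
  sizes <- if (is.null(n_components)) 1:3 else n_components
  stopifnot(all(sizes %in% 1:3))
  best <- NULL
  for (k in sizes) {
    fit <- fit_cdf_k(rs, ecdf_y, lag_t, k, n_starts)
    if (is.null(fit)) next
    # BIC on Gaussian residuals of the ECDF regression
    bic <- n * log(fit$rss / n) + (2 * k - 1) * log(n)
    fit$bic <- bic
    if (is.null(best) || bic < best$bic) best <- fit
  }
  if (is.null(best)) {
    stop("CDF mixture fit failed to converge from any start; ",
         "check the displacement sample (n = ", n, ", lag_t = ", lag_t, ")")
  }
  ord <- order(-best$D)
  D <- best$D[ord]; A <- best$A[ord]
  # negligible-weight components are fitting noise, not species
  pruned <- any(A < 0.02)
  if (pruned && any(A >= 0.02)) {
    D <- D[A >= 0.02]; A <- A[A >= 0.02]
    A <- A / sum(A)
  }
  merged <- FALSE
  j <- 1
  while (j < length(D)) {
    if (D[j] / D[j + 1] < 2) {
      Dm <- (A[j] * D[j] + A[j + 1] * D[j + 1]) / (A[j] + A[j + 1])
      Am <- A[j] + A[j + 1]
      D <- c(D[seq_len(j - 1)], Dm, D[-seq_len(j + 1)])
      A <- c(A[seq_len(j - 1)], Am, A[-seq_len(j + 1)])
      merged <- TRUE
    } else j <- j + 1
  }
  structure(list(fractions = A, D = D, lag_t = lag_t, rss = best$rss,
                 n_components_used = length(best$D), merged = merged,
                 pruned = pruned, bic = best$bic),
            class = "CdfMixtureFit")
}

fit_cdf_k <- function(rs, ecdf_y, lag_t, k, n_starts) {
  # starting D values from spread quantiles of the implied single-species D
  d_impl <- rs^2 / (4 * lag_t)
  d_impl <- d_impl[d_impl > 0]
  probs_sets <- lapply(seq_len(n_starts), function(s) {
    stats::quantile(d_impl,
                    probs = (seq_len(k) - 0.5) / k * (0.5 + 0.5 * s / n_starts))
  })
  model_resid <- function(par) {
    lw <- c(0, par[seq_len(k - 1)])
    w <- exp(lw) / sum(exp(lw))
    D <- exp(par[k:(2 * k - 1)])
    cdf_mixture_model(rs, w, D, lag_t) - ecdf_y
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    D0 <- pmax(as.numeric(probs_sets[[s]]), 1e-8)
    # jitter the start weights deterministically per start index
    w0 <- rep(0, k - 1) + 0.3 * (s %% 3 - 1)
    par0 <- c(w0, log(D0))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, fn = model_resid,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) {
      par <- fit$par
      lw <- c(0, par[seq_len(k - 1)])
      w <- exp(lw) / sum(exp(lw))
      best <- list(A = w, D = exp(par[k:(2 * k - 1)]), rss = rss)
    }
  }
  best
}

#' @export
print.CdfMixtureFit <- function(x, ...) {
  cat("Displacement-CDF mixture fit at lag", x$lag_t, "s:\n")
  for (j in seq_along(x$D)) {
    cat(sprintf("  component %d: A = %.3f, D = %.4g um^2/s\n",
                j, x$fractions[j], x$D[j]))
  }
  cat(sprintf("  rss = %.4g, %d component(s) fitted%s\n", x$rss,
              x$n_components_used,
              if (x$merged) " (close components merged)" else ""))
  invisible(x)
}
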