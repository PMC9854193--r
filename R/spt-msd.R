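#' Filter a track table by minimum consecutive duration
#'
#' Tracks shorter than \code{min_frames} consecutive frames carry too
#' little information for MSD model fitting and are removed (20 frames at
#' a 10-ms interval is 0.2 s of continuous observation). Malformed rows
#' (non-finite coordinates or missing frame numbers) are dropped with a
#' warning naming the offending row numbers.
#'
#' @param tracks data frame with columns \code{track_id}, \code{frame},
#'   \code{x_um}, \code{y_um} (and optionally \code{t_s}).
#' @param min_frames minimum number of consecutive frames.
#' @return the filtered track table.
#' @export
filter_tracks <- function(tracks, min_frames = 20L) {
  req <- c("track_id", "frame", "x_um", "y_um")
  stopifnot(all(req %in% names(tracks)))
  bad <- !is.finite(tracks$x_um) | !is.finite(tracks$y_um) |
    is.na(tracks$frame)
  if (any(bad)) {
    warning("dropping ", sum(bad), " malformed row(s): ",
            paste(head(which(bad), 10), collapse = ", "),
            if (sum(bad) > 10) ", ..." else "", call. = FALSE)
    tracks <- tracks[!bad, ]
  }
  if (!nrow(tracks)) {
    warning("empty track table", call. = FALSE)
    return(tracks)
  }
  keep_ids <- vapply(split(tracks$frame, tracks$track_id), function(fr) {
    fr <- sort(fr)
    # longest run of consecutive frame numbers
    max_run <- max(tapply(fr, cumsum(c(TRUE, diff(fr) != 1L)), length))
    max_run >= min_frames
  }, TRUE)
  tracks[tracks$track_id %in% names(keep_ids)[keep_ids], ]
}

#' Split a track table into trajectory objects
#'
#' @param tracks track table (\code{track_id}, \code{frame}, \code{x_um},
#'   \code{y_um}, optional \code{t_s}).
#' @param dt frame interval, seconds; inferred from \code{t_s} if absent.
#' @return named list of \code{\link{trajectory}} objects.
#' @export
split_tracks <- function(tracks, dt = NULL) {
  ids <- unique(tracks$track_id)
  setNames(lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, ]
    tr <- tr[order(tr$frame), ]
    dti <- dt %||% (if ("t_s" %in% names(tr) && nrow(tr) > 1)
      median(diff(tr$t_s)) else stop("'dt' required", call. = FALSE))
    trajectory(tr[, intersect(c("frame", "t_s", "x_um", "y_um"),
                              names(tr))], dt = dti, track_id = id)
  }), as.character(ids))
}

#' Time-averaged mean squared displacement of a trajectory
#'
#' For each lag \eqn{\ell}, averages the squared displacement over all
#' overlapping frame pairs \eqn{(i, i+\ell)}. The MSD at lag 0 is 0 by
#' definition and not stored.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param max_lag_frames largest lag to evaluate; truncated with a warning
#'   if it reaches the track length.
#' @return An \code{msd_curve}: data frame with columns \code{lag},
#'   \code{t_s}, \code{msd}, \code{n_pairs} and attribute \code{dt}.
#' @export
compute_msd <- function(traj, max_lag_frames = NULL) {
  n <- nrow(traj)
  if (n < 2) stop("need at least 2 frames", call. = FALSE)
  dt <- attr(traj, "dt")
  max_lag_frames <- max_lag_frames %||% (n - 1L)
  if (max_lag_frames >= n) {
    warning("max_lag_frames >= track length; truncated", call. = FALSE)
    max_lag_frames <- n - 1L
  }
  x <- traj$x_um; y <- traj$y_um
  lags <- seq_len(max_lag_frames)
  msd <- vapply(lags, function(l) {
    dx <- x[(1L + l):n] - x[1:(n - l)]
    dy <- y[(1L + l):n] - y[1:(n - l)]
    mean(dx * dx + dy * dy)
  }, 0)
  structure(data.frame(lag = lags, t_s = lags * dt, msd = msd,
                       n_pairs = n - lags),
            dt = dt, class = c("msd_curve", "data.frame"))
}

#' Ensemble (cohort-averaged) MSD
#'
#' Averages the time-averaged MSD curves of many trajectories at each lag,
#' weighting every track equally. Ensemble averaging suppresses the large
#' single-track fluctuations of time-averaged MSDs and is the curve used
#' for population-level parameter recovery.
#'
#' @param trajs list of \code{\link{trajectory}} objects (equal \code{dt}).
#' @param max_lag_frames largest lag.
#' @return An \code{msd_curve}.
#' @export
ensemble_msd <- function(trajs, max_lag_frames = 10L) {
  curves <- lapply(trajs, compute_msd, max_lag_frames = max_lag_frames)
  msd <- rowMeans(vapply(curves, `[[`, numeric(max_lag_frames), "msd"))
  out <- curves[[1]]
  out$msd <- msd
  out$n_pairs <- rowSums(vapply(curves, `[[`, numeric(max_lag_frames),
                                "n_pairs"))
  out
}

#' Anisotropy of a trajectory via principal radii of gyration
#'
#' The principal radii of gyration are the square roots of the eigenvalues
#' of the 2x2 positional covariance matrix. Their ratio (smaller/larger)
#' is 0 for perfectly collinear tracks and approaches 1 for isotropic
#' ones; a near-zero ratio is the signature of directed, linear motion.
#'
#' @param traj a \code{\link{trajectory}} with >= 3 frames.
#' @param of \code{"radii"} (default) takes the ratio of the radii;
#'   \code{"eigenvalues"} the ratio of the squared radii.
#' @return ratio in [0, 1]; a degenerate track (all points identical) is
#'   defined as 1 (isotropic limit) with attribute
#'   \code{degenerate = TRUE}.
#' @export
gyration_ratio <- function(traj, of = c("radii", "eigenvalues")) {
  of <- match.arg(of)
  if (nrow(traj) < 3) stop("need at least 3 frames", call. = FALSE)
  cm <- cov(cbind(traj$x_um, traj$y_um)) * (nrow(traj) - 1) / nrow(traj)
  ev <- sort(pmax(eigen(cm, symmetric = TRUE, only.values = TRUE)$values,
                  0), decreasing = TRUE)
  if (ev[1] <= 0)
    return(structure(1, degenerate = TRUE))
  r <- ev[2] / ev[1]
  if (of == "radii") r <- sqrt(r)
  structure(r, degenerate = FALSE)
}

#' Maximum displacement of a trajectory
#'
#' The largest Euclidean distance between any two positions of the track
#' (not the net start-to-end displacement). For long tracks only convex
#' hull vertices are compared.
#'
#' @param traj a \code{\link{trajectory}}.
#' @return distance in micrometres.
#' @export
max_displacement <- function(traj) {
  pts <- cbind(traj$x_um, traj$y_um)
  if (nrow(pts) > 50) {
    h <- tryCatch(grDevices::chull(pts), error = function(e) NULL)
    if (!is.null(h) && length(h) >= 2) pts <- pts[h, , drop = FALSE]
  }
  if (nrow(pts) < 2) return(0)
  max(dist(pts))
}

#' Fit MSD motion models to an MSD curve
#'
#' Fits, by nonlinear least squares over the chosen lags:
#' \itemize{
#'   \item the anomalous-diffusion power law
#'     \eqn{MSD(t) = 2 m D t^\alpha} with image dimensionality
#'     \eqn{m = 2}, the diffusive model (\eqn{\alpha = 1} is free
#'     Brownian motion; ballistic motion drives \eqn{\alpha} toward 2);
#'   \item the confinement model
#'     \eqn{MSD(t) = (L^2/3)\,(1 - e^{-t/\tau})}, whose plateau
#'     \eqn{L^2/3} is set by the confined microdomain size \eqn{L}, with
#'     derived diffusion coefficient \eqn{D = L^2/(12\tau)};
#'   \item the ballistic model \eqn{MSD(t) = (v t)^2} (closed-form least
#'     squares), used for tracks already recognized as directed.
#' }
#'
#' Starting values: \eqn{D_0 = MSD(\mathrm{lag 1})/(4\,\Delta t)},
#' \eqn{\alpha_0 = 1}, \eqn{L_0 = \sqrt{3\,\max MSD}}, \eqn{\tau_0} the
#' time to half-plateau. Bounds: \eqn{\alpha \in (0, 2]}, all other
#' parameters \eqn{\ge 0}. A model that fails to converge is marked
#' unavailable rather than raising an error.
#'
#' @param msd an \code{msd_curve}.
#' @param fit_lags integer lags used for fitting (default 1--10: the
#'   short-time regime, which still captures the plateau at
#'   equilibration times well below the observation window).
#' @return A \code{motion_fit_models} list with components
#'   \code{powerlaw} (\code{D}, \code{alpha}, \code{rss},
#'   \code{converged}), \code{confined} (\code{L}, \code{tau}, \code{D},
#'   \code{rss}, \code{converged}) and \code{directed} (\code{v},
#'   \code{rss}), plus \code{fit_lags} and \code{m = 2}.
#' @export
fit_msd_models <- function(msd, fit_lags = 1:10) {
  stopifnot(inherits(msd, "msd_curve"))
  fit_lags <- fit_lags[fit_lags %in% msd$lag]
  if (length(fit_lags) < 4)
    stop("need at least 4 lag points to fit", call. = FALSE)
  d <- msd[msd$lag %in% fit_lags, ]
  t <- d$t_s; y <- d$msd
  m <- 2

  D0 <- max(y[1] / (2 * m * t[1]), 1e-9)
  pl <- tryCatch({
    fit <- minpack.lm::nlsLM(y ~ 2 * m * D * t^alpha,
                             start = list(D = D0, alpha = 1),
                             lower = c(1e-12, 1e-6), upper = c(Inf, 2),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    p <- coef(fit)
    list(D = unname(p["D"]), alpha = unname(p["alpha"]),
         rss = sum(residuals(fit)^2), converged = TRUE)
  }, error = function(e) list(D = NA_real_, alpha = NA_real_,
                              rss = Inf, converged = FALSE))

  L0 <- sqrt(3 * max(y))
  tau0 <- t[which(y >= 0.5 * max(y))[1]] / log(2)
  cf <- tryCatch({
    fit <- minpack.lm::nlsLM(y ~ (L^2 / 3) * (1 - exp(-t / tau)),
                             start = list(L = L0, tau = max(tau0, t[1])),
                             lower = c(1e-12, 1e-9),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    p <- coef(fit)
    list(L = unname(p["L"]), tau = unname(p["tau"]),
         D = unname(p["L"])^2 / (12 * unname(p["tau"])),
         rss = sum(residuals(fit)^2), converged = TRUE)
  }, error = function(e) list(L = NA_real_, tau = NA_real_, D = NA_real_,
                              rss = Inf, converged = FALSE))

  # (v t)^2 is linear in v^2: closed-form least squares
  v2 <- sum(y * t^2) / sum(t^4)
  dir <- list(v = sqrt(max(v2, 0)),
              rss = sum((y - max(v2, 0) * t^2)^2))

  structure(list(powerlaw = pl, confined = cf, directed = dir,
                 fit_lags = fit_lags, m = m),
            class = "motion_fit_models")
}
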