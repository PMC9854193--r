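#' Simulate a 2-D single-particle trajectory
#'
#' Generates one track of time-stamped 2-D positions under one of the four
#' motion modes used to classify mRNP movement: \code{"stationary"} (fixed
#' position, localization noise only), \code{"diffusive"} (isotropic
#' Brownian motion), \code{"directed"} (Brownian motion plus
#' constant-velocity drift in a random fixed direction) and
#' \code{"corralled"} (motion confined to a microdomain of size
#' \code{L_box}). Independent Gaussian localization noise of SD
#' \code{sigma_loc} is added to every reported coordinate.
#'
#' Two corral geometries are available. The default \code{"harmonic"}
#' corral is an Ornstein-Uhlenbeck spring with per-axis stationary SD
#' \eqn{L/\sqrt{12}} and relaxation time \eqn{\tau = L^2/(12 D)}: its MSD
#' is \emph{exactly} the single-exponential confinement model
#' \eqn{(L^2/3)(1 - e^{-t/\tau})}, so the confinement fit recovers
#' \eqn{D = L^2/(12\tau)} without bias. The \code{"box"} corral reflects
#' Brownian steps at the walls of a square box of side \code{L_box}; it
#' shares the plateau \eqn{L^2/3} (per-axis uniform stationary
#' distribution, variance \eqn{L^2/12}) but relaxes multi-exponentially,
#' which biases the single-exponential fit's derived \eqn{D} low by
#' roughly 15 percent.
#'
#' Expected short-time behaviour: diffusive steps have per-axis variance
#' \eqn{2 D \Delta t}, so the 2-D MSD at lag \eqn{t} is \eqn{4 D t};
#' directed tracks add \eqn{(v t)^2}; corralled tracks saturate at a
#' plateau \eqn{L^2/3} (a square box of side \eqn{L} has per-axis uniform
#' stationary distribution, variance \eqn{L^2/12}, giving \eqn{2 L^2/12}
#' per axis at large lag).
#'
#' @param motion_class one of \code{"stationary"}, \code{"corralled"},
#'   \code{"diffusive"}, \code{"directed"}.
#' @param n_frames number of frames (>= 2).
#' @param dt frame interval, seconds.
#' @param D_micro microscopic diffusion coefficient, um^2/s.
#' @param v drift speed, um/s (directed only).
#' @param L_box confinement box side, um (corralled only).
#' @param sigma_loc localization noise SD, um.
#' @param corral_geometry \code{"harmonic"} (default) or \code{"box"},
#'   see Details.
#' @param seed integer seed; identical seed and parameters give identical
#'   output. \code{NULL} uses (and advances) the global RNG.
#' @param track_id identifier stored with the track.
#' @return A \code{trajectory}: a data frame with columns \code{frame}
#'   (0-based), \code{t_s}, \code{x_um}, \code{y_um} and attributes
#'   \code{dt}, \code{track_id}, \code{motion_class} and \code{params}.
#' @examples
#' tr <- gen_trajectory("diffusive", n_frames = 100, dt = 0.01,
#'                      D_micro = 0.28, seed = 1)
#' head(tr)
#' @export
gen_trajectory <- function(motion_class = c("diffusive", "directed",
                                            "corralled", "stationary"),
                           n_frames, dt, D_micro = 0, v = 0, L_box = NULL,
                           sigma_loc = 0,
                           corral_geometry = c("harmonic", "box"),
                           seed = NULL, track_id = 1L) {
  motion_class <- match.arg(motion_class)
  corral_geometry <- match.arg(corral_geometry)
  if (!is.numeric(n_frames) || length(n_frames) != 1L || n_frames < 2)
    stop("'n_frames' must be a single number >= 2", call. = FALSE)
  n_frames <- as.integer(n_frames)
  stop_if_not_scalar_num(dt, "dt", min = .Machine$double.xmin)
  stop_if_not_scalar_num(D_micro, "D_micro", min = 0)
  stop_if_not_scalar_num(v, "v", min = 0)
  stop_if_not_scalar_num(sigma_loc, "sigma_loc", min = 0)
  if (motion_class == "corralled") {
    if (is.null(L_box))
      stop("'L_box' is required for corralled motion", call. = FALSE)
    stop_if_not_scalar_num(L_box, "L_box", min = .Machine$double.xmin)
    if (corral_geometry == "harmonic" && D_micro <= 0)
      stop("harmonic corral needs D_micro > 0 (tau = L^2/(12 D))",
           call. = FALSE)
  }

  pos <- with_seed(seed, {
    n_steps <- n_frames - 1L
    step_sd <- sqrt(2 * D_micro * dt)
    xy <- switch(motion_class,
      stationary = matrix(0, nrow = n_frames, ncol = 2),
      diffusive = cbind(cumsum(c(0, rnorm(n_steps, 0, step_sd))),
                        cumsum(c(0, rnorm(n_steps, 0, step_sd)))),
      directed = {
        theta <- runif(1, 0, 2 * pi)
        drift <- v * dt * c(cos(theta), sin(theta))
        cbind(cumsum(c(0, rnorm(n_steps, 0, step_sd) + drift[1])),
              cumsum(c(0, rnorm(n_steps, 0, step_sd) + drift[2])))
      },
      corralled = {
        if (corral_geometry == "harmonic") {
          # Ornstein-Uhlenbeck spring corral: per-axis stationary SD
          # L/sqrt(12) and relaxation time tau = L^2/(12 D), so the MSD is
          # exactly (L^2/3)(1 - exp(-t/tau)) with short-time slope 4 D t
          s2 <- L_box^2 / 12
          tau <- L_box^2 / (12 * D_micro)
          a <- exp(-dt / tau)
          innov_sd <- sqrt(s2 * (1 - a^2))
          sim_axis <- function() {
            z <- numeric(n_frames)
            z[1] <- rnorm(1, 0, sqrt(s2))
            innov <- rnorm(n_steps, 0, innov_sd)
            for (i in seq_len(n_steps)) z[i + 1L] <- a * z[i] + innov[i]
            z
          }
          cbind(sim_axis(), sim_axis())
        } else {
          # reflecting square box: start at the uniform stationary
          # distribution; walls implemented by folding the free walk
          # with period 2 L_box
          x0 <- runif(2, 0, L_box)
          free_x <- x0[1] + cumsum(c(0, rnorm(n_steps, 0, step_sd)))
          free_y <- x0[2] + cumsum(c(0, rnorm(n_steps, 0, step_sd)))
          fold <- function(z) {
            z <- z %% (2 * L_box)
            ifelse(z > L_box, 2 * L_box - z, z)
          }
          cbind(fold(free_x), fold(free_y)) - L_box / 2
        }
      })
    if (sigma_loc > 0)
      xy <- xy + matrix(rnorm(2 * n_frames, 0, sigma_loc), ncol = 2)
    xy
  })

  frames <- seq_len(n_frames) - 1L
  out <- data.frame(frame = frames, t_s = frames * dt,
                    x_um = pos[, 1], y_um = pos[, 2])
  trajectory(out, dt = dt, track_id = track_id, motion_class = motion_class,
             params = list(D_micro = D_micro, v = v, L_box = L_box,
                           sigma_loc = sigma_loc, seed = seed))
}

#' Construct a trajectory object
#'
#' Lightweight constructor wrapping a data frame of per-frame positions.
#'
#' @param df data frame with columns \code{frame}, \code{t_s}, \code{x_um},
#'   \code{y_um} (or \code{x_um}/\code{y_um} plus \code{dt}).
#' @param dt frame interval in seconds.
#' @param track_id identifier.
#' @param motion_class optional known (ground-truth) motion class.
#' @param params optional generator parameter list.
#' @return An object of class \code{trajectory}.
#' @export
trajectory <- function(df, dt, track_id = 1L, motion_class = NA_character_,
                       params = NULL) {
  stopifnot(is.data.frame(df), all(c("x_um", "y_um") %in% names(df)))
  if (!all(is.finite(df$x_um)) || !all(is.finite(df$y_um)))
    stop("trajectory coordinates must be finite", call. = FALSE)
  if (is.null(df$frame)) df$frame <- seq_len(nrow(df)) - 1L
  if (is.null(df$t_s)) df$t_s <- df$frame * dt
  structure(df, dt = dt, track_id = track_id, motion_class = motion_class,
            params = params, class = c("trajectory", "data.frame"))
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> track %s: %d frames, dt = %g s%s\n",
              attr(x, "track_id"), nrow(x), attr(x, "dt"),
              if (!is.na(attr(x, "motion_class")))
                paste0(", class = ", attr(x, "motion_class")) else ""))
  print(as.data.frame(head(x, 6)))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Simulate a cohort of trajectories
#'
#' Convenience wrapper calling \code{\link{gen_trajectory}} once per track
#' with per-track seeds derived from \code{seed}, returning a long-format
#' track table plus the ground truth.
#'
#' @param n_tracks number of tracks.
#' @param motion_class,n_frames,dt,D_micro,v,L_box,sigma_loc,corral_geometry
#'   as in \code{\link{gen_trajectory}}.
#' @param seed base seed; track \code{i} uses \code{seed + i - 1}.
#' @return list with \code{tracks} (data frame: \code{track_id},
#'   \code{frame}, \code{t_s}, \code{x_um}, \code{y_um}),
#'   \code{trajectories} (list of \code{trajectory}) and
#'   \code{ground_truth} (per-track parameters).
#' @export
gen_trajectory_cohort <- function(n_tracks, motion_class, n_frames, dt,
                                  D_micro = 0, v = 0, L_box = NULL,
                                  sigma_loc = 0,
                                  corral_geometry = c("harmonic", "box"),
                                  seed = 1L) {
  corral_geometry <- match.arg(corral_geometry)
  trajs <- lapply(seq_len(n_tracks), function(i)
    gen_trajectory(motion_class, n_frames = n_frames, dt = dt,
                   D_micro = D_micro, v = v, L_box = L_box,
                   sigma_loc = sigma_loc, corral_geometry = corral_geometry,
                   seed = seed + i - 1L, track_id = i))
  tab <- do.call(rbind, lapply(trajs, function(tr)
    cbind(track_id = attr(tr, "track_id"), as.data.frame(tr))))
  gt <- data.frame(track_id = seq_len(n_tracks), motion_class = motion_class,
                   D_micro = D_micro, v = v,
                   L_box = if (is.null(L_box)) NA_real_ else L_box,
                   sigma_loc = sigma_loc, n_frames = n_frames, dt = dt)
  list(tracks = tab, trajectories = trajs, ground_truth = gt)
}
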