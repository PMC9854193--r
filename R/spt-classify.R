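#' Classify the motion of a single trajectory
#'
#' Four-class decision procedure for mRNP tracks:
#' \enumerate{
#'   \item if the ratio of the smaller to the larger principal radius of
#'     gyration is below \code{gyration_threshold} (default 0.001) and the
#'     maximum displacement exceeds \code{directed_min_disp_um} (default
#'     2 um), the track is essentially linear: \strong{directed}. Its
#'     speed comes from the ballistic model \eqn{MSD = (vt)^2}; the
#'     power-law fit (where \eqn{\alpha} approaches 2) is reported too.
#'   \item otherwise both the power-law and the confinement model are
#'     fitted over \code{fit_lags}; the track is \strong{diffusive} if
#'     the power law describes its MSD better and \strong{corralled} if
#'     the confinement model does. "Better" is the lower residual sum of
#'     squares over the common fit lags; as both models have two free
#'     parameters, an AIC ranking (\code{criterion = "aic"}) is
#'     identical.
#'   \item a diffusive or corralled track whose maximum displacement is
#'     below \code{stationary_max_disp_um} (default 0.4 um = 400 nm)
#'     \emph{and} whose diffusion coefficient is below
#'     \code{stationary_max_D} (default 0.03 um^2/s) is overridden to
#'     \strong{stationary}.
#' }
#' A track on which both fits fail is \code{"unclassified"}. The five
#' outcomes are mutually exclusive and exhaustive.
#'
#' @param traj a \code{\link{trajectory}} (already duration-filtered).
#' @param fit_lags lags for model fitting.
#' @param gyration_threshold anisotropy threshold for directed motion.
#' @param directed_min_disp_um minimum max-displacement for directed
#'   motion, um.
#' @param stationary_max_disp_um,stationary_max_D stationary override
#'   thresholds (um, um^2/s).
#' @param criterion \code{"rss"} or \code{"aic"} model ranking.
#' @param gyration_of \code{"radii"} or \code{"eigenvalues"}, see
#'   \code{\link{gyration_ratio}}.
#' @param require_saturation accept the confinement model only when its
#'   fitted equilibration time \eqn{\tau} lies within the fitted lag
#'   window, i.e. when the MSD actually shows saturation over the fitted
#'   lags. Without this guard the confinement model can shadow a straight
#'   line arbitrarily well (\eqn{\tau \to \infty} with slope
#'   \eqn{L^2/3\tau}), making the diffusive/corralled call a coin flip on
#'   noisy linear MSDs.
#' @return A \code{motion_classification} list: \code{class}, \code{D}
#'   (um^2/s, from the winning model), \code{alpha}, \code{v}, \code{L},
#'   \code{tau}, \code{gyration_ratio}, \code{max_displacement},
#'   \code{fits} (the \code{motion_fit_models}), \code{msd}.
#' @export
classify_motion <- function(traj, fit_lags = 1:10,
                            gyration_threshold = 0.001,
                            directed_min_disp_um = 2,
                            stationary_max_disp_um = 0.4,
                            stationary_max_D = 0.03,
                            criterion = c("rss", "aic"),
                            gyration_of = c("radii", "eigenvalues"),
                            require_saturation = TRUE) {
  criterion <- match.arg(criterion)
  gyration_of <- match.arg(gyration_of)
  msd <- compute_msd(traj, max_lag_frames = min(max(fit_lags),
                                                nrow(traj) - 1L))
  ratio <- gyration_ratio(traj, of = gyration_of)
  mdisp <- max_displacement(traj)
  fits <- fit_msd_models(msd, fit_lags = fit_lags)

  res <- list(gyration_ratio = as.numeric(ratio),
              max_displacement = mdisp, fits = fits, msd = msd,
              D = NA_real_, alpha = NA_real_, v = NA_real_,
              L = NA_real_, tau = NA_real_)

  if (ratio < gyration_threshold && mdisp > directed_min_disp_um) {
    res$class <- "directed"
    res$v <- fits$directed$v
    if (fits$powerlaw$converged) {
      res$D <- fits$powerlaw$D
      res$alpha <- fits$powerlaw$alpha
    }
  } else {
    pl <- fits$powerlaw; cf <- fits$confined
    if (!pl$converged && !cf$converged) {
      res$class <- "unclassified"
      class(res) <- "motion_classification"
      return(res)
    }
    score <- function(f) {
      if (!f$converged) return(Inf)
      if (criterion == "rss") f$rss
      else length(fits$fit_lags) * log(f$rss / length(fits$fit_lags)) + 4
    }
    t_max <- max(fits$fit_lags) * attr(msd, "dt")
    corral_ok <- cf$converged &&
      (!require_saturation || cf$tau <= t_max)
    if (score(pl) <= score(cf) || !corral_ok) {
      res$class <- "diffusive"
      res$D <- pl$D; res$alpha <- pl$alpha
    } else {
      res$class <- "corralled"
      res$D <- cf$D; res$L <- cf$L; res$tau <- cf$tau
    }
    # the override uses the power-law D: the confined fit of a flat,
    # noise-dominated MSD degenerates to tau -> 0 and an exploding
    # derived D, which would mask truly immobile particles
    D_check <- if (pl$converged) pl$D else res$D
    if (mdisp < stationary_max_disp_um && is.finite(D_check) &&
        D_check < stationary_max_D)
      res$class <- "stationary"
  }
  class(res) <- "motion_classification"
  res
}

#' @export
print.motion_classification <- function(x, ...) {
  cat(sprintf("<motion_classification> %s: D = %.4g um^2/s, gyration ratio = %.3g, max disp = %.3g um\n",
              x$class, x$D, x$gyration_ratio, x$max_displacement))
  invisible(x)
}

#' Classify every track of a cohort
#'
#' @param trajs list of \code{\link{trajectory}} objects, or a track
#'   table (then \code{dt} is required or taken from \code{t_s}).
#' @param dt frame interval, seconds (track-table input only).
#' @param ... passed to \code{\link{classify_motion}}.
#' @return data frame with one row per track: \code{track_id},
#'   \code{class}, \code{D}, \code{alpha}, \code{v}, \code{L},
#'   \code{tau}, \code{rss_powerlaw}, \code{rss_confined},
#'   \code{gyration_ratio}, \code{max_displacement}.
#' @export
classify_tracks <- function(trajs, dt = NULL, ...) {
  if (is.data.frame(trajs)) trajs <- split_tracks(trajs, dt = dt)
  do.call(rbind, lapply(trajs, function(tr) {
    cl <- classify_motion(tr, ...)
    data.frame(track_id = attr(tr, "track_id"), class = cl$class,
               D = cl$D, alpha = cl$alpha, v = cl$v, L = cl$L,
               tau = cl$tau,
               rss_powerlaw = cl$fits$powerlaw$rss,
               rss_confined = cl$fits$confined$rss,
               gyration_ratio = cl$gyration_ratio,
               max_displacement = cl$max_displacement,
               stringsAsFactors = FALSE)
  }))
}
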