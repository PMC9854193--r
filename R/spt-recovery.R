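#' Recover motion-model parameters from a cohort of tracks
#'
#' Population-level estimates of the motion parameters of a homogeneous
#' cohort, each computed under the model of the (known or already
#' classified) motion class:
#' \itemize{
#'   \item \code{"diffusive"}: per-track least-squares slope of the
#'     Brownian model \eqn{MSD = 4 D t} through the origin over the fit
#'     lags, averaged across tracks (\code{D}); the free-exponent
#'     power-law fit of the ensemble MSD is reported alongside
#'     (\code{D_powerlaw}, \code{alpha}) as a linearity check.
#'   \item \code{"directed"}: per-track closed-form fit of
#'     \eqn{MSD = (v t)^2}, averaged (\code{v}).
#'   \item \code{"corralled"}: confinement-model fit of the ensemble MSD,
#'     returning \code{L}, \code{tau} and the derived
#'     \code{D = L^2/(12 tau)}.
#'   \item \code{"stationary"}: mean per-track MSD plateau, reported as
#'     \code{msd_plateau} (\eqn{4\sigma_{loc}^2} for pure localization
#'     noise).
#' }
#'
#' Per-track free-exponent fits are deliberately not averaged for
#' \code{D}: the exponent-amplitude coupling of the power law makes the
#' mean of per-track \code{D} estimates badly biased at short-lag fits,
#' whereas the estimators above are consistent.
#'
#' @param trajs list of \code{\link{trajectory}} objects.
#' @param motion_class the cohort's motion class.
#' @param fit_lags lags used for fitting.
#' @return named list of estimates (see Details), plus \code{n_tracks}.
#' @export
recover_motion_parameters <- function(trajs,
                                      motion_class = c("diffusive",
                                                       "directed",
                                                       "corralled",
                                                       "stationary"),
                                      fit_lags = 1:10) {
  motion_class <- match.arg(motion_class)
  max_lag <- max(fit_lags)
  curves <- lapply(trajs, compute_msd, max_lag_frames = max_lag)
  sel <- function(cv) cv[cv$lag %in% fit_lags, ]
  out <- switch(motion_class,
    diffusive = {
      Ds <- vapply(curves, function(cv) {
        d <- sel(cv)
        sum(d$msd * d$t_s) / (4 * sum(d$t_s^2))
      }, 0)
      em <- ensemble_msd(trajs, max_lag)
      ft <- fit_msd_models(em, fit_lags)
      list(D = mean(Ds), D_powerlaw = ft$powerlaw$D,
           alpha = ft$powerlaw$alpha)
    },
    directed = {
      vs <- vapply(curves, function(cv) {
        d <- sel(cv)
        sqrt(max(sum(d$msd * d$t_s^2) / sum(d$t_s^4), 0))
      }, 0)
      list(v = mean(vs))
    },
    corralled = {
      em <- ensemble_msd(trajs, max_lag)
      ft <- fit_msd_models(em, fit_lags)
      list(L = ft$confined$L, tau = ft$confined$tau, D = ft$confined$D)
    },
    stationary = {
      list(msd_plateau = mean(vapply(curves,
                                     function(cv) mean(sel(cv)$msd), 0)))
    })
  c(out, list(n_tracks = length(trajs)))
}
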