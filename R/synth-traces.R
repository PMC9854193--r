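#' Simulate paired allelic transcription traces
#'
#' Generates, for each simulated cell, normalized-intensity time courses of
#' the two transcription sites (alleles) of one gene, with the statistical
#' structure assumed by the downstream memory and noise analyses:
#'
#' \itemize{
#'   \item a shared per-cell \emph{extrinsic} log-normal multiplier
#'     \eqn{E_c = \exp N(0, \mathrm{extrinsic\_sd}^2)} scales the output
#'     amplitude of both alleles;
#'   \item each allele additionally gets an independent \emph{intrinsic}
#'     log-normal multiplier \eqn{\exp N(0, \mathrm{intrinsic\_sd}^2)};
#'   \item allele 1 initiates at \code{t_first_on_min}; allele 2 initiates
#'     later by an offset drawn from a gamma distribution parameterized by
#'     \code{offset_mean_min} and \code{offset_sd_min} (SD 0 is a point
#'     mass, so both alleles fire simultaneously);
#'   \item with probability \code{p_silent_second_allele} the second allele
#'     never fires and stays at baseline;
#'   \item after initiation a trace ramps linearly to its plateau amplitude
#'     over \code{plateau_time_min} minutes, then fluctuates
#'     multiplicatively around the plateau;
#'   \item raw ROI values are emitted on top of a constant background
#'     \code{background_au}; photobleaching multiplies signal \emph{and}
#'     background by \eqn{\exp(-t/\mathrm{bleach\_tau\_min})}, so the
#'     background-ratio normalization cancels it exactly.
#' }
#'
#' @param n_cells number of cells (trace pairs).
#' @param n_timepoints time points per trace.
#' @param dt_min sampling interval, minutes.
#' @param offset_mean_min,offset_sd_min mean and SD (minutes) of the
#'   inter-allele initiation-time offset; gamma-distributed with matched
#'   moments (shape \eqn{(m/s)^2}, rate \eqn{m/s^2}), point mass at the
#'   mean when \code{offset_sd_min = 0}.
#' @param extrinsic_sd SD of the shared per-cell log output multiplier.
#' @param intrinsic_sd SD of the per-allele independent log multiplier.
#' @param plateau_time_min time from initiation to plateau, minutes.
#' @param bleach_tau_min photobleaching time constant, minutes
#'   (\code{Inf} disables bleaching).
#' @param p_silent_second_allele probability allele 2 never fires.
#' @param t_first_on_min initiation time of allele 1 after cycle start
#'   (\code{t0 = 0}), minutes.
#' @param amplitude_au plateau normalized intensity before noise
#'   multipliers (dimensionless, background-ratio units).
#' @param fluct_sd SD of the multiplicative plateau fluctuation.
#' @param meas_cv coefficient of variation of multiplicative measurement
#'   noise on the puncta signal.
#' @param background_au background (ROI-2 mean) level, arbitrary units.
#' @param cycle cycle label attached to every trace
#'   (\code{"de_novo"} or \code{"reactivation"}).
#' @param seed integer seed.
#' @return list with \code{traces}, a data frame in trace-table layout
#'   (\code{cell_id}, \code{cycle}, \code{t_min}, \code{allele},
#'   \code{roi1_max}, \code{roi2_mean}, \code{roi2_sd}, \code{identified}),
#'   and \code{ground_truth}, one row per allele (\code{cell_id},
#'   \code{allele}, \code{t_init_min} (NA when silent), \code{offset_min},
#'   \code{extrinsic}, \code{intrinsic}, \code{amplitude},
#'   \code{silent}).
#' @examples
#' sim <- gen_trace_pairs(n_cells = 4, n_timepoints = 30, dt_min = 5,
#'                        offset_mean_min = 20, offset_sd_min = 10, seed = 1)
#' head(sim$traces)
#' sim$ground_truth
#' @export
gen_trace_pairs <- function(n_cells, n_timepoints = 60, dt_min = 2,
                            offset_mean_min = 44.2, offset_sd_min = 33.5,
                            extrinsic_sd = 0.4, intrinsic_sd = 0.2,
                            plateau_time_min = 60, bleach_tau_min = Inf,
                            p_silent_second_allele = 0,
                            t_first_on_min = 10, amplitude_au = 2,
                            fluct_sd = 0.05, meas_cv = 0.02,
                            background_au = 100,
                            cycle = c("de_novo", "reactivation"),
                            seed = NULL) {
  cycle <- match.arg(cycle)
  stop_if_not_scalar_num(n_cells, "n_cells", min = 1)
  stop_if_not_scalar_num(offset_mean_min, "offset_mean_min", min = 0)
  stop_if_not_scalar_num(offset_sd_min, "offset_sd_min", min = 0)
  stop_if_not_scalar_num(extrinsic_sd, "extrinsic_sd", min = 0)
  stop_if_not_scalar_num(intrinsic_sd, "intrinsic_sd", min = 0)
  stop_if_not_scalar_num(bleach_tau_min, "bleach_tau_min", min = 0,
                         allow_inf = TRUE)
  if (p_silent_second_allele < 0 || p_silent_second_allele > 1)
    stop("'p_silent_second_allele' must lie in [0, 1]", call. = FALSE)

  t_min <- (seq_len(n_timepoints) - 1L) * dt_min

  with_seed(seed, {
    offsets <- draw_offsets(n_cells, offset_mean_min, offset_sd_min)
    extr <- exp(rnorm(n_cells, 0, extrinsic_sd))
    intr <- matrix(exp(rnorm(2L * n_cells, 0, intrinsic_sd)), ncol = 2)
    silent2 <- as.logical(rbinom(n_cells, 1, p_silent_second_allele))

    rows <- vector("list", 2L * n_cells)
    gt <- vector("list", 2L * n_cells)
    bleach <- exp(-t_min / bleach_tau_min)
    for (c_i in seq_len(n_cells)) {
      t_init <- c(t_first_on_min, t_first_on_min + offsets[c_i])
      for (a in 1:2) {
        is_silent <- a == 2L && silent2[c_i]
        amp <- amplitude_au * extr[c_i] * intr[c_i, a]
        norm_true <- if (is_silent) rep(0, n_timepoints) else {
          ramp <- pmin(pmax((t_min - t_init[a]) / plateau_time_min, 0), 1)
          amp * ramp * ifelse(ramp >= 1,
                              pmax(1 + rnorm(n_timepoints, 0, fluct_sd), 0), 1)
        }
        eps <- rnorm(n_timepoints, 0, meas_cv)
        roi1 <- background_au * (1 + norm_true) * (1 + eps) * bleach
        rows[[2L * (c_i - 1L) + a]] <- data.frame(
          cell_id = c_i, cycle = cycle, t_min = t_min, allele = a,
          roi1_max = roi1, roi2_mean = background_au * bleach,
          roi2_sd = 0.05 * background_au * bleach, identified = TRUE)
        gt[[2L * (c_i - 1L) + a]] <- data.frame(
          cell_id = c_i, allele = a,
          t_init_min = if (is_silent) NA_real_ else t_init[a],
          offset_min = offsets[c_i], extrinsic = extr[c_i],
          intrinsic = intr[c_i, a], amplitude = amp, silent = is_silent)
      }
    }
    list(traces = do.call(rbind, rows), ground_truth = do.call(rbind, gt))
  })
}

# gamma draw with matched mean/SD; SD = 0 collapses to a point mass
draw_offsets <- function(n, mean, sd) {
  if (mean == 0) return(rep(0, n))
  if (sd == 0) return(rep(mean, n))
  shape <- (mean / sd)^2
  rgamma(n, shape = shape, rate = mean / sd^2)
}
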