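#' Simulate a 2-D spot movie
#'
#' Builds an image stack in which every frame is the sum of 2-D Gaussian
#' puncta, a constant background and i.i.d. Gaussian noise. Optionally the
#' whole frame (signal, background and noise alike) decays as
#' \eqn{\exp(-t/\mathrm{bleach\_tau\_frames})}, emulating detector-referred
#' photobleaching, which the background-ratio normalization of
#' \code{\link{normalized_intensity}} cancels exactly.
#'
#' @param spots data frame with columns \code{x}, \code{y} (pixel centers,
#'   1-based), \code{amplitude} and \code{width} (Gaussian SD, pixels).
#'   Zero rows give a pure background movie.
#' @param dim_px image size, \code{c(rows, cols)}.
#' @param background_mean constant background level, a.u.
#' @param noise_sd SD of per-pixel Gaussian noise.
#' @param n_frames number of frames.
#' @param bleach_tau_frames bleaching time constant in frames
#'   (\code{Inf} disables).
#' @param seed integer seed; identical seed gives identical pixel values.
#' @return A \code{spot_movie}: a list with \code{frames} (list of
#'   matrices), \code{spots} (the ground truth, clipped spots flagged),
#'   \code{background_mean}, \code{noise_sd}, \code{dim_px}.
#' @examples
#' mv <- gen_spot_movie(data.frame(x = 16, y = 16, amplitude = 50,
#'                                 width = 1.5),
#'                      dim_px = c(32, 32), background_mean = 100,
#'                      noise_sd = 5, n_frames = 3, seed = 1)
#' dim(mv$frames[[1]])
#' @export
gen_spot_movie <- function(spots = NULL, dim_px = c(64, 64),
                           background_mean = 100, noise_sd = 5,
                           n_frames = 10, bleach_tau_frames = Inf,
                           seed = NULL) {
  stop_if_not_scalar_num(background_mean, "background_mean", min = 0)
  stop_if_not_scalar_num(noise_sd, "noise_sd", min = 0)
  stop_if_not_scalar_num(bleach_tau_frames, "bleach_tau_frames", min = 0,
                         allow_inf = TRUE)
  if (is.null(spots))
    spots <- data.frame(x = numeric(), y = numeric(),
                        amplitude = numeric(), width = numeric())
  stopifnot(all(c("x", "y", "amplitude", "width") %in% names(spots)))
  if (nrow(spots) && any(spots$width <= 0))
    stop("spot widths must be > 0", call. = FALSE)

  nr <- dim_px[1]; nc <- dim_px[2]
  clipped <- logical(nrow(spots))
  if (nrow(spots)) {
    outside <- spots$x < 1 | spots$x > nc | spots$y < 1 | spots$y > nr
    if (any(outside)) {
      warning(sum(outside), " spot(s) outside image bounds; clipped",
              call. = FALSE)
      spots$x <- pmin(pmax(spots$x, 1), nc)
      spots$y <- pmin(pmax(spots$y, 1), nr)
      clipped <- outside
    }
  }
  spots$clipped <- clipped

  base <- matrix(background_mean, nr, nc)
  if (nrow(spots)) {
    xs <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    ys <- matrix(rep(seq_len(nr), times = nc), nr, nc)
    for (i in seq_len(nrow(spots)))
      base <- base + spots$amplitude[i] *
        exp(-((xs - spots$x[i])^2 + (ys - spots$y[i])^2) /
              (2 * spots$width[i]^2))
  }

  frames <- with_seed(seed, {
    lapply(seq_len(n_frames), function(f) {
      img <- base
      if (noise_sd > 0) img <- img + matrix(rnorm(nr * nc, 0, noise_sd),
                                            nr, nc)
      img * exp(-(f - 1) / bleach_tau_frames)
    })
  })

  structure(list(frames = frames, spots = spots,
                 background_mean = background_mean, noise_sd = noise_sd,
                 dim_px = dim_px),
            class = "spot_movie")
}

#' @export
print.spot_movie <- function(x, ...) {
  cat(sprintf("<spot_movie> %d frame(s) of %dx%d px, %d spot(s), bg %g, noise SD %g\n",
              length(x$frames), x$dim_px[1], x$dim_px[2], nrow(x$spots),
              x$background_mean, x$noise_sd))
  invisible(x)
}

#' Write / read a spot movie as multi-page TIFF
#'
#' Frames are stored as 32-bit float TIFF pages, values as-is.
#'
#' @param movie a \code{spot_movie} or list of matrices.
#' @param path file path.
#' @return \code{write_movie_tiff} returns \code{path} invisibly;
#'   \code{read_movie_tiff} returns a list of matrices.
#' @export
write_movie_tiff <- function(movie, path) {
  frames <- if (inherits(movie, "spot_movie")) movie$frames else movie
  # writeTIFF expects samples in [0, 1]; record the scale in a text sidecar
  scale <- max(1, max(vapply(frames, max, 0)))
  tiff::writeTIFF(lapply(frames, function(f) f / scale), path,
                  bits.per.sample = 32L, reduce = FALSE)
  writeLines(as.character(scale), paste0(path, ".scale"))
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  scale_file <- paste0(path, ".scale")
  scale <- if (file.exists(scale_file))
    as.numeric(readLines(scale_file, n = 1L)) else 1
  lapply(frames, function(f) f * scale)
}
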