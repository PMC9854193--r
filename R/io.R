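#' Read and write particle-track tables
#'
#' Track tables use unit-suffixed columns \code{track_id}, \code{frame},
#' \code{t_s}, \code{x_um}, \code{y_um} (TrackMate-style export reduced
#' to the columns the analysis needs).
#'
#' @param tracks track table data frame.
#' @param path CSV file path.
#' @return \code{write_tracks} returns \code{path} invisibly;
#'   \code{read_tracks} returns the data frame.
#' @export
write_tracks <- function(tracks, path) {
  write.csv(tracks[, c("track_id", "frame", "t_s", "x_um", "y_um")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  tab <- read.csv(path)
  req <- c("track_id", "frame", "t_s", "x_um", "y_um")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols))
    stop("track CSV missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  tab
}

#' Read and write allele trace tables
#'
#' Trace tables carry one row per cell, allele and time point with
#' columns \code{cell_id}, \code{cycle}, \code{t_min}, \code{allele},
#' \code{roi1_max}, \code{roi2_mean}, \code{roi2_sd} and optionally
#' \code{identified}.
#'
#' @param traces trace table data frame.
#' @param path CSV file path.
#' @return \code{write_traces} returns \code{path} invisibly;
#'   \code{read_traces} returns the data frame.
#' @export
write_traces <- function(traces, path) {
  write.csv(traces, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  tab <- read.csv(path)
  req <- c("cell_id", "cycle", "t_min", "allele", "roi1_max", "roi2_mean")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols))
    stop("trace CSV missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  tab
}
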