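#' Detect and time a nuclear-export event on one trajectory
#'
#' Automates the event scoring applied to mRNPs crossing the nuclear
#' envelope: a particle \emph{docks} when it first comes within
#' \code{dock_radius_um} of the boundary (the ~200-nm scale of the
#' nuclear pore complex) having approached from the nuclear side, and is
#' \emph{released} at the first cytoplasmic-side frame from which its
#' distance to the boundary increases over the next two consecutive
#' frames -- the onset of quick diffusion away from the nuclear edge.
#' Transit time is release minus dock.
#'
#' The mode is \code{"directed"} when the dock-to-release sub-track has a
#' principal-radius-of-gyration ratio below 0.001 (a straight shot through
#' the pore), otherwise \code{"fast"} for transits under 1 s and
#' \code{"slow"} for 1 s and longer.
#'
#' @param traj a \code{\link{trajectory}} in the same coordinate frame as
#'   the boundary.
#' @param boundary data frame of ordered polyline vertices (\code{x_um},
#'   \code{y_um}); a closed polygon (first vertex repeated last) is
#'   treated as the nuclear outline, with its interior the nuclear side.
#' @param nucleus_point for an open polyline, a point \code{c(x, y)} on
#'   the nuclear side (ignored for closed polygons).
#' @param dock_radius_um docking distance to the boundary, um.
#' @return An \code{export_event} list (\code{track_id},
#'   \code{dock_frame}, \code{release_frame}, \code{dock_t_s},
#'   \code{release_t_s}, \code{transit_s}, \code{mode}), or \code{NULL}
#'   when the track never completes an export.
#' @export
export_transit <- function(traj, boundary, nucleus_point = NULL,
                           dock_radius_um = 0.2) {
  stopifnot(all(c("x_um", "y_um") %in% names(boundary)))
  nb <- nrow(boundary)
  closed <- nb >= 4 &&
    isTRUE(all.equal(c(boundary$x_um[1], boundary$y_um[1]),
                     c(boundary$x_um[nb], boundary$y_um[nb]),
                     tolerance = 1e-9, scale = 1))
  if (closed) boundary[nb, c("x_um", "y_um")] <- boundary[1, c("x_um", "y_um")]
  if (!closed && is.null(nucleus_point))
    stop("'nucleus_point' required for an open boundary polyline",
         call. = FALSE)

  pts <- cbind(traj$x_um, traj$y_um)
  dists <- apply(pts, 1, polyline_distance, boundary = boundary)
  nuclear <- if (closed) {
    apply(pts, 1, point_in_polygon, poly = boundary)
  } else {
    ref <- polyline_side(nucleus_point, boundary)
    apply(pts, 1, function(p) polyline_side(p, boundary) == ref)
  }

  in_zone <- dists <= dock_radius_um
  dock <- NA_integer_
  for (i in which(in_zone)) {
    before <- which(!in_zone[seq_len(i - 1L)])
    came_from_nucleus <- if (length(before)) nuclear[max(before)]
                         else nuclear[1] || i == 1L
    if (isTRUE(came_from_nucleus)) { dock <- i; break }
  }
  if (is.na(dock)) return(NULL)

  n <- nrow(traj)
  release <- NA_integer_
  for (r in seq.int(dock + 1L, length.out = max(0L, n - dock))) {
    if (nuclear[r]) next
    if (r + 2L <= n && dists[r + 1L] > dists[r] &&
        dists[r + 2L] > dists[r + 1L]) { release <- r; break }
  }
  if (is.na(release)) return(NULL)

  sub <- traj[dock:release, , drop = FALSE]
  ratio <- if (nrow(sub) >= 3)
    gyration_ratio(trajectory(as.data.frame(sub), dt = attr(traj, "dt")))
  else 1
  transit <- traj$t_s[release] - traj$t_s[dock]
  mode <- if (ratio < 0.001) "directed"
          else if (transit < 1) "fast" else "slow"
  structure(list(track_id = attr(traj, "track_id"), dock_frame = dock - 1L,
                 release_frame = release - 1L,
                 dock_t_s = traj$t_s[dock],
                 release_t_s = traj$t_s[release],
                 transit_s = transit, mode = mode),
            class = "export_event")
}

#' @export
print.export_event <- function(x, ...) {
  cat(sprintf("<export_event> track %s: transit %.3g s (%s), frames %d -> %d\n",
              x$track_id, x$transit_s, x$mode, x$dock_frame,
              x$release_frame))
  invisible(x)
}

#' Export events for a cohort of tracks
#'
#' @param trajs list of trajectories or a track table.
#' @param boundary,nucleus_point,dock_radius_um see
#'   \code{\link{export_transit}}.
#' @param dt frame interval (track-table input).
#' @return data frame of events (possibly zero rows).
#' @export
export_events <- function(trajs, boundary, nucleus_point = NULL,
                          dock_radius_um = 0.2, dt = NULL) {
  if (is.data.frame(trajs)) trajs <- split_tracks(trajs, dt = dt)
  evs <- Filter(Negate(is.null),
                lapply(trajs, export_transit, boundary = boundary,
                       nucleus_point = nucleus_point,
                       dock_radius_um = dock_radius_um))
  if (!length(evs))
    return(data.frame(track_id = character(), dock_frame = integer(),
                      release_frame = integer(), transit_s = numeric(),
                      mode = character()))
  do.call(rbind, lapply(evs, function(e) data.frame(
    track_id = as.character(e$track_id), dock_frame = e$dock_frame,
    release_frame = e$release_frame, transit_s = e$transit_s,
    mode = e$mode, stringsAsFactors = FALSE)))
}

#' Transit-time estimate for directed export
#'
#' A directed export event crosses the nuclear pore complex (nuclear
#' basket ~75 nm, central framework ~70 nm, cytoplasmic filaments
#' ~50 nm, together ~200 nm) at constant speed, so its transit time is
#' simply the NPC length divided by the measured speed.
#'
#' @param v speed of the directed mRNP, um/s (> 0).
#' @param npc_length_um NPC length, um.
#' @return transit time, seconds.
#' @examples
#' directed_transit_estimate(1.4193)  # ~0.141 s
#' @export
directed_transit_estimate <- function(v, npc_length_um = 0.2) {
  if (any(!is.finite(v)) || any(v <= 0))
    stop("'v' must be > 0", call. = FALSE)
  npc_length_um / v
}

# ---- geometry helpers -------------------------------------------------

# distance from point p = c(x, y) to a polyline
polyline_distance <- function(p, boundary) {
  bx <- boundary$x_um; by <- boundary$y_um
  n <- length(bx)
  if (n == 1) return(sqrt((p[1] - bx)^2 + (p[2] - by)^2))
  dmin <- Inf
  for (i in seq_len(n - 1L)) {
    dmin <- min(dmin, point_segment_distance(p, c(bx[i], by[i]),
                                             c(bx[i + 1L], by[i + 1L])))
  }
  dmin
}

point_segment_distance <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
  proj <- a + t * ab
  sqrt(sum((p - proj)^2))
}

# which side of the (open) polyline a point lies on, via the nearest
# segment's cross product; returns -1, 0 or 1
polyline_side <- function(p, boundary) {
  bx <- boundary$x_um; by <- boundary$y_um
  n <- length(bx)
  best <- Inf; side <- 0
  for (i in seq_len(n - 1L)) {
    a <- c(bx[i], by[i]); b <- c(bx[i + 1L], by[i + 1L])
    d <- point_segment_distance(p, a, b)
    if (d < best) {
      best <- d
      cr <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
      side <- sign(cr)
    }
  }
  side
}

# even-odd ray casting; boundary is a closed polygon
point_in_polygon <- function(p, poly) {
  x <- poly$x_um; y <- poly$y_um
  n <- length(x) - 1L  # last vertex repeats the first
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((y[i] > p[2]) != (y[j] > p[2]) &&
        p[1] < (x[j] - x[i]) * (p[2] - y[i]) / (y[j] - y[i]) + x[i])
      inside <- !inside
    j <- i
  }
  inside
}
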