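#' Interaction interval tracks
#'
#' An interval track holds the ordered, non-overlapping, half-open
#' \code{[onset, offset)} intervals (in milliseconds) during which the focal
#' child interacts with one partner class. Both manually coded reference
#' tracks and detector predictions use this container.
#'
#' @param onset,offset numeric vectors of interval bounds in ms; must satisfy
#'   \code{offset > onset}. Overlapping or touching same-class intervals are
#'   merged.
#' @param partner partner class, \code{"adult"} or \code{"peer"}.
#' @param source \code{"reference"} or \code{"predicted"}.
#' @return an object of class \code{interval_track} with elements
#'   \code{partner}, \code{source} and \code{intervals} (a data frame with
#'   columns \code{onset}, \code{offset}).
#' @export
interval_track <- function(onset = numeric(0), offset = numeric(0),
                           partner = c("adult", "peer"),
                           source = c("reference", "predicted")) {
  partner <- match.arg(partner)
  source <- match.arg(source)
  if (length(onset) != length(offset)) {
    stop("onset and offset must have equal length")
  }
  if (any(!is.finite(onset)) || any(!is.finite(offset))) {
    stop("interval bounds must be finite")
  }
  if (any(offset <= onset)) {
    stop("all intervals must satisfy offset > onset")
  }
  iv <- merge_intervals(onset, offset)
  structure(
    list(partner = partner, source = source, intervals = iv),
    class = "interval_track"
  )
}

#' @export
print.interval_track <- function(x, ...) {
  cat(sprintf("<interval_track> partner=%s source=%s n=%d total=%.1fs\n",
              x$partner, x$source, nrow(x$intervals),
              sum(x$intervals$offset - x$intervals$onset) / 1000))
  invisible(x)
}

# Union of half-open intervals; touching intervals ([a,b), [b,c)) coalesce.
merge_intervals <- function(onset, offset) {
  if (length(onset) == 0) {
    return(data.frame(onset = numeric(0), offset = numeric(0)))
  }
  o <- order(onset, offset)
  onset <- onset[o]
  offset <- offset[o]
  res_on <- onset[1]
  res_off <- offset[1]
  for (i in seq_along(onset)[-1]) {
    k <- length(res_on)
    if (onset[i] <= res_off[k]) {
      res_off[k] <- max(res_off[k], offset[i])
    } else {
      res_on <- c(res_on, onset[i])
      res_off <- c(res_off, offset[i])
    }
  }
  data.frame(onset = res_on, offset = res_off)
}

track_intervals <- function(track) {
  if (inherits(track, "interval_track")) track$intervals else track
}

#' Total duration of a track in milliseconds
#' @param track an \code{interval_track} (or bare intervals data frame).
#' @export
track_total_ms <- function(track) {
  iv <- track_intervals(track)
  sum(iv$offset - iv$onset)
}

#' Rasterize a track to fixed-rate binary labels
#'
#' Bin \code{b} covers \code{[(b-1)*dt, b*dt)} ms and is labeled 1 when it
#' has a positive-length intersection with any interval of the track.
#'
#' @param track an \code{interval_track} or intervals data frame.
#' @param session_ms session length in ms.
#' @param dt bin width in ms (default 250).
#' @return integer vector of 0/1 labels of length \code{ceiling(session_ms/dt)}.
#' @export
rasterize_track <- function(track, session_ms, dt = 250) {
  stopifnot(session_ms > 0, dt > 0)
  iv <- track_intervals(track)
  n_bins <- ceiling(session_ms / dt)
  bits <- integer(n_bins)
  if (nrow(iv) > 0) {
    for (i in seq_len(nrow(iv))) {
      lo <- floor(iv$onset[i] / dt) + 1
      hi <- ceiling(iv$offset[i] / dt)
      lo <- max(1L, lo)
      hi <- min(n_bins, hi)
      if (lo <= hi) bits[lo:hi] <- 1L
    }
  }
  bits
}

#' Convert a binary bin trajectory to an interval track
#'
#' Runs of consecutive 1-bins become intervals with bin-edge timestamps; the
#' inverse of \code{\link{rasterize_track}} for bin-aligned tracks.
#'
#' @param bits integer 0/1 vector, one element per bin.
#' @param dt bin width in ms.
#' @inheritParams interval_track
#' @export
bins_to_track <- function(bits, dt = 250, partner = c("adult", "peer"),
                          source = "predicted") {
  stopifnot(all(bits %in% c(0L, 1L)))
  r <- rle(as.integer(bits))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pos <- r$values == 1L
  interval_track(
    onset = (starts[pos] - 1) * dt,
    offset = ends[pos] * dt,
    partner = match.arg(partner),
    source = source
  )
}

#' Smooth a predicted track by merging short gaps and deleting short intervals
#'
#' Post-processing of raw detector output: first, consecutive intervals
#' separated by a gap shorter than \code{min_dur_ms} are merged; second,
#' remaining intervals shorter than \code{min_dur_ms} are deleted. The result
#' contains no interval and no inter-interval gap shorter than
#' \code{min_dur_ms}, and the operation is idempotent.
#'
#' @param track an \code{interval_track}.
#' @param min_dur_ms minimum interval duration and gap width in ms
#'   (default 1000, i.e. one second).
#' @return a smoothed \code{interval_track} with the same partner class.
#' @export
smooth_track <- function(track, min_dur_ms = 1000) {
  if (min_dur_ms < 0) stop("min_dur_ms must be non-negative")
  iv <- track_intervals(track)
  if (nrow(iv) > 0) {
    # merge gaps strictly shorter than min_dur_ms
    on <- iv$onset[1]
    off <- iv$offset[1]
    if (nrow(iv) > 1) {
      for (i in 2:nrow(iv)) {
        k <- length(on)
        if (iv$onset[i] - off[k] < min_dur_ms) {
          off[k] <- iv$offset[i]
        } else {
          on <- c(on, iv$onset[i])
          off <- c(off, iv$offset[i])
        }
      }
    }
    keep <- (off - on) >= min_dur_ms
    on <- on[keep]
    off <- off[keep]
  } else {
    on <- numeric(0)
    off <- numeric(0)
  }
  partner <- if (inherits(track, "interval_track")) track$partner else "adult"
  source <- if (inherits(track, "interval_track")) track$source else "predicted"
  interval_track(on, off, partner = partner, source = source)
}

# Positive-length intersection of [start, end) with any interval of a track.
overlaps_track <- function(start, end, track) {
  iv <- track_intervals(track)
  if (nrow(iv) == 0) return(rep(FALSE, length(start)))
  vapply(seq_along(start), function(i) {
    any(pmin(end[i], iv$offset) - pmax(start[i], iv$onset) > 0)
  }, logical(1))
}
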