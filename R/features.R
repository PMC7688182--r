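# Feature builder: converts labeled face frames and utterances into the
# fixed-rate 250 ms multivariate series the interaction detector consumes.
# Pipeline order is fixed: rasterize -> infill -> clip -> normalize, with
# normalization statistics always fitted on training sessions only.

.feature_channels <- c(
  "adult_area", "adult_yaw", "adult_roll", "adult_pitch", "adult_mouth",
  "adult_eyes",
  "peer_area", "peer_yaw", "peer_roll", "peer_pitch", "peer_mouth",
  "peer_eyes",
  "speech_active", "word_conf", "loudness"
)

#' Channel names of the full feature set
#' @return character vector of the 15 channel names: six facial features per
#'   partner class plus the three audio channels.
#' @export
feature_channels <- function() .feature_channels

new_feature_series <- function(channels, session_ms, dt, child_id) {
  structure(
    list(child_id = child_id, dt = dt, session_ms = session_ms,
         channels = channels),
    class = "feature_series"
  )
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series> %s: %d bins x %d channels (dt=%d ms)\n",
              x$child_id %||% "?", nrow(x$channels), ncol(x$channels), x$dt))
  invisible(x)
}

#' Rasterize labeled faces and utterances onto the 250 ms grid
#'
#' Each representative face sample fills the bins its native-resolution
#' window covers; bins with no face for a class carry gap markers (NA) on
#' that class's six channels. \code{speech_active} is 1 on bins with a
#' positive-length intersection with any utterance, and the utterance's mean
#' word confidence and loudness are broadcast over those bins (0 elsewhere).
#'
#' @param face_frames representative-face frames (see
#'   \code{\link{select_representative_faces}}).
#' @param utterances utterance data frame (see
#'   \code{\link{segment_utterances}}).
#' @param session_ms session length in ms (> 0).
#' @param dt bin width in ms (default 250).
#' @param native_ms native face-frame period in ms (default 500); each frame
#'   covers \code{[t, t + native_ms)}.
#' @param child_id stored in the result.
#' @return a \code{feature_series} with gaps (pre-infill).
#' @export
rasterize_features <- function(face_frames, utterances, session_ms,
                               dt = 250, native_ms = 500,
                               child_id = NULL) {
  if (session_ms <= 0) stop("session_ms must be > 0")
  n_bins <- ceiling(session_ms / dt)
  m <- matrix(NA_real_, nrow = n_bins, ncol = length(.feature_channels),
              dimnames = list(NULL, .feature_channels))
  m[, c("speech_active", "word_conf", "loudness")] <- 0
  feat_map <- c(area = "area", yaw = "yaw", roll = "roll", pitch = "pitch",
                mouth = "mouth_open_conf", eyes = "eyes_open_conf")
  for (cls in c("adult", "peer")) {
    ff <- face_frames[face_frames$class == cls, , drop = FALSE]
    cols <- paste0(cls, "_", c("area", "yaw", "roll", "pitch", "mouth",
                               "eyes"))
    for (i in seq_len(nrow(ff))) {
      lo <- max(1L, floor(ff$t_ms[i] / dt) + 1)
      hi <- min(n_bins, ceiling((ff$t_ms[i] + native_ms) / dt))
      if (lo > hi) next
      vals <- c(ff$area[i], ff$yaw[i], ff$roll[i], ff$pitch[i],
                ff$mouth_open_conf[i], ff$eyes_open_conf[i])
      m[lo:hi, cols] <- matrix(vals, nrow = hi - lo + 1, ncol = 6,
                               byrow = TRUE)
    }
  }
  for (i in seq_len(nrow(utterances))) {
    lo <- max(1L, floor(utterances$start[i] / dt) + 1)
    hi <- min(n_bins, ceiling(utterances$end[i] / dt))
    if (lo > hi) next
    m[lo:hi, "speech_active"] <- 1
    m[lo:hi, "word_conf"] <- utterances$mean_confidence[i]
    ld <- utterances$loudness[i]
    if (is.finite(ld)) m[lo:hi, "loudness"] <- ld
  }
  new_feature_series(m, session_ms, dt, child_id)
}

# Fill one gappy channel. Maximal NA runs no longer than `window_bins` are
# filled with the centered moving average of non-NA values within the window
# (nearest non-NA value if the window holds none); longer runs are filled
# with 0, the face-absent baseline -- carrying the last seen face across a
# long absence would fabricate proximity.
infill_channel <- function(x, window_bins) {
  if (!anyNA(x)) return(x)
  if (all(is.na(x))) {
    warning("all-gap channel filled with 0", call. = FALSE)
    return(rep(0, length(x)))
  }
  half <- window_bins %/% 2
  isna <- is.na(x)
  r <- rle(isna)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  obs_idx <- which(!isna)
  out <- x
  for (k in which(r$values)) {
    if (r$lengths[k] > window_bins) {
      out[starts[k]:ends[k]] <- 0
    } else {
      for (i in starts[k]:ends[k]) {
        lo <- max(1L, i - half)
        hi <- min(length(x), i + half)
        nb <- x[lo:hi]
        nb <- nb[!is.na(nb)]
        if (length(nb) > 0) {
          out[i] <- mean(nb)
        } else {
          nearest <- obs_idx[which.min(abs(obs_idx - i))]
          out[i] <- x[nearest]
        }
      }
    }
  }
  out
}

#' Infill face-channel gaps with centered moving averages
#'
#' Repairs short occlusion dropouts: maximal gap runs of at most
#' \code{window_bins} bins are replaced by the mean of observed values in a
#' centered window of that width; longer absences are set to 0 (no face
#' present). The returned series contains no gap markers.
#'
#' @param series a \code{feature_series} (or bare channel matrix).
#' @param window_bins odd window width in bins (default 5, i.e. 1.25 s).
#' @return series of the same shape with no NA values.
#' @export
infill_moving_average <- function(series, window_bins = 5) {
  if (window_bins < 1 || window_bins %% 2 == 0) {
    stop("window_bins must be odd and >= 1")
  }
  m <- if (inherits(series, "feature_series")) series$channels else series
  for (j in seq_len(ncol(m))) {
    m[, j] <- infill_channel(m[, j], window_bins)
  }
  if (inherits(series, "feature_series")) {
    series$channels <- m
    series
  } else {
    m
  }
}

is_boolean_channel <- function(x) all(x %in% c(0, 1))

#' Clip per-channel upper-tail outliers at a quantile
#'
#' Values above the \code{q}-quantile of a channel are set to that quantile
#' (upper tail only; the lower tail is untouched). Boolean channels are left
#' alone.
#'
#' @param series a \code{feature_series} or channel matrix (no gaps).
#' @param q clipping quantile in (0, 1); default 0.99.
#' @export
clip_outliers <- function(series, q = 0.99) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  m <- if (inherits(series, "feature_series")) series$channels else series
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    if (is_boolean_channel(x)) next
    cap <- quantile(x, q, names = FALSE, type = 7)
    x[x > cap] <- cap
    m[, j] <- x
  }
  if (inherits(series, "feature_series")) {
    series$channels <- m
    series
  } else {
    m
  }
}

#' Fit per-channel normalization statistics on training sessions
#'
#' Center and scale are the mean and standard deviation per channel, pooled
#' over all training sessions. Constant channels pass through unchanged
#' (center 0, scale 1). Held-out sessions must be normalized with training
#' statistics only; the leave-one-subject-out harness enforces this.
#'
#' @param series_list non-empty list of \code{feature_series} (or matrices),
#'   all with the same channels.
#' @return object of class \code{norm_stats} with \code{center} and
#'   \code{scale} vectors.
#' @export
fit_normalize <- function(series_list) {
  if (length(series_list) == 0) stop("training list must be non-empty")
  mats <- lapply(series_list, function(s) {
    if (inherits(s, "feature_series")) s$channels else s
  })
  pooled <- do.call(rbind, mats)
  center <- colMeans(pooled)
  scale <- apply(pooled, 2, sd)
  const <- !is.finite(scale) | scale == 0
  center[const] <- 0
  scale[const] <- 1
  structure(list(center = center, scale = scale), class = "norm_stats")
}

#' Apply normalization statistics to a series
#' @param series a \code{feature_series} or channel matrix.
#' @param stats a \code{norm_stats} from \code{\link{fit_normalize}}.
#' @export
apply_normalize <- function(series, stats) {
  m <- if (inherits(series, "feature_series")) series$channels else series
  m <- sweep(sweep(m, 2, stats$center[colnames(m)]), 2,
             stats$scale[colnames(m)], "/")
  if (inherits(series, "feature_series")) {
    series$channels <- m
    series
  } else {
    m
  }
}

#' Build the detector-ready (pre-normalization) feature series for a session
#'
#' Runs ingest, rasterization, infilling and outlier clipping. Normalization
#' is deliberately left to the training harness, which must use training-fold
#' statistics.
#'
#' @param session a \code{synthetic_session}, session directory path, or an
#'   already-ingested list from \code{\link{ingest_session}}.
#' @param window_bins infill window (bins).
#' @param q clipping quantile.
#' @param dt bin width in ms.
#' @return a \code{feature_series} with no gaps, clipped.
#' @export
build_feature_series <- function(session, window_bins = 5, q = 0.99,
                                 dt = 250) {
  ing <- if (is.list(session) && !is.null(session$face_frames)) {
    session
  } else {
    ingest_session(session)
  }
  fs <- rasterize_features(ing$face_frames, ing$utterances, ing$session_ms,
                           dt = dt, child_id = ing$child_id)
  fs <- infill_moving_average(fs, window_bins)
  clip_outliers(fs, q)
}

#' Write a feature series as CSV for inspection
#' @param series a \code{feature_series}.
#' @param path file path; one row per bin, channels as columns, leading
#'   \code{t_ms} column with the bin onset.
#' @export
write_feature_csv <- function(series, path) {
  d <- as.data.frame(series$channels)
  d <- cbind(t_ms = (seq_len(nrow(d)) - 1) * series$dt, d)
  write.csv(d, path, row.names = FALSE, quote = FALSE)
}
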