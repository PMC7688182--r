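# Scene-ingest stage: parse featurization output, resolve face identities
# against the enrolled identity map, select the most representative face per
# frame and class (largest bounding box, a proxy for distance to the focal
# child), and segment ASR output into utterances at sentence-final
# punctuation.

.face_cols <- c("t_ms", "x", "y", "w", "h", "yaw", "roll", "pitch",
                "mouth_open_conf", "eyes_open_conf")

#' Parse a face-detection stream
#'
#' Accepts a data frame or a path to a JSONL file (one detection object per
#' line). Malformed records — missing fields, bounding boxes outside the unit
#' square, negative timestamps — are skipped and counted.
#'
#' @param x data frame of raw detections or path to a face JSONL file.
#' @return data frame of valid detections sorted by \code{t_ms}, with a
#'   \code{skipped} attribute giving the number of records dropped.
#' @export
parse_face_detections <- function(x) {
  if (is.character(x)) x <- read_face_jsonl(x)
  if (nrow(x) == 0) {
    warning("empty face-detection stream", call. = FALSE)
    out <- x[, intersect(.face_cols, names(x)), drop = FALSE]
    attr(out, "skipped") <- 0L
    return(out)
  }
  missing_cols <- setdiff(.face_cols, names(x))
  for (mc in missing_cols) x[[mc]] <- NA_real_
  x <- x[, .face_cols]
  ok <- stats::complete.cases(x) &
    x$t_ms >= 0 &
    x$x >= 0 & x$y >= 0 & x$w > 0 & x$h > 0 &
    x$x + x$w <= 1 + 1e-9 & x$y + x$h <= 1 + 1e-9
  skipped <- sum(!ok)
  if (skipped > 0) {
    message(sprintf("parse_face_detections: skipped %d malformed record(s)",
                    skipped))
  }
  out <- x[ok, , drop = FALSE]
  out <- out[order(out$t_ms), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

# Intersection-over-union of two axis-aligned boxes given as (x, y, w, h).
bbox_iou <- function(a, b) {
  ix <- pmax(0, pmin(a[1] + a[3], b[1] + b[3]) - pmax(a[1], b[1]))
  iy <- pmax(0, pmin(a[2] + a[4], b[2] + b[4]) - pmax(a[2], b[2]))
  inter <- ix * iy
  union <- a[3] * a[4] + b[3] * b[4] - inter
  if (union <= 0) 0 else inter / union
}

#' Resolve face identities by aligning detections with recognition matches
#'
#' A detection takes a match's participant class when the timestamps agree
#' within \code{t_tol} ms, the bounding boxes overlap with IoU at least
#' \code{iou_min}, and the match similarity reaches \code{sim_threshold}.
#' Detections resolved to an \code{other_adult} identity (e.g. research
#' staff) are removed entirely; unmatched detections fall back to
#' \code{unmatched_class} (the classroom is child-dominated, so the default
#' is \code{"peer"}).
#'
#' @param detections parsed detections (see
#'   \code{\link{parse_face_detections}}).
#' @param matches data frame of recognition matches with \code{t_ms},
#'   \code{face_id}, \code{similarity}, and bbox columns \code{x,y,w,h}.
#' @param identity_map data frame \code{face_id, participant_id, class} with
#'   class one of \code{teacher}, \code{peer}, \code{other_adult}.
#' @param sim_threshold minimum similarity (0-100 scale; default 92).
#' @param t_tol timestamp alignment tolerance in ms.
#' @param iou_min minimum bounding-box IoU for alignment.
#' @param unmatched_class class given to below-threshold or unmatched faces.
#' @return detections with a \code{class} column (\code{"adult"} or
#'   \code{"peer"}); \code{other_adult} rows are absent from the output.
#' @export
resolve_identities <- function(detections, matches, identity_map,
                               sim_threshold = 92, t_tol = 250,
                               iou_min = 0.5, unmatched_class = "peer") {
  n <- nrow(detections)
  cls <- rep(unmatched_class, n)
  if (n > 0 && !is.null(matches) && nrow(matches) > 0) {
    valid <- matches[matches$similarity >= sim_threshold, , drop = FALSE]
    map <- setNames(identity_map$class, identity_map$face_id)
    if (nrow(valid) > 0) {
      ord <- order(valid$t_ms)
      valid <- valid[ord, , drop = FALSE]
      for (i in seq_len(n)) {
        lo <- findInterval(detections$t_ms[i] - t_tol - 1, valid$t_ms) + 1
        hi <- findInterval(detections$t_ms[i] + t_tol, valid$t_ms)
        if (lo > hi) next
        best <- 0
        best_j <- 0L
        a <- c(detections$x[i], detections$y[i], detections$w[i],
               detections$h[i])
        for (j in lo:hi) {
          iou <- bbox_iou(a, c(valid$x[j], valid$y[j], valid$w[j],
                               valid$h[j]))
          if (iou >= iou_min && iou > best) {
            best <- iou
            best_j <- j
          }
        }
        if (best_j > 0) {
          id_class <- map[valid$face_id[best_j]]
          if (!is.na(id_class)) {
            cls[i] <- switch(id_class,
                             teacher = "adult",
                             other_adult = "other_adult",
                             "peer")
          }
        }
      }
    }
  }
  detections$class <- cls
  out <- detections[detections$class != "other_adult", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the most representative face per frame and class
#'
#' Within each frame (one timestamp), the face with the largest bounding-box
#' area is selected for each participant class; area is the proxy for
#' distance to the focal child. Ties are broken by input order (earliest
#' wins).
#'
#' @param labeled detections with a \code{class} column, one or many frames.
#' @return data frame with one row per (t_ms, class): \code{t_ms},
#'   \code{class}, and the six facial features \code{area}, \code{yaw},
#'   \code{roll}, \code{pitch}, \code{mouth_open_conf},
#'   \code{eyes_open_conf}.
#' @export
select_representative_faces <- function(labeled) {
  if (nrow(labeled) == 0) {
    return(data.frame(t_ms = numeric(0), class = character(0),
                      area = numeric(0), yaw = numeric(0), roll = numeric(0),
                      pitch = numeric(0), mouth_open_conf = numeric(0),
                      eyes_open_conf = numeric(0)))
  }
  labeled$area <- labeled$w * labeled$h
  # stable sort: within (t, class) the largest area first, input order on ties
  ord <- order(labeled$t_ms, labeled$class, -labeled$area)
  labeled <- labeled[ord, , drop = FALSE]
  first <- !duplicated(paste(labeled$t_ms, labeled$class, sep = "\r"))
  out <- labeled[first, c("t_ms", "class", "area", "yaw", "roll", "pitch",
                          "mouth_open_conf", "eyes_open_conf")]
  rownames(out) <- NULL
  out
}

#' Segment ASR output into utterances at sentence-final punctuation
#'
#' Splits each ASR segment's punctuated text at sentence-final marks
#' (\code{. ? !}); each utterance spans its first to last word timing, and
#' its tokens are normalized with \code{\link{tokenize_utterance}}
#' (contractions expanded). Commas never split. Splitting neither creates
#' nor destroys words.
#'
#' @param asr an ASR result: list with a \code{segments} list, each segment
#'   carrying \code{start_ms}, \code{end_ms}, \code{speaker_class},
#'   \code{punctuated_text}, \code{loudness} and a \code{words} data frame
#'   (\code{w}, \code{conf}, \code{start_ms}, \code{end_ms}).
#' @return data frame of utterances: \code{start}, \code{end},
#'   \code{speaker_class}, \code{text}, \code{tokens} (list column),
#'   \code{n_tokens}, \code{mean_confidence}, \code{loudness}.
#' @export
segment_utterances <- function(asr) {
  segs <- asr$segments
  out <- list()
  for (seg in segs) {
    words <- seg$words
    nw <- if (is.null(words)) 0L else nrow(words)
    if (nw == 0) next
    if (is.null(seg$punctuated_text) || !nzchar(seg$punctuated_text)) {
      stop("inconsistent ASR record: segment has words but no text")
    }
    sentences <- strsplit(seg$punctuated_text, "(?<=[.?!])\\s*",
                          perl = TRUE)[[1]]
    sentences <- sentences[nzchar(trimws(sentences))]
    counts <- vapply(sentences, function(s) {
      toks <- strsplit(trimws(gsub("[.?!]+", " ", s)), "\\s+")[[1]]
      length(toks[nzchar(toks)])
    }, integer(1))
    if (sum(counts) != nw) {
      stop("inconsistent ASR record: text/word-timing mismatch")
    }
    hi <- cumsum(counts)
    lo <- hi - counts + 1L
    for (k in seq_along(sentences)) {
      toks <- tokenize_utterance(sentences[k])
      if (length(toks) == 0) next
      idx <- lo[k]:hi[k]
      out[[length(out) + 1]] <- data.frame(
        start = words$start_ms[idx[1]],
        end = words$end_ms[idx[length(idx)]],
        speaker_class = seg$speaker_class,
        text = trimws(gsub("[.?!]+$", "", sentences[k])),
        tokens = I(list(toks)),
        n_tokens = length(toks),
        mean_confidence = mean(words$conf[idx]),
        loudness = seg$loudness %||% NA_real_
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      speaker_class = character(0), text = character(0),
                      tokens = I(list()), n_tokens = integer(0),
                      mean_confidence = numeric(0), loudness = numeric(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-segment loudness: pass-through or energy proxy
#'
#' When segments already carry a precomputed loudness channel it is returned
#' unchanged. Otherwise a documented energy-based proxy is applied to raw
#' sample amplitudes: \code{(mean(x^2))^0.3}, a compressive power-law map of
#' mean energy that is strictly monotone in amplitude scale.
#'
#' @param segments list of ASR segments (each possibly carrying
#'   \code{loudness}).
#' @param samples optional list of numeric amplitude vectors, one per
#'   segment, used when the loudness channel is absent.
#' @return numeric vector of non-negative loudness values, one per segment.
#' @export
compute_segment_loudness <- function(segments, samples = NULL) {
  pre <- vapply(segments, function(s) s$loudness %||% NA_real_, numeric(1))
  if (all(is.finite(pre))) return(pre)
  if (is.null(samples)) {
    stop("loudness channel absent and no sample amplitudes supplied")
  }
  stopifnot(length(samples) == length(segments))
  vapply(samples, function(x) mean(x^2)^0.3, numeric(1))
}

#' Ingest a session into labeled face frames and utterances
#'
#' Convenience wrapper running the full ingest stage on an in-memory
#' synthetic session or a session directory: parse detections, resolve
#' identities, select representative faces, and segment utterances.
#'
#' @param session a \code{synthetic_session} or a path to a session
#'   directory written by \code{\link{write_session}}.
#' @param ... passed to \code{\link{resolve_identities}}.
#' @return list with \code{face_frames}, \code{utterances},
#'   \code{session_ms}, \code{child_id}.
#' @export
ingest_session <- function(session, ...) {
  if (is.character(session)) session <- read_session(session)
  det <- parse_face_detections(session$faces)
  labeled <- resolve_identities(det, session$matches, session$identity_map,
                                ...)
  list(
    face_frames = select_representative_faces(labeled),
    utterances = segment_utterances(session$asr),
    session_ms = session$session_ms,
    child_id = session$child_id
  )
}
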