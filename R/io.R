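# Readers and writers for the documented on-disk schemas: face detections
# (JSONL), identity matches (JSONL), ASR output (JSON), interaction interval
# tables (CSV), reference transcripts (TSV) and measure tables (CSV). All
# timestamps are integer-valued milliseconds; intervals are half-open.

jsonl_write <- function(rows, path) {
  lines <- vapply(rows, function(r) {
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, path)
}

jsonl_read <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lapply(seq_along(lines), function(i) {
    tryCatch(jsonlite::fromJSON(lines[i]),
             error = function(e) {
               stop(sprintf("malformed JSONL at line %d of %s", i, path),
                    call. = FALSE)
             })
  })
}

#' Write / read a face-detection stream as JSONL
#'
#' One object per detection:
#' \code{\{"t_ms", "bbox":\{"x","y","w","h"\}, "pose":\{"yaw","roll","pitch"\},
#' "mouth_open_conf", "eyes_open_conf"\}}.
#'
#' @param faces flat detections data frame (columns \code{t_ms}, \code{x},
#'   \code{y}, \code{w}, \code{h}, \code{yaw}, \code{roll}, \code{pitch},
#'   \code{mouth_open_conf}, \code{eyes_open_conf}).
#' @param path file path.
#' @export
write_face_jsonl <- function(faces, path) {
  rows <- lapply(seq_len(nrow(faces)), function(i) {
    list(
      t_ms = faces$t_ms[i],
      bbox = list(x = faces$x[i], y = faces$y[i], w = faces$w[i],
                  h = faces$h[i]),
      pose = list(yaw = faces$yaw[i], roll = faces$roll[i],
                  pitch = faces$pitch[i]),
      mouth_open_conf = faces$mouth_open_conf[i],
      eyes_open_conf = faces$eyes_open_conf[i]
    )
  })
  jsonl_write(rows, path)
}

#' @rdname write_face_jsonl
#' @export
read_face_jsonl <- function(path) {
  rows <- jsonl_read(path)
  if (length(rows) == 0) {
    return(data.frame(t_ms = numeric(0), x = numeric(0), y = numeric(0),
                      w = numeric(0), h = numeric(0), yaw = numeric(0),
                      roll = numeric(0), pitch = numeric(0),
                      mouth_open_conf = numeric(0),
                      eyes_open_conf = numeric(0)))
  }
  do.call(rbind, lapply(rows, function(r) {
    data.frame(
      t_ms = r$t_ms %||% NA_real_,
      x = r$bbox$x %||% NA_real_, y = r$bbox$y %||% NA_real_,
      w = r$bbox$w %||% NA_real_, h = r$bbox$h %||% NA_real_,
      yaw = r$pose$yaw %||% NA_real_, roll = r$pose$roll %||% NA_real_,
      pitch = r$pose$pitch %||% NA_real_,
      mouth_open_conf = r$mouth_open_conf %||% NA_real_,
      eyes_open_conf = r$eyes_open_conf %||% NA_real_
    )
  }))
}

#' Write / read identity matches as JSONL
#'
#' One object per match:
#' \code{\{"t_ms", "face_id", "similarity", "bbox":\{"x","y","w","h"\}\}}.
#'
#' @param matches data frame with \code{t_ms}, \code{face_id},
#'   \code{similarity} and bbox columns.
#' @param path file path.
#' @export
write_matches_jsonl <- function(matches, path) {
  rows <- lapply(seq_len(nrow(matches)), function(i) {
    list(
      t_ms = matches$t_ms[i],
      face_id = matches$face_id[i],
      similarity = matches$similarity[i],
      bbox = list(x = matches$x[i], y = matches$y[i], w = matches$w[i],
                  h = matches$h[i])
    )
  })
  jsonl_write(rows, path)
}

#' @rdname write_matches_jsonl
#' @export
read_matches_jsonl <- function(path) {
  rows <- jsonl_read(path)
  if (length(rows) == 0) {
    return(data.frame(t_ms = numeric(0), face_id = character(0),
                      similarity = numeric(0), x = numeric(0),
                      y = numeric(0), w = numeric(0), h = numeric(0)))
  }
  do.call(rbind, lapply(rows, function(r) {
    data.frame(t_ms = r$t_ms, face_id = r$face_id,
               similarity = r$similarity,
               x = r$bbox$x, y = r$bbox$y, w = r$bbox$w, h = r$bbox$h)
  }))
}

#' Write / read ASR output as JSON
#'
#' Schema: \code{\{"segments": [\{"start_ms", "end_ms", "speaker_class",
#' "punctuated_text", "loudness", "words": [\{"w","conf","start_ms",
#' "end_ms"\}]\}]\}}.
#'
#' @param asr ASR result (list with a \code{segments} list).
#' @param path file path.
#' @export
write_asr_json <- function(asr, path) {
  jsonlite::write_json(asr, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
}

#' @rdname write_asr_json
#' @export
read_asr_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  segments <- lapply(x$segments, function(s) {
    words <- if (length(s$words) == 0) {
      data.frame(w = character(0), conf = numeric(0),
                 start_ms = numeric(0), end_ms = numeric(0))
    } else {
      do.call(rbind, lapply(s$words, function(w) {
        data.frame(w = w$w, conf = w$conf, start_ms = w$start_ms,
                   end_ms = w$end_ms)
      }))
    }
    list(start_ms = s$start_ms, end_ms = s$end_ms,
         speaker_class = s$speaker_class,
         punctuated_text = s$punctuated_text,
         loudness = s$loudness %||% NA_real_,
         words = words)
  })
  list(segments = segments)
}

#' Write / read interaction interval tables as CSV
#'
#' Dialect: comma-separated, UTF-8, header row
#' \code{child_id,partner,onset_ms,offset_ms}; used for both reference and
#' predicted tracks.
#'
#' @param tracks named list of \code{interval_track}s per child (names are
#'   child ids), or a single track with \code{child_id} given.
#' @param path file path.
#' @param child_id child id used when \code{tracks} is a single track.
#' @export
write_track_csv <- function(tracks, path, child_id = NULL) {
  if (inherits(tracks, "interval_track")) {
    tracks <- setNames(list(tracks), child_id %||% "child01")
  }
  rows <- do.call(rbind, lapply(names(tracks), function(id) {
    iv <- tracks[[id]]$intervals
    if (nrow(iv) == 0) return(NULL)
    data.frame(child_id = id, partner = tracks[[id]]$partner,
               onset_ms = iv$onset, offset_ms = iv$offset)
  }))
  if (is.null(rows)) {
    rows <- data.frame(child_id = character(0), partner = character(0),
                       onset_ms = numeric(0), offset_ms = numeric(0))
  }
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
}

#' @rdname write_track_csv
#' @export
read_track_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

# Build an interval_track for one child/partner out of an interval table.
track_from_table <- function(tab, child_id, partner, source = "reference") {
  sel <- tab$child_id == child_id & tab$partner == partner
  interval_track(tab$onset_ms[sel], tab$offset_ms[sel], partner = partner,
                 source = source)
}

#' Write / read reference transcripts as tab-separated text
#'
#' One line per utterance: \code{speaker_code<TAB>onset_ms<TAB>offset_ms<TAB>
#' utterance text}.
#'
#' @param utterances data frame with \code{speaker_class}, \code{start},
#'   \code{end}, \code{text}.
#' @param path file path.
#' @export
write_transcript_tsv <- function(utterances, path) {
  lines <- sprintf("%s\t%d\t%d\t%s",
                   utterances$speaker_class,
                   as.integer(utterances$start),
                   as.integer(utterances$end),
                   utterances$text)
  writeLines(lines, path)
}

#' @rdname write_transcript_tsv
#' @export
read_transcript_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(speaker_class = character(0), start = numeric(0),
                      end = numeric(0), text = character(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 4)
  if (length(bad) > 0) {
    stop(sprintf("malformed transcript at line %d of %s", bad[1], path))
  }
  data.frame(
    speaker_class = vapply(parts, `[[`, character(1), 1),
    start = as.numeric(vapply(parts, `[[`, character(1), 2)),
    end = as.numeric(vapply(parts, `[[`, character(1), 3)),
    text = vapply(parts, `[[`, character(1), 4)
  )
}

#' Write / read a measure table as CSV
#'
#' Layout: \code{child_id,partner,tnu,tnw,ndw,mlu,ttr,recording_min,normed}.
#' @param tab measures data frame.
#' @param path file path.
#' @export
write_measures_csv <- function(tab, path) {
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
}

#' @rdname write_measures_csv
#' @export
read_measures_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write a synthetic session to a directory in the documented schemas
#'
#' Writes \code{faces.jsonl}, \code{matches.jsonl}, \code{identity_map.csv},
#' \code{asr.json}, \code{reference_intervals.csv},
#' \code{reference_transcript.tsv} and a \code{manifest.json} carrying the
#' child id, session length, seed and full config, sufficient to reproduce
#' the session.
#'
#' @param session a \code{synthetic_session}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_face_jsonl(session$faces, file.path(dir, "faces.jsonl"))
  write_matches_jsonl(session$matches, file.path(dir, "matches.jsonl"))
  write.csv(session$identity_map, file.path(dir, "identity_map.csv"),
            row.names = FALSE, quote = FALSE)
  write_asr_json(session$asr, file.path(dir, "asr.json"))
  iv_a <- session$truth_adult$intervals
  iv_p <- session$truth_peer$intervals
  tab <- rbind(
    data.frame(child_id = rep(session$child_id, nrow(iv_a)),
               partner = rep("adult", nrow(iv_a)),
               onset_ms = iv_a$onset, offset_ms = iv_a$offset),
    data.frame(child_id = rep(session$child_id, nrow(iv_p)),
               partner = rep("peer", nrow(iv_p)),
               onset_ms = iv_p$onset, offset_ms = iv_p$offset)
  )
  write.csv(tab, file.path(dir, "reference_intervals.csv"),
            row.names = FALSE, quote = FALSE)
  write_transcript_tsv(session$reference,
                       file.path(dir, "reference_transcript.tsv"))
  manifest <- list(
    child_id = session$child_id,
    session_ms = session$session_ms,
    seed = session$seed,
    config = unclass(session$config)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_session
#' @param recompute_bookkeeping recompute reference labels and measure sets
#'   from the transcript and truth intervals (default TRUE).
#' @export
read_session <- function(dir, recompute_bookkeeping = TRUE) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                                 simplifyVector = TRUE)
  cfg <- do.call(sim_config, manifest$config)
  tab <- read_track_csv(file.path(dir, "reference_intervals.csv"))
  truth_adult <- track_from_table(tab, manifest$child_id, "adult")
  truth_peer <- track_from_table(tab, manifest$child_id, "peer")
  reference <- read_transcript_tsv(file.path(dir, "reference_transcript.tsv"))
  session <- list(
    child_id = manifest$child_id,
    session_ms = manifest$session_ms,
    config = cfg,
    seed = manifest$seed,
    truth_adult = truth_adult,
    truth_peer = truth_peer,
    faces = read_face_jsonl(file.path(dir, "faces.jsonl")),
    matches = read_matches_jsonl(file.path(dir, "matches.jsonl")),
    identity_map = read.csv(file.path(dir, "identity_map.csv"),
                            stringsAsFactors = FALSE),
    asr = read_asr_json(file.path(dir, "asr.json")),
    reference = reference
  )
  if (recompute_bookkeeping) {
    ref <- label_reference(reference, truth_adult, truth_peer)
    session$reference <- ref
    session$bookkeeping <- session_bookkeeping(
      ref, truth_adult, truth_peer, cfg$session_minutes)
  }
  class(session) <- "synthetic_session"
  session
}
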