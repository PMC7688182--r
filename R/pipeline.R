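# End-to-end study harness: simulate a cohort, ingest, build features, run
# leave-one-subject-out interaction detection, map utterances to CDS classes
# with the predicted tracks, compute measures, and evaluate raw and
# OLP-adapted agreement with the reference. This is the validation loop the
# reports are derived from.

measure_rows <- function(utterances, adult_track, peer_track, minutes,
                         child_id) {
  focal <- utterances$speaker_class == "focal"
  others <- assign_utterances(utterances[!focal, , drop = FALSE],
                              adult_track, peer_track)
  foc <- collect_focal_speech(utterances[focal, , drop = FALSE],
                              adult_track, peer_track)
  sets <- list(
    adult = others[others$cds_label == "adult_cds", , drop = FALSE],
    peer = others[others$cds_label == "peer_cds", , drop = FALSE],
    focal = foc[foc$directed != "none", , drop = FALSE]
  )
  do.call(rbind, lapply(names(sets), function(sp) {
    ms <- cds_measures(sets[[sp]], minutes, norm = TRUE)
    data.frame(child_id = child_id, speaker = sp, tnu = ms$tnu,
               tnw = ms$tnw, ndw = ms$ndw, mlu = ms$mlu, ttr = ms$ttr)
  }))
}

bookkeeping_rows <- function(session) {
  bk <- session$bookkeeping$cds
  do.call(rbind, lapply(names(bk), function(sp) {
    data.frame(child_id = session$child_id, speaker = sp,
               tnu = bk[[sp]]$tnu, tnw = bk[[sp]]$tnw, ndw = bk[[sp]]$ndw,
               mlu = bk[[sp]]$mlu, ttr = bk[[sp]]$ttr)
  }))
}

#' Run the full synthetic validation study
#'
#' Generates a cohort, optionally round-trips every session through the
#' on-disk schemas, ingests and featurizes each session, trains and applies
#' the adult (full-feature) and peer (reduced-feature) detectors in a
#' leave-one-subject-out loop (or uses reference tracks when
#' \code{use_reference_tracks}), assigns the ASR utterances to CDS classes
#' with the resulting tracks, computes CDS and interaction measures, and
#' evaluates raw and OLP-adapted agreement against the generation-time
#' reference.
#'
#' @param config a \code{\link{sim_config}}.
#' @param n_children cohort size (default 13).
#' @param spec_adult,spec_peer detector specs; the defaults use a
#'   desk-scale architecture (16 hidden units, 8 epochs) rather than the
#'   full 200-unit one, seeded from the config.
#' @param use_reference_tracks skip detector training and diarize with the
#'   ground-truth tracks (isolates the transcript-measure pipeline).
#' @param io_dir when given, each session is written to and re-read from
#'   \code{io_dir/<child_id>} so the study exercises the documented formats.
#' @param min_dur_ms smoothing threshold for predicted tracks.
#' @return list of class \code{study_result} with \code{detect_report},
#'   \code{measure_report}, \code{tdi_report}, per-child data frames
#'   (\code{detect_metrics}, \code{raw_measures}, \code{ref_measures}),
#'   predicted \code{tracks}, the \code{measure_eval} object (with fold
#'   models), and the cohort.
#' @export
run_study <- function(config, n_children = 13,
                      spec_adult = NULL, spec_peer = NULL,
                      use_reference_tracks = FALSE,
                      io_dir = NULL, min_dur_ms = 1000) {
  if (is.null(spec_adult)) {
    spec_adult <- detector_spec("adult", "full", hidden_units = 16,
                                epochs = 8, learn_rate = 0.02,
                                seed = derive_seed(config$seed, 11))
  }
  if (is.null(spec_peer)) {
    spec_peer <- detector_spec("peer", "reduced", hidden_units = 16,
                               epochs = 8, learn_rate = 0.02,
                               seed = derive_seed(config$seed, 12))
  }
  cohort <- generate_cohort(config, n_children)
  if (!is.null(io_dir)) {
    cohort <- structure(lapply(cohort, function(s) {
      d <- file.path(io_dir, s$child_id)
      write_session(s, d)
      read_session(d)
    }), class = "synthetic_cohort")
  }
  ing <- lapply(cohort, ingest_session)
  fs <- lapply(ing, build_feature_series)
  child_ids <- vapply(cohort, function(s) s$child_id, character(1))
  minutes <- config$session_minutes

  refs <- list(adult = lapply(cohort, `[[`, "truth_adult"),
               peer = lapply(cohort, `[[`, "truth_peer"))
  if (use_reference_tracks) {
    tracks <- list(adult = refs$adult, peer = refs$peer)
    detect <- NULL
    detect_metrics <- NULL
  } else {
    detect <- list(
      adult = loso_detect(fs, refs$adult, spec_adult, child_ids,
                          min_dur_ms = min_dur_ms),
      peer = loso_detect(fs, refs$peer, spec_peer, child_ids,
                         min_dur_ms = min_dur_ms)
    )
    tracks <- list(adult = detect$adult$tracks, peer = detect$peer$tracks)
    detect_metrics <- rbind(
      cbind(partner = "adult", detect$adult$metrics),
      cbind(partner = "peer", detect$peer$metrics)
    )
  }

  raw <- do.call(rbind, lapply(seq_along(cohort), function(i) {
    measure_rows(ing[[i]]$utterances, tracks$adult[[i]], tracks$peer[[i]],
                 minutes, child_ids[i])
  }))
  ref <- do.call(rbind, lapply(cohort, bookkeeping_rows))
  eval_meas <- loso_measure_eval(raw, ref)

  detect_report <- if (is.null(detect_metrics)) NULL else {
    do.call(rbind, lapply(split(detect_metrics, detect_metrics$partner),
                          function(d) {
      # means over the children for whom the ratio is defined (a child with
      # no true or no predicted interaction has undefined precision/recall)
      data.frame(partner = d$partner[1],
                 accuracy = mean(d$accuracy, na.rm = TRUE),
                 precision = mean(d$precision, na.rm = TRUE),
                 recall = mean(d$recall, na.rm = TRUE),
                 f1 = mean(d$f1, na.rm = TRUE))
    }))
  }

  tdi_report <- do.call(rbind, lapply(c("adult", "peer"), function(pc) {
    ref_tdi <- vapply(refs[[pc]], function(tr) track_total_ms(tr) / 1000,
                      numeric(1))
    pred_tdi <- vapply(tracks[[pc]], function(tr) track_total_ms(tr) / 1000,
                       numeric(1))
    ag <- agreement_summary(ref_tdi, pred_tdi)
    data.frame(partner = pc, mre = ag$mre, mare = ag$mare, r = ag$r,
               n = ag$n)
  }))

  structure(
    list(config = config, spec_adult = spec_adult, spec_peer = spec_peer,
         detect_report = detect_report, detect_metrics = detect_metrics,
         measure_report = eval_meas$report, measure_eval = eval_meas,
         tdi_report = tdi_report, raw_measures = raw, ref_measures = ref,
         tracks = tracks, detect = detect, cohort = cohort),
    class = "study_result"
  )
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result>\n")
  if (!is.null(x$detect_report)) {
    cat("Detector LOSO means:\n")
    print(x$detect_report, row.names = FALSE, digits = 3)
  }
  cat("Measure agreement (mARE / r):\n")
  print(x$measure_report, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a study report as a flat CSV
#'
#' One row per reported quantity (\code{block}, \code{group}, \code{measure},
#' \code{adaptation}, \code{value}); values are rounded to six significant
#' digits at write time so the file is stable across platforms.
#'
#' @param study a \code{study_result}.
#' @param path output CSV path.
#' @export
write_study_report <- function(study, path) {
  fmt <- function(x) {
    ifelse(is.na(x), "NA", formatC(signif(x, 6), format = "g", digits = 6))
  }
  rows <- NULL
  if (!is.null(study$detect_report)) {
    for (i in seq_len(nrow(study$detect_report))) {
      d <- study$detect_report[i, ]
      for (m in c("accuracy", "precision", "recall", "f1")) {
        rows <- rbind(rows, data.frame(block = "detection",
                                       group = d$partner, measure = m,
                                       adaptation = "", value = fmt(d[[m]])))
      }
    }
  }
  for (i in seq_len(nrow(study$measure_report))) {
    d <- study$measure_report[i, ]
    for (m in c("mare", "mre", "r")) {
      rows <- rbind(rows, data.frame(block = "measures", group = d$speaker,
                                     measure = paste(d$measure, m, sep = "_"),
                                     adaptation = d$adaptation,
                                     value = fmt(d[[m]])))
    }
  }
  for (i in seq_len(nrow(study$tdi_report))) {
    d <- study$tdi_report[i, ]
    for (m in c("mre", "mare", "r")) {
      rows <- rbind(rows, data.frame(block = "interaction", group = d$partner,
                                     measure = paste("tdi", m, sep = "_"),
                                     adaptation = "", value = fmt(d[[m]])))
    }
  }
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
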