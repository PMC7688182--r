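# Utterance diarization by interval overlap: every non-focal utterance is
# assigned to adult-CDS, peer-CDS or non-CDS according to which interaction
# track it intersects; adult takes precedence when both intersect. Focal-child
# utterances are partitioned the same way into directed-to-adult /
# directed-to-peer / outside-interaction speech.

#' Assign utterances to CDS classes by interaction overlap
#'
#' An utterance with a positive-length intersection with the adult
#' interaction track is labeled \code{adult_cds}; otherwise, a positive
#' intersection with the peer track gives \code{peer_cds}; otherwise the
#' utterance is \code{non_cds}. Intervals are half-open \code{[start, end)},
#' so touching at a single endpoint does not count as intersection. The rule
#' depends only on timing, not on who spoke.
#'
#' @param utterances data frame with \code{start}, \code{end} (ms) columns;
#'   rows with \code{speaker_class == "focal"} should be handled with
#'   \code{\link{collect_focal_speech}} instead.
#' @param adult_track,peer_track \code{interval_track}s (reference or
#'   predicted).
#' @return \code{utterances} with a \code{cds_label} column added, one of
#'   \code{"adult_cds"}, \code{"peer_cds"}, \code{"non_cds"}.
#' @export
assign_utterances <- function(utterances, adult_track, peer_track) {
  n <- nrow(utterances)
  lab <- rep("non_cds", n)
  if (n > 0) {
    in_adult <- overlaps_track(utterances$start, utterances$end, adult_track)
    in_peer <- overlaps_track(utterances$start, utterances$end, peer_track)
    lab[in_peer] <- "peer_cds"
    lab[in_adult] <- "adult_cds"  # adult precedence
  }
  utterances$cds_label <- lab
  utterances
}

#' Partition focal-child utterances by the partner they were directed to
#'
#' A focal utterance intersecting the adult track is directed to an adult
#' (adult precedence over peer, as for CDS assignment); otherwise to a peer
#' if it intersects the peer track; utterances outside all interactions are
#' excluded from speech measures.
#'
#' @param utterances data frame of focal-child utterances with \code{start},
#'   \code{end} columns.
#' @inheritParams assign_utterances
#' @return \code{utterances} with a \code{directed} column, one of
#'   \code{"adult"}, \code{"peer"}, \code{"none"}.
#' @export
collect_focal_speech <- function(utterances, adult_track, peer_track) {
  n <- nrow(utterances)
  dir <- rep("none", n)
  if (n > 0) {
    in_adult <- overlaps_track(utterances$start, utterances$end, adult_track)
    in_peer <- overlaps_track(utterances$start, utterances$end, peer_track)
    dir[in_peer] <- "peer"
    dir[in_adult] <- "adult"
  }
  utterances$directed <- dir
  utterances
}
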