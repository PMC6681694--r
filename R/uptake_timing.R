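# Uptake-time matching. Two sessions of the same modality acquire
# list-mode data over windows that may start at different times
# post-injection; a static frame of fixed duration is chosen inside the
# overlap of the two windows so that both sessions share the *same* real
# uptake interval. Policy "latest" takes the latest such frame (used for
# the shorter, earlier PET/CT windows), "earliest" the earliest (used for
# PET/MRI, minimizing the gap to the PET/CT frames). Intervals are
# half-open [start, end) real-valued minutes; no list-mode discretization.

#' An acquisition window in minutes post-injection
#'
#' @param startMin window start, minutes post-injection.
#' @param durationMin window duration, minutes (> 0); 15 min is typical
#'   for a PET/CT station, 30 min for PET/MRI.
#' @return A list with `startMin`, `durationMin`, `endMin`.
#' @export
acquisitionWindow <- function(startMin, durationMin) {
  stopifnot(is.finite(startMin), durationMin > 0)
  list(startMin = startMin, durationMin = durationMin,
       endMin = startMin + durationMin)
}

#' Select a frame with identical effective uptake time in two windows
#'
#' The overlap of the two windows is
#' `[max(start1, start2), min(end1, end2)]`; it must be at least
#' `frameDurationMin` long. Policy `"latest"` places the frame at
#' `[min(end) - f, min(end)]`, `"earliest"` at
#' `[max(start), max(start) + f]`. Both sessions then reconstruct the
#' exact same real interval; the per-session `offsets` give the time to
#' skip from each window's start.
#'
#' @param w1,w2 windows from [acquisitionWindow()] (sessions 1 and 2).
#' @param frameDurationMin static frame duration, minutes (1, 3 or 5 in a
#'   typical protocol; any positive value is accepted).
#' @param policy `"latest"` or `"earliest"`.
#' @return A list with `frameDurationMin`, `uptakeInterval` (numeric(2),
#'   minutes post-injection), `offsets` (numeric(2), skip from each
#'   window start) and `policy`.
#' @examples
#' w1 <- acquisitionWindow(60, 15); w2 <- acquisitionWindow(62, 15)
#' matchedInterval(w1, w2, 5, "latest")$uptakeInterval  # c(70, 75)
#' @export
matchedInterval <- function(w1, w2, frameDurationMin,
                            policy = c("latest", "earliest")) {
  policy <- match.arg(policy)
  stopifnot(frameDurationMin > 0)
  lo <- max(w1$startMin, w2$startMin)
  hi <- min(w1$endMin, w2$endMin)
  if (hi - lo < frameDurationMin)
    stop(sprintf(
      "windows overlap for %.3g min, %.3g min short of the %.3g-min frame",
      max(0, hi - lo), frameDurationMin - max(0, hi - lo),
      frameDurationMin))
  iv <- if (policy == "latest") c(hi - frameDurationMin, hi)
        else c(lo, lo + frameDurationMin)
  list(frameDurationMin = frameDurationMin, uptakeInterval = iv,
       offsets = c(iv[1] - w1$startMin, iv[1] - w2$startMin),
       policy = policy)
}

#' Audit summary of matched uptake intervals
#'
#' For a set of matched intervals (one per subject, one modality),
#' reports the mean and range of the frame endpoints (policy `"latest"`)
#' or start points (policy `"earliest"`), mirroring the per-modality
#' uptake-time audit of a test-retest study report.
#'
#' @param intervals a list of results from [matchedInterval()].
#' @param policy which anchor to summarize; defaults to the policy of the
#'   first interval.
#' @return A list with `n`, `anchor` (`"endpoint"` or `"startpoint"`),
#'   `meanMin` and `rangeMin` (numeric(2)).
#' @export
uptakeReport <- function(intervals, policy = NULL) {
  stopifnot(length(intervals) >= 1L)
  if (is.null(policy)) policy <- intervals[[1]]$policy
  anchor <- if (policy == "latest") "endpoint" else "startpoint"
  t <- vapply(intervals, function(iv)
    if (anchor == "endpoint") iv$uptakeInterval[2]
    else iv$uptakeInterval[1], numeric(1))
  list(n = length(t), anchor = anchor, meanMin = mean(t),
       rangeMin = range(t))
}
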