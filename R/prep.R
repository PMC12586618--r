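# Duration normalization to the cohort median and assembly of the
# analysis-ready functional data table.

#' Median utterance duration in frames
#'
#' The sample median of the trial durations. Durations are integer frame
#' counts, so for even counts the mean of the two middle values is rounded
#' half-up to an integer.
#'
#' @param durations integer vector of per-trial frame counts.
#' @return integer median frame count T*.
#' @export
#' @examples
#' medianDuration(c(5, 7, 9))    # 7
#' medianDuration(c(4, 5, 6, 7)) # 6 (5.5 rounds half-up)
medianDuration <- function(durations) {
  if (!length(durations)) stop("empty duration list")
  if (any(durations < 1)) stop("durations must be positive frame counts")
  s <- sort(as.numeric(durations))
  n <- length(s)
  m <- if (n %% 2L == 1L) s[(n + 1L) %/% 2L] else (s[n %/% 2L] + s[n %/% 2L + 1L]) / 2
  as.integer(floor(m + 0.5))
}

#' Stretch or compress a trajectory to a target frame count
#'
#' The source index grid `[0, L-1]` is mapped affinely onto `[0, T*-1]` and
#' values are read off by linear interpolation, preserving both endpoints
#' exactly (and, being linear, never overshooting the source range).
#'
#' @param traj numeric vector (length >= 2).
#' @param t_star target number of frames.
#' @return numeric vector of length `t_star`.
#' @export
#' @examples
#' resampleLinear(0:10, 21)
resampleLinear <- function(traj, t_star) {
  L <- length(traj)
  if (L < 2L) stop("trajectory must have at least 2 frames")
  if (t_star < 2L) stop("target length must be at least 2 frames")
  if (L == t_star) return(as.numeric(traj))
  xout <- seq(0, L - 1, length.out = t_star)
  stats::approx(x = 0:(L - 1), y = traj, xout = xout, method = "linear")$y
}

#' Assemble the analysis-ready, time-normalized trajectory set
#'
#' Applies the trial screening bookkeeping: metadata-flagged exclusions
#' (stuttered / mispronounced trials supplied as `include = FALSE`), the
#' training-repetition rule (the first `drop_first` repetition indices are
#' dropped), the cap of at most `max_reps` analyzed repetitions per subject
#' (the first surviving ones, in repetition order), and a minimum-repetition
#' requirement per subject. Surviving trajectories are resampled to the joint
#' median duration T* by linear interpolation. Every exclusion is logged.
#'
#' @param trajectories long data.frame with columns subject, group,
#'   repetition, site, frame, width (optionally archetype and width_mm;
#'   `width_px` is accepted as the width column).
#' @param metadata optional data.frame with columns subject, repetition,
#'   include (logical) and reason.
#' @param min_reps subjects with fewer surviving repetitions are dropped.
#' @param max_reps analyzed-repetition cap (default 10).
#' @param drop_first number of leading training repetitions to drop
#'   (default 0; the study rule is 2 when the recordings include them).
#' @return a [TrajectorySet-class].
#' @export
assembleTrajectories <- function(trajectories, metadata = NULL, min_reps = 1L,
                                 max_reps = 10L, drop_first = 0L) {
  tr <- as.data.frame(trajectories)
  if (!"width" %in% names(tr) && "width_px" %in% names(tr))
    tr$width <- tr$width_px
  need <- c("subject", "group", "repetition", "site", "frame", "width")
  if (!all(need %in% names(tr)))
    stop("trajectory table must have subject, group, repetition, site, frame, width")
  if (!setequal(unique(tr$site), .SITES))
    stop("trajectory table must cover exactly the six canonical sites")

  excl <- list()
  note <- function(subject, repetition, reason)
    excl[[length(excl) + 1L]] <<- data.frame(subject = subject,
      repetition = repetition, reason = reason)

  trials <- unique(tr[, c("subject", "group", "repetition")])
  trials <- trials[order(trials$subject, trials$repetition), ]
  keep <- rep(TRUE, nrow(trials))

  if (!is.null(metadata) && nrow(metadata)) {
    for (i in seq_len(nrow(metadata))) {
      m <- metadata[i, ]
      if (isFALSE(m$include)) {
        j <- which(trials$subject == m$subject & trials$repetition == m$repetition)
        if (length(j)) {
          keep[j] <- FALSE
          note(m$subject, m$repetition,
               if (!is.null(m$reason) && !is.na(m$reason)) m$reason else "flagged")
        }
      }
    }
  }
  if (drop_first > 0L) {
    j <- which(trials$repetition <= drop_first & keep)
    keep[j] <- FALSE
    for (i in j) note(trials$subject[i], trials$repetition[i], "training repetition")
  }
  # cap analyzed repetitions per subject at max_reps (first surviving ones)
  for (s in unique(trials$subject)) {
    j <- which(trials$subject == s & keep)
    if (length(j) > max_reps) {
      drop <- j[-seq_len(max_reps)]
      keep[drop] <- FALSE
      for (i in drop) note(s, trials$repetition[i], "repetition cap")
    }
  }
  # minimum repetitions per subject
  for (s in unique(trials$subject)) {
    j <- which(trials$subject == s & keep)
    if (length(j) < min_reps && length(j) > 0L) {
      keep[j] <- FALSE
      for (i in j) note(s, trials$repetition[i],
                        sprintf("subject has < %d repetitions", min_reps))
    }
  }
  trials <- trials[keep, , drop = FALSE]
  if (!nrow(trials)) stop("no trials survive the exclusion rules")

  key <- function(s, r) paste(s, r, sep = "\r")
  tr <- tr[key(tr$subject, tr$repetition) %in% key(trials$subject, trials$repetition), ]

  durs <- vapply(seq_len(nrow(trials)), function(i) {
    sel <- tr$subject == trials$subject[i] & tr$repetition == trials$repetition[i]
    max(tr$frame[sel])
  }, numeric(1))
  t_star <- medianDuration(durs)

  has_arch <- "archetype" %in% names(tr)
  cols <- list(); idx <- list()
  for (i in seq_len(nrow(trials))) {
    sel <- tr$subject == trials$subject[i] & tr$repetition == trials$repetition[i]
    td <- tr[sel, ]
    for (site in .SITES) {
      ts_rows <- td[td$site == site, ]
      y <- ts_rows$width[order(ts_rows$frame)]
      cols[[length(cols) + 1L]] <- resampleLinear(y, t_star)
      idx[[length(idx) + 1L]] <- data.frame(
        subject = trials$subject[i], group = trials$group[i],
        repetition = trials$repetition[i], site = site,
        archetype = if (has_arch) td$archetype[td$site == site][1] else NA_character_)
    }
  }
  widths <- do.call(cbind, cols)
  index <- do.call(rbind, idx)
  if (!has_arch) index$archetype <- NULL
  colnames(widths) <- paste(index$subject, index$repetition, index$site, sep = ".")
  TrajectorySet(widths, index,
                exclusions = if (length(excl)) do.call(rbind, excl) else data.frame())
}
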