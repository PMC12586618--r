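# Synthetic vocal-tract cohort generator: smooth per-site gesture curves with
# group-archetype coupling, subject-level random curves and repetition noise.

#' CohortDesign: design of a synthetic articulation cohort
#'
#' @slot n_subjects_per_group named integer, subjects per archetype.
#' @slot n_repetitions repetitions per subject.
#' @slot n_frames_mean mean utterance duration in frames.
#' @slot duration_jitter_sd SD of the duration jitter (frames).
#' @slot sites the six canonical site labels.
#' @slot group_archetypes named list; each entry a list with elements `group`
#'   ("AWS"/"FS"), `amp` (global gesture amplitude scale), `ttr_amp` (scale of
#'   the tongue-tip-retraction gesture amplitudes, the inter-articulator
#'   coupling knob) and `ttr_shift` (relative timing shift of the TTR gestures,
#'   in normalized time).
#' @slot subject_sd SD of the subject-level random-curve amplitudes (px).
#' @slot rep_noise_sd SD of the within-subject repetition noise (px).
#' @slot seed integer RNG seed; a fixed seed makes the bundle bit-reproducible.
#' @export
setClass("CohortDesign",
  representation(n_subjects_per_group = "integer", n_repetitions = "integer",
                 n_frames_mean = "numeric", duration_jitter_sd = "numeric",
                 sites = "character", group_archetypes = "list",
                 subject_sd = "numeric", rep_noise_sd = "numeric",
                 seed = "integer")
)

setValidity("CohortDesign", function(object) {
  msg <- NULL
  if (object@n_repetitions < 1L) msg <- c(msg, "n_repetitions must be >= 1")
  if (any(object@n_subjects_per_group < 1L))
    msg <- c(msg, "subject counts must be positive")
  if (object@subject_sd < 0 || object@rep_noise_sd < 0 ||
      object@duration_jitter_sd < 0)
    msg <- c(msg, "all sd parameters must be >= 0")
  if (!identical(object@sites, .SITES))
    msg <- c(msg, "sites must be exactly the six canonical labels")
  if (!setequal(names(object@group_archetypes), names(object@n_subjects_per_group)))
    msg <- c(msg, "archetype names must match n_subjects_per_group names")
  grp <- vapply(object@group_archetypes, function(a) a$group, character(1))
  if (!all(grp %in% .GROUPS))
    msg <- c(msg, "archetype group labels must be 'AWS' or 'FS'")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "CohortDesign", function(object) {
  cat("CohortDesign:\n")
  for (nm in names(object@group_archetypes)) {
    a <- object@group_archetypes[[nm]]
    cat(sprintf("  %s (%s): %d subjects, amp %.2f, ttr_amp %.2f, ttr_shift %.2f\n",
                nm, a$group, object@n_subjects_per_group[[nm]], a$amp,
                a$ttr_amp, a$ttr_shift))
  }
  cat(sprintf("  %d reps/subject, %.0f +/- %.0f frames, subject sd %.2f, rep sd %.2f, seed %d\n",
              object@n_repetitions, object@n_frames_mean,
              object@duration_jitter_sd, object@subject_sd,
              object@rep_noise_sd, object@seed))
})

.archetype <- function(group, amp = 1, ttr_amp = 1, ttr_shift = 0) {
  list(group = group, amp = amp, ttr_amp = ttr_amp, ttr_shift = ttr_shift)
}

#' Default two-group archetypes
#'
#' Fluent speakers (FS) carry the reference gesture pattern; adults who
#' stutter (AWS) differ mainly in the coupling between tongue tip retraction
#' and the other articulators: attenuated TTR gesture amplitude and a small
#' relative timing shift.
#'
#' @return named list of archetype parameter lists.
#' @export
defaultArchetypes <- function() {
  list(FS  = .archetype("FS"),
       AWS = .archetype("AWS", ttr_amp = 0.65, ttr_shift = 0.06))
}

#' Construct a CohortDesign
#'
#' Defaults emulate the study conditions: 17 FS and 15 AWS subjects, up to
#' eight analyzed repetitions each, utterances of about 60 frames at 55
#' frames/s (~1.1 s pseudoword), with moderate between-subject and
#' within-subject variability.
#'
#' @param n_subjects_per_group named vector of subject counts, names matching
#'   `group_archetypes`.
#' @param n_repetitions repetitions per subject (the assembly step caps
#'   analyzed repetitions at 10).
#' @param n_frames_mean,duration_jitter_sd duration model (frames).
#' @param group_archetypes named list of archetypes, see [defaultArchetypes()].
#' @param subject_sd,rep_noise_sd variability scales in px.
#' @param seed integer RNG seed.
#' @return a [CohortDesign-class].
#' @export
#' @examples
#' d <- cohortDesign(n_subjects_per_group = c(FS = 3, AWS = 3), n_repetitions = 2)
#' bundle <- genTrajectories(d)
cohortDesign <- function(n_subjects_per_group = c(FS = 17, AWS = 15),
                         n_repetitions = 8,
                         n_frames_mean = 60,
                         duration_jitter_sd = 6,
                         group_archetypes = defaultArchetypes(),
                         subject_sd = 0.8,
                         rep_noise_sd = 0.5,
                         seed = 1L) {
  n_subjects_per_group <- unlist(n_subjects_per_group)  # tolerate YAML lists
  if (any(n_subjects_per_group <= 0) || n_repetitions <= 0)
    stop("configuration error: subject and repetition counts must be positive")
  counts <- as.integer(n_subjects_per_group)
  names(counts) <- names(n_subjects_per_group)
  new("CohortDesign",
      n_subjects_per_group = counts,
      n_repetitions = as.integer(n_repetitions),
      n_frames_mean = n_frames_mean,
      duration_jitter_sd = duration_jitter_sd,
      sites = .SITES,
      group_archetypes = group_archetypes,
      subject_sd = subject_sd,
      rep_noise_sd = rep_noise_sd,
      seed = as.integer(seed))
}

#' Three-archetype design for cluster-recovery studies
#'
#' Two fluent-speaker archetypes with weak and strong tongue-tip-retraction
#' coupling and one AWS archetype with intermediate coupling, mirroring the
#' cluster geometry the dissimilarity analysis is meant to resolve.
#'
#' @param n_per subjects per archetype.
#' @param seed RNG seed.
#' @return a [CohortDesign-class] with archetypes FS_hypo, FS_hyper, AWS_mid.
#' @export
threeGroupDesign <- function(n_per = c(FS_hypo = 6, FS_hyper = 6, AWS_mid = 6),
                             seed = 1L) {
  cohortDesign(
    n_subjects_per_group = n_per,
    n_repetitions = 6,
    n_frames_mean = 60,
    duration_jitter_sd = 4,
    group_archetypes = list(
      FS_hypo  = .archetype("FS", ttr_amp = 0.15),
      FS_hyper = .archetype("FS", ttr_amp = 1.85),
      AWS_mid  = .archetype("AWS", ttr_amp = 1.0, ttr_shift = 0.06)),
    subject_sd = 0.25,
    rep_noise_sd = 0.3,
    seed = seed)
}

# ---------------------------------------------------------------------------
# Gesture model
# ---------------------------------------------------------------------------

# Per-site base gestures: a baseline offset plus Gaussian bumps at
# phoneme-target times (normalized utterance time u in [0, 1]). Amplitudes in
# px, ranges chosen so curves fit the phantom's measurement-line geometry.
# Closure phonemes pull gap sites toward 0; alveolar closures extend the
# tongue tip (larger TTR).
.GESTURES <- list(
  "LA"     = list(offset = 9,  center = c(0.02, 0.50, 0.97),
                  width = c(0.05, 0.25, 0.05), amp = c(-3, 2, -8)),
  "TTR"    = list(offset = 16, center = c(0.06, 0.30, 0.55, 0.72, 0.92),
                  width = c(0.04, 0.06, 0.04, 0.04, 0.04),
                  amp = c(4, -3, 4, 4, 4)),
  "TT-TD"  = list(offset = 7,  center = c(0.06, 0.45, 0.55, 0.72, 0.92),
                  width = c(0.04, 0.08, 0.04, 0.04, 0.04),
                  amp = c(-6, 2, -6, -6, -6)),
  "TT-ARD" = list(offset = 8,  center = c(0.08, 0.45, 0.57, 0.74, 0.94),
                  width = c(0.04, 0.08, 0.04, 0.04, 0.04),
                  amp = c(-6, 1, -6, -6, -6)),
  "TB-PD1" = list(offset = 8,  center = c(0.02, 0.30, 0.60),
                  width = c(0.04, 0.06, 0.10), amp = c(-7, -3, 2)),
  "TB-PD2" = list(offset = 6,  center = c(0.05, 0.40, 0.85),
                  width = c(0.06, 0.10, 0.08), amp = c(-4, 1, -4))
)

.bumps <- function(u, center, width, amp) {
  y <- numeric(length(u))
  for (j in seq_along(center))
    y <- y + amp[j] * exp(-(u - center[j])^2 / (2 * width[j]^2))
  y
}

# Base gesture for one site under one archetype.
.baseGesture <- function(site, u, arch) {
  g <- .GESTURES[[site]]
  amp <- g$amp * arch$amp
  center <- g$center
  if (site == "TTR") {
    amp <- amp * arch$ttr_amp
    center <- center + arch$ttr_shift
  }
  g$offset + .bumps(u, center, g$width, amp)
}

# Smooth subject-level random curve: three Gaussian bumps with random
# amplitudes, fixed centers, scale `sd` (px).
.subjectCurve <- function(u, z) {
  .bumps(u, center = c(0.25, 0.5, 0.75), width = rep(0.15, 3), amp = z)
}

# Evaluate an expression with a locally seeded RNG, restoring global state.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# ---------------------------------------------------------------------------
# TrajectoryBundle
# ---------------------------------------------------------------------------

#' TrajectoryBundle: ground-truth synthetic trajectories
#'
#' @slot data long data.frame: subject, group, archetype, repetition, site,
#'   frame, width (px).
#' @slot durations data.frame: subject, group, archetype, repetition, duration
#'   (frames).
#' @slot design the generating [CohortDesign-class].
#' @export
setClass("TrajectoryBundle",
  representation(data = "data.frame", durations = "data.frame",
                 design = "CohortDesign")
)

setValidity("TrajectoryBundle", function(object) {
  msg <- NULL
  if (any(object@data$width < 0)) msg <- c(msg, "widths must be >= 0")
  if (!all(object@data$group %in% .GROUPS))
    msg <- c(msg, "group labels must be 'AWS' or 'FS'")
  if (any(object@durations$duration < 1))
    msg <- c(msg, "durations must be positive")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "TrajectoryBundle", function(object) {
  d <- object@durations
  cat(sprintf("TrajectoryBundle: %d subjects x %d reps, durations %d-%d frames\n",
              length(unique(d$subject)), max(d$repetition), min(d$duration),
              max(d$duration)))
})

#' Long trajectory table of a bundle
#' @param bundle a `TrajectoryBundle`
#' @return data.frame: subject, group, archetype, repetition, site, frame, width.
#' @export
bundleData <- function(bundle) bundle@data

#' Trial durations of a bundle
#' @param bundle a `TrajectoryBundle`
#' @return data.frame: subject, group, archetype, repetition, duration.
#' @export
bundleDurations <- function(bundle) bundle@durations

#' Generate synthetic articulator trajectories
#'
#' Each trajectory is a smooth base gesture (baseline offset plus Gaussian
#' bumps at phoneme-target times), modulated by the subject's group archetype
#' (amplitude and TTR-coupling parameters), plus a smooth subject-level random
#' curve and per-frame repetition noise, clipped at zero. Trial durations are
#' drawn around `n_frames_mean` (integer frames, floor 20).
#'
#' @param design a [CohortDesign-class].
#' @return a [TrajectoryBundle-class].
#' @export
#' @examples
#' b <- genTrajectories(cohortDesign(c(FS = 2, AWS = 2), n_repetitions = 2))
#' head(bundleData(b))
genTrajectories <- function(design) {
  stopifnot(is(design, "CohortDesign"))
  validObject(design)
  .withSeed(design@seed, {
    rows <- list(); durs <- list(); si <- 0L
    arch_names <- names(design@group_archetypes)
    for (an in arch_names) {
      arch <- design@group_archetypes[[an]]
      for (s in seq_len(design@n_subjects_per_group[[an]])) {
        si <- si + 1L
        subj <- sprintf("S%02d", si)
        # subject random-curve amplitudes, one triple per site
        z <- matrix(stats::rnorm(3 * length(.SITES), 0, design@subject_sd),
                    nrow = 3, dimnames = list(NULL, .SITES))
        for (r in seq_len(design@n_repetitions)) {
          L <- max(20L, as.integer(round(stats::rnorm(
            1, design@n_frames_mean, design@duration_jitter_sd))))
          u <- seq(0, 1, length.out = L)
          for (site in .SITES) {
            w <- .baseGesture(site, u, arch) + .subjectCurve(u, z[, site])
            if (design@rep_noise_sd > 0) {
              eps <- stats::rnorm(L, 0, design@rep_noise_sd)
              # light smoothing keeps repetition noise physiologically plausible
              eps <- stats::filter(eps, c(0.25, 0.5, 0.25), sides = 2)
              eps[is.na(eps)] <- 0
              w <- w + as.numeric(eps)
            }
            rows[[length(rows) + 1L]] <- data.frame(
              subject = subj, group = arch$group, archetype = an,
              repetition = r, site = site, frame = seq_len(L),
              width = pmax(w, 0))
          }
          durs[[length(durs) + 1L]] <- data.frame(
            subject = subj, group = arch$group, archetype = an,
            repetition = r, duration = L)
        }
      }
    }
    new("TrajectoryBundle",
        data = do.call(rbind, rows),
        durations = do.call(rbind, durs),
        design = design)
  })
}
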