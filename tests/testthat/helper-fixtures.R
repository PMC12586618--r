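# Shared fixtures and independent oracles.

# adjusted Rand index between two partitions (contingency-table form)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# long trajectory table for hand-specified curves: `curves` is a function
# (subject, group, repetition, site) -> numeric vector
makeLong <- function(subjects, groups, n_reps, curves) {
  do.call(rbind, lapply(seq_along(subjects), function(i)
    do.call(rbind, lapply(seq_len(n_reps), function(r)
      do.call(rbind, lapply(articulationSites(), function(s) {
        y <- curves(subjects[i], groups[i], r, s)
        data.frame(subject = subjects[i], group = groups[i], repetition = r,
                   site = s, frame = seq_along(y), width = y)
      }))))))
}

# hand-built single-trial bundle from a frames x 6-sites width matrix
makeBundle <- function(widths, subject = "S01", group = "FS") {
  sites <- articulationSites()
  stopifnot(identical(colnames(widths), sites))
  L <- nrow(widths)
  dat <- do.call(rbind, lapply(sites, function(s) data.frame(
    subject = subject, group = group, archetype = group, repetition = 1L,
    site = s, frame = seq_len(L), width = widths[, s])))
  new("TrajectoryBundle", data = dat,
      durations = data.frame(subject = subject, group = group,
                             archetype = group, repetition = 1L, duration = L),
      design = cohortDesign(c(FS = 1, AWS = 1)))
}

# default per-site widths that fit the phantom geometry comfortably
flatWidths <- function(L, la = 8, ttr = 16, gap = 6) {
  w <- cbind(LA = rep(la, L), TTR = rep(ttr, L), `TT-TD` = rep(gap, L),
             `TT-ARD` = rep(gap, L), `TB-PD1` = rep(gap, L),
             `TB-PD2` = rep(gap, L))
  colnames(w) <- articulationSites()
  w
}

# compare extracted widths against a phantom's ground-truth table
phantomErrors <- function(study, method = "raster") {
  tru <- phantomTruth(study)
  unlist(lapply(names(phantomSequences(study)), function(id) {
    s <- phantomSequences(study)[[id]]
    key <- strsplit(id, "_r")[[1]]
    t1 <- tru[tru$subject == key[1] & tru$repetition == as.integer(key[2]), ]
    ew <- extractWidths(s, study@grid, method = method)$widths
    m <- merge(ew, t1, by = c("site", "frame"))
    abs(m$width_px.x - m$width_px.y)
  }))
}

# noise-free FoSR fixture: truth drawn from the model's own P-spline span so
# the unpenalized fit must recover it exactly
fosrTruthFixture <- function(t_star = 40, n_basis = 10, seed = 2) {
  sm <- mgcv::smoothCon(mgcv::s(t, bs = "ps", k = n_basis, m = c(2, 2)),
                        data = data.frame(t = seq_len(t_star)))[[1]]
  set.seed(seed)
  beta0 <- as.numeric(sm$X %*% rnorm(n_basis))
  beta1 <- as.numeric(sm$X %*% rnorm(n_basis))
  subj <- sprintf("S%02d", 1:6)
  grp <- rep(c("FS", "AWS"), each = 3)
  long <- makeLong(subj, grp, 2, function(s, g, r, site)
    beta0 + (g == "AWS") * beta1)
  shift <- min(long$width) - 1
  long$width <- long$width - shift
  list(long = long, beta0 = beta0 - shift, beta1 = beta1)
}

# null / effect cohorts for the FoSR simulations: both groups share the FS
# gesture pattern unless ttr_amp_aws differs from 1
fosrSimDesign <- function(seed, n_per_group = 4, n_reps = 2, frames = 30,
                          ttr_amp_aws = 1, subject_sd = 0.5, rep_noise_sd = 0.5) {
  cohortDesign(
    n_subjects_per_group = c(FS = n_per_group, AWS = n_per_group),
    n_repetitions = n_reps, n_frames_mean = frames, duration_jitter_sd = 0,
    group_archetypes = list(
      FS  = list(group = "FS", amp = 1, ttr_amp = 1, ttr_shift = 0),
      AWS = list(group = "AWS", amp = 1, ttr_amp = ttr_amp_aws, ttr_shift = 0)),
    subject_sd = subject_sd, rep_noise_sd = rep_noise_sd, seed = seed)
}
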