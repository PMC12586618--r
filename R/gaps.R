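# Air/tissue segmentation of line profiles and gap tracking.
#
# Grey values are modelled as a constrained three-component Gaussian mixture
# (air dark < uncertain grey < matter light, means ordered by construction).
# The dark component sets the binarization threshold; air runs are tracked
# over frames by pixel overlap.

#' Fit a constrained three-component Gaussian mixture to grey values
#'
#' EM with an ordered-means constraint (components relabelled in ascending
#' mean order after every M-step), initialized at the 10/50/90 percentiles of
#' the data. Convergence is declared when the relative log-likelihood change
#' falls below `tol`. Component SDs are floored at a small fraction of the
#' data spread to keep degenerate profiles (e.g. exactly two grey levels)
#' well-defined; such fits are flagged, not fatal.
#'
#' @param values numeric grey values (>= 30 required, with nonzero spread).
#' @param seed RNG seed (the fit itself is deterministic; the seed is part of
#'   the interface so stochastic initialization variants stay reproducible).
#' @param max_iter maximum EM iterations.
#' @param tol relative log-likelihood convergence tolerance.
#' @return a [MixtureFit-class].
#' @export
#' @examples
#' v <- c(rnorm(200, 30, 8), rnorm(200, 110, 8), rnorm(200, 200, 8))
#' fitGmm3(v)
fitGmm3 <- function(values, seed = 1L, max_iter = 500L, tol = 1e-8) {
  values <- as.numeric(values[is.finite(values)])
  if (length(values) < 30L)
    stop("segmentation error: need at least 30 grey values to fit the mixture")
  if (stats::sd(values) < .Machine$double.eps^0.5)
    stop("segmentation error: grey values have no spread; set a manual threshold")
  flags <- character()

  mu <- as.numeric(stats::quantile(values, c(0.1, 0.5, 0.9), names = FALSE))
  if (any(diff(mu) <= 0)) mu <- mu + c(-1, 0, 1) * 1e-6 * max(1, diff(range(values)))
  sd_floor <- max(1e-3 * stats::sd(values), 1e-9)
  sg <- rep(max(stats::sd(values) / 3, sd_floor), 3)
  w <- rep(1 / 3, 3)

  n <- length(values)
  loglik <- -Inf; converged <- FALSE; it <- 0L
  for (it in seq_len(max_iter)) {
    # E-step in log space for stability
    lp <- vapply(1:3, function(k)
      log(w[k]) + stats::dnorm(values, mu[k], sg[k], log = TRUE),
      numeric(n))
    m <- apply(lp, 1, max)
    lse <- m + log(rowSums(exp(lp - m)))
    ll <- sum(lse)
    resp <- exp(lp - lse)
    # M-step with collapse guards
    nk <- colSums(resp)
    for (k in 1:3) {
      if (nk[k] > 1e-8 * n) {
        mu[k] <- sum(resp[, k] * values) / nk[k]
        sg[k] <- sqrt(sum(resp[, k] * (values - mu[k])^2) / nk[k])
      }
      sg[k] <- max(sg[k], sd_floor)
    }
    w <- pmax(nk / n, 0)
    w <- w / sum(w)
    # ordered-means constraint: relabel ascending
    o <- order(mu)
    mu <- mu[o]; sg <- sg[o]; w <- w[o]
    if (is.finite(loglik) && abs(ll - loglik) < tol * (abs(loglik) + 1e-12)) {
      loglik <- ll; converged <- TRUE; break
    }
    loglik <- ll
  }
  if (!converged) flags <- c(flags, "EM did not converge")
  if (min(w) < 1e-3)
    flags <- c(flags, sprintf("near-zero component weight (%.2g)", min(w)))
  # strict ordering for validity; collapsed means are separated infinitesimally
  eps <- 1e-9 * max(1, diff(range(values)))
  for (k in 2:3) if (mu[k] <= mu[k - 1]) {
    mu[k] <- mu[k - 1] + eps
    flags <- c(flags, "collapsed component means")
  }
  new("MixtureFit", weights = w, means = mu, sds = sg, loglik = loglik,
      n_iter = it, converged = converged, flags = unique(flags))
}

#' Binarization threshold from the dark mixture component
#'
#' The threshold is the smallest grey value above the dark-component mean at
#' which the weighted density of the dark component drops below the summed
#' weighted density of the other two components (posterior crossover). If no
#' crossover exists in range (e.g. the dark weight vanishes), the fallback
#' `dark mean + 3 * dark sd` is used and recorded in the `"fallback"`
#' attribute.
#'
#' @param fit a [MixtureFit-class].
#' @return numeric threshold (grey units), with attribute `fallback` (logical).
#'   Pixels strictly below it classify as air.
#' @export
thresholdFromDark <- function(fit) {
  stopifnot(is(fit, "MixtureFit"))
  w <- fit@weights; mu <- fit@means; sg <- fit@sds
  g <- function(x)
    w[1] * stats::dnorm(x, mu[1], sg[1]) -
      w[2] * stats::dnorm(x, mu[2], sg[2]) - w[3] * stats::dnorm(x, mu[3], sg[3])
  grid <- seq(mu[1], mu[3], length.out = 4096L)
  vals <- g(grid)
  below <- which(vals < 0)
  below <- below[below > 1L]
  if (!length(below) || vals[1] < 0) {
    thr <- mu[1] + 3 * sg[1]
    attr(thr, "fallback") <- TRUE
    return(thr)
  }
  i <- below[1]
  thr <- if (vals[i - 1] > 0)
    stats::uniroot(g, c(grid[i - 1], grid[i]), tol = 1e-10)$root
  else grid[i]
  attr(thr, "fallback") <- FALSE
  thr
}

#' Binarize a line profile into air and matter
#'
#' @param profile a [LineProfile-class] or numeric matrix.
#' @param threshold grey threshold; pixels strictly below it are air.
#' @return integer matrix of the profile's shape, 1 = air, 0 = matter.
#' @export
binarizeProfile <- function(profile, threshold) {
  vals <- if (is(profile, "LineProfile")) profile@values else profile
  m <- (vals < as.numeric(threshold)) + 0L
  storage.mode(m) <- "integer"
  m
}

# maximal runs of 1s in a binary vector -> data.frame(start, end, len)
.airRuns <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L
  data.frame(start = starts[keep], end = ends[keep], len = r$lengths[keep])
}

#' Track an articulator gap across frames by pixel overlap
#'
#' Per frame, candidate gaps are the maximal air runs. The retained gap is the
#' run with the largest pixel-index overlap with the previously retained gap
#' (ties: longer run, then smaller start index). If no run overlaps, the gap
#' is recorded as closed (width 0) and the last open gap is remembered; on
#' reopening, the run whose midpoint is nearest to the last open gap's
#' midpoint is taken. Manual overrides (frame -> run index) are applied from
#' the `overrides` table and logged.
#'
#' @param binary integer matrix (positions x frames), 1 = air.
#' @param init_run run index to retain at the first frame; default the longest
#'   run (ties: smaller start).
#' @param overrides data.frame with columns frame, run_index.
#' @param site site label stored on the result.
#' @param spacing mm per pixel.
#' @return a [GapTrajectory-class].
#' @export
trackGap <- function(binary, init_run = NULL, overrides = NULL, site = "gap",
                     spacing = 1.4) {
  stopifnot(is.matrix(binary), nrow(binary) > 0L)
  nf <- ncol(binary)
  width <- numeric(nf); start <- rep(NA_integer_, nf); end <- rep(NA_integer_, nf)
  olog <- list()
  last_open <- NULL   # c(start, end) of most recent open retained gap
  opened <- FALSE

  for (f in seq_len(nf)) {
    runs <- .airRuns(binary[, f])
    pick <- NA_integer_
    ov <- if (!is.null(overrides) && nrow(overrides))
      overrides[overrides$frame == f, , drop = FALSE] else NULL
    if (!is.null(ov) && nrow(ov)) {
      ri <- ov$run_index[1]
      if (is.na(ri) || ri < 1 || ri > nrow(runs))
        stop(sprintf("configuration error: override at frame %d names run %s but %d runs exist",
                     f, as.character(ri), nrow(runs)))
      pick <- ri
      olog[[length(olog) + 1L]] <- data.frame(frame = f,
        action = sprintf("forced run %d", ri))
    } else if (nrow(runs)) {
      if (!opened) {
        # first appearance: configured choice, else longest run / smaller start
        pick <- if (!is.null(init_run)) {
          if (init_run < 1 || init_run > nrow(runs))
            stop(sprintf("configuration error: init run %d but %d runs exist at frame %d",
                         init_run, nrow(runs), f))
          init_run
        } else order(-runs$len, runs$start)[1]
      } else if (!is.null(last_open)) {
        gap_px <- last_open[1]:last_open[2]
        overlap <- vapply(seq_len(nrow(runs)), function(i)
          length(intersect(runs$start[i]:runs$end[i], gap_px)), integer(1))
        if (max(overlap) > 0L) {
          pick <- order(-overlap, -runs$len, runs$start)[1]
        } else if (width[f - 1L] == 0) {
          # reopening after closure: nearest run midpoint to last open gap
          mid <- (last_open[1] + last_open[2]) / 2
          d <- abs((runs$start + runs$end) / 2 - mid)
          pick <- order(d, runs$start)[1]
        } # else: open gap lost all overlap -> record closed, carry state
      }
    }
    if (!is.na(pick)) {
      width[f] <- runs$len[pick]
      start[f] <- runs$start[pick]; end[f] <- runs$end[pick]
      last_open <- c(runs$start[pick], runs$end[pick])
      opened <- TRUE
    }
  }
  new("GapTrajectory", site = site, width_px = width, start = start, end = end,
      spacing = spacing,
      overrides = if (length(olog)) do.call(rbind, olog) else data.frame(),
      flags = character())
}

#' Measure tongue tip retraction on the 0-degree line
#'
#' TTR is the extension of the tongue from the baseline midpoint to the tongue
#' tip: the run of consecutive tissue pixels from position 1 (the line origin)
#' outward to the first tissue-to-air transition. An origin lying in air gives
#' 0 with a warning flag; a fully-tissue line saturates at the line length and
#' is flagged "no tip found".
#'
#' @param binary integer matrix (positions x frames), 1 = air.
#' @param spacing mm per pixel.
#' @return a [GapTrajectory-class] whose widths are TTR extensions.
#' @export
measureTTR <- function(binary, spacing = 1.4) {
  stopifnot(is.matrix(binary), nrow(binary) > 0L)
  nf <- ncol(binary); M <- nrow(binary)
  width <- numeric(nf); flags <- character()
  for (f in seq_len(nf)) {
    air <- which(binary[, f] == 1L)
    if (!length(air)) {
      width[f] <- M
      flags <- c(flags, sprintf("frame %d: no tip found (fully tissue)", f))
    } else if (air[1] == 1L) {
      width[f] <- 0
      flags <- c(flags, sprintf("frame %d: line origin lies in air", f))
    } else {
      width[f] <- air[1] - 1L
    }
  }
  if (any(grepl("origin lies in air", flags)))
    warning("TTR line origin lies in air in some frames; widths set to 0")
  start <- ifelse(width > 0, 1L, NA_integer_)
  end <- ifelse(width > 0, as.integer(width), NA_integer_)
  new("GapTrajectory", site = "TTR", width_px = width,
      start = as.integer(start), end = as.integer(end), spacing = spacing,
      overrides = data.frame(), flags = flags)
}

#' Extract all site widths from one image sequence
#'
#' Runs the full per-trial chain: profile extraction for each mapped line,
#' per-profile mixture fit, dark-component threshold (a forced threshold
#' override takes precedence), binarization, and gap tracking (TTR uses the
#' tissue-extension measure).
#'
#' @param seq an [ImageSequence-class].
#' @param grid a [ProfileGrid-class].
#' @param method profile sampling, "raster" (default; reads the raw grid
#'   pixels) or "bilinear".
#' @param overrides optional data.frame with columns site, frame, run_index
#'   and/or threshold (per-site forced threshold).
#' @param gmm_seed,gmm_tol,gmm_max_iter mixture-fit settings.
#' @return list with `widths` (long data.frame: site, frame, width_px,
#'   width_mm), `trajectories` (named list of [GapTrajectory-class]),
#'   `fits` (named list of [MixtureFit-class]) and `thresholds`.
#' @export
extractWidths <- function(seq, grid, method = "raster", overrides = NULL,
                          gmm_seed = 1L, gmm_tol = 1e-8, gmm_max_iter = 500L) {
  sites <- gridLines(grid)$site
  trajs <- list(); fits <- list(); thr <- numeric()
  for (s in sites) {
    prof <- extractProfile(seq, grid, s, method = method)
    ov_s <- if (!is.null(overrides) && nrow(overrides))
      overrides[overrides$site == s, , drop = FALSE] else NULL
    forced <- if (!is.null(ov_s) && "threshold" %in% names(ov_s) &&
                  any(!is.na(ov_s$threshold))) ov_s$threshold[!is.na(ov_s$threshold)][1]
              else NA_real_
    if (is.na(forced)) {
      fit <- fitGmm3(profileValues(prof), seed = gmm_seed, tol = gmm_tol,
                     max_iter = gmm_max_iter)
      fits[[s]] <- fit
      tau <- thresholdFromDark(fit)
    } else tau <- forced
    thr[s] <- as.numeric(tau)
    bin <- binarizeProfile(prof, tau)
    run_ov <- if (!is.null(ov_s) && "run_index" %in% names(ov_s))
      ov_s[!is.na(ov_s$run_index), c("frame", "run_index"), drop = FALSE] else NULL
    trajs[[s]] <- if (s == "TTR") measureTTR(bin, spacing = seq@spacing)
                  else trackGap(bin, overrides = run_ov, site = s,
                                spacing = seq@spacing)
  }
  widths <- do.call(rbind, lapply(sites, function(s) data.frame(
    site = s, frame = seq_along(widthPx(trajs[[s]])),
    width_px = widthPx(trajs[[s]]), width_mm = widthMm(trajs[[s]]))))
  list(widths = widths, trajectories = trajs, fits = fits, thresholds = thr)
}
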