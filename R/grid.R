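# Measurement-line grid construction and line-profile extraction.
#
# Coordinate convention: (row, col), 1-based, row increases downward (image
# convention). The 0-degree direction points from the baseline midpoint toward
# the anterior landmark; positive angles rotate clockwise as seen on screen.

.DEFAULT_ANGLES <- c("TTR" = 0, "TT-TD" = 7.5, "TT-ARD" = 15,
                     "TB-PD1" = 60, "TB-PD2" = 90)

# Rotate a (row, col) unit direction clockwise (on screen, row-down) by deg.
.rotateCW <- function(dir_rc, deg) {
  th <- deg * pi / 180
  x <- dir_rc[2]; y <- dir_rc[1]            # x = col (right), y = row (down)
  c(x * sin(th) + y * cos(th),              # row'
    x * cos(th) - y * sin(th))              # col'
}

#' Build the measurement-line grid from anatomical landmarks
#'
#' A baseline runs from the posterior landmark (upper frontal edge of cervical
#' vertebra 4) to the anterior landmark (incisor-palate transition). Five
#' lines of half the baseline length fan out clockwise from the baseline
#' midpoint at 0 (TTR), 7.5 (TT-TD), 15 (TT-ARD), 60 (TB-PD1) and 90 degrees
#' (TB-PD2); the lip-aperture (LA) line connects the upper and lower lip
#' centers. Extra angles (e.g. 30, 120, 150) are constructible but left
#' unmapped; the posterior baseline half can be added as an unmapped line.
#'
#' @param landmarks list with numeric(2) elements `posterior` and `anterior`,
#'   each (row, col).
#' @param lip_endpoints list with numeric(2) elements `upper` and `lower`
#'   (lip centers).
#' @param angles_deg named numeric, site -> clockwise angle in degrees;
#'   default maps the five angled sites.
#' @param extra_angles numeric, additional unmapped angles to construct.
#' @param include_posterior also construct the posterior baseline half
#'   (unmapped; it records head motion, not articulation).
#' @return a [ProfileGrid-class].
#' @export
#' @examples
#' g <- buildGrid(list(posterior = c(64, 90), anterior = c(64, 30)),
#'                list(upper = c(50, 22), lower = c(78, 22)))
#' gridLines(g)
buildGrid <- function(landmarks, lip_endpoints,
                      angles_deg = .DEFAULT_ANGLES,
                      extra_angles = numeric(),
                      include_posterior = FALSE) {
  post <- as.numeric(landmarks$posterior)
  ant <- as.numeric(landmarks$anterior)
  if (length(post) != 2L || length(ant) != 2L)
    stop("geometry error: landmarks must be (row, col) pairs")
  blen <- sqrt(sum((ant - post)^2))
  if (blen < .Machine$double.eps^0.5)
    stop("geometry error: coincident baseline landmarks")
  if (any(angles_deg < 0 | angles_deg >= 180))
    stop("geometry error: angles must lie in [0, 180)")
  mid <- (post + ant) / 2
  dir0 <- (ant - mid) / sqrt(sum((ant - mid)^2))

  mk <- function(site, ang, mapped) {
    d <- .rotateCW(dir0, ang)
    data.frame(site = site, angle_deg = ang, origin_r = mid[1],
               origin_c = mid[2], dir_r = d[1], dir_c = d[2],
               length_px = blen / 2, mapped = mapped)
  }
  rows <- mapply(mk, names(angles_deg), angles_deg,
                 MoreArgs = list(mapped = TRUE), SIMPLIFY = FALSE)
  for (a in extra_angles)
    rows[[length(rows) + 1L]] <- mk(sprintf("angle%g", a), a, FALSE)
  if (include_posterior)
    rows[[length(rows) + 1L]] <- mk("baseline-posterior", 180 - 1e-9, FALSE)

  up <- as.numeric(lip_endpoints$upper); lo <- as.numeric(lip_endpoints$lower)
  llen <- sqrt(sum((lo - up)^2))
  if (llen < .Machine$double.eps^0.5)
    stop("geometry error: coincident lip endpoints")
  ld <- (lo - up) / llen
  rows[[length(rows) + 1L]] <- data.frame(
    site = "LA", angle_deg = NA_real_, origin_r = up[1], origin_c = up[2],
    dir_r = ld[1], dir_c = ld[2], length_px = llen, mapped = TRUE)

  lines <- do.call(rbind, rows)
  rownames(lines) <- NULL
  new("ProfileGrid", baseline = rbind(posterior = post, anterior = ant),
      midpoint = mid, lines = lines)
}

#' Rebuild the grid for one trial from a per-trial landmark table
#'
#' Subjects may move their head between repetitions, so the grid is readjusted
#' per trial from landmarks placed on that trial's reference (first) frame.
#'
#' @param landmark_table data.frame with columns trial, point, row, col; point
#'   labels must include posterior, anterior, upper_lip, lower_lip.
#' @param trial trial identifier to look up.
#' @param ... passed to [buildGrid()].
#' @return a [ProfileGrid-class] for that trial.
#' @export
regridPerTrial <- function(landmark_table, trial, ...) {
  need <- c("trial", "point", "row", "col")
  if (!all(need %in% names(landmark_table)))
    stop("configuration error: landmark table needs columns trial, point, row, col")
  tab <- landmark_table[landmark_table$trial == trial, , drop = FALSE]
  pt <- function(name) {
    i <- match(name, tab$point)
    if (is.na(i))
      stop(sprintf("configuration error: no '%s' landmark for trial '%s'",
                   name, trial))
    c(tab$row[i], tab$col[i])
  }
  buildGrid(landmarks = list(posterior = pt("posterior"), anterior = pt("anterior")),
            lip_endpoints = list(upper = pt("upper_lip"), lower = pt("lower_lip")),
            ...)
}

# ---------------------------------------------------------------------------
# Sampling
# ---------------------------------------------------------------------------

# Continuous sample points at 1 px steps from origin outward (inclusive).
.linePoints <- function(origin, dir, length_px) {
  t <- 0:floor(length_px + 1e-9)
  cbind(r = origin[1] + t * dir[1], c = origin[2] + t * dir[2])
}

# Unique pixel chain of a line: nearest pixels at 1 px steps, consecutive
# duplicates collapsed (the raster reading: all pixels the line lies on).
.lineChain <- function(origin, dir, length_px) {
  pts <- round(.linePoints(origin, dir, length_px))
  keep <- c(TRUE, rowSums(abs(diff(pts))) > 0)
  pts[keep, , drop = FALSE]
}

# Bilinear interpolation of matrix `img` at continuous (row, col) points.
.bilinear <- function(img, pts) {
  nr <- nrow(img); nc <- ncol(img)
  r <- pts[, 1]; c <- pts[, 2]
  bad <- which(r < 1 | r > nr | c < 1 | c > nc)
  if (length(bad))
    stop(sprintf("geometry error: sample position %d at (%.2f, %.2f) outside image",
                 bad[1], r[bad[1]], c[bad[1]]))
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    img[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Extract a space-by-time line profile from an image sequence
#'
#' All positions of one measurement line are read in every frame, producing a
#' positions-by-frames intensity matrix. `"bilinear"` samples at exact 1 px
#' steps along the continuous line with bilinear interpolation; `"raster"`
#' reads the raw grid pixels the line lies on (nearest pixels, consecutive
#' duplicates collapsed), which reproduces painted pixel classes exactly.
#'
#' @param seq an [ImageSequence-class].
#' @param grid a [ProfileGrid-class].
#' @param site site label of the line to extract.
#' @param method "bilinear" (default) or "raster".
#' @return a [LineProfile-class].
#' @export
extractProfile <- function(seq, grid, site, method = c("bilinear", "raster")) {
  method <- match.arg(method)
  ln <- grid@lines[grid@lines$site == site, , drop = FALSE]
  if (nrow(ln) != 1L)
    stop(sprintf("geometry error: site '%s' not present in grid", site))
  origin <- c(ln$origin_r, ln$origin_c)
  dir <- c(ln$dir_r, ln$dir_c)
  fr <- seq@frames
  nf <- dim(fr)[3]
  if (method == "bilinear") {
    pts <- .linePoints(origin, dir, ln$length_px)
    vals <- vapply(seq_len(nf), function(f) .bilinear(fr[, , f], pts),
                   numeric(nrow(pts)))
  } else {
    px <- .lineChain(origin, dir, ln$length_px)
    if (any(px < 1) || any(px[, 1] > dim(fr)[1]) || any(px[, 2] > dim(fr)[2]))
      stop("geometry error: raster chain outside image")
    vals <- vapply(seq_len(nf), function(f) fr[, , f][px],
                   numeric(nrow(px)))
  }
  if (nf == 1L) vals <- matrix(vals, ncol = 1L)
  new("LineProfile", site = site, values = vals, spacing = seq@spacing,
      method = method)
}
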