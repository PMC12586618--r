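#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

.SITES <- c("LA", "TTR", "TT-TD", "TT-ARD", "TB-PD1", "TB-PD2")
.GROUPS <- c("AWS", "FS")

#' Canonical articulation-site labels
#'
#' The six measurement sites: lip aperture (LA), tongue tip retraction (TTR),
#' tongue tip-to-teeth (TT-TD), tongue tip-to-alveolar-ridge (TT-ARD) and the
#' two tongue body-to-palate distances (TB-PD1, TB-PD2).
#'
#' @return Character vector of the six site labels.
#' @export
#' @examples
#' articulationSites()
articulationSites <- function() .SITES

# ---------------------------------------------------------------------------
# ImageSequence: one utterance repetition as a grey-value frame stack
# ---------------------------------------------------------------------------

#' ImageSequence: a grey-value midsagittal frame stack
#'
#' One utterance repetition: an array of frames with pixel spacing (mm/px)
#' and frame rate (frames/s).
#'
#' @slot frames numeric array, rows x cols x frames.
#' @slot spacing numeric(1), mm per pixel (isotropic in-plane).
#' @slot fps numeric(1), frames per second.
#' @export
setClass("ImageSequence",
  representation(frames = "array", spacing = "numeric", fps = "numeric"),
  prototype(spacing = 1.4, fps = 55)
)

setValidity("ImageSequence", function(object) {
  msg <- NULL
  if (length(dim(object@frames)) != 3L)
    msg <- c(msg, "'frames' must be a rows x cols x frames array")
  if (length(object@spacing) != 1L || object@spacing <= 0)
    msg <- c(msg, "'spacing' must be a single positive number")
  if (length(object@fps) != 1L || object@fps <= 0)
    msg <- c(msg, "'fps' must be a single positive number")
  if (is.null(msg)) TRUE else msg
})

#' Construct an ImageSequence
#'
#' @param frames numeric array (rows x cols x frames).
#' @param spacing mm per pixel, default 1.4.
#' @param fps frames per second, default 55.
#' @return An [ImageSequence-class] object.
#' @export
ImageSequence <- function(frames, spacing = 1.4, fps = 55) {
  new("ImageSequence", frames = frames, spacing = spacing, fps = fps)
}

#' @describeIn ImageSequence-class number of frames
#' @param x,object an `ImageSequence`
#' @export
setMethod("length", "ImageSequence", function(x) dim(x@frames)[3L])

setMethod("show", "ImageSequence", function(object) {
  d <- dim(object@frames)
  cat(sprintf("ImageSequence: %d x %d px, %d frames, %.2f mm/px, %.1f fps\n",
              d[1], d[2], d[3], object@spacing, object@fps))
})

#' Frame array of an ImageSequence
#' @param x an `ImageSequence`
#' @return numeric array rows x cols x frames.
#' @export
frames <- function(x) x@frames

#' Pixel spacing in mm
#' @param x an `ImageSequence` or `LineProfile`
#' @return numeric(1), mm per pixel.
#' @export
pixelSpacing <- function(x) x@spacing

# ---------------------------------------------------------------------------
# ProfileGrid
# ---------------------------------------------------------------------------

#' ProfileGrid: anatomical measurement-line grid
#'
#' The grid is anchored on a baseline from a posterior landmark (upper frontal
#' edge of cervical vertebra 4) to an anterior landmark (incisor-palate
#' transition). Five half-baseline-length lines fan out clockwise from the
#' baseline midpoint, and a sixth line connects the upper and lower lip
#' centers. Coordinates are (row, col), 1-based, row increasing downward;
#' positive angles rotate clockwise on screen.
#'
#' @slot baseline 2x2 matrix, rows = posterior/anterior landmark, cols = (row, col).
#' @slot midpoint numeric(2), baseline midpoint (row, col).
#' @slot lines data.frame with columns site, angle_deg, origin_r, origin_c,
#'   dir_r, dir_c, length_px, mapped.
#' @export
setClass("ProfileGrid",
  representation(baseline = "matrix", midpoint = "numeric", lines = "data.frame")
)

setValidity("ProfileGrid", function(object) {
  msg <- NULL
  ln <- object@lines
  need <- c("site", "angle_deg", "origin_r", "origin_c", "dir_r", "dir_c",
            "length_px", "mapped")
  if (!all(need %in% names(ln)))
    msg <- c(msg, "grid 'lines' table is missing columns")
  else {
    mapped <- ln$site[ln$mapped]
    if (!setequal(mapped, .SITES))
      msg <- c(msg, "mapped sites must be exactly the six canonical site labels")
    nrm <- sqrt(ln$dir_r^2 + ln$dir_c^2)
    if (any(abs(nrm - 1) > 1e-8))
      msg <- c(msg, "line directions must be unit vectors")
    blen <- sqrt(sum((object@baseline[1, ] - object@baseline[2, ])^2))
    ang <- ln$mapped & ln$site != "LA"
    if (any(abs(ln$length_px[ang] - blen / 2) > 1e-8))
      msg <- c(msg, "angled lines must have length = half the baseline length")
  }
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "ProfileGrid", function(object) {
  blen <- sqrt(sum((object@baseline[1, ] - object@baseline[2, ])^2))
  cat(sprintf("ProfileGrid: baseline %.1f px, midpoint (%.1f, %.1f)\n",
              blen, object@midpoint[1], object@midpoint[2]))
  print(object@lines[, c("site", "angle_deg", "length_px", "mapped")],
        row.names = FALSE)
})

#' Measurement-line table of a grid
#' @param grid a `ProfileGrid`
#' @param mapped_only keep only lines mapped to the six sites (default TRUE).
#' @return data.frame of line definitions.
#' @export
gridLines <- function(grid, mapped_only = TRUE) {
  ln <- grid@lines
  if (mapped_only) ln[ln$mapped, , drop = FALSE] else ln
}

# ---------------------------------------------------------------------------
# LineProfile
# ---------------------------------------------------------------------------

#' LineProfile: space-by-time intensity profile of one measurement line
#'
#' @slot site site label.
#' @slot values numeric matrix, rows = positions along the line, cols = frames.
#' @slot spacing mm per pixel.
#' @slot method sampling method used ("bilinear" or "raster").
#' @export
setClass("LineProfile",
  representation(site = "character", values = "matrix", spacing = "numeric",
                 method = "character")
)

setValidity("LineProfile", function(object) {
  msg <- NULL
  if (!is.numeric(object@values)) msg <- c(msg, "'values' must be numeric")
  if (!object@method %in% c("bilinear", "raster"))
    msg <- c(msg, "'method' must be 'bilinear' or 'raster'")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "LineProfile", function(object) {
  cat(sprintf("LineProfile [%s]: %d positions x %d frames (%s sampling)\n",
              object@site, nrow(object@values), ncol(object@values),
              object@method))
})

#' Intensity matrix of a line profile
#' @param x a `LineProfile`
#' @return numeric matrix positions x frames.
#' @export
profileValues <- function(x) x@values

# ---------------------------------------------------------------------------
# MixtureFit
# ---------------------------------------------------------------------------

#' MixtureFit: constrained three-component Gaussian mixture fit
#'
#' Components are ordered by mean: air (dark) < uncertain (grey) < matter
#' (light).
#'
#' @slot weights,means,sds numeric(3) per component.
#' @slot loglik final log-likelihood.
#' @slot n_iter EM iterations used.
#' @slot converged logical flag.
#' @slot flags character log of anomalies (near-zero weights etc.).
#' @export
setClass("MixtureFit",
  representation(weights = "numeric", means = "numeric", sds = "numeric",
                 loglik = "numeric", n_iter = "integer", converged = "logical",
                 flags = "character")
)

setValidity("MixtureFit", function(object) {
  msg <- NULL
  if (length(object@weights) != 3L || any(object@weights < 0) ||
      abs(sum(object@weights) - 1) > 1e-6)
    msg <- c(msg, "weights must be 3 nonnegative values summing to 1")
  if (length(object@means) != 3L || any(diff(object@means) <= 0))
    msg <- c(msg, "means must be 3 strictly increasing values")
  if (length(object@sds) != 3L || any(object@sds <= 0))
    msg <- c(msg, "sds must be 3 positive values")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "MixtureFit", function(object) {
  cat("Constrained 3-component Gaussian mixture fit\n")
  cat(sprintf("  means: %s\n", paste(sprintf("%.2f", object@means), collapse = ", ")))
  cat(sprintf("  sds:   %s\n", paste(sprintf("%.2f", object@sds), collapse = ", ")))
  cat(sprintf("  weights: %s\n", paste(sprintf("%.3f", object@weights), collapse = ", ")))
  cat(sprintf("  logLik %.2f after %d iterations (%s)\n", object@loglik,
              object@n_iter, if (object@converged) "converged" else "NOT converged"))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})

#' Component parameters of a mixture fit
#' @param fit a `MixtureFit`
#' @return data.frame with weight, mean, sd per component.
#' @export
mixtureComponents <- function(fit) {
  data.frame(component = c("air", "uncertain", "matter"),
             weight = fit@weights, mean = fit@means, sd = fit@sds)
}

# ---------------------------------------------------------------------------
# GapTrajectory
# ---------------------------------------------------------------------------

#' GapTrajectory: per-frame articulator gap width for one site
#'
#' For gap sites the width is the length of the tracked air run; for TTR it is
#' the tongue-tip extension (tissue run from the baseline midpoint outward).
#'
#' @slot site site label.
#' @slot width_px numeric, gap width (or TTR extension) per frame in pixels.
#' @slot start,end integer run bounds per frame (NA where width is 0).
#' @slot spacing mm per pixel, for mm conversion.
#' @slot overrides data.frame log of manual overrides applied (frame, action).
#' @slot flags character log of warnings ("no tip found" etc.).
#' @export
setClass("GapTrajectory",
  representation(site = "character", width_px = "numeric", start = "integer",
                 end = "integer", spacing = "numeric", overrides = "data.frame",
                 flags = "character"),
  prototype(spacing = 1.4, overrides = data.frame(), flags = character())
)

setValidity("GapTrajectory", function(object) {
  msg <- NULL
  if (any(object@width_px < 0)) msg <- c(msg, "widths must be >= 0")
  if (length(object@start) != length(object@width_px) ||
      length(object@end) != length(object@width_px))
    msg <- c(msg, "start/end must match the frame count")
  open <- which(object@width_px > 0)
  if (any(object@start[open] > object@end[open], na.rm = TRUE))
    msg <- c(msg, "start must be <= end where width > 0")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "GapTrajectory", function(object) {
  cat(sprintf("GapTrajectory [%s]: %d frames, width %.1f-%.1f px (%.2f-%.2f mm)\n",
              object@site, length(object@width_px), min(object@width_px),
              max(object@width_px), min(object@width_px) * object@spacing,
              max(object@width_px) * object@spacing))
  if (nrow(object@overrides)) cat("  overrides applied:", nrow(object@overrides), "\n")
  if (length(object@flags)) cat("  flags:", paste(unique(object@flags), collapse = "; "), "\n")
})

#' Gap widths in pixels
#' @param x a `GapTrajectory`
#' @return numeric vector, one width per frame.
#' @export
widthPx <- function(x) x@width_px

#' Gap widths in millimetres
#' @param x a `GapTrajectory`
#' @param spacing mm per pixel; defaults to the trajectory's own spacing.
#' @return numeric vector of widths in mm.
#' @export
widthMm <- function(x, spacing = NULL) {
  x@width_px * (if (is.null(spacing)) x@spacing else spacing)
}

# ---------------------------------------------------------------------------
# TrajectorySet (SummarizedExperiment subclass)
# ---------------------------------------------------------------------------

#' TrajectorySet: analysis-ready time-normalized trajectories
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' whose single assay `"width"` holds one column per (subject, group,
#' repetition, site) unit and one row per normalized time frame (all columns
#' share the cohort-median length T*). Column metadata carries subject, group,
#' repetition and site; `metadata()` carries the exclusion log and T*.
#'
#' @export
setClass("TrajectorySet", contains = "SummarizedExperiment")

setValidity("TrajectorySet", function(object) {
  msg <- NULL
  cd <- colData(object)
  need <- c("subject", "group", "repetition", "site")
  if (!all(need %in% names(cd)))
    msg <- c(msg, "colData must contain subject, group, repetition, site")
  else {
    if (!all(cd$group %in% .GROUPS))
      msg <- c(msg, "group labels must be 'AWS' or 'FS'")
    if (!all(cd$site %in% .SITES))
      msg <- c(msg, "site labels must be canonical")
    reps <- unique(as.data.frame(cd)[, c("subject", "repetition")])
    if (any(table(reps$subject) > 10))
      msg <- c(msg, "at most 10 repetitions per subject")
  }
  if (!"width" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'width' is required")
  if (is.null(msg)) TRUE else msg
})

#' Construct a TrajectorySet
#'
#' @param widths numeric matrix, rows = T* frames, cols = trajectory units.
#' @param index data.frame with one row per column of `widths`: subject,
#'   group, repetition, site (optionally archetype).
#' @param exclusions data.frame log of excluded trials/subjects.
#' @return a [TrajectorySet-class].
#' @export
TrajectorySet <- function(widths, index, exclusions = data.frame()) {
  se <- SummarizedExperiment(assays = list(width = widths),
                             colData = DataFrame(index))
  ts <- new("TrajectorySet", se)
  metadata(ts)$t_star <- nrow(widths)
  metadata(ts)$exclusions <- exclusions
  ts
}

setMethod("show", "TrajectorySet", function(object) {
  cd <- as.data.frame(colData(object))
  cat(sprintf("TrajectorySet: T* = %d frames, %d trajectory units\n",
              nrow(object), ncol(object)))
  cat(sprintf("  %d subjects (%s), %d sites\n",
              length(unique(cd$subject)),
              paste(sprintf("%s: %d", names(table(unique(cd[, c("subject", "group")])$group)),
                            table(unique(cd[, c("subject", "group")])$group)), collapse = ", "),
              length(unique(cd$site))))
  ex <- metadata(object)$exclusions
  if (!is.null(ex) && nrow(ex)) cat(sprintf("  %d exclusions logged\n", nrow(ex)))
})

#' Common normalized length T*
#' @param ts a `TrajectorySet`
#' @return integer, the median frame count all trajectories share.
#' @export
tStar <- function(ts) nrow(ts)

#' Trajectory matrix (frames x units)
#' @param ts a `TrajectorySet`
#' @return numeric matrix.
#' @export
trajMatrix <- function(ts) assay(ts, "width")

#' Trajectory index (one row per unit)
#' @param ts a `TrajectorySet`
#' @return data.frame with subject, group, repetition, site.
#' @export
trajIndex <- function(ts) as.data.frame(colData(ts))

#' Exclusion log of a TrajectorySet
#' @param ts a `TrajectorySet`
#' @return data.frame of logged exclusions.
#' @export
exclusionLog <- function(ts) metadata(ts)$exclusions

# ---------------------------------------------------------------------------
# FosrFit
# ---------------------------------------------------------------------------

#' FosrFit: penalized function-on-scalar regression fit for one site
#'
#' Model: y_ij(t) = beta0(t) + x_i beta1(t) + b_i(t) + eps_ij(t), with
#' x_i = 1 for AWS and 0 for the reference group (FS), so beta1(t) is the
#' group-difference curve and its test is a test for a difference in the mean
#' course.
#'
#' @slot site site label.
#' @slot model the underlying `mgcv::gam` fit.
#' @slot beta0,beta1 numeric curves of length T*.
#' @slot edf named numeric, effective degrees of freedom per smooth term.
#' @slot p_group Wald p-value of the group-difference term.
#' @slot reference reference group label.
#' @slot t_star normalized length.
#' @export
setClass("FosrFit",
  representation(site = "character", model = "ANY", beta0 = "numeric",
                 beta1 = "numeric", edf = "numeric", p_group = "numeric",
                 reference = "character", t_star = "integer")
)

setMethod("show", "FosrFit", function(object) {
  cat(sprintf("FosrFit [%s]: T* = %d, reference group %s\n",
              object@site, object@t_star, object@reference))
  cat(sprintf("  edf: %s\n",
              paste(sprintf("%s = %.1f", names(object@edf), object@edf), collapse = ", ")))
  cat(sprintf("  group-effect Wald p = %.4g\n", object@p_group))
})

# ---------------------------------------------------------------------------
# ClusterResult
# ---------------------------------------------------------------------------

#' ClusterResult: subject clustering report
#'
#' @slot dist symmetric subject distance matrix (energy distances).
#' @slot linkage linkage used ("ward" or "complete").
#' @slot tree the `stats::hclust` merge tree.
#' @slot k chosen number of clusters.
#' @slot labels integer cluster labels per subject.
#' @slot cindex_curve named numeric, C-index per candidate k.
#' @slot contingency cluster x group table.
#' @slot fisher_p Fisher exact p for cluster/group independence.
#' @slot allocation list: per-subject flags, overall fraction, majorities.
#' @export
setClass("ClusterResult",
  representation(dist = "matrix", linkage = "character", tree = "ANY",
                 k = "integer", labels = "integer", cindex_curve = "numeric",
                 contingency = "table", fisher_p = "numeric",
                 allocation = "list")
)

setValidity("ClusterResult", function(object) {
  msg <- NULL
  D <- object@dist
  if (!isSymmetric(unname(D), tol = 1e-8) || any(abs(diag(D)) > 1e-12))
    msg <- c(msg, "distance matrix must be symmetric with zero diagonal")
  if (length(object@labels) && (any(object@labels < 1) ||
      any(object@labels > object@k)))
    msg <- c(msg, "labels must lie in 1..k")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: %d subjects, %s linkage, k* = %d\n",
              nrow(object@dist), object@linkage, object@k))
  cat(sprintf("  C-index per k: %s\n",
              paste(sprintf("%s: %.3f", names(object@cindex_curve),
                            object@cindex_curve), collapse = ", ")))
  cat("  cluster x group table:\n")
  print(object@contingency)
  cat(sprintf("  Fisher exact p = %.4g; correctly allocated fraction = %.3f\n",
              object@fisher_p, object@allocation$fraction))
})

#' Cluster labels of a ClusterResult
#' @param x a `ClusterResult`
#' @return named integer vector of cluster labels.
#' @export
clusterLabels <- function(x) x@labels

#' Chosen cluster count of a ClusterResult
#' @param x a `ClusterResult`
#' @return integer k*.
#' @export
selectedK <- function(x) x@k
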