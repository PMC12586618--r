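# Synthetic midsagittal phantom renderer. Frames are painted in three tissue
# classes (air dark, uncertain grey, matter light); the air gaps along each
# measurement line realize a TrajectoryBundle's widths, giving pixel-exact
# ground truth for the segmentation chain.

#' PhantomSpec: rendering parameters for the synthetic phantom
#'
#' @slot size integer(2), image rows and cols.
#' @slot spacing mm per pixel.
#' @slot grey_means numeric(3), class means for (air, uncertain, matter);
#'   must be strictly increasing.
#' @slot grey_sds numeric(3), per-class grey SDs (default 0).
#' @slot noise_sd additive Gaussian noise SD in grey units.
#' @slot fps frames per second (metadata only).
#' @slot landmarks list of (row, col) points: posterior (cervical vertebra),
#'   anterior (incisor-palate transition), upper_lip, lower_lip.
#' @export
setClass("PhantomSpec",
  representation(size = "integer", spacing = "numeric", grey_means = "numeric",
                 grey_sds = "numeric", noise_sd = "numeric", fps = "numeric",
                 landmarks = "list")
)

setValidity("PhantomSpec", function(object) {
  msg <- NULL
  if (any(diff(object@grey_means) <= 0))
    msg <- c(msg, "grey means must be strictly increasing (air < uncertain < matter)")
  if (any(object@grey_sds < 0) || object@noise_sd < 0)
    msg <- c(msg, "grey sds and noise_sd must be >= 0")
  for (nm in c("posterior", "anterior", "upper_lip", "lower_lip")) {
    p <- object@landmarks[[nm]]
    if (is.null(p) || any(p < 1) || p[1] > object@size[1] || p[2] > object@size[2])
      msg <- c(msg, sprintf("landmark '%s' missing or outside image", nm))
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a PhantomSpec
#'
#' Defaults emulate the acquisition geometry: 128 x 128 px at 1.4 mm/px,
#' 55 frames/s, with air/uncertain/matter grey means 30/110/200.
#'
#' @param size image size (rows, cols).
#' @param spacing mm per pixel.
#' @param grey_means,grey_sds class grey-value means and SDs.
#' @param noise_sd additive Gaussian noise SD (grey units).
#' @param fps frames per second.
#' @param landmarks list of (row, col) anatomical points; see
#'   [PhantomSpec-class].
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(size = c(128L, 128L), spacing = 1.4,
                        grey_means = c(30, 110, 200), grey_sds = c(0, 0, 0),
                        noise_sd = 0, fps = acquisitionTiming()$fps,
                        landmarks = list(posterior = c(80, 96),
                                         anterior = c(80, 36),
                                         upper_lip = c(66, 26),
                                         lower_lip = c(92, 26))) {
  new("PhantomSpec", size = as.integer(size), spacing = spacing,
      grey_means = grey_means, grey_sds = grey_sds, noise_sd = noise_sd,
      fps = fps, landmarks = landmarks)
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d x %d px, %.2f mm/px, classes (%s), noise sd %.1f\n",
              object@size[1], object@size[2], object@spacing,
              paste(object@grey_means, collapse = "/"), object@noise_sd))
})

#' Grid implied by a phantom specification
#' @param spec a `PhantomSpec`
#' @return the [ProfileGrid-class] built from the phantom's landmarks.
#' @export
phantomGrid <- function(spec) {
  buildGrid(landmarks = list(posterior = spec@landmarks$posterior,
                             anterior = spec@landmarks$anterior),
            lip_endpoints = list(upper = spec@landmarks$upper_lip,
                                 lower = spec@landmarks$lower_lip))
}

#' PhantomStudy: rendered phantom sequences with ground truth
#'
#' @slot sequences named list of [ImageSequence-class], one per trial
#'   ("subject_rep").
#' @slot truth data.frame: subject, group, repetition, site, frame, width_px
#'   (the realized integer widths painted into the frames).
#' @slot grid the [ProfileGrid-class] used for painting.
#' @slot spec the [PhantomSpec-class].
#' @export
setClass("PhantomStudy",
  representation(sequences = "list", truth = "data.frame",
                 grid = "ProfileGrid", spec = "PhantomSpec")
)

setMethod("show", "PhantomStudy", function(object) {
  cat(sprintf("PhantomStudy: %d trials, %d ground-truth rows\n",
              length(object@sequences), nrow(object@truth)))
})

#' Rendered trial sequences
#' @param x a `PhantomStudy`
#' @return named list of `ImageSequence` objects.
#' @export
phantomSequences <- function(x) x@sequences

#' Ground-truth gap table
#' @param x a `PhantomStudy`
#' @return data.frame: subject, group, repetition, site, frame, width_px.
#' @export
phantomTruth <- function(x) x@truth

# Tissue pixels kept between the grid origin and any gap, so the line fan
# stays unambiguous where neighbouring lines share pixels.
.MIN_TONGUE_PX <- 12L
.PALATE_PX <- 4L

# class codes
.AIR <- 1L; .UNC <- 2L; .TIS <- 3L

# Per-line class vector along the pixel chain for one frame.
.chainClasses <- function(site, w, M, where) {
  cls <- rep(.TIS, M)
  if (site == "TTR") {
    ttr <- as.integer(round(w))
    if (ttr > M)
      stop(sprintf("geometry error: TTR %d px exceeds line length %d (%s)",
                   ttr, M, where))
    if (ttr < M) cls[(ttr + 1L):M] <- .AIR
  } else if (site == "LA") {
    wi <- as.integer(round(w))
    if (wi > M - 2L)
      stop(sprintf("geometry error: LA gap %d px exceeds lip line capacity %d (%s)",
                   wi, M - 2L, where))
    if (wi > 0L) {
      start <- (M - wi) %/% 2L + 1L
      cls[start:(start + wi - 1L)] <- .AIR
    }
  } else {
    wi <- as.integer(round(w))
    p <- M - .PALATE_PX + 1L                 # first palate pixel
    if (wi > p - 1L - .MIN_TONGUE_PX)
      stop(sprintf("geometry error: %s gap %d px exceeds line capacity %d (%s)",
                   site, wi, p - 1L - .MIN_TONGUE_PX, where))
    if (wi > 0L) cls[(p - wi):(p - 1L)] <- .AIR
  }
  cls
}

#' Render a synthetic phantom image study from a trajectory bundle
#'
#' Each frame shows a tissue head region with an uncertain-grey band on an air
#' background; along every measurement line the painted air runs equal the
#' bundle's (rounded) widths for that frame, so the returned ground-truth
#' table is pixel-exact. Pixel values are the class means, plus per-class
#' Gaussian spread (`grey_sds`) and additive Gaussian noise (`noise_sd`).
#' Lines are painted posterior-to-anterior with the TTR (0 degree) line last,
#' so each line owns its pixels where the near-origin fan overlaps.
#'
#' @param bundle a [TrajectoryBundle-class].
#' @param spec a [PhantomSpec-class].
#' @param seed RNG seed for the noise draws.
#' @return a [PhantomStudy-class].
#' @export
renderPhantom <- function(bundle, spec = phantomSpec(), seed = 1L) {
  stopifnot(is(bundle, "TrajectoryBundle"), is(spec, "PhantomSpec"))
  validObject(spec)
  grid <- phantomGrid(spec)
  nr <- spec@size[1]; nc <- spec@size[2]

  # static anatomy: air background, elliptic head tissue, grey band (spine)
  base <- matrix(.AIR, nr, nc)
  rc <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  inside <- ((rc$r - 78) / 48)^2 + ((rc$c - 60) / 40)^2 <= 1
  base[cbind(rc$r[inside], rc$c[inside])] <- .TIS
  band_c <- intersect(110:122, seq_len(nc))
  if (length(band_c)) base[intersect(20:108, seq_len(nr)), band_c] <- .UNC

  paint_order <- c("TB-PD1", "TB-PD2", "LA", "TT-ARD", "TT-TD", "TTR")
  ln <- gridLines(grid)
  chains <- lapply(paint_order, function(s) {
    li <- ln[ln$site == s, ]
    px <- .lineChain(c(li$origin_r, li$origin_c), c(li$dir_r, li$dir_c),
                     li$length_px)
    if (any(px < 1) || any(px[, 1] > nr) || any(px[, 2] > nc))
      stop(sprintf("geometry error: line %s leaves the image", s))
    (px[, 2] - 1L) * nr + px[, 1]            # linear indices
  })
  names(chains) <- paint_order

  dat <- bundle@data
  trials <- unique(dat[, c("subject", "group", "repetition")])
  .withSeed(seed, {
    sequences <- list(); truth <- list()
    for (i in seq_len(nrow(trials))) {
      tr <- trials[i, ]
      sel <- dat$subject == tr$subject & dat$repetition == tr$repetition
      tdat <- dat[sel, ]
      L <- max(tdat$frame)
      arr <- array(0, dim = c(nr, nc, L))
      wmat <- matrix(NA_real_, L, length(paint_order),
                     dimnames = list(NULL, paint_order))
      for (s in paint_order)
        wmat[, s] <- tdat$width[tdat$site == s][order(tdat$frame[tdat$site == s])]
      for (f in seq_len(L)) {
        cls <- base
        for (s in paint_order) {
          M <- length(chains[[s]])
          where <- sprintf("subject %s rep %d frame %d", tr$subject,
                           tr$repetition, f)
          cc <- .chainClasses(s, wmat[f, s], M, where)
          cls[chains[[s]]] <- cc
          wmat[f, s] <- round(wmat[f, s])    # realized integer truth
        }
        img <- spec@grey_means[cls]
        if (any(spec@grey_sds > 0))
          img <- img + stats::rnorm(length(img), 0, spec@grey_sds[cls])
        if (spec@noise_sd > 0)
          img <- img + stats::rnorm(length(img), 0, spec@noise_sd)
        arr[, , f] <- img
      }
      id <- sprintf("%s_r%d", tr$subject, tr$repetition)
      sequences[[id]] <- ImageSequence(arr, spacing = spec@spacing,
                                       fps = spec@fps)
      truth[[id]] <- data.frame(
        subject = tr$subject, group = tr$group, repetition = tr$repetition,
        site = rep(paint_order, each = L), frame = rep(seq_len(L),
        times = length(paint_order)), width_px = as.vector(wmat))
    }
    new("PhantomStudy", sequences = sequences,
        truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
        grid = grid, spec = spec)
  })
}
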