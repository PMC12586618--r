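#' artikin: articulatory kinematics from real-time vocal-tract MRI
#'
#' Extraction of articulator gap-width trajectories from midsagittal
#' grey-value image sequences (landmark grid, line profiles, constrained
#' Gaussian-mixture air/tissue segmentation, overlap gap tracking), duration
#' normalization, penalized function-on-scalar regression of movement curves
#' on group, and energy-distance hierarchical clustering of speakers by
#' inter-articulator spatiotemporal dissimilarities, with a synthetic
#' vocal-tract phantom generator for ground-truth validation. See the
#' methods vignette for the model and the design choices.
#'
#' @keywords internal
"_PACKAGE"

#' Acquisition timing arithmetic
#'
#' Radial FLASH acquisition: the time per image is the number of spokes times
#' the repetition time; the frame rate is 1000 / (ms per image), rounded to
#' whole frames per second. The defaults (9 spokes at TR 2.02 ms) give
#' 18.18 ms per image, i.e. 55 frames/s.
#'
#' @param tr_ms repetition time in milliseconds.
#' @param n_spokes radial spokes per image.
#' @return list with `ms_per_image` and `fps`.
#' @export
#' @examples
#' acquisitionTiming()
acquisitionTiming <- function(tr_ms = 2.02, n_spokes = 9) {
  ms <- n_spokes * tr_ms
  list(ms_per_image = ms, fps = round(1000 / ms))
}
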