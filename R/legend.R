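#' Tissue label legend
#'
#' Fixed mapping from tissue compartment name to the integer code used in
#' face labels and label rasters. Code 0 is reserved for background. The
#' mitral valve is represented as a thin flat disk compartment, mirroring
#' anatomical models that include valves as planar structures.
#'
#' @return named integer vector of tissue codes.
#' @export
#' @examples
#' tissue_legend()
tissue_legend <- function() {
  c(background = 0L, lv_pool = 1L, lv_myo = 2L, la = 3L, rv = 4L,
    ra = 5L, aorta = 6L, valve = 7L)
}

# Default gray level per tissue code for the pseudo-ultrasound intensity
# proxy: blood pools dark, myocardium bright, background zero.
default_gray_levels <- function() {
  c(background = 0, lv_pool = 0.10, lv_myo = 0.70, la = 0.12, rv = 0.12,
    ra = 0.12, aorta = 0.15, valve = 0.55)
}
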