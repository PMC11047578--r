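#' Unit converters
#'
#' The package uses SI units (m, s, Pa, m^3/s) inside the solver and
#' clinically conventional units at the user surface: lengths and radii in mm,
#' areas in mm^2, flows in ml/s, pressures in Pa with mmHg converters.
#' One mmHg is 133.322387415 Pa.
#'
#' @param x numeric vector to convert.
#' @return converted numeric vector.
#' @examples
#' mmHg_to_Pa(85)      # 11332.4
#' Pa_to_mmHg(11332.4) # 85
#' @name units
NULL

MMHG <- 133.322387415

#' @rdname units
#' @export
mmHg_to_Pa <- function(x) x * MMHG

#' @rdname units
#' @export
Pa_to_mmHg <- function(x) x / MMHG

#' @rdname units
#' @export
ml_to_m3 <- function(x) x * 1e-6

#' @rdname units
#' @export
m3_to_ml <- function(x) x * 1e6

#' @rdname units
#' @export
mm_to_m <- function(x) x * 1e-3

#' @rdname units
#' @export
m_to_mm <- function(x) x * 1e3

#' @rdname units
#' @export
mm2_to_m2 <- function(x) x * 1e-6

#' @rdname units
#' @export
m2_to_mm2 <- function(x) x * 1e6
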