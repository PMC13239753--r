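#' Body surface area by the Du Bois formula
#'
#' Computes body surface area (m^2) from height and weight using the classical
#' Du Bois & Du Bois formula, `0.007184 * weight^0.425 * height^0.725`, the
#' form recommended by current echocardiography guidelines for ratiometric
#' indexation.
#'
#' @param height_cm Height in centimetres. Vectorised.
#' @param weight_kg Weight in kilograms. Vectorised.
#'
#' @return Numeric vector of body surface areas in m^2.
#'
#' @examples
#' bsa_dubois(180, 75) # 1.942
#' @export
bsa_dubois <- function(height_cm, weight_kg) {
  check_positive(height_cm, "height_cm")
  check_positive(weight_kg, "weight_kg")
  0.007184 * weight_kg^0.425 * height_cm^0.725
}

#' Body mass index
#'
#' @param height_cm Height in centimetres. Vectorised.
#' @param weight_kg Weight in kilograms. Vectorised.
#'
#' @return Numeric vector of BMI values in kg/m^2.
#'
#' @examples
#' compute_bmi(170, 57.8) # 20
#' @export
compute_bmi <- function(height_cm, weight_kg) {
  check_positive(height_cm, "height_cm")
  weight_kg / (height_cm / 100)^2
}

#' Ratiometric BSA indexation
#'
#' Divides a measured dimension (mm) by body surface area (m^2), the
#' guideline isometric-scaling approach that the allometric correction is
#' compared against.
#'
#' @param yu Measured (uncorrected) dimension in mm.
#' @param bsa Body surface area in m^2.
#'
#' @return Numeric vector, mm/m^2.
#' @export
index_bsa <- function(yu, bsa) {
  check_positive(bsa, "bsa")
  yu / bsa
}

#' Allometric correction ratio
#'
#' The corrected value Yc is the ratio of the measured dimension Yu to the
#' model-predicted dimension Yp; it is dimensionless and centred near 1 in
#' the population the model was fitted to.
#'
#' @param yu Measured (uncorrected) dimension in mm.
#' @param yp Model-predicted dimension in mm.
#'
#' @return Numeric vector of dimensionless ratios.
#' @export
correct_yc <- function(yu, yp) {
  check_positive(yp, "yp")
  yu / yp
}

check_positive <- function(x, name) {
  if (length(x) == 0 || anyNA(x) || any(x <= 0)) {
    abort(sprintf("`%s` must be positive and non-missing.", name))
  }
  invisible(x)
}
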