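#' Body mass from BMI under geometric similarity
#'
#' Inverts the BMI definition (BMI = mass / stature^2) to obtain body mass
#' for a crew member of given stature.  With a fixed BMI across a stature
#' range this encodes the geometric-similarity assumption: mass scales
#' exactly with stature squared.
#'
#' @param stature Standing height in metres.
#' @param bmi Body mass index in kg/m^2.
#' @return Body mass in kg (unrounded).
#' @examples
#' body_mass_from_bmi(1.70, 26.5)  # 76.585 kg
#' @export
body_mass_from_bmi <- function(stature, bmi) {
  check_positive(stature, "stature")
  check_positive(bmi, "bmi")
  bmi * stature^2
}

#' Du Bois body surface area
#'
#' Classical Du Bois & Du Bois formula,
#' \deqn{BSA = 0.007184 \cdot H^{0.725} \cdot M^{0.425}}
#' with height \eqn{H} in centimetres and mass \eqn{M} in kg.  Note that the
#' formula is sometimes misquoted with height in metres; only the
#' centimetre form yields surface areas in the physiological 1.5--2.5 m^2
#' range, and that form is used here.
#'
#' @param stature Standing height in metres (converted to cm internally).
#' @param body_mass Body mass in kg.
#' @return Body surface area in m^2.
#' @examples
#' bsa_dubois(1.70, 76.585)  # ~1.88 m^2
#' @export
bsa_dubois <- function(stature, body_mass) {
  check_positive(stature, "stature")
  check_positive(body_mass, "body_mass")
  0.007184 * (stature * 100)^0.725 * body_mass^0.425
}

#' Absolute aerobic capacity from relative VO2max
#'
#' @param body_mass Body mass in kg.
#' @param vo2max_rel Relative maximal oxygen uptake in mL/kg/min.
#' @return Absolute VO2max in L/min.
#' @examples
#' vo2max_absolute(76.585, 43.4)  # ~3.32 L/min
#' @export
vo2max_absolute <- function(body_mass, vo2max_rel) {
  check_positive(body_mass, "body_mass")
  check_positive(vo2max_rel, "vo2max_rel")
  body_mass * vo2max_rel / 1000
}

#' Construct a crew member
#'
#' Bundles one astronaut's anthropometric and physiological parameters and
#' derives body mass (from BMI and stature), Du Bois body surface area and
#' absolute VO2max.  Defaults encode the reference all-male astronaut
#' population: age 40 y, BMI 26.5 kg/m^2, VO2max 43.4 mL/kg/min, resting VO2
#' 3.3 mL/kg/min, respiratory exchange ratios 0.788 (rest) and 0.898
#' (exercise at 75\% VO2max).
#'
#' @param stature Standing height in metres; must lie in (1.0, 2.5).
#' @param age Age in years.
#' @param bmi Body mass index, kg/m^2.
#' @param vo2max_rel Relative VO2max, mL/kg/min.
#' @param vo2_rest_rel Resting VO2, mL/kg/min.
#' @param rer_rest Resting respiratory exchange ratio, in [0.6, 1.0].
#' @param rer_exercise Exercising respiratory exchange ratio, in [0.6, 1.2].
#' @return An object of class `crew_member`: a list with the input fields
#'   plus `body_mass` (kg), `bsa` (m^2) and `vo2max_abs` (L/min).
#' @examples
#' m <- crew_member(1.70)
#' m$body_mass  # 76.585
#' @export
crew_member <- function(stature,
                        age = DEFAULT_AGE,
                        bmi = DEFAULT_BMI,
                        vo2max_rel = DEFAULT_VO2MAX_REL,
                        vo2_rest_rel = DEFAULT_VO2_REST_REL,
                        rer_rest = DEFAULT_RER_REST,
                        rer_exercise = DEFAULT_RER_EXERCISE) {
  check_positive(stature, "stature")
  if (stature <= 1.0 || stature >= 2.5) {
    stop_domain("stature", "must lie strictly between 1.0 and 2.5 m")
  }
  if (!is.numeric(age) || age <= 0 || age >= 120) {
    stop_domain("age", "must lie strictly between 0 and 120 years")
  }
  check_positive(bmi, "bmi")
  if (rer_rest < 0.6 || rer_rest > 1.0) {
    stop_domain("rer_rest", "must lie in [0.6, 1.0]")
  }
  if (rer_exercise < 0.6 || rer_exercise > 1.2) {
    stop_domain("rer_exercise", "must lie in [0.6, 1.2]")
  }
  body_mass <- body_mass_from_bmi(stature, bmi)
  structure(
    list(
      stature = stature,
      age = age,
      bmi = bmi,
      vo2max_rel = vo2max_rel,
      vo2_rest_rel = vo2_rest_rel,
      rer_rest = rer_rest,
      rer_exercise = rer_exercise,
      body_mass = body_mass,
      bsa = bsa_dubois(stature, body_mass),
      vo2max_abs = vo2max_absolute(body_mass, vo2max_rel)
    ),
    class = "crew_member"
  )
}

#' @export
print.crew_member <- function(x, ...) {
  cat(sprintf(
    "<crew_member> stature %.2f m, age %g y, BMI %.1f kg/m^2\n",
    x$stature, x$age, x$bmi
  ))
  cat(sprintf(
    "  body mass %.1f kg, BSA %.2f m^2, VO2max %.2f L/min\n",
    x$body_mass, x$bsa, x$vo2max_abs
  ))
  invisible(x)
}

is_crew_member <- function(x) inherits(x, "crew_member")
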